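#' Detect fluorescence puncta within a dendrite mask
#'
#' Thresholds a single-channel image inside a dendrite mask, labels
#' connected components (8-connectivity), filters them by pixel area, and
#' reports intensity-weighted centroids ordered along the dendrite. This is
#' the automated equivalent of thresholding PSD-95-like puncta by intensity
#' and outlining them as regions of interest on dendrite portions.
#'
#' Threshold methods: `"otsu"` computes Otsu's threshold from the intensity
#' histogram of the masked pixels (parameter-free, invariant to positive
#' rescaling); `"ksd"` uses `median + k_sd * MAD` of the masked pixels as an
#' absolute background + k*SD rule.
#'
#' @param image numeric matrix, or a `puncta_image` from
#'   [gen_puncta_image()] (its image, mask and geometry are used).
#' @param dendrite_mask logical matrix of the same shape; pixels eligible
#'   for detection. Required unless `image` is a `puncta_image`.
#' @param threshold_method `"otsu"` or `"ksd"`.
#' @param k_sd multiplier for the `"ksd"` rule.
#' @param min_area_px,max_area_px component area limits (px), inclusive.
#' @param px_size_um pixel size, for um coordinates.
#' @param dendrite_length_um dendrite length for density computations.
#' @param channel channel name carried into the result.
#' @return list of class `puncta_set`: `channel`, `puncta` (data.frame
#'   `id`, `x_px`, `y_px`, `pos_um`, `area_px`, `intensity`; 0-based pixel
#'   coordinates, um = (px + 0.5) * px_size_um), `dendrite_length_um`,
#'   `threshold`.
#' @export
detect_puncta <- function(image, dendrite_mask = NULL,
                          threshold_method = c("otsu", "ksd"), k_sd = 4,
                          min_area_px = 4, max_area_px = 200,
                          px_size_um = 0.1, dendrite_length_um = NULL,
                          channel = "PSD95") {
  threshold_method <- match.arg(threshold_method)
  if (inherits(image, "puncta_image")) {
    if (is.null(dendrite_mask)) dendrite_mask <- image$mask
    if (is.null(dendrite_length_um)) dendrite_length_um <- image$dendrite_length_um
    px_size_um <- image$spec$px_size_um
    channel <- image$spec$channel
    image <- image$image
  }
  stopifnot(is.matrix(image))
  if (is.null(dendrite_mask))
    stop("dendrite_mask is required (missing dendrite annotation)")
  stopifnot(identical(dim(dendrite_mask), dim(image)))
  if (!any(dendrite_mask))
    stop("dendrite_mask is empty (missing dendrite annotation)")
  if (is.null(dendrite_length_um))
    dendrite_length_um <- ncol(image) * px_size_um

  vals <- image[dendrite_mask]
  if (max(vals) - min(vals) < .Machine$double.eps * max(abs(vals), 1)) {
    warning("masked image is constant (all-saturated or empty field)")
    return(new_puncta_set(channel, empty_puncta(), dendrite_length_um,
                           Inf, px_size_um))
  }

  thr <- switch(threshold_method,
    otsu = {
      rg <- range(vals)
      img1 <- EBImage::Image(matrix((vals - rg[1]) / diff(rg), ncol = 1))
      EBImage::otsu(img1, range = c(0, 1)) * diff(rg) + rg[1]
    },
    ksd = stats::median(vals) + k_sd * stats::mad(vals))

  bin <- (image > thr) & dendrite_mask
  # split touching puncta at intensity saddles deeper than the noise scale;
  # spots without a distinct local maximum (e.g. 1 px apart) stay merged
  h <- matrix(0, nrow(image), ncol(image))
  h[bin] <- image[bin] - thr
  tol <- max(3 * stats::mad(vals), 0.01 * max(h))
  lab <- EBImage::watershed(EBImage::Image(h), tolerance = tol, ext = 1)
  lab <- as.integer(lab)  # component label per pixel, 0 = background
  keep <- lab > 0L
  if (!any(keep))
    return(new_puncta_set(channel, empty_puncta(), dendrite_length_um,
                           thr, px_size_um))

  bg <- stats::median(vals)
  nr <- nrow(image)
  pix <- which(keep)
  lb <- lab[pix]
  wgt <- pmax(image[pix] - bg, 0)
  rowp <- (pix - 1L) %% nr        # 0-based row
  colp <- (pix - 1L) %/% nr       # 0-based col
  area <- tabulate(lb)
  ids <- which(area >= min_area_px & area <= max_area_px)
  if (!length(ids))
    return(new_puncta_set(channel, empty_puncta(), dendrite_length_um,
                           thr, px_size_um))

  sw  <- rowsum(wgt, lb)[, 1]
  swx <- rowsum(wgt * colp, lb)[, 1]
  swy <- rowsum(wgt * rowp, lb)[, 1]
  lev <- as.integer(rownames(rowsum(wgt, lb)))
  m <- match(ids, lev)
  cx <- swx[m] / sw[m]
  cy <- swy[m] / sw[m]
  puncta <- data.frame(id = seq_along(ids),
                       x_px = cx, y_px = cy,
                       pos_um = (cx + 0.5) * px_size_um,
                       area_px = area[ids],
                       intensity = sw[m])
  puncta <- puncta[order(puncta$x_px), , drop = FALSE]
  puncta$id <- seq_len(nrow(puncta))
  rownames(puncta) <- NULL
  new_puncta_set(channel, puncta, dendrite_length_um, thr, px_size_um)
}

empty_puncta <- function() {
  data.frame(id = integer(), x_px = numeric(), y_px = numeric(),
             pos_um = numeric(), area_px = integer(), intensity = numeric())
}

new_puncta_set <- function(channel, puncta, dendrite_length_um, threshold,
                           px_size_um = 0.1) {
  structure(list(channel = channel, puncta = puncta,
                 dendrite_length_um = dendrite_length_um,
                 threshold = threshold, px_size_um = px_size_um),
            class = "puncta_set")
}

#' @export
print.puncta_set <- function(x, ...) {
  cat(sprintf("<puncta_set> %s: %d puncta on %.1f um (%.3f/um)\n",
              x$channel, nrow(x$puncta), x$dendrite_length_um,
              puncta_density(x)))
  invisible(x)
}

#' Puncta density per micrometer of dendrite
#'
#' @param ps a `puncta_set` from [detect_puncta()].
#' @return puncta count divided by dendrite length (puncta/um).
#' @examples
#' # 24 puncta on a 25-um segment -> 0.96/um
#' @export
puncta_density <- function(ps) {
  stopifnot(inherits(ps, "puncta_set"))
  check_scalar(ps$dendrite_length_um, "dendrite_length_um", positive = TRUE)
  nrow(ps$puncta) / ps$dendrite_length_um
}

#' Colocalize two puncta sets by greedy nearest-pair matching
#'
#' Matches puncta of `setA` to puncta of `setB` within `max_dist_um`
#' (Euclidean, um), greedily by ascending distance, each punctum used at
#' most once. Unmatched A-puncta are the "A without B" population, e.g.
#' GFP protrusions lacking a PSD-95 punctum.
#'
#' @param setA,setB `puncta_set` objects from the same registered frame.
#' @param max_dist_um maximum match distance (um, >= 0).
#' @return list with `matches` (data.frame `id_a`, `id_b`, `dist_um`),
#'   `unmatched_a`, `unmatched_b` (ids), and `frac_a_unmatched`.
#' @export
colocalize <- function(setA, setB, max_dist_um = 0.5) {
  stopifnot(inherits(setA, "puncta_set"), inherits(setB, "puncta_set"))
  if (max_dist_um < 0) stop("max_dist_um must be >= 0")
  a <- setA$puncta; b <- setB$puncta
  pxum <- setA$px_size_um
  if (nrow(a) == 0L || nrow(b) == 0L) {
    return(list(matches = data.frame(id_a = integer(), id_b = integer(),
                                     dist_um = numeric()),
                unmatched_a = a$id, unmatched_b = b$id,
                frac_a_unmatched = if (nrow(a)) 1 else NA_real_))
  }
  d <- sqrt(outer(a$x_px, b$x_px, `-`)^2 + outer(a$y_px, b$y_px, `-`)^2) * pxum
  cand <- which(d <= max_dist_um, arr.ind = TRUE)
  ord <- order(d[cand])
  cand <- cand[ord, , drop = FALSE]
  used_a <- logical(nrow(a)); used_b <- logical(nrow(b))
  ia <- integer(0); ib <- integer(0); dd <- numeric(0)
  for (r in seq_len(nrow(cand))) {
    i <- cand[r, 1]; j <- cand[r, 2]
    if (!used_a[i] && !used_b[j]) {
      used_a[i] <- TRUE; used_b[j] <- TRUE
      ia <- c(ia, i); ib <- c(ib, j); dd <- c(dd, d[i, j])
    }
  }
  list(matches = data.frame(id_a = a$id[ia], id_b = b$id[ib], dist_um = dd),
       unmatched_a = a$id[!used_a], unmatched_b = b$id[!used_b],
       frac_a_unmatched = mean(!used_a))
}

#' Normalized density change between conditions
#'
#' Divides each treated density by the control mean and reports the percent
#' decrease of the normalized mean, the convention used when puncta
#' densities are expressed relative to an untreated control.
#'
#' @param treated,control numeric vectors of densities (or any positive
#'   summary values); `control` must be non-empty with positive mean.
#' @return list with `normalized` (treated / mean(control)), `norm_mean`,
#'   `norm_sem` and `percent_decrease` = 100 * (1 - norm_mean).
#' @examples
#' density_change(c(0.79, 0.74), c(0.96, 0.97))
#' @export
density_change <- function(treated, control) {
  if (!length(control) || mean(control) <= 0)
    stop("control must be non-empty with positive mean")
  norm <- treated / mean(control)
  list(normalized = norm, norm_mean = mean(norm), norm_sem = sem(norm),
       percent_decrease = 100 * (1 - mean(norm)))
}
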