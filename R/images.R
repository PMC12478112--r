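#' Synthetic fluorescence image specification
#'
#' Describes the emulated confocal acquisition used by [gen_puncta_image()]:
#' image shape in pixels, pixel size, the isotropic Gaussian point-spread
#' approximation, spot amplitude, camera background and additive white
#' Gaussian readout noise. The default 64 x 250 px frame at 0.1 um/px holds a
#' 25-um dendrite segment along its middle row.
#'
#' @param shape_px c(rows, cols) image size in pixels.
#' @param px_size_um pixel size (um/px).
#' @param psf_sigma_px Gaussian spot SD (px).
#' @param amplitude peak intensity of a punctum above background (a.u.).
#' @param background constant background level (a.u.).
#' @param noise_sd additive Gaussian noise SD (a.u.).
#' @param channel channel name.
#' @return list of class `image_spec`.
#' @export
image_spec <- function(shape_px = c(64L, 250L), px_size_um = 0.1,
                       psf_sigma_px = 1.5, amplitude = 1000,
                       background = 100, noise_sd = 10, channel = "PSD95") {
  stopifnot(length(shape_px) == 2L, all(shape_px >= 1))
  check_scalar(px_size_um, "px_size_um", positive = TRUE)
  check_scalar(psf_sigma_px, "psf_sigma_px", positive = TRUE)
  check_scalar(amplitude, "amplitude", nonneg = TRUE)
  check_scalar(background, "background", nonneg = TRUE)
  check_scalar(noise_sd, "noise_sd", nonneg = TRUE)
  structure(list(shape_px = as.integer(shape_px), px_size_um = px_size_um,
                 psf_sigma_px = psf_sigma_px, amplitude = amplitude,
                 background = background, noise_sd = noise_sd,
                 channel = channel),
            class = "image_spec")
}

#' Render a synthetic puncta image with ground truth
#'
#' Lays a straight dendrite along the middle row of the frame and renders
#' each punctum as an isotropic Gaussian spot of amplitude
#' `spec$amplitude` on a constant background, plus white Gaussian noise.
#' Input is either a [spine_map()] (one punctum per spine at its arclength
#' position) or a puncta density in puncta/um (positions drawn uniformly
#' along the dendrite). Ground truth lists every centroid in 0-based pixel
#' coordinates and in um; puncta whose centroid falls outside the frame are
#' clipped to the border and flagged.
#'
#' Coordinate convention: a punctum at `pos_um` is centered at 0-based
#' column `pos_um / px_size_um - 0.5`, so `um = (px + 0.5) * px_size_um`
#' (pixel-center convention).
#'
#' @param x a [spine_map()] or a single number (puncta per um).
#' @param spec an [image_spec()].
#' @param seed integer RNG seed.
#' @param y_jitter_px SD of the puncta offset from the dendrite axis (px).
#' @param min_sep_um hard-core minimum separation between density-placed
#'   puncta (um); emulates the physical exclusion between spine heads.
#'   Ignored when `x` is a spine map (map positions are used as-is).
#' @return list of class `puncta_image` with elements `image` (matrix),
#'   `truth` (data.frame: `id`, `x_px`, `y_px`, `pos_um`, `amplitude`,
#'   `clipped`), `mask` (logical matrix, the dendrite strip),
#'   `dendrite_length_um` and `spec`.
#' @export
gen_puncta_image <- function(x, spec = image_spec(), seed, y_jitter_px = 2,
                             min_sep_um = 0.6) {
  stopifnot(inherits(spec, "image_spec"))
  set.seed(as.integer(seed))
  nr <- spec$shape_px[1]; nc <- spec$shape_px[2]
  len_um <- nc * spec$px_size_um
  mid <- (nr + 1) / 2

  if (inherits(x, "spine_map")) {
    pos_um <- x$pos_um
    len_um <- min(len_um, attr(x, "length_um"))
  } else {
    check_scalar(x, "density", nonneg = TRUE)
    n <- round(x * len_um)
    pos_um <- numeric(0)
    tries <- 0L
    while (length(pos_um) < n && tries < 200L * max(n, 1L)) {
      p <- stats::runif(1, 0, len_um)
      if (!length(pos_um) || min(abs(pos_um - p)) >= min_sep_um)
        pos_um <- c(pos_um, p)
      tries <- tries + 1L
    }
    if (length(pos_um) < n)
      warning("could not place all puncta at the requested separation")
  }
  n <- length(pos_um)
  xc <- pos_um / spec$px_size_um - 0.5           # 0-based column coordinate
  yc <- rep(mid - 1, n) + if (n) stats::rnorm(n, 0, y_jitter_px) else numeric(0)

  clipped <- xc < 0 | xc > nc - 1 | yc < 0 | yc > nr - 1
  xc <- pmin(pmax(xc, 0), nc - 1)
  yc <- pmin(pmax(yc, 0), nr - 1)

  img <- matrix(spec$background, nr, nc)
  s2 <- 2 * spec$psf_sigma_px^2
  w <- ceiling(4 * spec$psf_sigma_px)
  for (i in seq_len(n)) {
    ci <- round(xc[i]) + 1L; ri <- round(yc[i]) + 1L
    cols <- max(1L, ci - w):min(nc, ci + w)
    rows <- max(1L, ri - w):min(nr, ri + w)
    dx2 <- ((cols - 1) - xc[i])^2
    dy2 <- ((rows - 1) - yc[i])^2
    img[rows, cols] <- img[rows, cols] +
      spec$amplitude * exp(-outer(dy2, dx2, `+`) / s2)
  }
  if (spec$noise_sd > 0)
    img <- img + matrix(stats::rnorm(nr * nc, 0, spec$noise_sd), nr, nc)

  strip <- ceiling(1 / spec$px_size_um)  # dendrite strip half-width: 1 um
  mask <- matrix(FALSE, nr, nc)
  mask[max(1, round(mid) - strip - 2 * y_jitter_px):
         min(nr, round(mid) + strip + 2 * y_jitter_px), ] <- TRUE

  truth <- data.frame(id = seq_len(n),
                      x_px = xc, y_px = yc,
                      pos_um = (xc + 0.5) * spec$px_size_um,
                      amplitude = rep(spec$amplitude, n),
                      clipped = clipped)
  structure(list(image = img, truth = truth, mask = mask,
                 dendrite_length_um = len_um, spec = spec),
            class = "puncta_image")
}

#' @export
print.puncta_image <- function(x, ...) {
  cat(sprintf("<puncta_image> %dx%d px, %d puncta on %.1f um dendrite\n",
              nrow(x$image), ncol(x$image), nrow(x$truth),
              x$dendrite_length_um))
  invisible(x)
}
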