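#' Track spines across two timepoints
#'
#' Matches spines of the t0 map to spines of the t3h map one-to-one by
#' nearest arclength position, greedily by ascending distance within
#' `match_tol_um`; ties are broken toward the lower spine ID. Unmatched t0
#' spines are labelled pruned; unmatched t3h spines are reported separately
#' as new and excluded from fate statistics.
#'
#' @param map_t0,map_t3h [spine_map()] objects on the same dendrite frame.
#' @param match_tol_um maximum displacement for a match (um).
#' @return data.frame with `spine_id` (t0), `fate` (`"maintained"` /
#'   `"pruned"`), `matched_id` (t3h id or NA); attribute `new_spines`
#'   holds unmatched t3h ids.
#' @export
track_spines <- function(map_t0, map_t3h, match_tol_um = 0.5) {
  stopifnot(inherits(map_t0, "spine_map"), inherits(map_t3h, "spine_map"))
  n0 <- nrow(map_t0); n3 <- nrow(map_t3h)
  matched0 <- rep(NA_character_, n0)
  used3 <- logical(n3)
  if (n0 && n3) {
    d <- abs(outer(map_t0$pos_um, map_t3h$pos_um, `-`))
    cand <- which(d <= match_tol_um, arr.ind = TRUE)
    if (nrow(cand)) {
      # ascending distance, ties by lower t0 then t3h spine id
      ord <- order(d[cand], map_t0$spine_id[cand[, 1]],
                   map_t3h$spine_id[cand[, 2]])
      cand <- cand[ord, , drop = FALSE]
      for (r in seq_len(nrow(cand))) {
        i <- cand[r, 1]; j <- cand[r, 2]
        if (is.na(matched0[i]) && !used3[j]) {
          matched0[i] <- map_t3h$spine_id[j]
          used3[j] <- TRUE
        }
      }
    }
  }
  out <- data.frame(spine_id = map_t0$spine_id,
                    fate = ifelse(is.na(matched0), "pruned", "maintained"),
                    matched_id = matched0,
                    stringsAsFactors = FALSE)
  attr(out, "new_spines") <- map_t3h$spine_id[!used3]
  out
}

#' Synaptotagmin-uptake intensity at a spine position
#'
#' Mean intensity in a circular region of interest around the spine,
#' background-subtracted and clamped at zero (negative estimates are
#' flagged). The ROI is centered at the spine's arclength position on the
#' dendrite axis row of the image.
#'
#' @param pos_um spine arclength position (um).
#' @param uptake_image numeric matrix.
#' @param px_size_um pixel size (um/px).
#' @param roi_radius_um ROI radius (um, > 0).
#' @param background background level to subtract; default the image median.
#' @param center_row 1-based image row of the dendrite axis; default middle.
#' @return single activity value (a.u., >= 0) with attribute `clamped`.
#' @export
uptake_intensity <- function(pos_um, uptake_image, px_size_um = 0.1,
                             roi_radius_um = 0.5, background = NULL,
                             center_row = NULL) {
  check_scalar(roi_radius_um, "roi_radius_um", positive = TRUE)
  stopifnot(is.matrix(uptake_image))
  nr <- nrow(uptake_image); nc <- ncol(uptake_image)
  if (is.null(center_row)) center_row <- round((nr + 1) / 2)
  if (is.null(background)) background <- stats::median(uptake_image)
  cx <- pos_um / px_size_um - 0.5          # 0-based col
  cy <- center_row - 1                     # 0-based row
  if (cx < 0 || cx > nc - 1) stop("spine position outside image")
  r_px <- roi_radius_um / px_size_um
  cols <- max(1, floor(cx + 1 - r_px)):min(nc, ceiling(cx + 1 + r_px))
  rows <- max(1, floor(cy + 1 - r_px)):min(nr, ceiling(cy + 1 + r_px))
  inroi <- outer((rows - 1 - cy)^2, (cols - 1 - cx)^2, `+`) <= r_px^2
  vals <- uptake_image[rows, cols, drop = FALSE][inroi]
  est <- mean(vals) - background
  structure(max(est, 0), clamped = est < 0)
}

#' Nearest-neighbor distances along the dendrite
#'
#' For each spine, the minimum arclength distance to any other spine of the
#' same map. A map with a single spine yields `NA` with the isolated flag.
#'
#' @param map a [spine_map()].
#' @return data.frame `spine_id`, `nn_dist_um`, `isolated`.
#' @export
nearest_neighbor <- function(map) {
  stopifnot(inherits(map, "spine_map"))
  n <- nrow(map)
  if (n == 0L)
    return(data.frame(spine_id = character(), nn_dist_um = numeric(),
                      isolated = logical()))
  if (n == 1L)
    return(data.frame(spine_id = map$spine_id, nn_dist_um = NA_real_,
                      isolated = TRUE))
  p <- map$pos_um  # sorted by construction
  gap_prev <- c(Inf, diff(p))
  gap_next <- c(diff(p), Inf)
  data.frame(spine_id = map$spine_id,
             nn_dist_um = pmin(gap_prev, gap_next),
             isolated = FALSE)
}

#' Neighborhood covariates of every spine
#'
#' Neighbors are other spines of the same map strictly within the given
#' radius. Returns, per spine, the neighbor count and mean neighbor
#' activity at `activity_radius_um` (the 5-um "surrounding spines"
#' vicinity) and the neighbor count at `cluster_radius_um` (the 20-um
#' cluster neighborhood). Mean neighbor activity is `NA` (flagged) when a
#' spine has no neighbor within the activity radius.
#'
#' @param map a [spine_map()].
#' @param activity_radius_um radius for neighbor activity (um, > 0).
#' @param cluster_radius_um radius for cluster counts (um, > 0).
#' @return data.frame `spine_id`, `n_neighbors_within_radius`,
#'   `mean_neighbor_activity_au`, `n_neighbors_cluster_radius`,
#'   `no_neighbor_flag`.
#' @export
neighborhood_covariates <- function(map, activity_radius_um = 5,
                                    cluster_radius_um = 20) {
  stopifnot(inherits(map, "spine_map"))
  check_scalar(activity_radius_um, "activity_radius_um", positive = TRUE)
  check_scalar(cluster_radius_um, "cluster_radius_um", positive = TRUE)
  n <- nrow(map)
  p <- map$pos_um; a <- map$activity_au   # positions sorted by construction
  # windowed counts/sums on the sorted positions: strictly-within radius
  win <- function(r) {
    hi <- findInterval(p + r, p, left.open = TRUE)   # j: p_j <  p_i + r
    lo <- findInterval(p - r, p)                     # j: p_j <= p_i - r
    cnt <- hi - lo - 1L                              # exclude self
    cs <- c(0, cumsum(a))
    list(n = cnt, sum = cs[hi + 1L] - cs[lo + 1L] - a)
  }
  w5 <- win(activity_radius_um)
  n5 <- w5$n
  m5 <- ifelse(n5 > 0, w5$sum / n5, NA_real_)
  n20 <- win(cluster_radius_um)$n
  data.frame(spine_id = map$spine_id,
             n_neighbors_within_radius = n5,
             mean_neighbor_activity_au = m5,
             n_neighbors_cluster_radius = n20,
             no_neighbor_flag = n5 == 0L)
}

#' En-passant flag per spine
#'
#' TRUE when the spine's axon contacts this dendrite exactly once (a single
#' "en-passant" bouton); FALSE for spines of multi-contact axons.
#'
#' @param map a [spine_map()].
#' @return data.frame `spine_id`, `axon_contact_count`, `en_passant`.
#' @export
en_passant_flag <- function(map) {
  stopifnot(inherits(map, "spine_map"))
  if (any(is.na(map$axon_id)) || (nrow(map) && any(map$axon_id == "")))
    stop("every spine must carry an axon_id")
  cnt <- table(map$axon_id)
  k <- as.integer(cnt[map$axon_id])
  data.frame(spine_id = map$spine_id,
             axon_contact_count = if (nrow(map)) k else integer(0),
             en_passant = if (nrow(map)) k == 1L else logical(0))
}

#' Assemble the spine fate table
#'
#' Joins cross-timepoint tracking ([track_spines()]) with activities,
#' nearest-neighbor distances, neighborhood covariates and en-passant flags
#' computed on the t0 map.
#'
#' @inheritParams track_spines
#' @param activity_radius_um,cluster_radius_um see
#'   [neighborhood_covariates()].
#' @return a `fate_table` data.frame: `spine_id`, `fate`, `activity_au`,
#'   `nn_dist_um`, `isolated`, `n_neighbors_within_radius`,
#'   `mean_neighbor_activity_au`, `n_neighbors_cluster_radius`,
#'   `no_neighbor_flag`, `en_passant`, `axon_contact_count`.
#' @export
fate_table <- function(map_t0, map_t3h, match_tol_um = 0.5,
                       activity_radius_um = 5, cluster_radius_um = 20) {
  tr <- track_spines(map_t0, map_t3h, match_tol_um)
  out <- build_fate_table(map_t0, tr$fate, activity_radius_um,
                          cluster_radius_um)
  attr(out, "new_spines") <- attr(tr, "new_spines")
  out
}

# fate: character vector aligned with map_t0 rows
build_fate_table <- function(map_t0, fate, activity_radius_um = 5,
                             cluster_radius_um = 20) {
  nn <- nearest_neighbor(map_t0)
  nb <- neighborhood_covariates(map_t0, activity_radius_um, cluster_radius_um)
  ep <- en_passant_flag(map_t0)
  out <- data.frame(spine_id = map_t0$spine_id,
                    fate = fate,
                    activity_au = map_t0$activity_au,
                    nn_dist_um = nn$nn_dist_um,
                    isolated = nn$isolated,
                    stringsAsFactors = FALSE)
  out <- cbind(out, nb[, -1, drop = FALSE], ep[, -1, drop = FALSE])
  rownames(out) <- NULL
  structure(out, class = c("fate_table", "data.frame"))
}

#' @export
print.fate_table <- function(x, ...) {
  cat(sprintf("<fate_table> %d spines: %d maintained, %d pruned\n",
              nrow(x), sum(x$fate == "maintained"), sum(x$fate == "pruned")))
  if (nrow(x)) print.data.frame(utils::head(as.data.frame(x), 8), digits = 4)
  invisible(x)
}

#' Matched-control selection of maintained spines
#'
#' Implements the matched-control rules used when comparing maintained and
#' pruned spines without confounds:
#' * mode `"neighbor_activity"` (neighbor-activity comparison): keep
#'   maintained spines whose own activity lies within
#'   `mean(pruned activity) +/- activity_window_au`, and pruned spines that
#'   have at least one neighbor within the activity radius.
#' * mode `"neighbor_distance"` (neighbor-distance comparison): keep
#'   maintained spines whose own activity lies within the pruned-mean
#'   window and whose mean neighbor activity is within
#'   `+/- neighbor_window_au` of their own activity; all pruned spines are
#'   kept.
#'
#' Defaults are +/-2000 a.u. around the pruned mean and +/-1000 a.u. for
#' the moderate-neighbor rule. The window center is the mean activity of
#' the pruned spines that enter the neighbor comparison (those with a
#' neighbor within the radius), so applying a selection twice gives the
#' same result as applying it once.
#'
#' @param fates a `fate_table`.
#' @param mode `"neighbor_activity"` or `"neighbor_distance"`.
#' @param activity_window_au half-width of the own-activity window (a.u.).
#' @param neighbor_window_au half-width of the neighbor-activity window
#'   (a.u., `"neighbor_distance"` mode).
#' @return the filtered `fate_table` (attribute `pruned_mean_au` records
#'   the window center). Empty pruned set yields an empty selection with a
#'   warning.
#' @export
matched_control_selection <- function(fates,
                                      mode = c("neighbor_activity",
                                               "neighbor_distance"),
                                      activity_window_au = 2000,
                                      neighbor_window_au = 1000) {
  mode <- match.arg(mode)
  stopifnot(inherits(fates, "fate_table"))
  pruned <- fates$fate == "pruned"
  if (!any(pruned)) {
    warning("no pruned spines; empty selection")
    out <- fates[0, , drop = FALSE]
    attr(out, "pruned_mean_au") <- NA_real_
    return(out)
  }
  # window center: mean activity of the pruned spines that enter the
  # comparison (those with a neighbor within the radius); this makes the
  # selection stable under re-application
  pr_nbr <- pruned & fates$n_neighbors_within_radius > 0
  center <- if (any(pr_nbr)) mean(fates$activity_au[pr_nbr])
            else mean(fates$activity_au[pruned])
  in_window <- abs(fates$activity_au - center) <= activity_window_au
  keep <- switch(mode,
    neighbor_activity =
      (fates$fate == "maintained" & in_window) |
      (pruned & fates$n_neighbors_within_radius > 0),
    neighbor_distance =
      (fates$fate == "maintained" & in_window &
         !is.na(fates$mean_neighbor_activity_au) &
         abs(fates$mean_neighbor_activity_au - fates$activity_au) <=
           neighbor_window_au) |
      pruned)
  out <- fates[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "pruned_mean_au") <- center
  class(out) <- c("fate_table", "data.frame")
  out
}

#' Per-fate summary report
#'
#' Summarizes a fate table per fate: spine counts, activity and
#' nearest-neighbor distance (mean +/- SEM), fraction of spines with a
#' neighbor closer than 4 um, en-passant fractions, and the cluster-size
#' composition (fractions of spines with 1, 2, 3+ neighbors) at both the
#' 5-um vicinity radius and the 20-um cluster radius.
#'
#' @param fates a non-empty `fate_table`.
#' @return list of class `fate_report`: `by_fate` (summary data.frame),
#'   `composition_5um`, `composition_20um` (fraction matrices, rows =
#'   fates, columns = neighbor counts 0/1/2/3+; rows sum to 100).
#' @export
fate_report <- function(fates) {
  stopifnot(inherits(fates, "fate_table"))
  if (!nrow(fates)) stop("fate table is empty")
  fl <- c("maintained", "pruned")
  comp <- function(counts) {
    bin <- cut(counts, c(-0.5, 0.5, 1.5, 2.5, Inf),
               labels = c("0", "1", "2", "3+"))
    tab <- vapply(fl, function(f) {
      b <- bin[fates$fate == f]
      if (!length(b)) return(rep(NA_real_, 4))
      as.numeric(table(b)) / length(b) * 100
    }, numeric(4))
    out <- t(tab)
    colnames(out) <- levels(bin)
    out
  }
  by_fate <- do.call(rbind, lapply(fl, function(f) {
    d <- fates[fates$fate == f, , drop = FALSE]
    data.frame(fate = f, n = nrow(d),
               activity_mean_au = mean(d$activity_au),
               activity_sem_au = sem(d$activity_au),
               nn_mean_um = mean(d$nn_dist_um, na.rm = TRUE),
               nn_sem_um = sem(d$nn_dist_um),
               frac_nn_lt_4um = mean(d$nn_dist_um < 4, na.rm = TRUE),
               en_passant_frac = mean(d$en_passant),
               stringsAsFactors = FALSE)
  }))
  structure(list(by_fate = by_fate,
                 composition_5um = comp(fates$n_neighbors_within_radius),
                 composition_20um = comp(fates$n_neighbors_cluster_radius)),
            class = "fate_report")
}

#' @export
print.fate_report <- function(x, ...) {
  cat("<fate_report>\n")
  print(x$by_fate, digits = 4, row.names = FALSE)
  cat("cluster composition at 5 um (% of spines by neighbor count):\n")
  print(round(x$composition_5um, 1))
  invisible(x)
}
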