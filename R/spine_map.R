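#' Dendrite spine map
#'
#' A `spine_map` holds the spines of one dendritic segment as a 1-D arclength
#' map: spine positions are measured in micrometers along the dendrite from
#' its origin (the convention used for inter-spine distances measured at the
#' dendritic shaft, at the initiation of the spine necks). Each spine carries
#' a presynaptic activity score in arbitrary units (a.u., synaptotagmin-uptake
#' scale) and the identity of the axon contacting it.
#'
#' @param spines data.frame with columns `spine_id`, `pos_um`, `activity_au`,
#'   `axon_id` and optionally `present` (logical, default `TRUE`).
#' @param length_um dendrite segment length in micrometers (> 0, or 0 for an
#'   empty degenerate segment).
#' @param dendrite_id identifier of the segment.
#' @return An object of class `spine_map`: the spine data.frame with
#'   attributes `length_um` and `dendrite_id`.
#' @export
spine_map <- function(spines, length_um, dendrite_id = "dend1") {
  check_scalar(length_um, "length_um", nonneg = TRUE)
  if (is.null(spines) || nrow(spines) == 0L) {
    spines <- data.frame(spine_id = character(), pos_um = numeric(),
                         activity_au = numeric(), axon_id = character(),
                         present = logical(), stringsAsFactors = FALSE)
  }
  req <- c("spine_id", "pos_um", "activity_au", "axon_id")
  miss <- setdiff(req, names(spines))
  if (length(miss))
    stop("spine table lacks columns: ", paste(miss, collapse = ", "))
  if (!"present" %in% names(spines)) spines$present <- TRUE
  if (anyDuplicated(spines$spine_id))
    stop("spine IDs must be unique within a map")
  if (nrow(spines) && (any(spines$pos_um < 0) || any(spines$pos_um > length_um)))
    stop("spine positions must lie in [0, length_um]")
  if (nrow(spines) && any(spines$activity_au < 0))
    stop("spine activities must be >= 0")
  spines <- spines[order(spines$pos_um), , drop = FALSE]
  rownames(spines) <- NULL
  structure(spines, length_um = length_um, dendrite_id = dendrite_id,
            class = c("spine_map", "data.frame"))
}

#' @export
print.spine_map <- function(x, ...) {
  cat(sprintf("<spine_map> %s: %d spines on %.1f um (%.2f spines/um)\n",
              attr(x, "dendrite_id"), nrow(x), attr(x, "length_um"),
              if (attr(x, "length_um") > 0) nrow(x) / attr(x, "length_um") else 0))
  if (nrow(x)) print.data.frame(utils::head(as.data.frame(x), 8))
  if (nrow(x) > 8) cat("... and", nrow(x) - 8L, "more spines\n")
  invisible(x)
}

#' Spine-map generator configuration
#'
#' Parameters of the clustered spine-position process used by
#' [gen_spine_map()]. Spines arise from two superposed point processes along
#' the dendrite: a Poisson cluster process (cluster centers at
#' `cluster_rate` per um, each with `2 + rpois(cluster_size_mean - 2)` spines
#' scattered with SD `cluster_spread_um` around the center) and an isolated
#' homogeneous Poisson process at `isolated_rate` per um. Defaults emulate
#' the visible-spine maps of two-timepoint live imaging (one map ~ the
#' pooled dendrite portions of one neuron): about 90-100 spines on 600 um,
#' roughly 80% with a nearest neighbor within 4 um and about 18% spatially
#' isolated (no neighbor within 5 um). This substrate is sparser and
#' clumpier than fixed-immunostaining puncta, which the image generator
#' emulates separately at its own density.
#'
#' Activities are lognormal with arithmetic mean `activity_mean_au`
#' (default 14,000 a.u., the synaptotagmin-uptake magnitude at which
#' +/-2000 a.u. matching windows are meaningful) and CV `activity_cv`.
#' Spines of the same cluster share a latent cluster factor with
#' intra-class correlation `activity_icc` on the log scale (neighboring
#' synapses show coordinated activity); the marginal distribution is
#' unchanged.
#'
#' Axon wiring: each spine is an "en-passant" contact (its axon touches
#' this dendrite exactly once) with marginal probability `en_passant_prob`.
#' Spatially isolated spines (no neighbor within 5 um) are more likely to
#' carry a dedicated single-bouton axon: their conditional en-passant
#' probability is boosted by `en_passant_iso_boost`, and the probability of
#' clustered spines is lowered so the map-wide expectation stays at
#' `en_passant_prob`. Multi-contact spines are grouped with nearby
#' multi-contact spines into axons of 2..`max_axon_contacts` boutons.
#'
#' @param length_um dendrite length (um).
#' @param cluster_rate cluster centers per um.
#' @param cluster_size_mean mean spines per cluster (>= 2).
#' @param cluster_spread_um SD of within-cluster spine scatter (um).
#' @param isolated_rate isolated spines per um.
#' @param activity_mean_au,activity_cv lognormal activity parameters.
#' @param activity_icc intra-cluster correlation of log-activity, in [0, 1).
#' @param en_passant_prob marginal probability a spine's axon is
#'   single-contact.
#' @param en_passant_iso_boost multiplier on `en_passant_prob` for
#'   spatially isolated spines (capped so probabilities stay in [0, 1]).
#' @param max_axon_contacts maximum boutons per multi-contact axon.
#' @return list of class `spine_map_config`.
#' @export
spine_map_config <- function(length_um = 600, cluster_rate = 0.025,
                             cluster_size_mean = 4, cluster_spread_um = 0.8,
                             isolated_rate = 0.08,
                             activity_mean_au = 14000, activity_cv = 0.5,
                             activity_icc = 0.65,
                             en_passant_prob = 0.35,
                             en_passant_iso_boost = 2.2,
                             max_axon_contacts = 3) {
  check_scalar(length_um, "length_um", nonneg = TRUE)
  check_scalar(cluster_rate, "cluster_rate", nonneg = TRUE)
  check_scalar(isolated_rate, "isolated_rate", nonneg = TRUE)
  check_scalar(cluster_spread_um, "cluster_spread_um", nonneg = TRUE)
  check_scalar(activity_mean_au, "activity_mean_au", positive = TRUE)
  check_scalar(activity_cv, "activity_cv", nonneg = TRUE)
  if (cluster_size_mean < 2) stop("cluster_size_mean must be >= 2")
  if (activity_icc < 0 || activity_icc >= 1)
    stop("activity_icc must be in [0, 1)")
  if (en_passant_iso_boost < 1) stop("en_passant_iso_boost must be >= 1")
  if (en_passant_prob < 0 || en_passant_prob > 1)
    stop("en_passant_prob must be in [0, 1]")
  if (max_axon_contacts < 2) stop("max_axon_contacts must be >= 2")
  structure(as.list(environment()), class = "spine_map_config")
}

#' Generate a synthetic spine map
#'
#' Draws a clustered spine map along a dendrite with known activities and
#' axon wiring; see [spine_map_config()] for the generative process.
#' Deterministic given `(config, seed)`.
#'
#' @param config a [spine_map_config()].
#' @param seed integer RNG seed.
#' @param dendrite_id identifier for the generated segment.
#' @return a [spine_map()].
#' @examples
#' m <- gen_spine_map(spine_map_config(length_um = 50), seed = 1)
#' nrow(m) / attr(m, "length_um")  # spine density per um
#' @export
gen_spine_map <- function(config = spine_map_config(), seed,
                          dendrite_id = "dend1") {
  stopifnot(inherits(config, "spine_map_config"))
  L <- config$length_um
  if (L == 0) return(spine_map(NULL, 0, dendrite_id))

  set.seed(as.integer(seed))

  # clustered component; each cluster carries a latent activity factor
  n_clust <- stats::rpois(1, config$cluster_rate * L)
  pos <- numeric(0)
  clust_of <- integer(0)
  if (n_clust > 0) {
    centers <- stats::runif(n_clust, 0, L)
    sizes <- 2L + stats::rpois(n_clust, config$cluster_size_mean - 2)
    pos <- unlist(lapply(seq_len(n_clust), function(i) {
      centers[i] + stats::rnorm(sizes[i], 0, config$cluster_spread_um)
    }))
    clust_of <- rep(seq_len(n_clust), sizes)
  }
  # isolated component: each spine is its own activity unit
  n_iso <- stats::rpois(1, config$isolated_rate * L)
  if (n_iso > 0) {
    pos <- c(pos, stats::runif(n_iso, 0, L))
    clust_of <- c(clust_of, n_clust + seq_len(n_iso))
  }
  pos <- pmin(pmax(pos, 0), L)
  n <- length(pos)
  if (n == 0L) return(spine_map(NULL, L, dendrite_id))

  # lognormal activities with intra-cluster correlation on the log scale
  lp <- lnorm_pars(config$activity_mean_au, config$activity_cv)
  icc <- config$activity_icc
  z_c <- stats::rnorm(max(clust_of))[clust_of]
  z_i <- stats::rnorm(n)
  activity <- exp(lp$meanlog +
                    lp$sdlog * (sqrt(icc) * z_c + sqrt(1 - icc) * z_i))

  # isolation-aware en-passant draw (overall expectation = en_passant_prob)
  iso <- vapply(seq_len(n), function(i)
    all(abs(pos[-i] - pos[i]) >= 5) || n == 1L, TRUE)
  p_en <- config$en_passant_prob
  p_iso <- min(1, config$en_passant_iso_boost * p_en)
  f_iso <- mean(iso)
  p_cl <- if (f_iso < 1) max(0, (p_en - f_iso * p_iso) / (1 - f_iso)) else p_en
  axon <- assign_axons(pos, ifelse(iso, p_iso, p_cl),
                       config$max_axon_contacts)

  ord <- order(pos)
  spines <- data.frame(
    spine_id = sprintf("s%04d", seq_len(n)),
    pos_um = pos[ord],
    activity_au = activity[ord],
    axon_id = axon[ord],
    present = TRUE,
    stringsAsFactors = FALSE
  )
  spine_map(spines, L, dendrite_id)
}

# Bernoulli en-passant draw per spine (probability may vary by spine);
# multi-contact spines are grouped with their nearest multi-contact
# neighbors (consecutive in position) into axons of 2..kmax boutons.  A
# single leftover spine is attached to an existing multi-contact axon so
# the realized en-passant fraction equals the Bernoulli draws.
assign_axons <- function(pos, p_en, kmax) {
  n <- length(pos)
  en <- stats::runif(n) < p_en
  axon <- character(n)
  axon[en] <- sprintf("axE%04d", seq_len(sum(en)))
  idx <- which(!en)[order(pos[!en])]
  gid <- 0L
  groups <- list()
  while (length(idx) > 0) {
    if (length(idx) == 1L) {
      if (gid > 0L) {
        groups[[gid]] <- c(groups[[gid]], idx)
      } else {
        axon[idx] <- "axE0000"  # forced single contact: no group exists
      }
      idx <- integer(0)
    } else {
      k <- min(length(idx), sample(2:kmax, 1))
      gid <- gid + 1L
      groups[[gid]] <- idx[seq_len(k)]
      idx <- idx[-seq_len(k)]
    }
  }
  for (g in seq_along(groups)) axon[groups[[g]]] <- sprintf("axM%04d", g)
  axon
}
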