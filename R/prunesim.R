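#' Pruning-model configuration
#'
#' Parameters of the activity-dependent pruning model. Upon chemical LTD
#' induction each synapse expresses LTD with probability `p_ltd`; an
#' LTD-expressing synapse is pruned over the 3-h horizon unless protected.
#' The protection signal of spine i is
#'
#' `P_i = clamp01( g_network * ( w_self * s(a_i)
#'        + w_nbr * s(abar_i) * [has neighbor < nbr_radius_um]
#'        + w_axon * [axon contacts dendrite more than once] ) )`
#'
#' with `s(a) = a / (a + a_half)` a saturating function of activity (a.u.),
#' `abar_i` the mean activity of neighbors within `nbr_radius_um`, and
#' `g_network` a global network-activity multiplier (1 under control
#' conditions, 0 under action-potential block). An LTD-expressing spine is
#' pruned with probability `1 - P_i`; spines that do not express LTD are
#' never pruned.
#'
#' The default weights are calibrated (see [calibrate_prune_model()] and the
#' methods vignette) so that the default spine-map generator yields mean
#' pruned fractions of about 30% under control, 70% under TTX, 47% under
#' AMPAR block, and about 0% under high network activity.
#'
#' @param p_ltd probability a synapse expresses LTD on induction.
#' @param w_self,w_nbr,w_axon non-negative protection weights for own
#'   activity, neighbor activity, and same-axon multi-contact.
#' @param a_half activity half-saturation constant (a.u.).
#' @param g_network global network-activity multiplier (>= 0).
#' @param g_ampar_block residual network-activity multiplier under AMPAR
#'   block (the depolarization-independent fraction of the maintenance
#'   drive); a calibrated condition parameter.
#' @param g_high_activity network-activity multiplier under GABA-A block /
#'   raised extracellular calcium (>= 2; protection saturates).
#' @param nbr_radius_um neighbor radius (um, > 0).
#' @return list of class `prune_config`.
#' @export
prune_config <- function(p_ltd = 0.70, w_self = 1.5, w_nbr = 2.2,
                         w_axon = 0.2, a_half = 90000, g_network = 1,
                         g_ampar_block = 0.55, g_high_activity = 8,
                         nbr_radius_um = 5) {
  if (p_ltd < 0 || p_ltd > 1) stop("p_ltd must be in [0, 1]")
  check_scalar(w_self, "w_self", nonneg = TRUE)
  check_scalar(w_nbr, "w_nbr", nonneg = TRUE)
  check_scalar(w_axon, "w_axon", nonneg = TRUE)
  check_scalar(a_half, "a_half", positive = TRUE)
  check_scalar(g_network, "g_network", nonneg = TRUE)
  check_scalar(g_ampar_block, "g_ampar_block", nonneg = TRUE)
  check_scalar(g_high_activity, "g_high_activity", nonneg = TRUE)
  check_scalar(nbr_radius_um, "nbr_radius_um", positive = TRUE)
  structure(as.list(environment()), class = "prune_config")
}

#' @export
print.prune_config <- function(x, ...) {
  cat(sprintf(paste0("<prune_config> p_ltd=%.2f  w_self=%.3g  w_nbr=%.3g  ",
                     "w_axon=%.3g  a_half=%g  g_network=%.2f\n"),
              x$p_ltd, x$w_self, x$w_nbr, x$w_axon, x$a_half, x$g_network))
  invisible(x)
}

#' Pharmacological condition presets
#'
#' Named modifications of a base [prune_config()]:
#' * `control`: `g_network = 1`.
#' * `ttx`: action-potential block, `g_network = 0` (no protective
#'   activity; pruned fraction equals `p_ltd` in expectation).
#' * `high_activity`: GABA-A block / raised extracellular calcium,
#'   `g_network = config$g_high_activity` (protection saturates; pruning
#'   abolished).
#' * `ampar_block`: AMPAR antagonist, `g_network = config$g_ampar_block`
#'   (depolarization-driven protection lost; only the AMPAR-independent
#'   residual drive remains).
#' * `l_type_block`: L-type calcium channel block; the calcium-dependent
#'   terms `w_self` and `w_nbr` are scaled by 0.7 at `g_network = 1`.
#'
#' @param config base [prune_config()].
#' @return named list of `prune_config` objects.
#' @export
prune_conditions <- function(config = prune_config()) {
  mod <- function(g = config$g_network, w_scale = 1) {
    cfg <- config
    cfg$g_network <- g
    cfg$w_self <- cfg$w_self * w_scale
    cfg$w_nbr <- cfg$w_nbr * w_scale
    cfg
  }
  list(control = mod(g = 1),
       ttx = mod(g = 0),
       high_activity = mod(g = config$g_high_activity),
       ampar_block = mod(g = config$g_ampar_block),
       l_type_block = mod(g = 1, w_scale = 0.7))
}

#' Per-spine protection signal
#'
#' Deterministic protection probability of every spine of a map under a
#' configuration; see [prune_config()] for the functional form.
#'
#' @param map a [spine_map()].
#' @param config a [prune_config()].
#' @return numeric vector in [0, 1], one value per spine.
#' @export
protection_signal <- function(map, config = prune_config()) {
  stopifnot(inherits(map, "spine_map"), inherits(config, "prune_config"))
  if (nrow(map) == 0L) return(numeric(0))
  protection_from_features(map_features(map, config$nbr_radius_um), config)
}

# per-spine model inputs: activity, mean neighbor activity, neighbor and
# multi-contact indicators
map_features <- function(map, nbr_radius_um) {
  nb <- neighborhood_covariates(map, activity_radius_um = nbr_radius_um)
  ep <- en_passant_flag(map)
  data.frame(activity_au = map$activity_au,
             abar = nb$mean_neighbor_activity_au,
             has_nbr = nb$n_neighbors_within_radius > 0,
             multi = !ep$en_passant)
}

protection_from_features <- function(feat, config) {
  sat <- function(a) a / (a + config$a_half)
  raw <- config$g_network *
    (config$w_self * sat(feat$activity_au) +
       config$w_nbr * ifelse(feat$has_nbr, sat(feat$abar), 0) +
       config$w_axon * as.numeric(feat$multi))
  raw[is.na(raw)] <- 0
  pmin(pmax(raw, 0), 1)
}

#' Simulate activity-dependent pruning on a spine map
#'
#' Runs the one-shot pruning model over the 3-h horizon: each spine
#' independently expresses LTD with probability `p_ltd`; LTD-expressing
#' spines are pruned with probability `1 - P_i` (protection signal
#' [protection_signal()]); non-LTD spines are never pruned. Deterministic
#' given `(map, config, seed)`.
#'
#' @param map a non-empty [spine_map()].
#' @param config a [prune_config()].
#' @param seed integer RNG seed.
#' @return a `fate_table` (see [fate_table()]) with extra columns
#'   `ltd_expressed` and `protection`.
#' @export
simulate_pruning <- function(map, config = prune_config(), seed) {
  stopifnot(inherits(map, "spine_map"))
  if (nrow(map) == 0L) stop("map has no spines")
  P <- protection_signal(map, config)
  set.seed(as.integer(seed))
  n <- nrow(map)
  ltd <- stats::runif(n) < config$p_ltd
  pruned <- ltd & (stats::runif(n) < (1 - P))
  out <- build_fate_table(map, ifelse(pruned, "pruned", "maintained"),
                          activity_radius_um = config$nbr_radius_um)
  out$ltd_expressed <- ltd
  out$protection <- P
  out
}

#' Pruned fraction of a fate table
#' @param fates a `fate_table`.
#' @return fraction of spines with fate `"pruned"`.
#' @export
pruned_fraction <- function(fates) mean(fates$fate == "pruned")

#' Run the pruning model across pharmacological conditions
#'
#' Simulates `n_reps` replicate dendrite maps per condition (fresh map and
#' pruning draw per replicate seed, identical seeds across conditions so
#' conditions are compared on the same maps) and reports mean +/- SEM of
#' the pruned fraction per condition.
#'
#' @param map_config a [spine_map_config()].
#' @param config base [prune_config()].
#' @param conditions character vector of preset names
#'   (see [prune_conditions()]), or a named list of `prune_config`s.
#' @param n_reps replicates per condition (ignored when `seeds` given).
#' @param seeds integer vector of replicate seeds.
#' @return data.frame `condition`, `mean_pruned_frac`, `sem_pruned_frac`,
#'   `n_reps`; attribute `per_rep` holds the full replicate matrix.
#' @export
run_condition_panel <- function(map_config = spine_map_config(),
                                config = prune_config(),
                                conditions = c("control", "ttx",
                                               "high_activity", "ampar_block"),
                                n_reps = 20, seeds = NULL) {
  if (is.null(seeds)) seeds <- seq_len(n_reps)
  presets <- if (is.character(conditions)) {
    all <- prune_conditions(config)
    bad <- setdiff(conditions, names(all))
    if (length(bad)) stop("unknown conditions: ", paste(bad, collapse = ", "))
    all[conditions]
  } else conditions
  per_rep <- vapply(seeds, function(s) {
    map <- gen_spine_map(map_config, seed = s)
    vapply(presets, function(cfg)
      pruned_fraction(simulate_pruning(map, cfg, seed = s + 500000L)),
      numeric(1))
  }, numeric(length(presets)))
  per_rep <- matrix(per_rep, nrow = length(presets),
                    dimnames = list(names(presets), NULL))
  out <- data.frame(condition = names(presets),
                    mean_pruned_frac = rowMeans(per_rep),
                    sem_pruned_frac = apply(per_rep, 1, sem),
                    n_reps = length(seeds),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "per_rep") <- per_rep
  out
}

#' Calibrate the pruning model to target pruned fractions
#'
#' Exhaustive grid search over the supplied free parameters, minimizing the
#' sum of squared residuals between the model's mean pruned fractions and
#' the target fractions per condition. Dendrite maps are generated once
#' from fixed seeds and held fixed across grid points; on each map the
#' pruned fraction is evaluated as its exact expectation over the pruning
#' draws, `mean(p_ltd * (1 - P))`, so the objective is deterministic and
#' free of Monte-Carlo noise.
#'
#' @param map_config a [spine_map_config()].
#' @param targets named numeric vector of target pruned fractions in [0, 1]
#'   per condition preset name, e.g.
#'   `c(control = 0.30, ttx = 0.70, ampar_block = 0.47)`.
#' @param free named list of numeric grids for `prune_config` fields, e.g.
#'   `list(w_self = seq(0.2, 0.8, 0.1))`.
#' @param base_config starting [prune_config()]; non-free fields are kept.
#' @param seeds replicate seeds per evaluation.
#' @return list of class `prune_calibration`: `config` (best), `residuals`
#'   (data.frame per condition), `sse`, `grid` (all evaluated points with
#'   objective).
#' @export
calibrate_prune_model <- function(map_config = spine_map_config(),
                                  targets = c(control = 0.30, ttx = 0.70,
                                              ampar_block = 0.47),
                                  free = list(w_self = seq(0.2, 0.8, 0.2),
                                              w_nbr = seq(0.2, 0.8, 0.2),
                                              w_axon = seq(0.3, 0.9, 0.2)),
                                  base_config = prune_config(),
                                  seeds = 1:10) {
  if (!length(targets) || is.null(names(targets)))
    stop("targets must be a named vector of condition fractions")
  if (!length(free) || any(!lengths(free)))
    stop("free parameter grid is empty")
  bad <- setdiff(names(free), names(base_config))
  if (length(bad)) stop("unknown config fields: ", paste(bad, collapse = ", "))
  if ("nbr_radius_um" %in% names(free))
    stop("nbr_radius_um cannot be calibrated (fixes the map features)")
  feats <- lapply(seeds, function(s)
    map_features(gen_spine_map(map_config, seed = s),
                 base_config$nbr_radius_um))
  expected_fracs <- function(cfg) {
    presets <- prune_conditions(cfg)[names(targets)]
    vapply(presets, function(cc)
      mean(vapply(feats, function(f)
        mean(cc$p_ltd * (1 - protection_from_features(f, cc))), 0)),
      numeric(1))
  }
  grid <- expand.grid(free, KEEP.OUT.ATTRS = FALSE)
  obj <- numeric(nrow(grid))
  sims <- matrix(NA_real_, nrow(grid), length(targets),
                 dimnames = list(NULL, names(targets)))
  for (g in seq_len(nrow(grid))) {
    cfg <- base_config
    for (nm in names(free)) cfg[[nm]] <- grid[[nm]][g]
    sims[g, ] <- expected_fracs(cfg)
    obj[g] <- sum((sims[g, ] - targets)^2)
  }
  best <- which.min(obj)
  cfg <- base_config
  for (nm in names(free)) cfg[[nm]] <- grid[[nm]][best]
  res <- data.frame(condition = names(targets),
                    target = as.numeric(targets),
                    simulated = sims[best, ],
                    residual = sims[best, ] - as.numeric(targets))
  rownames(res) <- NULL
  structure(list(config = cfg, residuals = res, sse = obj[best],
                 grid = cbind(grid, sse = obj)),
            class = "prune_calibration")
}

#' @export
print.prune_calibration <- function(x, ...) {
  cat("<prune_calibration> best configuration:\n")
  print(x$config)
  print(x$residuals, digits = 3, row.names = FALSE)
  invisible(x)
}
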