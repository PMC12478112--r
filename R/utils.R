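#' synaprune: activity-dependent synaptic pruning analysis and simulation
#'
#' Detection and quantification of synaptic puncta and EPSC events,
#' spine-fate neighborhood analysis across imaging timepoints, and a
#' calibrated stochastic model of NMDAR-dependent LTD-induced pruning,
#' together with synthetic-data generators providing exact ground truth.
#'
#' @keywords internal
"_PACKAGE"

# standard error of the mean
sem <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) < 2) return(NA_real_)
  stats::sd(x) / sqrt(length(x))
}

# lognormal meanlog/sdlog from arithmetic mean and coefficient of variation
lnorm_pars <- function(mean, cv) {
  stopifnot(mean > 0, cv >= 0)
  sdlog <- sqrt(log(1 + cv^2))
  meanlog <- log(mean) - sdlog^2 / 2
  list(meanlog = meanlog, sdlog = sdlog)
}

check_scalar <- function(x, name, positive = FALSE, nonneg = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
  if (positive && x <= 0)
    stop(sprintf("'%s' must be > 0", name), call. = FALSE)
  if (nonneg && x < 0)
    stop(sprintf("'%s' must be >= 0", name), call. = FALSE)
  invisible(x)
}
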