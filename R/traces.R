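#' EPSC trace specification
#'
#' Parameters of the synthetic voltage-clamp current trace produced by
#' [gen_trace()]. Unitary events are difference-of-exponentials
#' (tau_rise, tau_decay) scaled to a lognormal peak amplitude; minis arrive
#' as a Poisson process; poly-synaptic bursts are sums of `burst_size`
#' unitary events with onsets jittered within `burst_jitter_ms`. Inward
#' currents are negative; baseline noise is white Gaussian. Defaults emulate
#' whole-cell recordings at -70 mV holding potential: 10 kHz sampling,
#' mini amplitudes near 12 pA.
#'
#' @param duration_s trace length (s).
#' @param rate_hz sampling rate (Hz).
#' @param mini_rate_hz Poisson rate of unitary miniature events (Hz).
#' @param amp_mean_pA,amp_cv lognormal peak-amplitude parameters (pA).
#' @param tau_rise_ms,tau_decay_ms kernel time constants (ms);
#'   `tau_decay_ms > tau_rise_ms > 0`.
#' @param burst_rate_hz Poisson rate of poly-synaptic bursts (Hz).
#' @param burst_size unitary events per burst.
#' @param burst_jitter_ms onset jitter window within a burst (ms).
#' @param noise_sd_pA baseline noise SD (pA).
#' @return list of class `trace_spec`.
#' @export
trace_spec <- function(duration_s = 60, rate_hz = 10000, mini_rate_hz = 0.5,
                       amp_mean_pA = 12, amp_cv = 0.35,
                       tau_rise_ms = 1, tau_decay_ms = 8,
                       burst_rate_hz = 0, burst_size = 10,
                       burst_jitter_ms = 4, noise_sd_pA = 1.2) {
  check_scalar(duration_s, "duration_s", positive = TRUE)
  check_scalar(rate_hz, "rate_hz", positive = TRUE)
  check_scalar(mini_rate_hz, "mini_rate_hz", nonneg = TRUE)
  check_scalar(burst_rate_hz, "burst_rate_hz", nonneg = TRUE)
  check_scalar(noise_sd_pA, "noise_sd_pA", nonneg = TRUE)
  check_scalar(amp_mean_pA, "amp_mean_pA", positive = TRUE)
  if (!(tau_decay_ms > tau_rise_ms && tau_rise_ms > 0))
    stop("need tau_decay_ms > tau_rise_ms > 0")
  if (burst_size < 2) stop("burst_size must be >= 2")
  structure(as.list(environment()), class = "trace_spec")
}

# difference-of-exponentials kernel, unit peak, t in ms (vectorized)
epsc_kernel <- function(t_ms, tau_rise_ms, tau_decay_ms) {
  pk <- epsc_kernel_peak(tau_rise_ms, tau_decay_ms)
  k <- ifelse(t_ms >= 0,
              exp(-t_ms / tau_decay_ms) - exp(-t_ms / tau_rise_ms), 0)
  k / pk
}

# peak value and time of the unnormalized kernel (closed form)
epsc_kernel_peak <- function(tau_rise_ms, tau_decay_ms) {
  tp <- log(tau_decay_ms / tau_rise_ms) *
    tau_rise_ms * tau_decay_ms / (tau_decay_ms - tau_rise_ms)
  exp(-tp / tau_decay_ms) - exp(-tp / tau_rise_ms)
}

# closed-form area (pA*ms) of a unit-peak kernel scaled to amplitude amp
epsc_kernel_area <- function(amp_pA, tau_rise_ms, tau_decay_ms) {
  amp_pA * (tau_decay_ms - tau_rise_ms) /
    epsc_kernel_peak(tau_rise_ms, tau_decay_ms)
}

# time (ms) the unit-peak kernel spends above `frac` of its peak
epsc_kernel_duration <- function(tau_rise_ms, tau_decay_ms, frac = 0.1) {
  f <- function(t) epsc_kernel(t, tau_rise_ms, tau_decay_ms) - frac
  tp <- log(tau_decay_ms / tau_rise_ms) *
    tau_rise_ms * tau_decay_ms / (tau_decay_ms - tau_rise_ms)
  t1 <- stats::uniroot(f, c(1e-9, tp))$root
  t2 <- stats::uniroot(f, c(tp, tp + 40 * tau_decay_ms))$root
  t2 - t1
}

#' Generate a synthetic EPSC current trace with ground truth
#'
#' Renders a voltage-clamp current trace from a [trace_spec()]: unitary
#' miniature events and poly-synaptic bursts on white Gaussian noise, inward
#' currents negative. Ground truth records every unitary event's onset, peak
#' amplitude (magnitude, pA), closed-form area (pA*ms) and duration (ms,
#' time above `duration_frac` of the peak), plus the burst each event
#' belongs to. Deterministic given `(spec, seed)`.
#'
#' @param spec a [trace_spec()].
#' @param seed integer RNG seed.
#' @param duration_frac peak fraction defining the ground-truth duration.
#' @return list of class `epsc_trace` with elements `current_pA` (numeric
#'   vector), `rate_hz`, `duration_s`, `events` (ground-truth data.frame:
#'   `event_id`, `onset_s`, `amp_pA`, `area_pAms`, `duration_ms`, `kind`,
#'   `burst_id`), `saturated` (logical) and `spec`.
#' @export
gen_trace <- function(spec = trace_spec(), seed, duration_frac = 0.1) {
  stopifnot(inherits(spec, "trace_spec"))
  set.seed(as.integer(seed))
  n_samp <- round(spec$duration_s * spec$rate_hz)
  dt_ms <- 1000 / spec$rate_hz

  n_mini <- stats::rpois(1, spec$mini_rate_hz * spec$duration_s)
  onsets <- if (n_mini) stats::runif(n_mini, 0, spec$duration_s) else numeric(0)
  kind <- rep("mini", n_mini)
  burst_id <- rep(NA_integer_, n_mini)

  n_burst <- stats::rpois(1, spec$burst_rate_hz * spec$duration_s)
  if (n_burst) {
    b0 <- stats::runif(n_burst, 0, spec$duration_s)
    for (b in seq_len(n_burst)) {
      on <- b0[b] + stats::runif(spec$burst_size, 0, spec$burst_jitter_ms) / 1000
      onsets <- c(onsets, on)
      kind <- c(kind, rep("burst", spec$burst_size))
      burst_id <- c(burst_id, rep(b, spec$burst_size))
    }
  }
  n_ev <- length(onsets)
  lp <- lnorm_pars(spec$amp_mean_pA, spec$amp_cv)
  amps <- if (n_ev) stats::rlnorm(n_ev, lp$meanlog, lp$sdlog) else numeric(0)

  current <- stats::rnorm(n_samp, 0, spec$noise_sd_pA)
  klen <- ceiling(8 * spec$tau_decay_ms / dt_ms)
  kt <- (0:klen) * dt_ms
  for (i in seq_len(n_ev)) {
    i0 <- floor(onsets[i] * spec$rate_hz) + 1L
    if (i0 > n_samp) next
    idx <- i0:min(n_samp, i0 + klen)
    # kernel evaluated at sample times relative to the exact onset
    trel <- (idx - 1) * dt_ms - onsets[i] * 1000
    current[idx] <- current[idx] -
      amps[i] * epsc_kernel(trel, spec$tau_rise_ms, spec$tau_decay_ms)
  }

  dur_ms <- if (n_ev) epsc_kernel_duration(spec$tau_rise_ms, spec$tau_decay_ms,
                                           duration_frac) else numeric(0)
  events <- data.frame(
    event_id = seq_len(n_ev),
    onset_s = onsets, amp_pA = amps,
    area_pAms = epsc_kernel_area(amps, spec$tau_rise_ms, spec$tau_decay_ms),
    duration_ms = rep(dur_ms, length.out = n_ev),
    kind = kind, burst_id = burst_id,
    stringsAsFactors = FALSE)
  events <- events[order(events$onset_s), , drop = FALSE]
  rownames(events) <- NULL

  saturated <- n_ev * dur_ms[1] / 1000 > 0.8 * spec$duration_s
  if (isTRUE(saturated))
    warning("event rate saturates the trace; ground truth flagged")

  structure(list(current_pA = current, rate_hz = spec$rate_hz,
                 duration_s = spec$duration_s, events = events,
                 saturated = isTRUE(saturated), spec = spec),
            class = "epsc_trace")
}

#' @export
print.epsc_trace <- function(x, ...) {
  cat(sprintf("<epsc_trace> %.1f s at %g Hz, %d ground-truth events (%d in bursts)\n",
              x$duration_s, x$rate_hz, nrow(x$events),
              sum(x$events$kind == "burst")))
  invisible(x)
}

#' Time vector of a trace (seconds)
#' @param trace an `epsc_trace`.
#' @return numeric vector of sample times.
#' @export
trace_time <- function(trace) {
  (seq_along(trace$current_pA) - 1) / trace$rate_hz
}
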