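#' Event table constructor (internal)
#'
#' @noRd
new_event_table <- function(onset_s, peak_amp_pA, area_pAms, duration_ms,
                            cutoff = 1.5) {
  s <- ifelse(area_pAms > 0 & duration_ms > 0,
              log10(area_pAms / duration_ms), NA_real_)
  df <- data.frame(onset_s = onset_s, peak_amp_pA = peak_amp_pA,
                   area_pAms = area_pAms, duration_ms = duration_ms,
                   s_stat = s,
                   class = ifelse(is.na(s), NA_character_,
                                  classify_event(ifelse(is.na(s), 0, s), cutoff)),
                   stringsAsFactors = FALSE)
  structure(df, class = c("event_table", "data.frame"))
}

#' @export
print.event_table <- function(x, ...) {
  cat(sprintf("<event_table> %d events (%d mono, %d poly)\n", nrow(x),
              sum(x$class == "mono", na.rm = TRUE),
              sum(x$class == "poly", na.rm = TRUE)))
  if (nrow(x)) print.data.frame(utils::head(as.data.frame(x), 8), digits = 4)
  invisible(x)
}

# resolve (current vector, sampling rate) from an epsc_trace or numeric
resolve_trace <- function(trace, rate_hz) {
  if (inherits(trace, "epsc_trace"))
    return(list(i = trace$current_pA, rate = trace$rate_hz))
  if (is.null(rate_hz)) stop("rate_hz is required for a bare numeric trace")
  list(i = as.numeric(trace), rate = rate_hz)
}

# robust baseline level and noise SD (median / MAD) over a leading window
baseline_stats <- function(i, rate, baseline_window_s) {
  n_b <- round(baseline_window_s * rate)
  if (n_b > length(i)) stop("trace shorter than baseline window")
  w <- i[seq_len(n_b)]
  list(level = stats::median(w), sd = stats::mad(w))
}

#' Detect miniature EPSC events by the baseline-noise threshold rule
#'
#' Detects inward (negative) current deflections whose magnitude exceeds
#' `k_sd` times the SD of the baseline noise, keeping only events with peak
#' amplitude between `amp_min_pA` and `amp_max_pA` (the 3x-SD / 5-50 pA
#' mini-detection convention). Baseline level and SD are estimated robustly
#' (median and MAD) over the leading `baseline_window_s`. Detection runs on
#' a short moving-average smoothed copy of the trace (suppressing
#' single-sample noise excursions), and peak amplitudes are read from the
#' same smoothed copy (a raw single-sample peak is biased upward by the
#' noise maximum). Events separated by less than `merge_ms` (default one
#' decay constant) are merged.
#'
#' @param trace an `epsc_trace` from [gen_trace()], or numeric current (pA,
#'   inward negative) with `rate_hz`.
#' @param rate_hz sampling rate, for bare numeric traces.
#' @param baseline_window_s leading window for baseline estimation (s).
#' @param k_sd detection threshold in baseline-noise SDs.
#' @param amp_min_pA,amp_max_pA amplitude acceptance window (pA).
#' @param smooth_ms moving-average width for detection (ms).
#' @param merge_ms events closer than this are merged (ms).
#' @return an `event_table` (data.frame): `onset_s`, `peak_amp_pA`
#'   (magnitude), `area_pAms`, `duration_ms` (threshold-to-threshold),
#'   `s_stat` = log10(area/duration), `class` (mono/poly at cutoff 1.5).
#'   Attribute `zero_variance_fallback` is TRUE when the baseline SD was
#'   zero and the absolute `amp_min_pA` floor was used instead.
#' @export
detect_minis <- function(trace, rate_hz = NULL, baseline_window_s = 1,
                         k_sd = 3, amp_min_pA = 5, amp_max_pA = 50,
                         smooth_ms = 1, merge_ms = 8) {
  tr <- resolve_trace(trace, rate_hz)
  bs <- baseline_stats(tr$i, tr$rate, baseline_window_s)
  fallback <- FALSE
  thr <- k_sd * bs$sd
  if (bs$sd <= 0) { thr <- amp_min_pA; fallback <- TRUE }

  x <- bs$level - tr$i                      # inward magnitude, >= 0 for events
  k <- max(1L, round(smooth_ms / 1000 * tr$rate))
  xs <- if (k > 1L) stats::filter(x, rep(1 / k, k), sides = 2) else x
  xs[is.na(xs)] <- 0
  ev <- find_events(as.numeric(xs), x, thr, tr$rate, merge_ms,
                    peak_on_smooth = TRUE)
  if (nrow(ev) == 0L) {
    out <- new_event_table(numeric(0), numeric(0), numeric(0), numeric(0))
  } else {
    keep <- ev$peak >= thr & ev$peak >= amp_min_pA & ev$peak <= amp_max_pA
    ev <- ev[keep, , drop = FALSE]
    out <- new_event_table(ev$onset_s, ev$peak, ev$area, ev$duration_ms)
  }
  attr(out, "zero_variance_fallback") <- fallback
  attr(out, "threshold_pA") <- thr
  out
}

# shared event segmentation: contiguous runs of xs > thr, merged when closer
# than merge_ms; area = sum(x)*dt over the run; peak from the smoothed or
# the raw magnitude trace
find_events <- function(xs, x, thr, rate, merge_ms, peak_on_smooth = FALSE) {
  above <- xs > thr
  if (!any(above))
    return(data.frame(onset_s = numeric(0), peak = numeric(0),
                      area = numeric(0), duration_ms = numeric(0)))
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- data.frame(start = starts[r$values], end = ends[r$values])
  gap <- round(merge_ms / 1000 * rate)
  merged <- runs[1, , drop = FALSE]
  if (nrow(runs) > 1) {
    for (j in 2:nrow(runs)) {
      if (runs$start[j] - merged$end[nrow(merged)] <= gap) {
        merged$end[nrow(merged)] <- runs$end[j]
      } else {
        merged <- rbind(merged, runs[j, ])
      }
    }
  }
  dt_ms <- 1000 / rate
  data.frame(
    onset_s = (merged$start - 1) / rate,
    peak = vapply(seq_len(nrow(merged)), function(j) {
      xp <- if (peak_on_smooth) xs else x
      max(xp[merged$start[j]:merged$end[j]])
    }, 0),
    area = vapply(seq_len(nrow(merged)),
                  function(j) sum(pmax(x[merged$start[j]:merged$end[j]], 0)) * dt_ms, 0),
    duration_ms = (merged$end - merged$start + 1) * dt_ms)
}

#' Template-based detection of spontaneous EPSC events
#'
#' Slides a normalized difference-of-exponentials template along the trace
#' and marks events at local maxima of the normalized cross-correlation
#' above `corr_threshold`. Each event's boundaries are then the
#' `k_sd`-SD threshold crossings of the (smoothed) inward magnitude around
#' the correlation peak; overlapping spans are merged, so a burst of
#' overlapping unitary events is reported as one compound event with
#' correspondingly larger area. Area is the magnitude of the current
#' integral between the crossings (pA*ms); duration is the crossing-to-
#' crossing time (ms).
#'
#' @inheritParams detect_minis
#' @param tau_rise_ms,tau_decay_ms template kinetics (ms).
#' @param corr_threshold minimum normalized cross-correlation (0..1].
#' @return an `event_table`; see [detect_minis()].
#' @export
template_detect <- function(trace, rate_hz = NULL, tau_rise_ms = 1,
                            tau_decay_ms = 8, corr_threshold = 0.6,
                            baseline_window_s = 1, k_sd = 3,
                            smooth_ms = 1, merge_ms = 8) {
  tr <- resolve_trace(trace, rate_hz)
  dt_ms <- 1000 / tr$rate
  tmpl <- epsc_kernel((0:ceiling(5 * tau_decay_ms / dt_ms)) * dt_ms,
                      tau_rise_ms, tau_decay_ms)
  m <- length(tmpl)
  n <- length(tr$i)
  if (m > n) stop("template longer than trace")
  bs <- baseline_stats(tr$i, tr$rate, baseline_window_s)
  x <- bs$level - tr$i

  cc <- running_corr(x, tmpl)
  peaks <- local_maxima(cc, corr_threshold, min_sep = round(m / 2))
  if (!length(peaks))
    return(new_event_table(numeric(0), numeric(0), numeric(0), numeric(0)))

  thr <- k_sd * bs$sd
  if (bs$sd <= 0) thr <- .Machine$double.eps
  k <- max(1L, round(smooth_ms / 1000 * tr$rate))
  xs <- if (k > 1L) stats::filter(x, rep(1 / k, k), sides = 2) else x
  xs[is.na(xs)] <- 0
  xs <- as.numeric(xs)

  # event span: contiguous xs > thr region containing/after each corr peak
  spans <- t(vapply(peaks, function(p) {
    seg <- p:min(n, p + m)
    i_pk <- seg[which.max(xs[seg])]
    if (xs[i_pk] <= thr) return(c(NA_real_, NA_real_))
    lo <- i_pk; while (lo > 1 && xs[lo - 1] > thr) lo <- lo - 1
    hi <- i_pk; while (hi < n && xs[hi + 1] > thr) hi <- hi + 1
    c(lo, hi)
  }, numeric(2)))
  spans <- spans[stats::complete.cases(spans), , drop = FALSE]
  if (!nrow(spans))
    return(new_event_table(numeric(0), numeric(0), numeric(0), numeric(0)))
  spans <- unique(as.data.frame(spans))
  names(spans) <- c("lo", "hi")
  spans <- spans[order(spans$lo), , drop = FALSE]
  # merge overlapping spans (compound / poly-synaptic events)
  out <- spans[1, , drop = FALSE]
  if (nrow(spans) > 1) {
    for (j in 2:nrow(spans)) {
      if (spans$lo[j] <= out$hi[nrow(out)]) {
        out$hi[nrow(out)] <- max(out$hi[nrow(out)], spans$hi[j])
      } else out <- rbind(out, spans[j, ])
    }
  }
  onset <- (out$lo - 1) / tr$rate
  peak <- vapply(seq_len(nrow(out)), function(j) max(x[out$lo[j]:out$hi[j]]), 0)
  area <- vapply(seq_len(nrow(out)),
                 function(j) sum(pmax(x[out$lo[j]:out$hi[j]], 0)) * dt_ms, 0)
  dur <- (out$hi - out$lo + 1) * dt_ms
  new_event_table(onset, peak, area, dur)
}

# normalized sliding cross-correlation of x with template (length m);
# value at i corresponds to the window starting at sample i. FFT-based.
running_corr <- function(x, tmpl) {
  n <- length(x); m <- length(tmpl)
  nw <- n - m + 1L
  sxy <- stats::convolve(x, tmpl, type = "open")[m:(m + nw - 1L)]
  ones <- rep(1, m)
  sx  <- stats::convolve(x,  ones, type = "open")[m:(m + nw - 1L)]
  sx2 <- stats::convolve(x^2, ones, type = "open")[m:(m + nw - 1L)]
  st <- sum(tmpl); st2 <- sum(tmpl^2)
  num <- m * sxy - sx * st
  den2 <- pmax(m * sx2 - sx^2, 0) * (m * st2 - st^2)
  cc <- ifelse(den2 > 0, num / sqrt(den2), 0)
  pmin(pmax(cc, -1), 1)
}

local_maxima <- function(cc, threshold, min_sep) {
  n <- length(cc)
  if (n < 3) return(integer(0))
  cand <- which(cc >= threshold &
                  cc >= c(-Inf, cc[-n]) & cc >= c(cc[-1], -Inf))
  if (!length(cand)) return(integer(0))
  keep <- integer(0); last <- -Inf
  for (p in cand) {
    if (p - last >= min_sep) { keep <- c(keep, p); last <- p }
  }
  keep
}

#' Per-event log-ratio statistic log10(area/duration)
#'
#' The classifier statistic for mono- vs poly-synaptic responses:
#' `s = log10(area_pAms / duration_ms)`, i.e. the log10 of the event's mean
#' inward current in pA. Single-synapse responses fall below 1.5; compound
#' poly-synaptic responses above.
#'
#' @param area_pAms event area, magnitude of the current integral (pA*ms, > 0).
#' @param duration_ms event duration (ms, > 0).
#' @return numeric vector of s values.
#' @examples
#' event_statistic(841.4, 100)  # ~0.925
#' @export
event_statistic <- function(area_pAms, duration_ms) {
  if (any(!is.finite(duration_ms)) || any(duration_ms <= 0))
    stop("duration_ms must be finite and > 0")
  if (any(!is.finite(area_pAms)) || any(area_pAms <= 0))
    stop("area_pAms must be finite and > 0")
  log10(area_pAms / duration_ms)
}

#' Classify events as mono- or poly-synaptic
#'
#' @param s_stat numeric vector of log10(area/duration) values.
#' @param cutoff class boundary; `s < cutoff` is mono, `s >= cutoff` poly
#'   (the boundary itself is assigned to poly).
#' @return character vector, `"mono"` or `"poly"`.
#' @export
classify_event <- function(s_stat, cutoff = 1.5) {
  if (any(!is.finite(s_stat))) stop("s_stat must be finite")
  ifelse(s_stat < cutoff, "mono", "poly")
}

#' Summarize an event table over a recording epoch
#'
#' @param events an `event_table`.
#' @param epoch_s epoch length (s, > 0).
#' @return list: `n`, `amp_mean_pA`, `amp_sem_pA`, `freq_hz`
#'   (events/s), `freq_mono_hz`, `freq_poly_hz`, `amp_defined` (FALSE with
#'   a flag when the table is empty).
#' @export
summarize_epoch <- function(events, epoch_s) {
  check_scalar(epoch_s, "epoch_s", positive = TRUE)
  n <- nrow(events)
  mono <- sum(events$class == "mono", na.rm = TRUE)
  poly <- sum(events$class == "poly", na.rm = TRUE)
  list(n = n,
       amp_mean_pA = if (n) mean(events$peak_amp_pA) else NA_real_,
       amp_sem_pA = if (n > 1) sem(events$peak_amp_pA) else NA_real_,
       freq_hz = n / epoch_s,
       freq_mono_hz = mono / epoch_s,
       freq_poly_hz = poly / epoch_s,
       amp_defined = n > 0)
}
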