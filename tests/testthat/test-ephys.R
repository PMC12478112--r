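test_that("flat and too-short traces are handled", {
  expect_equal(nrow(detect_minis(rep(0, 20000), rate_hz = 10000)), 0)
  expect_error(detect_minis(rep(0, 100), rate_hz = 10000), "shorter")
  ev <- detect_minis(rep(0, 20000), rate_hz = 10000)
  expect_true(attr(ev, "zero_variance_fallback"))
})

test_that("injected events are recovered with accurate amplitudes", {
  # 10 well-separated 20-pA events in noise SD 1: all found, none spurious
  rate <- 10000
  k <- synaprune:::epsc_kernel((0:800) / 10, 1, 8)
  for (s in 1:5) {
    set.seed(s)
    x <- rnorm(rate * 12, 0, 1)
    onsets <- (1:10) * rate + 1
    for (o in onsets) x[o + 0:800] <- x[o + 0:800] - 20 * k
    ev <- detect_minis(x, rate_hz = rate)
    expect_equal(nrow(ev), 10)
    expect_true(all(abs(ev$peak_amp_pA - 20) < 2 * 1))
  }
})

test_that("the 5-50 pA amplitude window excludes out-of-range events", {
  # one 4 pA and one 60 pA event, far apart, low noise
  rate <- 10000; n <- rate * 4
  x <- rnorm(n, 0, 0.3)
  k <- synaprune:::epsc_kernel((0:800) / 10, 1, 8)
  x[10000 + 0:800] <- x[10000 + 0:800] - 4 * k
  x[30000 + 0:800] <- x[30000 + 0:800] - 60 * k
  ev <- detect_minis(x, rate_hz = rate)
  expect_equal(nrow(ev), 0)
  # the same events pass with a wider window
  ev2 <- detect_minis(x, rate_hz = rate, amp_min_pA = 1, amp_max_pA = 100)
  expect_equal(nrow(ev2), 2)
})

test_that("all detector outputs obey the k-SD and amplitude-window rules", {
  for (s in 1:5) {
    tr <- gen_trace(trace_spec(duration_s = 30, mini_rate_hz = 1,
                               noise_sd_pA = 1.2), seed = s)
    ev <- detect_minis(tr)
    thr <- attr(ev, "threshold_pA")
    if (nrow(ev)) {
      expect_true(all(ev$peak_amp_pA >= thr))
      expect_true(all(ev$peak_amp_pA >= 5 & ev$peak_amp_pA <= 50))
    }
  }
})

test_that("detection recall is high at SNR 10 with few false positives", {
  # recall on injected events, amp 20 pA vs noise SD 2
  hits <- total <- 0
  for (s in 1:5) {
    tr <- gen_trace(trace_spec(duration_s = 30, mini_rate_hz = 0.4,
                               amp_mean_pA = 20, amp_cv = 0,
                               noise_sd_pA = 2), seed = s)
    ev <- detect_minis(tr)
    d <- outer(tr$events$onset_s, ev$onset_s, function(a, b) abs(a - b))
    hits <- hits + sum(apply(d, 1, min) < 0.01)
    total <- total + nrow(tr$events)
  }
  expect_gte(hits / total, 0.95)

  # false positives on pure noise: at most 1 per 60 s
  fp <- vapply(1:3, function(s) {
    tr <- gen_trace(trace_spec(duration_s = 60, mini_rate_hz = 0,
                               noise_sd_pA = 2), seed = s + 100)
    nrow(detect_minis(tr))
  }, 0)
  expect_lte(mean(fp), 1)
})

test_that("template detection measures a noiseless event exactly", {
  rate <- 10000
  x <- rep(0, rate * 3)
  amp <- 20; tr_ms <- 1; td_ms <- 8
  kt <- (0:1600) / 10
  x[10000 + 0:1600] <- -amp * synaprune:::epsc_kernel(kt, tr_ms, td_ms)
  x <- x + rnorm(length(x), 0, 1e-4)  # non-degenerate baseline
  ev <- template_detect(x, rate_hz = rate, corr_threshold = 0.9)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$peak_amp_pA, amp, tolerance = 0.01)
  # area between crossings approximates the full kernel integral
  quad <- synaprune:::epsc_kernel_area(amp, tr_ms, td_ms)
  expect_equal(ev$area_pAms, quad, tolerance = 0.05 * quad)
  expect_equal(ev$class, "mono")
})

test_that("perfect-correlation threshold yields no events under noise", {
  tr <- gen_trace(trace_spec(duration_s = 10, mini_rate_hz = 1), seed = 2)
  ev <- template_detect(tr, corr_threshold = 1)
  expect_equal(nrow(ev), 0)
  expect_error(template_detect(rep(0, 10), rate_hz = 10000), "template")
})

test_that("overlapping bursts form one compound event with larger area", {
  sp <- trace_spec(duration_s = 20, mini_rate_hz = 0, burst_rate_hz = 0.1,
                   burst_size = 5, burst_jitter_ms = 5, noise_sd_pA = 1)
  tr <- gen_trace(sp, seed = 4)
  ev <- template_detect(tr)
  n_bursts <- length(unique(tr$events$burst_id))
  expect_equal(nrow(ev), n_bursts)
  # compound area exceeds every constituent unitary area
  max_unit <- max(tr$events$area_pAms)
  expect_true(all(ev$area_pAms > max_unit))
})

test_that("the log-ratio statistic behaves as log10 mean current", {
  expect_equal(event_statistic(10, 10), 0)
  expect_equal(event_statistic(841.4, 100), log10(8.414))
  expect_error(event_statistic(10, 0), "duration")
  expect_error(event_statistic(-1, 10), "area")

  # invariance: joint rescaling leaves s unchanged; area alone adds 1
  s0 <- event_statistic(120, 15)
  expect_equal(event_statistic(1200, 150), s0)
  expect_equal(event_statistic(1200, 15), s0 + 1)
})

test_that("classification cutoff assigns the boundary to poly", {
  expect_equal(classify_event(0.93), "mono")
  expect_equal(classify_event(1.5), "poly")
  expect_equal(classify_event(c(0.2, 1.49, 1.51)),
               c("mono", "mono", "poly"))
  expect_error(classify_event(Inf), "finite")
})

test_that("mixed mono/poly populations are classified accurately", {
  sp <- trace_spec(duration_s = 60, mini_rate_hz = 0.4, burst_rate_hz = 0.08,
                   noise_sd_pA = 1.2)
  correct <- total <- 0
  for (s in 1:5) {
    tr <- gen_trace(sp, seed = s)
    ev <- template_detect(tr)
    truth <- tr$events
    burst_onsets <- tapply(truth$onset_s[truth$kind == "burst"],
                           truth$burst_id[truth$kind == "burst"], min)
    for (j in seq_len(nrow(ev))) {
      # ground-truth label: does this event span a burst?
      is_burst <- length(burst_onsets) &&
        any(abs(burst_onsets - ev$onset_s[j]) < 0.02)
      mono_near <- any(abs(truth$onset_s[truth$kind == "mini"] -
                             ev$onset_s[j]) < 0.02)
      if (!is_burst && !mono_near) next
      total <- total + 1
      correct <- correct +
        ((is_burst && ev$class[j] == "poly") ||
           (!is_burst && ev$class[j] == "mono"))
    }
  }
  expect_gte(correct / total, 0.9)
})

test_that("epoch summaries report frequencies per class", {
  ev <- synaprune:::new_event_table(
    onset_s = seq(0, 59.5, length.out = 120),
    peak_amp_pA = rep(12, 120),
    area_pAms = rep(120, 120), duration_ms = rep(12, 120))
  s <- summarize_epoch(ev, 60)
  expect_equal(s$freq_hz, 2)
  expect_equal(s$freq_mono_hz, 2)
  expect_equal(s$amp_mean_pA, 12)

  s0 <- summarize_epoch(synaprune:::new_event_table(numeric(0), numeric(0),
                                                    numeric(0), numeric(0)), 60)
  expect_equal(s0$freq_hz, 0)
  expect_false(s0$amp_defined)
})

test_that("amplitude decrease between epochs mirrors LTD magnitude", {
  # generator means 12 vs 8.4 pA -> ~30% decrease in detected amplitude
  dec <- vapply(1:10, function(s) {
    pre <- detect_minis(gen_trace(trace_spec(duration_s = 30, mini_rate_hz = 1,
                                             amp_mean_pA = 12, amp_cv = 0.2,
                                             noise_sd_pA = 1), seed = s))
    post <- detect_minis(gen_trace(trace_spec(duration_s = 30, mini_rate_hz = 1,
                                              amp_mean_pA = 8.4, amp_cv = 0.2,
                                              noise_sd_pA = 1), seed = s + 50))
    100 * (1 - mean(post$peak_amp_pA) / mean(pre$peak_amp_pA))
  }, 0)
  se <- sd(dec) / sqrt(length(dec))
  expect_lt(abs(mean(dec) - 30), 3 * se + 5)
})
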