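test_that("tracking handles identical, reduced and displaced maps", {
  m0 <- toy_map(c(1, 4, 9, 15))
  tr <- track_spines(m0, m0)
  expect_true(all(tr$fate == "maintained"))

  m3 <- toy_map(c(1, 4, 15))
  tr2 <- track_spines(m0, m3)
  expect_equal(tr2$fate[m0$pos_um == 9], "pruned")
  expect_equal(sum(tr2$fate == "pruned"), 1)

  # displacement beyond the tolerance counts as pruned + new
  m0b <- toy_map(5)
  m3b <- toy_map(5.6)
  tr3 <- track_spines(m0b, m3b, match_tol_um = 0.5)
  expect_equal(tr3$fate, "pruned")
  expect_length(attr(tr3, "new_spines"), 1)
})

test_that("greedy tracking matches the exhaustive assignment on small maps", {
  # oracle: enumerate all one-to-one assignments within tolerance and pick
  # the greedy-by-distance solution
  set.seed(42)
  for (rep in 1:20) {
    n0 <- sample(2:6, 1); n3 <- sample(1:6, 1)
    p0 <- sort(runif(n0, 0, 20)); p3 <- sort(runif(n3, 0, 20))
    m0 <- toy_map(p0, length_um = 21)
    m3 <- toy_map(p3, length_um = 21)
    tr <- track_spines(m0, m3, match_tol_um = 1)
    # oracle greedy
    d <- abs(outer(p0, p3, `-`))
    cand <- which(d <= 1, arr.ind = TRUE)
    cand <- cand[order(d[cand]), , drop = FALSE]
    u0 <- logical(n0); u3 <- logical(n3); match0 <- rep(NA_integer_, n0)
    for (r in seq_len(nrow(cand))) {
      i <- cand[r, 1]; j <- cand[r, 2]
      if (!u0[i] && !u3[j]) { u0[i] <- TRUE; u3[j] <- TRUE; match0[i] <- j }
    }
    expect_identical(tr$fate, ifelse(is.na(match0), "pruned", "maintained"))
  }
})

test_that("uptake intensity recovers spot intensity and clamps at zero", {
  img <- matrix(100, 64, 250)
  expect_equal(as.numeric(uptake_intensity(5, img, background = 100)), 0)

  # synthetic spot at SNR 10: noisy ROI estimate within 5% of the
  # noiseless ROI value
  m <- toy_map(12.5, length_um = 25)
  clean <- gen_puncta_image(m, image_spec(amplitude = 2000, background = 100,
                                          noise_sd = 0),
                            seed = 1, y_jitter_px = 0)$image
  truth <- as.numeric(uptake_intensity(12.5, clean, roi_radius_um = 0.3,
                                       background = 100))
  spec <- image_spec(amplitude = 2000, background = 100, noise_sd = 200)
  rec <- vapply(1:20, function(s) {
    img <- gen_puncta_image(m, spec, seed = s, y_jitter_px = 0)$image
    as.numeric(uptake_intensity(12.5, img, roi_radius_um = 0.3,
                                background = 100))
  }, 0)
  expect_lt(abs(mean(rec) - truth) / truth, 0.05)

  # below-background ROI is clamped and flagged
  dark <- matrix(50, 64, 250)
  u <- uptake_intensity(5, dark, background = 100)
  expect_equal(as.numeric(u), 0)
  expect_true(attr(u, "clamped"))
})

test_that("nearest-neighbor distances match the O(n^2) oracle", {
  expect_true(nearest_neighbor(toy_map(5))$isolated)
  expect_equal(nearest_neighbor(toy_map(c(3, 7.2)))$nn_dist_um, c(4.2, 4.2))

  set.seed(7)
  for (rep in 1:10) {
    m <- gen_spine_map(spine_map_config(length_um = 80), seed = rep)
    if (nrow(m) < 2) next
    nn <- nearest_neighbor(m)
    oracle <- brute_covariates(m)
    expect_equal(nn$nn_dist_um, unname(oracle[, "nn"]))
    expect_equal(mean(nn$nn_dist_um < 4), mean(oracle[, "nn"] < 4))
  }
})

test_that("neighborhood covariates match the brute-force oracle", {
  # 3 neighbors with activities 10k/12k/14k -> mean 12k
  m <- toy_map(c(0, 1, 2, 3), activity = c(1, 10000, 12000, 14000))
  nb <- neighborhood_covariates(m)
  expect_equal(nb$mean_neighbor_activity_au[1], 12000)

  # no neighbors within 5 um -> flagged
  m2 <- toy_map(c(0, 10))
  nb2 <- neighborhood_covariates(m2)
  expect_true(all(nb2$no_neighbor_flag))
  expect_true(all(is.na(nb2$mean_neighbor_activity_au)))

  set.seed(8)
  for (rep in 1:10) {
    m <- gen_spine_map(spine_map_config(length_um = 80), seed = rep + 100)
    if (nrow(m) < 2) next
    nb <- neighborhood_covariates(m)
    oracle <- brute_covariates(m)
    expect_equal(nb$n_neighbors_within_radius, unname(as.integer(oracle[, "n5"])))
    expect_equal(nb$mean_neighbor_activity_au, unname(oracle[, "m5"]))
    expect_equal(nb$n_neighbors_cluster_radius, unname(as.integer(oracle[, "n20"])))
  }
})

test_that("en-passant flags reflect axon contact counts", {
  m <- toy_map(c(1, 3, 5, 8), axon = c("a", "b", "b", "b"))
  ep <- en_passant_flag(m)
  expect_identical(ep$en_passant, c(TRUE, FALSE, FALSE, FALSE))
  expect_identical(ep$axon_contact_count, c(1L, 3L, 3L, 3L))
})

test_that("covariates are invariant to spine relabeling", {
  m <- gen_spine_map(spine_map_config(length_um = 60), seed = 3)
  perm <- sample(nrow(m))
  df <- as.data.frame(m)[perm, ]
  df$spine_id <- sprintf("z%02d", seq_len(nrow(df)))
  m2 <- spine_map(df, attr(m, "length_um"))
  expect_equal(nearest_neighbor(m)$nn_dist_um, nearest_neighbor(m2)$nn_dist_um)
  expect_equal(neighborhood_covariates(m)$n_neighbors_within_radius,
               neighborhood_covariates(m2)$n_neighbors_within_radius)
})

test_that("fate tables partition t0 spines and conserve counts", {
  for (s in 1:5) {
    ds <- gen_fate_dataset(spine_map_config(length_um = 150), prune_config(),
                           seed = s)
    ft <- fate_table(ds$map_t0, ds$map_t3h)
    expect_equal(nrow(ft), nrow(ds$map_t0))
    expect_true(all(ft$fate %in% c("maintained", "pruned")))
    expect_equal(sum(ft$fate == "maintained"), nrow(ds$map_t3h))
    expect_identical(ft$fate, ds$truth$fate)   # tracking recovers truth
  }
})

test_that("matched-control selection follows the windows and is idempotent", {
  # hand-built 8-spine table
  m <- toy_map(pos = c(0, 1, 2, 3, 10, 11, 20, 30),
               activity = c(9000, 9500, 12500, 8200, 11500, 14500, 9900, 5000))
  fate <- c("pruned", "maintained", "maintained", "pruned",
            "maintained", "maintained", "pruned", "maintained")
  ft <- synaprune:::build_fate_table(m, fate)
  # pruned-with-neighbor activities: 9000, 8200 -> center 8600, +/-2000
  sel <- matched_control_selection(ft, "neighbor_activity")
  expect_equal(attr(sel, "pruned_mean_au"), 8600)
  kept_m <- sel$spine_id[sel$fate == "maintained"]
  expect_setequal(kept_m, m$spine_id[2])  # only 9500 lies in [6600, 10600]
  # pruned kept only with a neighbor within 5 um: spines at 0,3 yes; 20 no
  kept_p <- sel$spine_id[sel$fate == "pruned"]
  expect_setequal(kept_p, m$spine_id[c(1, 4)])
  # idempotence
  sel2 <- matched_control_selection(sel, "neighbor_activity")
  expect_identical(as.data.frame(sel2), as.data.frame(sel))

  # neighbor_distance mode keeps all pruned and window-matched maintained
  sel3 <- matched_control_selection(ft, "neighbor_distance")
  expect_equal(sum(sel3$fate == "pruned"), 3)
  expect_true(all(abs(sel3$activity_au[sel3$fate == "maintained"] -
                        attr(sel3, "pruned_mean_au")) <= 2000))

  # maintained activities all outside the window -> only pruned remain
  m4 <- toy_map(c(0, 1, 2), activity = c(1000, 20000, 21000))
  ft4 <- synaprune:::build_fate_table(m4, c("pruned", "maintained", "maintained"))
  sel4 <- matched_control_selection(ft4, "neighbor_activity")
  expect_equal(sum(sel4$fate == "maintained"), 0)

  # empty pruned set warns and returns empty
  ft5 <- synaprune:::build_fate_table(m4, rep("maintained", 3))
  expect_warning(sel5 <- matched_control_selection(ft5), "pruned")
  expect_equal(nrow(sel5), 0)
})

test_that("fate reports summarize composition per fate", {
  m <- toy_map(c(0, 1, 10), activity = c(1, 2, 3), axon = c("a", "b", "c"))
  ft <- synaprune:::build_fate_table(m, c("maintained", "maintained", "pruned"))
  rep_ <- fate_report(ft)
  # the single pruned spine has 0 neighbors within 5 um
  expect_equal(unname(rep_$composition_5um["pruned", "0"]), 100)
  expect_equal(unname(rowSums(rep_$composition_5um)), c(100, 100))
  expect_equal(unname(rowSums(rep_$composition_20um)), c(100, 100))
  expect_error(fate_report(ft[0, ]), "empty")
})
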