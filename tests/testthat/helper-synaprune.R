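# hand-built spine map from positions (and optional activities / axons)
toy_map <- function(pos, activity = NULL, axon = NULL, length_um = NULL) {
  n <- length(pos)
  if (is.null(activity)) activity <- rep(10000, n)
  if (is.null(axon)) axon <- sprintf("ax%02d", seq_len(n))
  if (is.null(length_um)) length_um <- max(pos, 1) + 1
  spine_map(data.frame(spine_id = sprintf("t%02d", seq_len(n)),
                       pos_um = pos, activity_au = activity,
                       axon_id = axon, stringsAsFactors = FALSE),
            length_um = length_um)
}

# greedy nearest-centroid matching of ground truth vs detections (px units)
match_centroids <- function(truth, det, r_px = 2) {
  if (!nrow(det) || !nrow(truth))
    return(list(recall = 0, precision = if (nrow(det)) 0 else NA_real_))
  d <- sqrt(outer(truth$x_px, det$x_px, `-`)^2 +
              outer(truth$y_px, det$y_px, `-`)^2)
  cand <- which(d <= r_px, arr.ind = TRUE)
  cand <- cand[order(d[cand]), , drop = FALSE]
  ut <- logical(nrow(truth)); ud <- logical(nrow(det)); nm <- 0L
  for (r in seq_len(nrow(cand))) {
    i <- cand[r, 1]; j <- cand[r, 2]
    if (!ut[i] && !ud[j]) { ut[i] <- TRUE; ud[j] <- TRUE; nm <- nm + 1L }
  }
  list(recall = nm / nrow(truth), precision = nm / nrow(det))
}

# brute-force O(n^2) neighborhood oracle
brute_covariates <- function(map, r_act = 5, r_clust = 20) {
  n <- nrow(map)
  t(vapply(seq_len(n), function(i) {
    d <- abs(map$pos_um - map$pos_um[i])
    nbr <- which(d < r_act & seq_len(n) != i)
    c(nn = if (n > 1) min(d[-i]) else NA_real_,
      n5 = length(nbr),
      m5 = if (length(nbr)) mean(map$activity_au[nbr]) else NA_real_,
      n20 = sum(d < r_clust & seq_len(n) != i))
  }, numeric(4)))
}
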