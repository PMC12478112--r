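#' Generate a two-timepoint spine dataset with known fates
#'
#' Emulates the two-timepoint live-imaging experiment: draws a t0 spine map,
#' runs the pruning simulator on it, and returns the t0 map, the t3h map
#' (the t0 map minus the pruned spines) and the ground-truth fate table.
#' Deterministic given `(map_config, sim_config, seed)`.
#'
#' @param map_config a [spine_map_config()].
#' @param sim_config a [prune_config()].
#' @param seed integer RNG seed (map and pruning draws are derived from it).
#' @return list with `map_t0`, `map_t3h` (both [spine_map()]s) and `truth`
#'   (the simulator's `fate_table`).
#' @export
gen_fate_dataset <- function(map_config = spine_map_config(),
                             sim_config = prune_config(), seed) {
  map_t0 <- gen_spine_map(map_config, seed = seed)
  if (nrow(map_t0) == 0L)
    return(list(map_t0 = map_t0, map_t3h = map_t0,
                truth = NULL))
  truth <- simulate_pruning(map_t0, sim_config, seed = seed + 500000L)
  keep <- truth$fate == "maintained"
  sp3 <- as.data.frame(map_t0)[keep, , drop = FALSE]
  sp3$present <- rep(TRUE, nrow(sp3))
  map_t3h <- spine_map(sp3, attr(map_t0, "length_um"),
                       attr(map_t0, "dendrite_id"))
  list(map_t0 = map_t0, map_t3h = map_t3h, truth = truth)
}
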