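#' Write / read a spine map as CSV
#'
#' Plain CSV with the spine columns; the dendrite id and length are stored
#' as `# key: value` comment lines at the top of the file.
#'
#' @param map a [spine_map()].
#' @param path file path.
#' @return `write_spine_map` returns `path` invisibly; `read_spine_map`
#'   returns a [spine_map()].
#' @export
write_spine_map <- function(map, path) {
  stopifnot(inherits(map, "spine_map"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# dendrite_id: %s", attr(map, "dendrite_id")),
               sprintf("# length_um: %.10g", attr(map, "length_um"))), con)
  utils::write.csv(as.data.frame(map), con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_spine_map
#' @export
read_spine_map <- function(path) {
  hdr <- readLines(path, n = 2)
  did <- sub("^# dendrite_id: ", "", hdr[1])
  len <- as.numeric(sub("^# length_um: ", "", hdr[2]))
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  spine_map(df, len, did)
}

#' Write / read an EPSC trace as two-column CSV
#'
#' Columns `time_s`, `current_pA`; the sampling rate is recovered from the
#' time column on read.
#'
#' @param trace an `epsc_trace` (ground-truth events are not stored).
#' @param path file path.
#' @return `read_trace_csv` returns a list with `current_pA`, `rate_hz`,
#'   `duration_s` usable by the detectors.
#' @export
write_trace_csv <- function(trace, path) {
  stopifnot(inherits(trace, "epsc_trace"))
  utils::write.csv(data.frame(time_s = trace_time(trace),
                              current_pA = trace$current_pA),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trace_csv
#' @export
read_trace_csv <- function(path) {
  df <- utils::read.csv(path)
  stopifnot(all(c("time_s", "current_pA") %in% names(df)))
  rate <- 1 / stats::median(diff(df$time_s))
  list(current_pA = df$current_pA, rate_hz = rate,
       duration_s = nrow(df) / rate)
}

#' Write / read a single-channel image as 16-bit TIFF
#'
#' Intensities are stored as `round(img) / 65535` (16-bit scale) and
#' rescaled on read, so values must lie in [0, 65535].
#'
#' @param img numeric matrix.
#' @param path file path.
#' @export
write_image_tiff <- function(img, path) {
  stopifnot(is.matrix(img))
  if (min(img) < 0 || max(img) > 65535)
    stop("image values must lie in [0, 65535] for 16-bit TIFF storage")
  tiff::writeTIFF(round(img) / 65535, path, bits.per.sample = 16)
  invisible(path)
}

#' @rdname write_image_tiff
#' @export
read_image_tiff <- function(path) {
  tiff::readTIFF(path) * 65535
}

#' Write / read generator and simulator configurations as YAML
#'
#' @param config a `spine_map_config`, `image_spec`, `trace_spec` or
#'   `prune_config`.
#' @param path file path.
#' @export
write_config_yaml <- function(config, path) {
  cls <- class(config)[1]
  stopifnot(cls %in% c("spine_map_config", "image_spec", "trace_spec",
                       "prune_config"))
  yaml::write_yaml(c(list(.type = cls), unclass(config)), path)
  invisible(path)
}

#' @rdname write_config_yaml
#' @export
read_config_yaml <- function(path) {
  lst <- yaml::read_yaml(path)
  cls <- lst$.type
  lst$.type <- NULL
  ctor <- switch(cls,
                 spine_map_config = spine_map_config,
                 image_spec = image_spec,
                 trace_spec = trace_spec,
                 prune_config = prune_config,
                 stop("unknown config type: ", cls))
  do.call(ctor, lst)
}

#' Write an event table or fate table as CSV
#'
#' @param x an `event_table` or `fate_table`.
#' @param path file path.
#' @export
write_table_csv <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}
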