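#' Read and write snapshot tables
#'
#' Snapshots are delimited text with columns `worm_id`, `time_h`, `load`,
#' `condition` (extra columns, e.g. synthetic ground truth, are preserved).
#' The delimiter is inferred from the extension (`.tsv` = tab, otherwise
#' comma).
#'
#' @param path File path.
#' @param snapshot Snapshot data frame to write.
#' @return `read_snapshot()` returns a validated tibble; `write_snapshot()`
#'   returns `path` invisibly.
#' @export
read_snapshot <- function(path) {
  if (!file.exists(path)) abort(sprintf("snapshot file not found: %s", path))
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  out <- as_tibble(utils::read.table(path, header = TRUE, sep = sep,
                                     stringsAsFactors = FALSE))
  assert_snapshot(out)
  out
}

#' @rdname read_snapshot
#' @export
write_snapshot <- function(snapshot, path) {
  assert_snapshot(snapshot)
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  utils::write.table(snapshot, path, sep = sep, row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read calibration pairs
#'
#' @param path CSV with columns `log_cfu`, `log_gfp`.
#' @return A tibble.
#' @export
read_calibration_pairs <- function(path) {
  if (!file.exists(path)) abort(sprintf("calibration file not found: %s", path))
  out <- as_tibble(utils::read.csv(path))
  if (!all(c("log_cfu", "log_gfp") %in% names(out))) {
    abort("calibration pairs need columns log_cfu, log_gfp")
  }
  out
}

#' Serialize a calibration map to/from JSON
#' @param map A [calibration_map()].
#' @param path File path.
#' @export
write_calibration_json <- function(map, path) {
  stopifnot(inherits(map, "calibration_map"))
  jsonlite::write_json(list(a = map$a, b = map$b, c = map$c, rms = map$rms),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_calibration_json
#' @export
read_calibration_json <- function(path) {
  rec <- jsonlite::read_json(path, simplifyVector = TRUE)
  calibration_map(rec$a, rec$b, rec$c, rms = rec$rms)
}
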