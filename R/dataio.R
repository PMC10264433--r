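# Readers/writers for the package's stable text formats:
#   recordings  -> CSV (time_s, left_force_n, right_force_n[, label])
#   segments    -> CSV (segment_id, start_idx, end_idx, task, skill, surgeon_id)
#   features    -> CSV with the canonical 29-name header
#   manifests / reports -> JSON; run configs -> YAML
# Readers reject silently-corrupting inputs (NaN, overlap, non-uniform time)
# instead of coercing.

#' Construct a force recording
#'
#' @param left,right Per-prong force, newtons.
#' @param fs Sampling rate, Hz (default 20).
#' @param label Optional per-sample "ON"/"OFF" labels.
#' @param time_s Optional time stamps; default a uniform grid from 0.
#' @return Object of class `force_recording`: a data.frame with columns
#'   `time_s`, `left_force_n`, `right_force_n` and optionally `label`,
#'   with the sampling rate in `attr(, "fs")`.
#' @export
force_recording <- function(left, right, fs = 20, label = NULL,
                            time_s = NULL) {
  n <- length(left)
  stopifnot(length(right) == n, n >= 1)
  if (is.null(time_s)) time_s <- (seq_len(n) - 1) / fs
  df <- data.frame(time_s = time_s, left_force_n = left,
                   right_force_n = right)
  if (!is.null(label)) df$label <- label
  structure(df, fs = fs, class = c("force_recording", "data.frame"))
}

#' @export
print.force_recording <- function(x, ...) {
  fs <- attr(x, "fs")
  cat(sprintf("<force_recording> %d samples at %g Hz (%.1f s)%s\n",
              nrow(x), fs, nrow(x) / fs,
              if ("label" %in% names(x)) ", labeled" else ""))
  invisible(x)
}

#' Duration of a recording in seconds
#' @param rec A `force_recording`.
#' @export
recording_duration <- function(rec) nrow(rec) / attr(rec, "fs")

#' Write / read a force recording as CSV
#'
#' The CSV has columns `time_s`, `left_force_n`, `right_force_n` and an
#' optional `label` column. Values round-trip to well below 1e-9 N.
#' `read_recording` validates the schema, rejects NaN forces (naming the
#' first offending row) and requires a uniform time grid at `fs` within
#' 1e-6 s.
#'
#' @param rec A `force_recording`.
#' @param path File path.
#' @param fs Expected sampling rate, Hz.
#' @return `read_recording` returns a `force_recording`.
#' @export
write_recording <- function(rec, path) {
  data.table::fwrite(as.data.frame(rec), path)
  invisible(path)
}

#' @rdname write_recording
#' @export
read_recording <- function(path, fs = 20) {
  df <- as.data.frame(data.table::fread(path))
  need <- c("time_s", "left_force_n", "right_force_n")
  missing_col <- setdiff(need, names(df))
  if (length(missing_col))
    stop_labeled("schema_error", "recording CSV missing column(s): %s",
                 paste(missing_col, collapse = ", "))
  for (col in c("left_force_n", "right_force_n")) {
    bad <- which(!is.finite(df[[col]]))
    if (length(bad))
      stop_labeled("value_error", "non-finite force in column %s at row %d",
                   col, bad[1])
  }
  if (nrow(df) > 1) {
    dt <- diff(df$time_s)
    bad <- which(abs(dt - 1 / fs) > 1e-6)
    if (length(bad))
      stop_labeled("sampling_error",
                   "non-uniform sampling at row %d (step %.8f s, expected %.8f)",
                   bad[1] + 1, dt[bad[1]], 1 / fs)
  }
  force_recording(df$left_force_n, df$right_force_n, fs = fs,
                  label = df[["label"]], time_s = df$time_s)
}

#' Write / read a segment table as CSV
#'
#' Segment indices are 0-based and half-open `[start_idx, end_idx)`.
#' `read_segments` rejects tables with `start >= end` or overlapping
#' segments.
#'
#' @param segments A data.frame with columns `segment_id`, `start_idx`,
#'   `end_idx`, `task`, `skill`, `surgeon_id`.
#' @param path File path.
#' @return `read_segments` returns the validated data.frame (possibly with
#'   zero rows).
#' @export
write_segments <- function(segments, path) {
  data.table::fwrite(segments, path)
  invisible(path)
}

#' @rdname write_segments
#' @export
read_segments <- function(path) {
  df <- as.data.frame(data.table::fread(path))
  need <- c("segment_id", "start_idx", "end_idx", "task", "skill",
            "surgeon_id")
  if (nrow(df) == 0)
    return(stats::setNames(
      as.data.frame(lapply(need, function(x) vector(
        if (x %in% c("segment_id", "start_idx", "end_idx")) "integer"
        else "character"))), need))
  missing_col <- setdiff(need, names(df))
  if (length(missing_col))
    stop_labeled("schema_error", "segment CSV missing column(s): %s",
                 paste(missing_col, collapse = ", "))
  if (any(df$start_idx >= df$end_idx))
    stop_labeled("segment_error", "segment with start_idx >= end_idx at row %d",
                 which(df$start_idx >= df$end_idx)[1])
  o <- order(df$start_idx)
  so <- df[o, ]
  if (nrow(so) > 1 && any(so$start_idx[-1] < so$end_idx[-nrow(so)]))
    stop_labeled("overlap_error", "overlapping segments in table")
  df
}

#' Segment durations in seconds under the half-open index convention
#' @param segments Segment table (see [read_segments()]).
#' @param fs Sampling rate, Hz.
#' @export
segment_durations <- function(segments, fs = 20)
  (segments$end_idx - segments$start_idx) / fs

#' Write / read a dataset manifest as JSON
#' @param manifest Manifest list (see [dataset_manifest()]).
#' @param path File path.
#' @export
write_manifest <- function(manifest, path) {
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) jsonlite::read_json(path, simplifyVector = TRUE)

#' Read a YAML run configuration
#' @param path Path to a YAML file.
#' @export
read_run_config <- function(path) yaml::read_yaml(path)

#' Write a feature table as CSV with the canonical header
#' @param features Feature table from [feature_matrix()].
#' @param path File path.
#' @export
write_features <- function(features, path) {
  data.table::fwrite(features, path)
  invisible(path)
}

#' @rdname write_features
#' @export
read_features <- function(path) {
  df <- as.data.frame(data.table::fread(path, check.names = FALSE))
  missing_col <- setdiff(feature_names(), names(df))
  if (length(missing_col))
    stop_labeled("schema_error", "feature CSV missing column(s): %s",
                 paste(missing_col, collapse = ", "))
  df
}
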