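# Sensor-log and feature-table I/O.
#
# One CSV per (subject, activity): columns t, hip_x, hip_y, hip_z, wrist_x,
# wrist_y, wrist_z, vent, plus a JSON sidecar (same basename, .json) with
# subject_id, activity, intensity and rate.

#' Write one recording as a CSV sensor log with JSON sidecar
#'
#' @param recording A `sensor_recording`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the CSV path.
#' @export
write_recording <- function(recording, dir) {
  stopifnot(inherits(recording, "sensor_recording"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  stem <- sprintf("%s_%s", recording$subject_id, recording$activity)
  csv <- file.path(dir, paste0(stem, ".csv"))
  n <- nrow(recording$channels)
  df <- cbind(t = (seq_len(n) - 1) / recording$rate, recording$channels)
  utils::write.csv(df, csv, row.names = FALSE)
  meta <- list(subject_id = recording$subject_id,
               activity = recording$activity,
               intensity = recording$intensity,
               rate = recording$rate,
               n_samples = n)
  jsonlite::write_json(meta, file.path(dir, paste0(stem, ".json")),
                       auto_unbox = TRUE, digits = NA)
  invisible(csv)
}

#' Read one sensor log (CSV + JSON sidecar) back into a recording
#'
#' @param csv_path Path to the CSV written by [write_recording()].
#' @return A `sensor_recording`.
#' @export
read_recording <- function(csv_path) {
  meta_path <- sub("\\.csv$", ".json", csv_path)
  if (!file.exists(csv_path)) stop("sensor log not found: ", csv_path)
  if (!file.exists(meta_path)) stop("metadata sidecar not found: ", meta_path)
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  df <- utils::read.csv(csv_path)
  missing <- setdiff(channel_names(), names(df))
  if (length(missing) > 0) {
    stop("sensor log ", csv_path, " lacks channel(s): ",
         paste(missing, collapse = ", "))
  }
  if (meta$intensity != intensity_of(meta$activity)) {
    stop("sidecar intensity inconsistent with taxonomy in ", meta_path)
  }
  structure(
    list(subject_id = meta$subject_id, activity = meta$activity,
         intensity = meta$intensity, rate = meta$rate,
         channels = df[, channel_names()]),
    class = "sensor_recording"
  )
}

#' Read all sensor logs in a directory
#'
#' @param dir Directory of CSV/JSON pairs.
#' @return List of `sensor_recording` objects (alphabetical by file name).
#' @export
read_recordings <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.csv$", full.names = TRUE))
  if (length(files) == 0) stop("no sensor logs found in ", dir)
  lapply(files, read_recording)
}

#' Write a feature table to CSV
#'
#' @param table Feature table from [features_table()].
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_features_csv <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' Read a feature table from CSV
#'
#' @param path CSV path written by [write_features_csv()].
#' @param manifest A [feature_manifest()] used to check the columns.
#' @return The feature table data.frame.
#' @export
read_features_csv <- function(path, manifest = feature_manifest()) {
  if (!file.exists(path)) stop("feature table not found: ", path)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("subject_id", "activity", "intensity", "window_index",
              manifest$names)
  missing <- setdiff(needed, names(tab))
  if (length(missing) > 0) {
    stop("feature table lacks columns: ", paste(missing, collapse = ", "))
  }
  tab
}
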