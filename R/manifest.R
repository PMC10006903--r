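# The 64-feature descriptor of a window.
#
# 49 time-domain features: 7 channels x {mean, sd, p10, p25, median, p75,
# p90}; 1 correlation feature between the Euclidean acceleration magnitudes
# of the hip and wrist nodes; 14 frequency-domain features: energy and
# spectral entropy for each of the 6 accelerometer channels, plus the
# dominant (breathing) frequency and spectral energy of the ventilation
# channel.

#' Feature manifest
#'
#' Describes the 64-dimensional window descriptor: the per-channel time
#' statistics, the hip-wrist correlation feature, and the frequency-domain
#' block, together with its tunable parameters.
#'
#' @param K Number of subframes for spectral entropy (default 8).
#' @param breathing_band Search band in Hz for the ventilation dominant
#'   frequency; default `c(0.1, 1.0)` (6-60 breaths/min).
#' @return A `feature_manifest` list with the feature names in canonical
#'   order (`$names`, length 64) and the parameters.
#' @export
feature_manifest <- function(K = 8L, breathing_band = c(0.1, 1.0)) {
  stats_nm <- c("mean", "sd", "p10", "p25", "p50", "p75", "p90")
  accel <- setdiff(channel_names(), "vent")
  nms <- c(
    as.vector(t(outer(channel_names(), stats_nm, paste, sep = "_"))),
    "corr_hip_wrist",
    as.vector(t(outer(accel, c("energy", "entropy"), paste, sep = "_"))),
    "vent_domfreq", "vent_energy"
  )
  stopifnot(length(nms) == 64L)
  structure(
    list(names = nms, stats = stats_nm, K = as.integer(K),
         breathing_band = breathing_band),
    class = "feature_manifest"
  )
}

#' Extract the 64-feature descriptor of one window
#'
#' @param window A `sensor_window`.
#' @param manifest A [feature_manifest()].
#' @return Named numeric vector of length 64, in manifest order. Values are
#'   raw (unnormalised); see [fit_normalization()].
#' @export
extract_features <- function(window, manifest = feature_manifest()) {
  stopifnot(inherits(window, "sensor_window"))
  ch <- window$channels
  for (nm in channel_names()) {
    if (anyNA(ch[[nm]]) || any(!is.finite(ch[[nm]]))) {
      stop("non-finite values in channel '", nm, "'")
    }
  }
  probs <- c(0.10, 0.25, 0.50, 0.75, 0.90)
  time_feats <- unlist(lapply(channel_names(), function(nm) {
    x <- ch[[nm]]
    c(signal_mean(x), sqrt(signal_variance(x)),
      stats::quantile(x, probs, names = FALSE, type = 7))
  }))
  hip_mag <- sqrt(ch$hip_x^2 + ch$hip_y^2 + ch$hip_z^2)
  wrist_mag <- sqrt(ch$wrist_x^2 + ch$wrist_y^2 + ch$wrist_z^2)
  corr <- suppressWarnings(correlation_coefficient(hip_mag, wrist_mag))
  accel <- setdiff(channel_names(), "vent")
  freq_feats <- unlist(lapply(accel, function(nm) {
    x <- ch[[nm]]
    c(signal_energy(x), spectral_entropy(x, manifest$K))
  }))
  vent <- ch$vent
  out <- c(time_feats, corr, freq_feats,
           dominant_frequency(vent, window$rate, manifest$breathing_band),
           signal_energy(vent))
  names(out) <- manifest$names
  out
}

#' Build a feature table from windows
#'
#' One row per window: `subject_id`, `activity`, `intensity`,
#' `window_index`, followed by the 64 raw feature columns.
#'
#' @param windows List of `sensor_window` objects (e.g. from
#'   [segment_all()]).
#' @param manifest A [feature_manifest()].
#' @return A data.frame of `length(windows)` rows and 68 columns.
#' @export
features_table <- function(windows, manifest = feature_manifest()) {
  stopifnot(length(windows) >= 1)
  feats <- t(vapply(windows, extract_features, numeric(64L),
                    manifest = manifest))
  meta <- data.frame(
    subject_id = vapply(windows, `[[`, character(1), "subject_id"),
    activity = vapply(windows, `[[`, character(1), "activity"),
    intensity = vapply(windows, `[[`, character(1), "intensity"),
    window_index = vapply(windows, `[[`, integer(1), "window_index"),
    stringsAsFactors = FALSE
  )
  cbind(meta, as.data.frame(feats))
}

#' Extract the feature matrix from a feature table
#'
#' @param table A data.frame from [features_table()] (or read back from
#'   CSV).
#' @param manifest A [feature_manifest()].
#' @return Numeric matrix, one row per window, 64 manifest columns.
#' @export
instance_features <- function(table, manifest = feature_manifest()) {
  missing <- setdiff(manifest$names, names(table))
  if (length(missing) > 0) {
    stop("feature table lacks columns: ", paste(missing, collapse = ", "))
  }
  as.matrix(table[, manifest$names, drop = FALSE])
}
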