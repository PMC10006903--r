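#' Segment a recording into non-overlapping fixed-length windows
#'
#' Splits the recording into `floor(L / N)` disjoint consecutive windows of
#' `N = floor(window_seconds * rate)` samples, starting at sample 1; a
#' trailing partial segment is discarded.
#'
#' @param recording A `sensor_recording`.
#' @param window_seconds Window length in seconds; must give a window of at
#'   least 2 samples and no longer than the recording.
#' @return List of `sensor_window` objects, each carrying the recording's
#'   labels, subject id, rate and a 1-based `window_index`.
#' @export
#' @examples
#' prof <- subject_profiles(1, seed = 1)
#' rec <- generate_recording(prof[1, ], "T3", duration = 30, rate = 20, seed = 2)
#' length(segment(rec, 5))  # 6 windows
segment <- function(recording, window_seconds) {
  stopifnot(inherits(recording, "sensor_recording"))
  n_win <- floor(window_seconds * recording$rate)
  L <- nrow(recording$channels)
  if (n_win < 2) stop("window length must be at least 2 samples")
  if (n_win > L) {
    stop(sprintf("window of %d samples longer than recording of %d samples",
                 n_win, L))
  }
  count <- L %/% n_win
  lapply(seq_len(count), function(w) {
    rows <- ((w - 1L) * n_win + 1L):(w * n_win)
    structure(
      list(subject_id = recording$subject_id,
           activity = recording$activity,
           intensity = recording$intensity,
           rate = recording$rate,
           window_index = w,
           channels = recording$channels[rows, , drop = FALSE]),
      class = "sensor_window"
    )
  })
}

#' Segment a list of recordings
#'
#' @param recordings List of `sensor_recording` objects.
#' @param window_seconds Window length in seconds.
#' @return Flat list of `sensor_window` objects.
#' @export
segment_all <- function(recordings, window_seconds) {
  unlist(lapply(recordings, segment, window_seconds = window_seconds),
         recursive = FALSE)
}
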