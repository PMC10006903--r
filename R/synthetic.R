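# Synthetic multi-sensor recordings.
#
# Each activity is modelled per body node (hip, wrist, ventilation) as a
# fundamental sinusoid plus a second harmonic, scaled per subject, with
# additive white Gaussian noise. The parameter table encodes the qualitative
# contrasts the recognition method relies on: during sedentary tasks the hip
# trace is far more stable than the wrist trace; mean breathing rate increases
# strictly from sedentary through household and moderate to vigorous; within
# an intensity category the activities overlap in amplitude (so a flat
# ten-way classifier faces confusable classes) but differ in their harmonic
# content, which is scale-invariant and therefore survives per-subject
# amplitude variation. The treadmill activities (T3, T4, T6) form a single
# graded movement continuum that straddles the moderate/vigorous border:
# their intensity is carried mainly by the respiratory channel, which is the
# situation the intensity-first cascade is designed for.

#' Per-activity signal-model parameters
#'
#' Defaults for the synthetic generator. Amplitudes are in g for the
#' accelerometer nodes and arbitrary units for the ventilation channel;
#' frequencies in Hz. `hip_harm` / `wrist_harm` give the amplitude of the
#' second harmonic relative to the fundamental. `breath_rate` is the
#' activity's nominal breathing frequency and `breath_amp` the ventilation
#' oscillation amplitude.
#'
#' @return A data.frame with one row per activity code.
#' @export
activity_model_params <- function() {
  p <- data.frame(
    activity   = c("CW", "FP", "MB", "VA", "C1", "T3", "T4", "T6", "TE", "BA"),
    hip_amp    = c(0.02, 0.03, 0.25, 0.20, 0.45, 0.52, 0.60, 0.68, 0.85, 1.00),
    wrist_amp  = c(0.12, 0.16, 0.45, 0.52, 0.22, 0.30, 0.38, 0.44, 0.80, 0.90),
    hip_freq   = c(0.8,  1.0,  0.9,  1.1,  1.5,  1.7,  1.9,  2.1,  2.4,  2.6),
    wrist_freq = c(2.2,  2.6,  1.2,  1.5,  1.5,  1.7,  1.9,  2.1,  3.2,  3.0),
    hip_harm   = c(0.0,  0.3,  0.1,  0.4,  0.0,  0.25, 0.5,  0.45, 0.2,  0.7),
    wrist_harm = c(0.1,  0.4,  0.1,  0.5,  0.0,  0.25, 0.5,  0.45, 0.6,  0.2),
    breath_rate = c(0.18, 0.20, 0.30, 0.33, 0.42, 0.44, 0.46, 0.60, 0.64, 0.68),
    breath_amp  = c(0.5,  0.5,  1.0,  1.0,  1.5,  1.5,  1.5,  2.4,  2.4,  2.4),
    stringsAsFactors = FALSE
  )
  p$intensity <- intensity_of(p$activity)
  p
}

# Relative amplitude of the x/y/z axes of one accelerometer node; gravity
# (+1 g) is added to the z axis only.
.axis_mix <- c(x = 1.0, y = 0.6, z = 0.35)
.gravity_g <- 1.0

#' Deterministic per-subject variability profiles
#'
#' Draws one profile per subject: log-normal amplitude scale factors per body
#' node (hip, wrist, ventilation), a small additive breathing-rate offset,
#' and the per-channel white-noise standard deviation.
#'
#' @param n_subjects Number of subjects (>= 1).
#' @param seed Integer seed; profiles are a pure function of
#'   `(seed, subject index)`.
#' @param scale_sdlog Log-sd of the per-node amplitude scale factors.
#' @param breath_offset_sd Sd (Hz) of the per-subject breathing-rate offset
#'   (0.005 Hz = 0.3 breaths/min).
#' @param noise_level Per-channel white-noise sd (g / a.u.); >= 0.
#' @return A data.frame with one row per subject: `subject_id`, `hip_scale`,
#'   `wrist_scale`, `vent_scale`, `breath_offset`, `noise_level`.
#' @export
subject_profiles <- function(n_subjects, seed = 1L, scale_sdlog = 0.08,
                             breath_offset_sd = 0.005, noise_level = 0.05) {
  stopifnot(n_subjects >= 1, noise_level >= 0)
  withr::with_seed(as.integer(seed), {
    data.frame(
      subject_id = sprintf("S%03d", seq_len(n_subjects)),
      hip_scale = stats::rlnorm(n_subjects, 0, scale_sdlog),
      wrist_scale = stats::rlnorm(n_subjects, 0, scale_sdlog),
      vent_scale = stats::rlnorm(n_subjects, 0, scale_sdlog),
      breath_offset = stats::rnorm(n_subjects, 0, breath_offset_sd),
      noise_level = noise_level,
      stringsAsFactors = FALSE
    )
  })
}

#' Channel names of a multi-sensor recording
#' @return Character vector of the seven channel names.
#' @export
channel_names <- function() {
  c("hip_x", "hip_y", "hip_z", "wrist_x", "wrist_y", "wrist_z", "vent")
}

#' Generate one labelled multi-sensor recording
#'
#' Simulates one subject performing one activity: seven synchronous channels
#' (hip x/y/z, wrist x/y/z in g; abdominal ventilation in arbitrary units)
#' at a common sampling rate. Accelerometer channels are a fundamental
#' sinusoid plus second harmonic at the activity's node frequency, scaled by
#' the activity amplitude, the axis mix and the subject's node scale factor,
#' with +1 g of gravity on the z axes; the ventilation channel oscillates at
#' the activity breathing rate plus the subject's offset. White Gaussian
#' noise of sd `noise_level` is added to every channel. Phases are drawn
#' uniformly per channel from the recording seed, so the output is a pure
#' function of its arguments.
#'
#' @param subject One row of [subject_profiles()] (data.frame or list).
#' @param activity Activity code (see [activity_taxonomy()]).
#' @param duration Recording length in seconds (> 0).
#' @param rate Sampling rate in Hz (> 0); all channels share it.
#' @param seed Integer seed for phases and noise.
#' @param params Parameter table, by default [activity_model_params()].
#' @return A `sensor_recording`: list with `subject_id`, `activity`,
#'   `intensity`, `rate`, and `channels` (data.frame of
#'   `floor(duration * rate)` rows, columns [channel_names()]).
#' @export
#' @examples
#' prof <- subject_profiles(1, seed = 1)
#' rec <- generate_recording(prof[1, ], "CW", duration = 10, rate = 20, seed = 7)
#' nrow(rec$channels)
generate_recording <- function(subject, activity, duration, rate, seed,
                               params = activity_model_params()) {
  if (!is.numeric(duration) || duration <= 0) stop("duration must be > 0")
  if (!is.numeric(rate) || rate <= 0) stop("rate must be > 0")
  row <- params[params$activity == activity, ]
  if (nrow(row) != 1L) stop("unknown activity code: ", activity)
  subject <- as.list(subject)

  n <- floor(duration * rate)
  if (n < 1) stop("duration * rate must yield at least one sample")
  t <- (seq_len(n) - 1) / rate

  node_tone <- function(amp, freq, harm, scale, phase) {
    amp * scale * (sin(2 * pi * freq * t + phase[1]) +
                     harm * sin(2 * pi * 2 * freq * t + phase[2]))
  }

  withr::with_seed(as.integer(seed), {
    ph <- matrix(stats::runif(14, 0, 2 * pi), nrow = 2)  # 2 phases x 7 channels
    ch <- list()
    for (i in seq_along(.axis_mix)) {
      ax <- names(.axis_mix)[i]
      ch[[paste0("hip_", ax)]] <- node_tone(
        row$hip_amp * .axis_mix[[i]], row$hip_freq, row$hip_harm,
        subject$hip_scale, ph[, i])
      ch[[paste0("wrist_", ax)]] <- node_tone(
        row$wrist_amp * .axis_mix[[i]], row$wrist_freq, row$wrist_harm,
        subject$wrist_scale, ph[, 3 + i])
    }
    ch$hip_z <- ch$hip_z + .gravity_g
    ch$wrist_z <- ch$wrist_z + .gravity_g
    breath_f <- row$breath_rate + subject$breath_offset
    ch$vent <- row$breath_amp * subject$vent_scale *
      sin(2 * pi * breath_f * t + ph[1, 7])
    noise_sd <- subject$noise_level
    if (noise_sd > 0) {
      for (nm in names(ch)) ch[[nm]] <- ch[[nm]] + stats::rnorm(n, 0, noise_sd)
    }
    channels <- as.data.frame(ch[channel_names()])
  })

  structure(
    list(subject_id = subject$subject_id, activity = activity,
         intensity = intensity_of(activity), rate = rate,
         channels = channels),
    class = "sensor_recording"
  )
}

#' @export
print.sensor_recording <- function(x, ...) {
  cat(sprintf("<sensor_recording> subject %s, activity %s (%s), %d samples @ %g Hz\n",
              x$subject_id, x$activity, x$intensity, nrow(x$channels), x$rate))
  invisible(x)
}

#' Generate a synthetic multi-subject cohort
#'
#' Produces one recording per (subject, activity) pair. Subject profiles and
#' per-recording seeds are derived deterministically from `seed`, so the
#' whole cohort is reproducible across sessions.
#'
#' @param n_subjects Number of subjects (>= 1).
#' @param activities Activity codes to record; default all ten.
#' @param duration Seconds per recording; default 300 (5-minute bouts).
#' @param rate Sampling rate in Hz.
#' @param seed Integer master seed.
#' @param noise_level Per-channel white-noise sd passed to the profiles.
#' @return List of `n_subjects * length(activities)` `sensor_recording`
#'   objects, grouped by subject.
#' @export
#' @examples
#' recs <- generate_dataset(2, c("CW", "BA"), duration = 10, rate = 20, seed = 1)
#' length(recs)
generate_dataset <- function(n_subjects, activities = activity_levels(),
                             duration = 300, rate = 20, seed = 1L,
                             noise_level = 0.05) {
  stopifnot(n_subjects >= 1)
  if (length(activities) == 0) stop("activity list must be non-empty")
  intensity_of(activities)  # validates the codes
  profiles <- subject_profiles(n_subjects, seed = seed,
                               noise_level = noise_level)
  base <- (as.integer(seed) %% 100000L) * 10007L
  recs <- vector("list", n_subjects * length(activities))
  k <- 0L
  for (i in seq_len(n_subjects)) {
    for (j in seq_along(activities)) {
      k <- k + 1L
      recs[[k]] <- generate_recording(
        profiles[i, ], activities[j], duration, rate,
        seed = base + k)
    }
  }
  recs
}
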