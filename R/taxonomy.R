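#' Activity taxonomy: ten activity types in four intensity categories
#'
#' The recognition task carries two coupled labels per instance: an activity
#' type (one of ten codes) and the intensity category it belongs to. The
#' intensity is a deterministic function of the type:
#'
#' * sedentary: `CW` (computer work), `FP` (filing paper)
#' * household: `MB` (moving boxes), `VA` (vacuuming)
#' * moderate: `C1` (cycling, 1 kp resistance), `T3` / `T4` (treadmill at
#'   3.0 / 4.0 mph)
#' * vigorous: `T6` (treadmill at 6.0 mph), `TE` (tennis), `BA` (basketball)
#'
#' @return A data.frame with columns `activity` and `intensity` (one row per
#'   activity code, ordered by intensity then activity).
#' @export
#' @examples
#' activity_taxonomy()
activity_taxonomy <- function() {
  data.frame(
    activity = c("CW", "FP", "MB", "VA", "C1", "T3", "T4", "T6", "TE", "BA"),
    intensity = rep(intensity_levels(), times = c(2L, 2L, 3L, 3L)),
    stringsAsFactors = FALSE
  )
}

#' Ordered intensity categories
#'
#' @return Character vector of the four intensity categories in increasing
#'   order of exertion.
#' @export
intensity_levels <- function() {
  c("sedentary", "household", "moderate", "vigorous")
}

#' Ordered activity codes
#'
#' @return Character vector of the ten activity codes, grouped by intensity.
#' @export
activity_levels <- function() {
  activity_taxonomy()$activity
}

#' Look up the intensity category of one or more activity codes
#'
#' @param activity Character vector of activity codes.
#' @return Character vector of intensity categories, same length.
#' @export
#' @examples
#' intensity_of(c("CW", "BA"))
intensity_of <- function(activity) {
  tax <- activity_taxonomy()
  idx <- match(activity, tax$activity)
  if (anyNA(idx)) {
    stop("unknown activity code(s): ",
         paste(unique(activity[is.na(idx)]), collapse = ", "))
  }
  tax$intensity[idx]
}

#' Activities belonging to one intensity category
#'
#' @param intensity One of the four intensity categories.
#' @return Character vector of activity codes in that category.
#' @export
activities_of <- function(intensity) {
  if (!intensity %in% intensity_levels()) {
    stop("unknown intensity category: ", intensity)
  }
  tax <- activity_taxonomy()
  tax$activity[tax$intensity == intensity]
}
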