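#' Pipeline configuration
#'
#' Central configuration for the generate / features / evaluate pipeline,
#' grouped into blocks mirroring the pipeline stages. Any block entry can be
#' overridden via `...` using nested lists, or loaded from a YAML file with
#' [read_config()].
#'
#' @param ... Named nested-list overrides, e.g.
#'   `generator = list(n_subjects = 4)`.
#' @return A `ccm_config` list with blocks:
#' \describe{
#'   \item{generator}{`n_subjects`, `activities`, `duration` (s), `rate`
#'     (Hz), `noise_level`, `seed`.}
#'   \item{features}{`window_seconds`, `K` (entropy subframes),
#'     `breathing_band` (Hz), `subsample_fraction`.}
#'   \item{learner}{`kind` (RF/SMO/KNN), `hyperparameters` (list).}
#'   \item{cascade}{`layer1_vent_only`: restrict the intensity layer to the
#'     ventilation-derived features instead of a random subset.}
#'   \item{evaluation}{`mode` (ccm/flat/both), `n_subjects_eval` (NULL =
#'     all subjects), `seeds`.}
#' }
#' @export
#' @examples
#' cfg <- ccm_config(generator = list(n_subjects = 4, duration = 30))
#' cfg$generator$n_subjects
ccm_config <- function(...) {
  cfg <- list(
    generator = list(
      n_subjects = 10L, activities = activity_levels(), duration = 300,
      rate = 20, noise_level = 0.05, seed = 1L
    ),
    features = list(
      window_seconds = 5, K = 8L, breathing_band = c(0.1, 1.0),
      subsample_fraction = 0.7
    ),
    learner = list(kind = "RF", hyperparameters = list()),
    cascade = list(layer1_vent_only = FALSE),
    evaluation = list(mode = "both", n_subjects_eval = NULL, seeds = 1:10)
  )
  overrides <- list(...)
  unknown <- setdiff(names(overrides), names(cfg))
  if (length(unknown) > 0) {
    stop("unknown config block(s): ", paste(unknown, collapse = ", "))
  }
  for (blk in names(overrides)) {
    cfg[[blk]] <- utils::modifyList(cfg[[blk]], overrides[[blk]])
  }
  validate_config(structure(cfg, class = "ccm_config"))
}

#' Validate a pipeline configuration
#'
#' @param config A `ccm_config`.
#' @return The config, invisibly checked; stops on invalid ranges.
#' @export
validate_config <- function(config) {
  g <- config$generator
  f <- config$features
  if (g$n_subjects < 1) stop("generator$n_subjects must be >= 1")
  if (g$duration <= 0) stop("generator$duration must be > 0")
  if (g$rate <= 0) stop("generator$rate must be > 0")
  if (g$noise_level < 0) stop("generator$noise_level must be >= 0")
  intensity_of(g$activities)
  if (f$window_seconds <= 0) stop("features$window_seconds must be > 0")
  if (f$subsample_fraction <= 0 || f$subsample_fraction > 1) {
    stop("features$subsample_fraction must be in (0, 1]")
  }
  if (f$K < 2) stop("features$K must be >= 2")
  if (length(f$breathing_band) != 2 || f$breathing_band[1] >= f$breathing_band[2]) {
    stop("features$breathing_band must be (f_lo, f_hi) with f_lo < f_hi")
  }
  if (!config$learner$kind %in% c("RF", "SMO", "KNN")) {
    stop("learner$kind must be one of RF, SMO, KNN")
  }
  if (!config$evaluation$mode %in% c("ccm", "flat", "both")) {
    stop("evaluation$mode must be ccm, flat or both")
  }
  config
}

#' Read a configuration from YAML
#'
#' The YAML file holds the same blocks as [ccm_config()]; omitted entries
#' keep their defaults.
#'
#' @param path Path to a YAML config file.
#' @return A validated `ccm_config`.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  do.call(ccm_config, raw)
}

# Manifest implied by a config's feature block.
config_manifest <- function(config) {
  feature_manifest(K = config$features$K,
                   breathing_band = config$features$breathing_band)
}

# Deterministic per-(fold, node) seed derivation. Node indices: 1 = intensity
# layer, 2..5 = per-intensity activity layers, 6 = flat baseline.
node_seed <- function(seed, node_index, fold = 0L) {
  (as.integer(seed) %% 1000003L) + 7919L * as.integer(fold) +
    131L * as.integer(node_index)
}

learner_spec_from_config <- function(config) {
  do.call(base_learner_spec,
          c(list(method = config$learner$kind),
            config$learner$hyperparameters))
}
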