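#' Candidate feature registry
#'
#' The predictor set derived from a graded exercise test (GXT) comprises eight
#' feature families evaluated at each of the three heart-rate levels (85, 90
#' and 100 percent of age-predicted HRmax) plus age, for 25 candidates in
#' total. Within a single level the canonical (level-free) names are used,
#' since models are always fitted within one level.
#'
#' Families:
#' \describe{
#'   \item{hr}{heart rate at the level, beats/min}
#'   \item{time}{exercise time at which the level is reached, min}
#'   \item{vo2_abs}{ACSM-predicted oxygen uptake at the level, mL/min}
#'   \item{vo2_rel}{ACSM-predicted oxygen uptake at the level, mL/kg/min}
#'   \item{slope_speed}{treadmill slope (percent) times speed (km/h)}
#'   \item{slope_speed_time}{slope times speed times exercise time
#'     (the maximal-intensity composite)}
#'   \item{vo2_at_abs}{predicted oxygen uptake at the anaerobic-threshold
#'     surrogate, mL/min}
#'   \item{vo2_at_rel}{the same, mL/kg/min}
#' }
#'
#' @param levels numeric vector of HRmax fractions.
#' @return for `feature_families()`, the eight family names; for
#'   `feature_registry()`, the full 25-name registry with `age` and
#'   level-suffixed family names (e.g. `vo2_abs_85`).
#' @export
feature_families <- function() {
  c("hr", "time", "vo2_abs", "vo2_rel",
    "slope_speed", "slope_speed_time", "vo2_at_abs", "vo2_at_rel")
}

#' @rdname feature_families
#' @export
feature_registry <- function(levels = c(0.85, 0.90, 1.00)) {
  fams <- feature_families()
  c(as.vector(vapply(levels, function(l) {
    paste0(fams, "_", level_label(l))
  }, character(length(fams)))), "age")
}

# 0.85 -> "85", 1 -> "100"
#' @noRd
level_label <- function(level) {
  format(round(level * 100), trim = TRUE)
}

#' @noRd
check_level <- function(level) {
  if (!is.numeric(level) || length(level) != 1L || level <= 0 || level > 1) {
    wp_stop("`level` must be a single fraction in (0, 1]", "wp_invalid_input")
  }
  level
}
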