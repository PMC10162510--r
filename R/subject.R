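#' Subject profile
#'
#' Container for one subject's demographics, graded-exercise-test trajectory
#' and (optionally) measured Wingate outcomes. Invariants are checked at
#' construction: positive age and body mass, strictly increasing trajectory
#' times starting at or after zero, and an `at_time` (anaerobic-threshold
#' surrogate, minutes) inside the trajectory's time range when present.
#'
#' @param subject_id opaque identifier string.
#' @param age years.
#' @param sex `"female"` or `"male"`.
#' @param body_mass kg.
#' @param trajectory data.frame with columns `time` (min), `speed` (km/h),
#'   `slope` (percent grade, 0-100 scale), `hr` (beats/min).
#' @param body_height cm, optional.
#' @param at_time minutes from test start of the anaerobic-threshold
#'   surrogate, optional.
#' @param measured_pp,measured_mp measured Wingate peak / mean power, watts,
#'   optional.
#' @return an object of class `subject_profile`.
#' @export
subject_profile <- function(subject_id, age, sex, body_mass, trajectory,
                            body_height = NULL, at_time = NULL,
                            measured_pp = NULL, measured_mp = NULL) {
  if (!is.character(subject_id) || length(subject_id) != 1L || !nzchar(subject_id)) {
    wp_stop("`subject_id` must be a non-empty string", "wp_invalid_input")
  }
  if (!is.numeric(age) || length(age) != 1L || age <= 0) {
    wp_stop("`age` must be a single positive number (years)", "wp_invalid_input")
  }
  sex <- match.arg(sex, c("female", "male"))
  if (!is.numeric(body_mass) || length(body_mass) != 1L || body_mass <= 0) {
    wp_stop("`body_mass` must be a single positive number (kg)", "wp_invalid_input")
  }
  check_trajectory(trajectory)
  if (!is.null(at_time) && !is.na(at_time)) {
    if (at_time < trajectory$time[1L] || at_time > trajectory$time[nrow(trajectory)]) {
      wp_stop("`at_time` must lie within the trajectory's time range",
              "wp_invalid_input")
    }
  } else {
    at_time <- NULL
  }
  chk_opt <- function(x, nm) {
    if (!is.null(x) && (is.na(x) || !is.numeric(x) || x <= 0)) {
      if (is.null(x) || is.na(x)) return(NULL)
      wp_stop(sprintf("`%s` must be positive when given", nm), "wp_invalid_input")
    }
    x
  }
  structure(list(
    subject_id = subject_id,
    age = age,
    sex = sex,
    body_mass = body_mass,
    body_height = if (!is.null(body_height) && !is.na(body_height)) body_height,
    trajectory = trajectory[, c("time", "speed", "slope", "hr")],
    at_time = at_time,
    measured_pp = chk_opt(if (!is.null(measured_pp) && !is.na(measured_pp)) measured_pp, "measured_pp"),
    measured_mp = chk_opt(if (!is.null(measured_mp) && !is.na(measured_mp)) measured_mp, "measured_mp")
  ), class = "subject_profile")
}

#' @export
print.subject_profile <- function(x, ...) {
  cat(sprintf("<subject_profile %s> %s, age %.0f y, %.1f kg, %d trajectory points\n",
              x$subject_id, x$sex, x$age, x$body_mass, nrow(x$trajectory)))
  invisible(x)
}

# measured outcomes of a cohort as a vector, NA where absent
#' @noRd
cohort_outcome <- function(subjects, outcome = c("pp", "mp")) {
  outcome <- match.arg(outcome)
  field <- if (outcome == "pp") "measured_pp" else "measured_mp"
  vapply(subjects, function(s) s[[field]] %||% NA_real_, numeric(1))
}

#' @noRd
cohort_ids <- function(subjects) {
  vapply(subjects, function(s) s$subject_id, character(1))
}
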