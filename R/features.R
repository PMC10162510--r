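#' Age-predicted maximal heart rate (Tanaka formula)
#'
#' @param age age in years (vectorised); must be non-negative.
#' @return predicted maximal heart rate in beats/min, `208 - 0.7 * age`,
#'   not rounded.
#' @examples
#' tanaka_hrmax(26) # 189.8
#' @export
tanaka_hrmax <- function(age) {
  if (!is.numeric(age) || any(!is.finite(age)) || any(age < 0)) {
    wp_stop("`age` must be finite and non-negative (years)", "wp_invalid_input")
  }
  208 - 0.7 * age
}

#' ACSM running equation for predicted oxygen uptake
#'
#' The American College of Sports Medicine metabolic equation for treadmill
#' running: `VO2 = 0.2 * speed + 0.9 * speed * grade + 3.5`, with speed in
#' metres per minute and grade as a dimensionless fraction (e.g. a 10 percent
#' incline is `grade = 0.1`).
#'
#' @param speed treadmill speed, m/min; non-negative.
#' @param grade incline as a fraction in `[0, 1)`.
#' @return predicted relative oxygen uptake, mL/kg/min.
#' @examples
#' acsm_running_vo2(0, 0)      # 3.5 (resting component)
#' acsm_running_vo2(100, 0.10) # 32.5
#' @export
acsm_running_vo2 <- function(speed, grade) {
  if (!is.numeric(speed) || any(!is.finite(speed)) || any(speed < 0)) {
    wp_stop("`speed` must be finite and non-negative (m/min)", "wp_invalid_input")
  }
  if (!is.numeric(grade) || any(!is.finite(grade)) || any(grade < 0) || any(grade >= 1)) {
    wp_stop("`grade` must be a fraction in [0, 1)", "wp_invalid_input")
  }
  0.2 * speed + 0.9 * speed * grade + 3.5
}

#' Heart rate at a fraction of maximum
#'
#' @param hr_max maximal heart rate, beats/min.
#' @param fraction fraction of HRmax in `(0, 1]`.
#' @return `fraction * hr_max`, beats/min.
#' @export
hr_at_fraction <- function(hr_max, fraction) {
  if (!is.numeric(fraction) || any(fraction <= 0) || any(fraction > 1)) {
    wp_stop("`fraction` must lie in (0, 1]", "wp_invalid_input")
  }
  if (!is.numeric(hr_max) || any(hr_max <= 0)) {
    wp_stop("`hr_max` must be positive", "wp_invalid_input")
  }
  fraction * hr_max
}

#' Locate the first upward crossing of a target heart rate
#'
#' Scans a trajectory (columns `time`, `speed`, `slope`, `hr`) for the first
#' sample at which heart rate reaches `target_hr` and linearly interpolates
#' time, speed and slope at the crossing. If `target_hr` does not exceed the
#' first sample's HR the first point is returned.
#'
#' @param trajectory data.frame with numeric columns `time` (min, strictly
#'   increasing), `speed` (km/h), `slope` (percent grade), `hr` (beats/min).
#' @param target_hr target heart rate, beats/min.
#' @return named list with `time`, `speed`, `slope` at the crossing.
#' @export
locate_hr_crossing <- function(trajectory, target_hr) {
  check_trajectory(trajectory)
  hr <- trajectory$hr
  # absorb representation error (e.g. CSV round trips) at the trajectory top
  if (target_hr > max(hr) && target_hr <= max(hr) * (1 + 1e-8)) {
    target_hr <- max(hr)
  }
  if (target_hr > max(hr)) {
    wp_stop(sprintf(
      "target HR %.1f bpm not reached (trajectory maximum %.1f bpm)",
      target_hr, max(hr)
    ), "wp_level_not_reached")
  }
  if (target_hr <= hr[1L]) {
    return(list(time = trajectory$time[1L], speed = trajectory$speed[1L],
                slope = trajectory$slope[1L]))
  }
  k <- which(hr >= target_hr)[1L]
  # hr[k-1] < target <= hr[k] by construction, so the denominator is positive
  w <- (target_hr - hr[k - 1L]) / (hr[k] - hr[k - 1L])
  interp <- function(col) {
    trajectory[[col]][k - 1L] + w * (trajectory[[col]][k] - trajectory[[col]][k - 1L])
  }
  list(time = interp("time"), speed = interp("speed"), slope = interp("slope"))
}

#' @noRd
check_trajectory <- function(trajectory) {
  need <- c("time", "speed", "slope", "hr")
  if (!is.data.frame(trajectory) || !all(need %in% names(trajectory))) {
    wp_stop("trajectory must be a data.frame with columns time, speed, slope, hr",
            "wp_schema_error")
  }
  if (nrow(trajectory) < 1L) wp_stop("empty trajectory", "wp_schema_error")
  if (any(diff(trajectory$time) <= 0)) {
    wp_stop("trajectory times must be strictly increasing", "wp_schema_error")
  }
  if (trajectory$time[1L] < 0 || any(trajectory$speed < 0) ||
      any(trajectory$slope < 0) || any(trajectory$hr <= 0)) {
    wp_stop("trajectory values out of range (speed, slope >= 0; hr > 0; time >= 0)",
            "wp_schema_error")
  }
  invisible(trajectory)
}

# time at which the treadmill slope first increases: the visible surrogate of
# the protocol's RQ = 1 event, at which gas-exchange tests switch from speed
# to slope increments
#' @noRd
at_surrogate_time <- function(trajectory) {
  ds <- diff(trajectory$slope)
  k <- which(ds > 0)
  if (length(k) == 0L) return(NA_real_)
  trajectory$time[k[1L] + 1L]
}

#' Derive the GXT feature vector for one subject at one HR level
#'
#' Computes age-predicted HRmax, locates the first crossing of
#' `level * HRmax` in the trajectory, and evaluates the candidate predictors
#' there. Speed is converted from km/h to m/min and slope from percent to a
#' fraction before the ACSM equation is applied. Anaerobic-threshold (AT)
#' features use the subject's `at_time` when given, otherwise the time of the
#' first slope increase; if neither exists they are `NA`.
#'
#' @param subject a [subject_profile()].
#' @param level fraction of age-predicted HRmax in `(0, 1]`.
#' @return one-row data.frame with columns `subject_id`, `level`, `hr_max`,
#'   `hr_at_level`, `time_at_level`, `speed_at_level`, `slope_at_level`,
#'   `vo2_rel`, `vo2_abs`, `slope_speed`, `slope_speed_time`, `vo2_at_rel`,
#'   `vo2_at_abs`, `age`.
#' @export
derive_feature_vector <- function(subject, level) {
  stopifnot(inherits(subject, "subject_profile"))
  check_level(level)
  hr_max <- tanaka_hrmax(subject$age)
  target <- hr_at_fraction(hr_max, level)
  cross <- tryCatch(
    locate_hr_crossing(subject$trajectory, target),
    wp_level_not_reached = function(e) {
      wp_stop(sprintf("subject %s: %s", subject$subject_id, conditionMessage(e)),
              "wp_level_not_reached")
    }
  )
  speed_mmin <- cross$speed * 1000 / 60
  grade <- cross$slope / 100
  vo2_rel <- acsm_running_vo2(speed_mmin, grade)
  vo2_abs <- vo2_rel * subject$body_mass

  at_time <- subject$at_time %||% at_surrogate_time(subject$trajectory)
  if (is.na(at_time)) {
    vo2_at_rel <- NA_real_
    vo2_at_abs <- NA_real_
  } else {
    tr <- subject$trajectory
    sp_at <- stats::approx(tr$time, tr$speed, xout = at_time, rule = 2)$y
    sl_at <- stats::approx(tr$time, tr$slope, xout = at_time, rule = 2)$y
    vo2_at_rel <- acsm_running_vo2(sp_at * 1000 / 60, sl_at / 100)
    vo2_at_abs <- vo2_at_rel * subject$body_mass
  }

  data.frame(
    subject_id = subject$subject_id,
    level = level,
    hr_max = hr_max,
    hr_at_level = target,
    time_at_level = cross$time,
    speed_at_level = cross$speed,
    slope_at_level = cross$slope,
    vo2_rel = vo2_rel,
    vo2_abs = vo2_abs,
    slope_speed = cross$slope * cross$speed,
    slope_speed_time = cross$slope * cross$speed * cross$time,
    vo2_at_rel = vo2_at_rel,
    vo2_at_abs = vo2_at_abs,
    age = subject$age,
    stringsAsFactors = FALSE
  )
}

#' Derive the feature table for a cohort
#'
#' @param subjects list of [subject_profile()] objects.
#' @param levels HRmax fractions at which to derive features.
#' @return long data.frame, one row per subject and level (see
#'   [derive_feature_vector()] for columns).
#' @export
derive_features <- function(subjects, levels = c(0.85, 0.90, 1.00)) {
  stopifnot(length(subjects) >= 1L)
  rows <- lapply(subjects, function(s) {
    do.call(rbind, lapply(levels, function(l) derive_feature_vector(s, l)))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Candidate feature matrix at one level
#'
#' Reshapes the long feature table into the per-level candidate matrix used
#' for model fitting, with the canonical family names of
#' [feature_families()] plus `age`.
#'
#' @param features long feature table from [derive_features()].
#' @param level the HR level to extract.
#' @return data.frame with `subject_id` and the nine candidate columns.
#' @export
feature_matrix <- function(features, level) {
  rows <- features[abs(features$level - level) < 1e-9, , drop = FALSE]
  if (nrow(rows) == 0L) {
    wp_stop(sprintf("no rows at level %s in feature table", level), "wp_not_found")
  }
  data.frame(
    subject_id = rows$subject_id,
    hr = rows$hr_at_level,
    time = rows$time_at_level,
    vo2_abs = rows$vo2_abs,
    vo2_rel = rows$vo2_rel,
    slope_speed = rows$slope_speed,
    slope_speed_time = rows$slope_speed_time,
    vo2_at_abs = rows$vo2_at_abs,
    vo2_at_rel = rows$vo2_at_rel,
    age = rows$age,
    stringsAsFactors = FALSE
  )
}

#' Z-score standardisation with reusable statistics
#'
#' Standardises each column to zero mean and unit sample (n-1) standard
#' deviation. When `stats` is `NULL` the means and SDs are computed from `x`
#' (the calibration set) and returned for reuse on test and validation sets.
#'
#' @param x numeric matrix or data.frame of features.
#' @param stats optional list with numeric vectors `mean` and `sd` named by
#'   column.
#' @return list with `z` (standardised matrix) and `stats`.
#' @export
standardize_features <- function(x, stats = NULL) {
  xm <- as.matrix(x)
  if (!is.numeric(xm)) wp_stop("features must be numeric", "wp_invalid_input")
  if (is.null(stats)) {
    mu <- colMeans(xm)
    sdv <- apply(xm, 2L, stats::sd)
    bad <- names(which(!is.finite(sdv) | sdv <= 0))
    if (length(bad)) {
      wp_stop(paste0("degenerate (zero-variance) feature column(s): ",
                     paste(bad, collapse = ", ")), "wp_degenerate_feature")
    }
    stats <- list(mean = mu, sd = sdv)
  } else {
    mu <- stats$mean[colnames(xm)]
    sdv <- stats$sd[colnames(xm)]
    if (anyNA(mu) || anyNA(sdv)) {
      wp_stop("standardisation stats missing for some columns", "wp_invalid_input")
    }
  }
  z <- sweep(sweep(xm, 2L, mu, "-"), 2L, sdv, "/")
  list(z = z, stats = stats)
}
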