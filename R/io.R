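# CSV interchange dialect
#   subjects:   subject_id, age_y, sex, mass_kg, height_cm, at_time_min, pp_w, mp_w
#   trajectory: subject_id, time_min, speed_kmh, slope_pct, hr_bpm
# the last four subject columns are optional; empty cells mean missing

SUBJECT_REQUIRED <- c("subject_id", "age_y", "sex", "mass_kg")
SUBJECT_OPTIONAL <- c("height_cm", "at_time_min", "pp_w", "mp_w")
TRAJECTORY_COLS <- c("subject_id", "time_min", "speed_kmh", "slope_pct", "hr_bpm")

#' @noRd
check_headers <- function(df, required, what, path) {
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    wp_stop(sprintf("%s file '%s' is missing required column(s): %s",
                    what, path, paste(missing_cols, collapse = ", ")),
            "wp_schema_error")
  }
  invisible(df)
}

#' Read a cohort from subjects + trajectory CSV files
#'
#' `read_subjects_csv` reads and validates the demographics table;
#' `read_trajectories_csv` the per-subject treadmill trajectories;
#' `read_cohort` joins them into a list of [subject_profile()] objects.
#' Schema violations (missing headers, non-numeric cells, non-monotone
#' trajectory times) raise classed errors naming the offending column or
#' subject before any computation runs.
#'
#' @param path CSV file path.
#' @return `read_subjects_csv` / `read_trajectories_csv`: validated
#'   data.frames; `read_cohort`: list of `subject_profile`s.
#' @export
read_subjects_csv <- function(path) {
  if (!file.exists(path)) wp_stop(paste0("file not found: ", path), "wp_schema_error")
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  check_headers(df, SUBJECT_REQUIRED, "subjects", path)
  for (col in intersect(c("age_y", "mass_kg", SUBJECT_OPTIONAL), names(df))) {
    v <- df[[col]]
    if (!is.numeric(v) && !all(is.na(v))) {
      bad <- which(!grepl("^\\s*-?[0-9.eE+-]*\\s*$", as.character(v)))
      wp_stop(sprintf("column '%s' has unparseable numeric value(s) at data row(s) %s",
                      col, paste(bad, collapse = ", ")), "wp_schema_error")
    }
    df[[col]] <- as.numeric(v)
  }
  df
}

#' @rdname read_subjects_csv
#' @export
read_trajectories_csv <- function(path) {
  if (!file.exists(path)) wp_stop(paste0("file not found: ", path), "wp_schema_error")
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  check_headers(df, TRAJECTORY_COLS, "trajectory", path)
  for (col in setdiff(TRAJECTORY_COLS, "subject_id")) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    if (anyNA(v)) {
      wp_stop(sprintf("column '%s' has unparseable numeric value(s) at data row(s) %s",
                      col, paste(which(is.na(v)), collapse = ", ")), "wp_schema_error")
    }
    df[[col]] <- v
  }
  df
}

#' @rdname read_subjects_csv
#' @param subjects_path,trajectories_path paths to the two CSV files.
#' @export
read_cohort <- function(subjects_path, trajectories_path) {
  subs <- read_subjects_csv(subjects_path)
  traj <- read_trajectories_csv(trajectories_path)
  opt <- function(row, col) {
    if (col %in% names(subs) && !is.na(row[[col]])) row[[col]] else NULL
  }
  lapply(seq_len(nrow(subs)), function(i) {
    row <- subs[i, ]
    tr <- traj[traj$subject_id == row$subject_id, , drop = FALSE]
    if (nrow(tr) == 0L) {
      wp_stop(paste0("no trajectory rows for subject ", row$subject_id),
              "wp_schema_error")
    }
    subject_profile(
      subject_id = as.character(row$subject_id),
      age = row$age_y, sex = row$sex, body_mass = row$mass_kg,
      trajectory = data.frame(time = tr$time_min, speed = tr$speed_kmh,
                              slope = tr$slope_pct, hr = tr$hr_bpm),
      body_height = opt(row, "height_cm"),
      at_time = opt(row, "at_time_min"),
      measured_pp = opt(row, "pp_w"),
      measured_mp = opt(row, "mp_w")
    )
  })
}

#' Write a cohort to the CSV interchange dialect
#'
#' @param subjects list of [subject_profile()] objects.
#' @param subjects_path,trajectories_path output CSV paths.
#' @return invisibly, the two paths.
#' @export
write_cohort_csv <- function(subjects, subjects_path, trajectories_path) {
  na_if_null <- function(x) if (is.null(x)) NA_real_ else x
  subs <- do.call(rbind, lapply(subjects, function(s) {
    data.frame(subject_id = s$subject_id, age_y = s$age, sex = s$sex,
               mass_kg = s$body_mass,
               height_cm = na_if_null(s$body_height),
               at_time_min = na_if_null(s$at_time),
               pp_w = na_if_null(s$measured_pp),
               mp_w = na_if_null(s$measured_mp),
               stringsAsFactors = FALSE)
  }))
  traj <- do.call(rbind, lapply(subjects, function(s) {
    data.frame(subject_id = s$subject_id,
               time_min = s$trajectory$time, speed_kmh = s$trajectory$speed,
               slope_pct = s$trajectory$slope, hr_bpm = s$trajectory$hr,
               stringsAsFactors = FALSE)
  }))
  utils::write.csv(subs, subjects_path, row.names = FALSE)
  utils::write.csv(traj, trajectories_path, row.names = FALSE)
  invisible(c(subjects_path, trajectories_path))
}

#' Write / read the derived feature table
#'
#' @param features long feature table from [derive_features()].
#' @param path CSV path.
#' @export
write_features_csv <- function(features, path) {
  utils::write.csv(features, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_features_csv
#' @export
read_features_csv <- function(path) {
  if (!file.exists(path)) wp_stop(paste0("file not found: ", path), "wp_schema_error")
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  check_headers(df, c("subject_id", "level", "hr_at_level", "time_at_level",
                      "vo2_rel", "vo2_abs"), "features", path)
  df
}

#' Serialise / restore a fitted power model as JSON
#'
#' The JSON schema mirrors the model object: outcome, level,
#' selected_features, intercept, coefficients, standardization (mean, sd),
#' seed and diagnostics.
#'
#' @param model a `power_model`.
#' @param path JSON file path.
#' @export
write_model_json <- function(model, path) {
  stopifnot(inherits(model, "power_model"))
  d <- model$diagnostics
  jsonlite::write_json(list(
    outcome = model$outcome,
    level = model$level,
    selected_features = model$selected_features,
    intercept = model$intercept,
    coefficients = as.list(model$coefficients),
    standardization = list(mean = as.list(model$standardization$mean),
                           sd = as.list(model$standardization$sd)),
    seed = model$seed,
    diagnostics = list(
      train_adj_r2_path = d$train_adj_r2_path,
      test_spearman = d$test_spearman,
      validation_spearman = d$validation_spearman,
      validation_rmse = d$validation_rmse,
      pct_error_mean = d$pct_error_mean,
      pct_error_sd = d$pct_error_sd
    )
  ), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_model_json
#' @export
read_model_json <- function(path) {
  m <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  structure(list(
    outcome = m$outcome,
    level = m$level,
    selected_features = unlist(m$selected_features),
    intercept = m$intercept,
    coefficients = unlist(m$coefficients),
    standardization = list(mean = unlist(m$standardization$mean),
                           sd = unlist(m$standardization$sd)),
    seed = m$seed,
    diagnostics = m$diagnostics
  ), class = "power_model")
}
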