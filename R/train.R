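#' Train a power-prediction model on a cohort
#'
#' Full training pipeline for one outcome (Wingate peak or mean power) at one
#' heart-rate level: derive candidate features, split the cohort into
#' calibration (40%), test (30%) and validation (30%) subsets stratified on
#' ACSM-predicted VO2max, standardise candidates with calibration statistics,
#' run greedy forward selection, and evaluate the selected equation on the
#' held-out validation subset (Spearman rho, RMSE) plus a resampled
#' percent-error distribution over the whole cohort.
#'
#' @param subjects list of [subject_profile()] objects with measured outcomes.
#' @param outcome `"pp"` (peak power) or `"mp"` (mean power).
#' @param level fraction of age-predicted HRmax (0.85, 0.90 or 1.00 in the
#'   standard protocol).
#' @param seed root seed; split and resampling use named substreams of it.
#' @param fractions calibration/test/validation fractions.
#' @param n_bins stratification quantile bins.
#' @param min_pct_improvement greedy termination threshold, percent.
#' @param max_features cap on selected features.
#' @param n_error_reps resampled validation sets for the percent-error
#'   distribution.
#' @param error_frac fraction of the cohort per resampled validation set.
#' @param features optional precomputed long feature table (from
#'   [derive_features()]); derived from `subjects` when `NULL`.
#' @return object of class `power_model`.
#' @export
train_power_model <- function(subjects, outcome = c("pp", "mp"), level = 0.85,
                              seed = 1L, fractions = c(0.4, 0.3, 0.3),
                              n_bins = 4L, min_pct_improvement = 0.5,
                              max_features = 10L, n_error_reps = 100L,
                              error_frac = 0.3, features = NULL) {
  outcome <- match.arg(outcome)
  check_level(level)
  y_all <- cohort_outcome(subjects, outcome)
  if (anyNA(y_all)) {
    wp_stop(sprintf("measured %s missing for %d subject(s)",
                    toupper(outcome), sum(is.na(y_all))), "wp_invalid_input")
  }
  ids <- cohort_ids(subjects)

  levels_needed <- sort(unique(c(level, 1.00)))
  if (is.null(features)) features <- derive_features(subjects, levels = levels_needed)
  fm <- feature_matrix(features, level)
  fm <- fm[match(ids, fm$subject_id), , drop = FALSE]
  X_raw <- as.matrix(fm[, setdiff(names(fm), "subject_id")])
  rownames(X_raw) <- ids

  # drop candidates unavailable for part of the cohort (e.g. AT features
  # when no anaerobic-threshold surrogate exists)
  keep <- colnames(X_raw)[colSums(is.na(X_raw)) == 0L]
  dropped <- setdiff(colnames(X_raw), keep)
  if (length(dropped)) {
    message("dropping candidate feature(s) with missing values: ",
            paste(dropped, collapse = ", "))
  }
  X_raw <- X_raw[, keep, drop = FALSE]

  # stratify on predicted VO2max (relative VO2 at 100% of HRmax)
  strat <- feature_matrix(features, 1.00)
  strat <- stats::setNames(strat$vo2_rel, strat$subject_id)[ids]
  split <- stratified_split(strat, fractions = fractions, n_bins = n_bins,
                           seed = substream_seed(seed, "split"))

  i_cal <- match(split$calibration_ids, ids)
  i_test <- match(split$test_ids, ids)
  i_val <- match(split$validation_ids, ids)

  std <- standardize_features(X_raw[i_cal, , drop = FALSE])
  z_all <- standardize_features(X_raw, stats = std$stats)$z

  sel <- greedy_select(
    std$z, y_all[i_cal],
    X_test = z_all[i_test, , drop = FALSE], y_test = y_all[i_test],
    min_pct_improvement = min_pct_improvement, max_features = max_features
  )

  model <- structure(list(
    outcome = outcome,
    level = level,
    selected_features = sel$selected_features,
    intercept = sel$intercept,
    coefficients = sel$coefficients,
    standardization = list(
      mean = std$stats$mean[sel$selected_features],
      sd = std$stats$sd[sel$selected_features]
    ),
    split = split,
    seed = as.integer(seed),
    diagnostics = list(
      train_adj_r2_path = sel$train_adj_r2_path,
      test_spearman = sel$test_spearman
    )
  ), class = "power_model")

  pred_val <- predict_from_matrix(model, X_raw[i_val, , drop = FALSE])
  val_rho <- spearman_rho(y_all[i_val], pred_val)
  err <- validation_error_distribution(
    predict_fun = function(idx) predict_from_matrix(model, X_raw[idx, , drop = FALSE]),
    y_pool = y_all, n_reps = n_error_reps, frac = error_frac,
    seed = substream_seed(seed, "error-reps")
  )

  model$diagnostics$validation_spearman <- val_rho
  model$diagnostics$validation_rmse <- sqrt(mean((y_all[i_val] - pred_val)^2))
  model$diagnostics$pct_error_mean <- err$mean
  model$diagnostics$pct_error_sd <- err$sd
  model
}

# predict watts from a raw-scale feature matrix containing (at least) the
# model's selected columns
#' @noRd
predict_from_matrix <- function(model, X_raw) {
  feats <- model$selected_features
  missing_cols <- setdiff(feats, colnames(X_raw))
  if (length(missing_cols)) {
    wp_stop(paste0("missing required feature(s): ",
                   paste(missing_cols, collapse = ", ")), "wp_not_found")
  }
  z <- sweep(sweep(X_raw[, feats, drop = FALSE], 2L,
                   model$standardization$mean, "-"),
             2L, model$standardization$sd, "/")
  drop(model$intercept + z %*% model$coefficients)
}

#' Predict Wingate power for new subjects
#'
#' @param object a `power_model`.
#' @param newdata list of [subject_profile()] objects, a long feature table
#'   from [derive_features()], or a raw-scale candidate matrix.
#' @param ... unused.
#' @return named numeric vector of predicted watts.
#' @export
predict.power_model <- function(object, newdata, ...) {
  if (is.list(newdata) && !is.data.frame(newdata) &&
      all(vapply(newdata, inherits, logical(1), "subject_profile"))) {
    newdata <- derive_features(newdata, levels = object$level)
  }
  if (is.data.frame(newdata) && "level" %in% names(newdata)) {
    fm <- feature_matrix(newdata, object$level)
    X <- as.matrix(fm[, setdiff(names(fm), "subject_id")])
    rownames(X) <- fm$subject_id
  } else {
    X <- as.matrix(newdata)
  }
  predict_from_matrix(object, X)
}

#' @export
print.power_model <- function(x, ...) {
  cat(sprintf("<power_model> %s at %d%% of age-predicted HRmax\n",
              toupper(x$outcome), round(x$level * 100)))
  terms <- paste(sprintf("%+.4g*%s", x$coefficients, names(x$coefficients)),
                 collapse = " ")
  cat(sprintf("  watts = %.4g %s   (standardised features)\n", x$intercept, terms))
  d <- x$diagnostics
  if (!is.null(d$validation_spearman)) {
    cat(sprintf("  validation: rho = %.3f (p = %.2g), RMSE = %.1f W, %%error = %.1f +/- %.1f\n",
                d$validation_spearman$rho, d$validation_spearman$p_value,
                d$validation_rmse, d$pct_error_mean, d$pct_error_sd))
  }
  invisible(x)
}
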