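#' Run configuration for the end-to-end pipeline
#'
#' @param levels HRmax fractions to model.
#' @param outcomes outcomes to model (`"pp"`, `"mp"`).
#' @param seed root seed; every stage draws a named substream from it and the
#'   seed is recorded in every output artifact.
#' @param fractions calibration/test/validation split fractions.
#' @param n_bins stratification bins.
#' @param min_pct_improvement greedy termination threshold, percent.
#' @param n_error_reps resampled validation sets for percent error.
#' @param error_frac fraction of the cohort per resampled validation set.
#' @param out_dir optional output directory for model JSONs, feature CSV and
#'   the run report.
#' @return list of class `run_config`.
#' @export
run_config <- function(levels = c(0.85, 0.90, 1.00), outcomes = c("pp", "mp"),
                       seed = 1L, fractions = c(0.4, 0.3, 0.3), n_bins = 4L,
                       min_pct_improvement = 0.5, n_error_reps = 100L,
                       error_frac = 0.3, out_dir = NULL) {
  if (abs(sum(fractions) - 1) > 1e-8) {
    wp_stop("split fractions must sum to 1", "wp_invalid_input")
  }
  structure(list(
    levels = levels, outcomes = match.arg(outcomes, several.ok = TRUE),
    seed = as.integer(seed), fractions = fractions, n_bins = as.integer(n_bins),
    min_pct_improvement = min_pct_improvement,
    n_error_reps = as.integer(n_error_reps), error_frac = error_frac,
    out_dir = out_dir
  ), class = "run_config")
}

#' Run the full modelling pipeline on a cohort
#'
#' Derives features once, then trains one model per (outcome, level) cell and
#' assembles a machine-readable report mirroring the layout of the published
#' result tables: selected equation, validation Spearman rho and p, RMSE and
#' resampled percent error (mean +/- SD) per cell. When `config$out_dir` is
#' set, writes `features.csv`, one `model_<outcome>_<level>.json` per cell
#' and `report.json`; every artifact embeds the seed and a configuration
#' hash.
#'
#' @param subjects list of [subject_profile()] objects with measured
#'   outcomes.
#' @param config a [run_config()].
#' @return list of class `run_report` with `models` (named list of
#'   `power_model`s), `cells` (data.frame of per-cell diagnostics), `seed`,
#'   `config_hash`.
#' @export
run_pipeline <- function(subjects, config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  levels_all <- sort(unique(c(config$levels, 1.00)))
  features <- derive_features(subjects, levels = levels_all)
  hash <- config_hash(config[setdiff(names(config), "out_dir")])

  models <- list()
  cells <- list()
  for (outcome in config$outcomes) {
    for (level in config$levels) {
      key <- sprintf("%s_%d", outcome, round(level * 100))
      model <- tryCatch(
        train_power_model(
          subjects, outcome = outcome, level = level, seed = config$seed,
          fractions = config$fractions, n_bins = config$n_bins,
          min_pct_improvement = config$min_pct_improvement,
          max_features = 10L, n_error_reps = config$n_error_reps,
          error_frac = config$error_frac, features = features
        ),
        wantpower_error = function(e) {
          wp_stop(sprintf("stage fit(%s): %s", key, conditionMessage(e)),
                  class(e)[1L])
        }
      )
      models[[key]] <- model
      d <- model$diagnostics
      cells[[key]] <- data.frame(
        outcome = outcome, level = level,
        n_features = length(model$selected_features),
        equation = paste0(
          format(model$intercept, digits = 6), " ",
          paste(sprintf("%+.6g*z(%s)", model$coefficients,
                        names(model$coefficients)), collapse = " ")),
        validation_rho = d$validation_spearman$rho,
        validation_p = d$validation_spearman$p_value,
        validation_rmse = d$validation_rmse,
        pct_error_mean = d$pct_error_mean,
        pct_error_sd = d$pct_error_sd,
        stringsAsFactors = FALSE
      )
    }
  }
  cells <- do.call(rbind, cells)
  rownames(cells) <- NULL

  report <- structure(list(
    models = models, cells = cells,
    seed = config$seed, config_hash = hash
  ), class = "run_report")

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    write_features_csv(features, file.path(config$out_dir, "features.csv"))
    for (key in names(models)) {
      write_model_json(models[[key]],
                       file.path(config$out_dir, paste0("model_", key, ".json")))
    }
    jsonlite::write_json(list(
      seed = config$seed, config_hash = hash,
      cells = cells
    ), file.path(config$out_dir, "report.json"),
    auto_unbox = TRUE, digits = NA, dataframe = "rows")
  }
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("<run_report> seed %d, config %s\n", x$seed, x$config_hash))
  df <- x$cells
  df$equation <- NULL
  print(df, row.names = FALSE, digits = 3)
  invisible(x)
}
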