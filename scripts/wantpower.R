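#!/usr/bin/env Rscript
# Umbrella command-line interface over the wantpower package.
#
#   Rscript scripts/wantpower.R simulate --seed 1 --n-female 40 --n-male 53 --out-prefix data/cohort
#   Rscript scripts/wantpower.R derive   --subjects S.csv --trajectories T.csv --out features.csv
#   Rscript scripts/wantpower.R fit      --subjects S.csv --trajectories T.csv \
#                                        --outcome pp --level 85 --seed 1 --out model.json
#   Rscript scripts/wantpower.R predict  --subjects S.csv --trajectories T.csv \
#                                        --model model.json --out predictions.csv
#   Rscript scripts/wantpower.R evaluate --subjects S.csv --trajectories T.csv \
#                                        --model model.json --reps 100 --seed 1
#   Rscript scripts/wantpower.R run      --subjects S.csv --trajectories T.csv \
#                                        --seed 1 --out-dir results/
#
# Exit codes: 0 success, 2 schema/input error, 3 numeric or degeneracy error.

suppressPackageStartupMessages(library(wantpower))

argv <- commandArgs(trailingOnly = TRUE)
if (length(argv) < 1L) {
  cat("usage: wantpower.R <simulate|derive|fit|predict|evaluate|run> [options]\n")
  quit(status = 2)
}
cmd <- argv[1L]
argv <- argv[-1L]

opt <- function(flag, default = NULL) {
  i <- which(argv == paste0("--", flag))
  if (length(i) == 1L && i < length(argv)) argv[i + 1L] else default
}
opt_num <- function(flag, default = NULL) {
  v <- opt(flag)
  if (is.null(v)) default else as.numeric(v)
}

fail <- function(e) {
  cat("error:", conditionMessage(e), "\n", file = stderr())
  schema <- inherits(e, "wp_schema_error") || inherits(e, "wp_invalid_input") ||
    inherits(e, "wp_not_found")
  quit(status = if (schema) 2 else 3)
}

load_cohort <- function() {
  read_cohort(opt("subjects"), opt("trajectories"))
}

result <- tryCatch(switch(
  cmd,
  simulate = {
    cfg <- cohort_config(
      n_female = opt_num("n-female", 40), n_male = opt_num("n-male", 53),
      noise_sd = opt_num("noise-sd", 40)
    )
    seed <- as.integer(opt_num("seed", 1))
    co <- simulate_cohort(cfg, seed = seed)
    prefix <- opt("out-prefix", "cohort")
    dir.create(dirname(prefix), recursive = TRUE, showWarnings = FALSE)
    write_cohort_csv(co, paste0(prefix, "_subjects.csv"),
                     paste0(prefix, "_trajectory.csv"))
    truth <- attr(co, "truth")
    jsonlite::write_json(
      list(seed = seed, planted = truth$planted,
           planted_level = truth$planted_level, noise_sd = truth$noise_sd),
      paste0(prefix, "_truth.json"), auto_unbox = TRUE, digits = NA)
    cat("wrote", paste0(prefix, "_{subjects,trajectory}.csv"), "and truth.json\n")
  },
  derive = {
    feats <- derive_features(load_cohort())
    write_features_csv(feats, opt("out", "features.csv"))
    cat("wrote", opt("out", "features.csv"), "\n")
  },
  fit = {
    m <- train_power_model(
      load_cohort(),
      outcome = tolower(opt("outcome", "pp")),
      level = opt_num("level", 85) / 100,
      seed = as.integer(opt_num("seed", 1)),
      min_pct_improvement = opt_num("min-improvement", 0.5),
      n_error_reps = as.integer(opt_num("reps", 100))
    )
    print(m)
    write_model_json(m, opt("out", "model.json"))
    cat("wrote", opt("out", "model.json"), "\n")
  },
  predict = {
    m <- read_model_json(opt("model"))
    co <- load_cohort()
    pred <- predict(m, co)
    out <- opt("out", "predictions.csv")
    utils::write.csv(data.frame(
      subject_id = vapply(co, function(s) s$subject_id, character(1)),
      level = m$level, outcome = m$outcome,
      predicted_w = as.numeric(pred),
      warning = ifelse(pred <= 0, "non-positive prediction", "")
    ), out, row.names = FALSE)
    cat("wrote", out, "\n")
  },
  evaluate = {
    m <- read_model_json(opt("model"))
    co <- load_cohort()
    y <- vapply(co, function(s) {
      v <- if (m$outcome == "pp") s$measured_pp else s$measured_mp
      if (is.null(v)) NA_real_ else v
    }, numeric(1))
    if (anyNA(y)) stop("measured outcomes required for evaluation")
    pred <- predict(m, co)
    rho <- spearman_rho(y, pred)
    err <- validation_error_distribution(
      function(idx) pred[idx], y,
      n_reps = as.integer(opt_num("reps", 100)),
      seed = as.integer(opt_num("seed", 1)))
    rep <- list(outcome = m$outcome, level = m$level, n = length(y),
                spearman_rho = rho$rho, p_value = rho$p_value,
                rmse_w = sqrt(mean((y - pred)^2)),
                pct_error_mean = err$mean, pct_error_sd = err$sd)
    cat(sprintf("%s @ %d%%: rho = %.3f (p = %.2g), RMSE = %.1f W, %%error = %.1f +/- %.1f\n",
                toupper(rep$outcome), round(rep$level * 100), rep$spearman_rho,
                rep$p_value, rep$rmse_w, rep$pct_error_mean, rep$pct_error_sd))
    if (!is.null(opt("out"))) {
      jsonlite::write_json(rep, opt("out"), auto_unbox = TRUE, digits = NA)
      cat("wrote", opt("out"), "\n")
    }
  },
  run = {
    cfg <- run_config(seed = as.integer(opt_num("seed", 1)),
                      n_error_reps = as.integer(opt_num("reps", 100)),
                      out_dir = opt("out-dir", "results"))
    rep <- run_pipeline(load_cohort(), cfg)
    print(rep)
    cat("artifacts in", cfg$out_dir, "\n")
  },
  {
    cat("unknown command:", cmd, "\n", file = stderr())
    quit(status = 2)
  }
), wantpower_error = fail, error = fail)

invisible(result)
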