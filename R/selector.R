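#' Stratified three-way split of a cohort
#'
#' Splits subjects into calibration, test and validation subsets at the given
#' fractions (default 40/30/30), stratified on a continuous covariate —
#' conventionally the ACSM-predicted VO2max — so that all exercise-capacity
#' levels are represented in each subset.
#'
#' Subjects are ranked into `n_bins` quantile bins of `strat_values`, shuffled
#' within bins, and group labels are assigned along that order by a
#' largest-deficit sequencing against Hamilton (largest-remainder) global
#' quotas. This makes the three sets disjoint and exhaustive with each size
#' within one subject of `fraction * n`, for every seed, while keeping each
#' bin's composition close to the target fractions.
#'
#' @param strat_values numeric vector (one per subject) to stratify on;
#'   names, when present, are used as subject ids.
#' @param fractions length-3 numeric summing to 1:
#'   (calibration, test, validation).
#' @param n_bins number of quantile bins (1 = simple random split).
#' @param seed integer seed; the assignment is deterministic given
#'   `(strat_values, fractions, n_bins, seed)`.
#' @return list of class `split_assignment` with `calibration_ids`,
#'   `test_ids`, `validation_ids` (integer indices, or names when supplied),
#'   `seed` and `fractions`.
#' @export
stratified_split <- function(strat_values, fractions = c(0.4, 0.3, 0.3),
                             n_bins = 4, seed = 1L) {
  n <- length(strat_values)
  if (n < 10L) wp_stop("need at least 10 subjects to populate three subsets",
                       "wp_invalid_input")
  if (length(fractions) != 3L || abs(sum(fractions) - 1) > 1e-8 || any(fractions <= 0)) {
    wp_stop("`fractions` must be three positive numbers summing to 1",
            "wp_invalid_input")
  }
  ids <- names(strat_values) %||% seq_len(n)

  with_local_seed(seed, {
    n_bins <- max(1L, min(as.integer(n_bins), n))
    if (n_bins > 1L) {
      qs <- stats::quantile(strat_values, probs = seq(0, 1, length.out = n_bins + 1L))
      bin <- cut(strat_values, breaks = unique(qs), include.lowest = TRUE,
                 labels = FALSE)
    } else {
      bin <- rep(1L, n)
    }
    ord <- order(bin, stats::runif(n))

    sizes <- hamilton_apportion(n, fractions)
    labels <- deficit_sequence(n, fractions, sizes)

    list_ids <- split(ids[ord], labels)
    structure(list(
      calibration_ids = unname(list_ids[["1"]] %||% ids[0]),
      test_ids        = unname(list_ids[["2"]] %||% ids[0]),
      validation_ids  = unname(list_ids[["3"]] %||% ids[0]),
      seed = as.integer(seed),
      fractions = fractions
    ), class = "split_assignment")
  })
}

# largest-remainder apportionment of n seats at the given fractions;
# every size lies within 1 of fraction * n
#' @noRd
hamilton_apportion <- function(n, fractions) {
  q <- n * fractions
  base <- floor(q)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(q - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

# assign group labels position by position, always to the group with the
# largest running deficit (fraction * i - assigned) among groups below quota;
# yields a quasi-periodic pattern balanced in every window
#' @noRd
deficit_sequence <- function(n, fractions, sizes) {
  assigned <- integer(3)
  labels <- integer(n)
  for (i in seq_len(n)) {
    deficit <- fractions * i - assigned
    deficit[assigned >= sizes] <- -Inf
    g <- which.max(deficit)
    labels[i] <- g
    assigned[g] <- assigned[g] + 1L
  }
  labels
}

#' Ordinary least squares fit
#'
#' Thin wrapper over base R's QR least squares (`lm.fit`) returning the
#' coefficient vector for a design with an explicit intercept column.
#'
#' @param design numeric n-by-(p+1) matrix whose first column is the
#'   intercept.
#' @param y numeric response (watts, for power outcomes).
#' @return coefficient vector of length p+1.
#' @export
fit_ols <- function(design, y) {
  design <- as.matrix(design)
  if (nrow(design) <= ncol(design)) {
    wp_stop("need more observations than coefficients", "wp_invalid_input")
  }
  fit <- stats::lm.fit(design, y)
  if (fit$rank < ncol(design)) {
    wp_stop("singular design matrix (rank-deficient)", "wp_singular_design")
  }
  fit$coefficients
}

#' Adjusted coefficient of determination
#'
#' `1 - (1 - R^2) * (n - 1) / (n - p - 1)`; with `p = 0` this reduces to the
#' plain R-squared.
#'
#' @param y observed values.
#' @param y_hat fitted values.
#' @param p number of predictors (excluding the intercept).
#' @return adjusted R-squared.
#' @export
adjusted_r2 <- function(y, y_hat, p) {
  n <- length(y)
  if (n <= p + 1) wp_stop("adjusted R^2 undefined: n <= p + 1", "wp_invalid_input")
  sst <- sum((y - mean(y))^2)
  if (sst == 0) wp_stop("zero-variance response", "wp_degenerate_target")
  r2 <- 1 - sum((y - y_hat)^2) / sst
  1 - (1 - r2) * (n - 1) / (n - p - 1)
}

#' Spearman rank correlation with two-sided p-value
#'
#' Average ranks are used for ties; the p-value is the two-sided
#' t-approximation test of zero rank correlation.
#'
#' @param a,b numeric vectors of equal length (at least 3).
#' @return list with `rho` and `p_value`.
#' @export
spearman_rho <- function(a, b) {
  if (length(a) != length(b) || length(a) < 3L) {
    wp_stop("need two equal-length vectors with n >= 3", "wp_invalid_input")
  }
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    wp_stop("Spearman correlation undefined for a constant vector",
            "wp_degenerate_target")
  }
  ct <- suppressWarnings(
    stats::cor.test(a, b, method = "spearman", exact = FALSE)
  )
  list(rho = unname(ct$estimate), p_value = ct$p.value)
}

#' Absolute percent error
#'
#' `|y_real - y_pred| / y_real * 100`, elementwise.
#'
#' @param y_real true values (non-zero), watts.
#' @param y_pred predicted values, watts.
#' @return vector of percent errors.
#' @export
percent_error <- function(y_real, y_pred) {
  if (any(y_real == 0)) wp_stop("percent error undefined at y_real = 0",
                                "wp_invalid_input")
  abs(y_real - y_pred) / y_real * 100
}

#' Greedy forward feature selection by least squares
#'
#' The training algorithm: starting from the intercept-only model, each
#' iteration fits one multiple linear regression per remaining candidate on
#' the calibration set and permanently adds the candidate giving the smallest
#' residual sum of squares (ties broken by column order). Selection stops
#' before adding a feature whose relative improvement of the adjusted
#' R-squared is negative or below `min_pct_improvement` percent. After each
#' addition the current equation is scored on the test set by Spearman rank
#' correlation (recorded as a diagnostic; it takes no part in selection).
#'
#' Candidates are expected standardised with calibration-set statistics, so
#' the returned coefficients are on the standardised (per-SD) scale.
#'
#' @param X_cal,y_cal calibration candidate matrix (n x p, standardised) and
#'   response (watts).
#' @param X_test,y_test test-set counterparts, already standardised with the
#'   calibration statistics; may be `NULL` to skip test diagnostics.
#' @param min_pct_improvement minimal relative adjusted-R^2 improvement, in
#'   percent, required to keep adding features.
#' @param max_features hard cap on the number of selected features.
#' @return list of class `selection_result`: `selected_features`,
#'   `intercept`, `coefficients`, `train_adj_r2_path`, `test_spearman_path`,
#'   `test_spearman`.
#' @export
greedy_select <- function(X_cal, y_cal, X_test = NULL, y_test = NULL,
                          min_pct_improvement = 0.5, max_features = 10L) {
  X_cal <- as.matrix(X_cal)
  n <- nrow(X_cal)
  if (is.null(colnames(X_cal))) colnames(X_cal) <- paste0("f", seq_len(ncol(X_cal)))
  if (stats::sd(y_cal) == 0) {
    wp_stop("zero-variance target: nothing to select", "wp_degenerate_target")
  }
  sst <- sum((y_cal - mean(y_cal))^2)

  selected <- integer(0)
  remaining <- seq_len(ncol(X_cal))
  adj_path <- numeric(0)
  test_rho_path <- list()
  adj_prev <- NA_real_

  repeat {
    if (length(selected) >= max_features || length(remaining) == 0L) break
    if (n <= length(selected) + 2L) break  # next fit would exhaust the dof

    best_j <- NA_integer_
    best_sse <- Inf
    for (j in remaining) {
      cand <- c(selected, j)
      fit <- stats::lm.fit(cbind(1, X_cal[, cand, drop = FALSE]), y_cal)
      if (fit$rank < length(cand) + 1L) next  # collinear candidate, skip
      sse <- sum(fit$residuals^2)
      if (!is.finite(best_sse) ||
          sse < best_sse - 1e-12 * (1 + best_sse)) {  # strict: ties keep lowest index
        best_sse <- sse
        best_j <- j
      }
    }
    if (is.na(best_j)) break

    r2 <- 1 - best_sse / sst
    p_new <- length(selected) + 1L
    adj_new <- 1 - (1 - r2) * (n - 1) / (n - p_new - 1)

    stop_after <- FALSE
    if (length(selected) == 0L) {
      if (adj_new <= 0) {
        warning("no candidate improves on the intercept-only model; ",
                "keeping the single best feature")
        stop_after <- TRUE
      }
    } else {
      pct_change <- (adj_new - adj_prev) / abs(adj_prev) * 100
      if (!is.finite(pct_change) || pct_change < min_pct_improvement) break
    }

    selected <- c(selected, best_j)
    remaining <- setdiff(remaining, best_j)
    adj_prev <- adj_new
    adj_path <- c(adj_path, adj_new)

    if (!is.null(X_test)) {
      coefs <- fit_ols(cbind(1, X_cal[, selected, drop = FALSE]), y_cal)
      pred_test <- drop(cbind(1, as.matrix(X_test)[, selected, drop = FALSE]) %*% coefs)
      rho <- tryCatch(spearman_rho(y_test, pred_test),
                      wantpower_error = function(e) list(rho = NA_real_, p_value = NA_real_))
      test_rho_path[[length(test_rho_path) + 1L]] <- rho
    }
    if (stop_after) break
  }

  if (length(selected) == 0L) {
    wp_stop("greedy selection found no admissible feature", "wp_degenerate_feature")
  }

  coefs <- fit_ols(cbind(1, X_cal[, selected, drop = FALSE]), y_cal)
  structure(list(
    selected_features = colnames(X_cal)[selected],
    intercept = unname(coefs[1L]),
    coefficients = stats::setNames(unname(coefs[-1L]), colnames(X_cal)[selected]),
    train_adj_r2_path = adj_path,
    test_spearman_path = test_rho_path,
    test_spearman = if (length(test_rho_path)) test_rho_path[[length(test_rho_path)]]
  ), class = "selection_result")
}

#' Resampled validation percent-error distribution
#'
#' Holds a fitted equation fixed and applies it to `n_reps` randomly drawn
#' validation subsets (a fraction `frac` of the pool, without replacement
#' within each draw), recording the mean per-subject percent error of each
#' draw. Returns the mean and SD of those `n_reps` means.
#'
#' @param predict_fun function mapping a row-index vector of the pool to
#'   predicted watts (the fixed model).
#' @param y_pool true outcome values of the pool, watts.
#' @param n_reps number of resampled validation sets.
#' @param frac fraction of the pool per draw; `frac * length(y_pool)` must be
#'   at least 3.
#' @param seed integer seed for the draw stream.
#' @return list with `mean`, `sd` (percent), and `per_rep` means.
#' @export
validation_error_distribution <- function(predict_fun, y_pool, n_reps = 100L,
                                          frac = 0.3, seed = 1L) {
  if (n_reps < 2L) wp_stop("SD undefined for fewer than 2 resamples",
                           "wp_invalid_input")
  n <- length(y_pool)
  m <- round(frac * n)
  if (m < 3L) wp_stop("validation subsets need at least 3 subjects",
                      "wp_invalid_input")
  per_rep <- with_local_seed(seed, {
    vapply(seq_len(n_reps), function(r) {
      idx <- sample.int(n, m)
      mean(percent_error(y_pool[idx], predict_fun(idx)))
    }, numeric(1))
  })
  list(mean = mean(per_rep), sd = stats::sd(per_rep), per_rep = per_rep)
}
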