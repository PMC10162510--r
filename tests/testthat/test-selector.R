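test_that("stratified splits are disjoint, exhaustive, size-correct and seeded", {
  x <- rnorm(93, 40, 8)
  names(x) <- sprintf("S%02d", 1:93)
  sp <- stratified_split(x, seed = 5)
  all_ids <- c(sp$calibration_ids, sp$test_ids, sp$validation_ids)
  expect_setequal(all_ids, names(x))
  expect_equal(length(all_ids), 93L)  # disjoint union
  expect_lte(abs(length(sp$calibration_ids) - 0.4 * 93), 1)
  expect_lte(abs(length(sp$test_ids) - 0.3 * 93), 1)
  # same seed twice -> identical assignment
  expect_identical(sp, stratified_split(x, seed = 5))
  expect_false(identical(sp$calibration_ids,
                         stratified_split(x, seed = 6)$calibration_ids))
  # n = 10 forces sizes (4, 3, 3)
  sp10 <- stratified_split(rnorm(10), seed = 1)
  expect_equal(lengths(sp10[c("calibration_ids", "test_ids", "validation_ids")]),
               c(calibration_ids = 4L, test_ids = 3L, validation_ids = 3L))
  # n_bins = 1 degenerates to a simple random split at the fractions
  sp1 <- stratified_split(rnorm(30), n_bins = 1, seed = 2)
  expect_equal(length(sp1$calibration_ids), 12L)
  expect_error(stratified_split(rnorm(5)), class = "wp_invalid_input")
})

test_that("stratification balances the covariate across subsets", {
  set.seed(8)
  x <- rnorm(120, 45, 10)
  names(x) <- sprintf("S%03d", 1:120)
  sp <- stratified_split(x, n_bins = 4, seed = 3)
  meds <- vapply(sp[c("calibration_ids", "test_ids", "validation_ids")],
                 function(ids) median(x[ids]), numeric(1))
  expect_lt(max(meds) - min(meds), sd(x))  # subset medians stay close
})

test_that("least squares wrapper reproduces hand normal-equations results", {
  # y = {1,2,4} on x = {0,1,2}: slope 3/2, intercept 5/6
  co <- fit_ols(cbind(1, c(0, 1, 2)), c(1, 2, 4))
  expect_equal(unname(co), c(5 / 6, 3 / 2))
  # exact linear response -> zero residuals and exact coefficients
  x <- seq(0, 9)
  co2 <- fit_ols(cbind(1, x), 3 + 2 * x)
  expect_equal(unname(co2), c(3, 2))
  # response orthogonal to the centred column -> slope 0, intercept mean(y)
  xo <- c(-1, 0, 1, 0)
  yo <- c(1, 3, 1, 3)
  co3 <- fit_ols(cbind(1, xo), yo)
  expect_equal(unname(co3), c(2, 0))
  expect_error(fit_ols(cbind(1, x, 2 * x), 3 + 2 * x),
               class = "wp_singular_design")
})

test_that("adjusted R-squared penalises predictors and matches the closed form", {
  y <- c(1, 3, 2, 5, 4, 6, 8, 7, 9, 10)
  expect_equal(adjusted_r2(y, y, p = 3), 1)
  # R^2 = 0 at the mean predictor: 1 - (n-1)/(n-p-1) = -1/8 for n=10, p=1
  expect_equal(adjusted_r2(y, rep(mean(y), 10), p = 1), -1 / 8)
  # adjusted <= plain R^2 whenever p >= 1
  set.seed(3)
  for (rep in 1:20) {
    yy <- rnorm(15)
    yh <- yy + rnorm(15, 0, 0.5)
    p <- sample(1:5, 1)
    expect_lte(adjusted_r2(yy, yh, p), adjusted_r2(yy, yh, 0) + 1e-12)
  }
  expect_error(adjusted_r2(y[1:3], y[1:3], p = 2), class = "wp_invalid_input")
})

test_that("Spearman correlation handles monotone, reversed and tied inputs", {
  expect_equal(spearman_rho(1:8, (1:8)^3)$rho, 1)
  expect_equal(spearman_rho(1:8, rev(1:8))$rho, -1)
  # hand rank computation: d = (0,-1,1,-1,1), sum(d^2) = 4,
  # rho = 1 - 6*4 / (5*(25-1)) = 1 - 24/120 = 0.8
  r <- spearman_rho(c(1, 2, 3, 4, 5), c(1, 3, 2, 5, 4))
  expect_equal(r$rho, 0.8)
  expect_true(r$p_value > 0 && r$p_value <= 1)
  # ties get average ranks
  expect_equal(spearman_rho(c(1, 2, 2, 3), c(10, 20, 20, 30))$rho, 1)
  expect_error(spearman_rho(rep(1, 5), 1:5), class = "wp_degenerate_target")
})

test_that("percent error is the absolute relative deviation in percent", {
  expect_equal(percent_error(100, 85), 15)
  expect_equal(percent_error(200, 230), 15)
  expect_equal(percent_error(c(50, 80), c(50, 80)), c(0, 0))
  expect_error(percent_error(c(100, 0), c(90, 10)), class = "wp_invalid_input")
})

test_that("greedy selection recovers a planted noiseless pair exactly", {
  set.seed(11)
  X <- scale(matrix(rnorm(600), 60, 10))
  colnames(X) <- paste0("f", 1:10)
  y <- 2 * X[, 3] - X[, 7]
  sel <- greedy_select(X, y)
  expect_setequal(sel$selected_features, c("f3", "f7"))
  expect_equal(sel$train_adj_r2_path[length(sel$train_adj_r2_path)], 1)
  # exhaustive best-subset over all pairs agrees
  oracle <- brute_force_best_pair(X, y)
  expect_setequal(colnames(X)[oracle$pair], sel$selected_features)
  expect_equal(oracle$sse, 0, tolerance = 1e-18)
})

test_that("every greedy step matches the exhaustive scan over remaining candidates", {
  set.seed(21)
  for (case in 1:25) {
    n <- sample(25:60, 1)
    p <- sample(4:12, 1)
    X <- scale(matrix(rnorm(n * p), n, p))
    colnames(X) <- paste0("f", seq_len(p))
    k <- sample(2:min(4, p), 1)
    beta <- rnorm(k, 0, 2)
    y <- drop(X[, seq_len(k), drop = FALSE] %*% beta) + rnorm(n, 0, 0.5)
    sel <- greedy_select(X, y)
    chosen <- match(sel$selected_features, colnames(X))
    selected <- integer(0)
    for (step in seq_along(chosen)) {
      oracle_j <- brute_force_step(X, y, selected, setdiff(seq_len(p), selected))
      expect_identical(chosen[step], oracle_j)
      selected <- c(selected, chosen[step])
    }
  }
})

test_that("calibration SSE never increases along the greedy path", {
  set.seed(5)
  X <- scale(matrix(rnorm(50 * 8), 50, 8))
  colnames(X) <- paste0("f", 1:8)
  y <- X[, 1] - 0.5 * X[, 4] + rnorm(50, 0, 1)
  sel <- greedy_select(X, y, min_pct_improvement = -100, max_features = 8)
  sse_path <- vapply(seq_along(sel$selected_features), function(k) {
    idx <- match(sel$selected_features[seq_len(k)], colnames(X))
    sum(lm.fit(cbind(1, X[, idx, drop = FALSE]), y)$residuals^2)
  }, numeric(1))
  expect_true(all(diff(sse_path) <= 1e-9))
})

test_that("greedy selection rejects a constant target and tolerates weak signal", {
  X <- scale(matrix(rnorm(40 * 5), 40, 5))
  expect_error(greedy_select(X, rep(3, 40)), class = "wp_degenerate_target")
  set.seed(1)
  Xw <- scale(matrix(rnorm(60 * 2), 60, 2))
  colnames(Xw) <- c("f1", "f2")
  yw <- rnorm(60)
  expect_warning(sel <- greedy_select(Xw, yw), "single best")
  expect_length(sel$selected_features, 1L)
})

test_that("resampled validation error has the right limits and is seed-stable", {
  y <- runif(60, 400, 900)
  perfect <- validation_error_distribution(function(idx) y[idx], y, seed = 4)
  expect_equal(perfect$mean, 0)
  expect_equal(perfect$sd, 0)
  # constant +15% bias gives mean 15 and SD 0 regardless of the draws
  biased <- validation_error_distribution(function(idx) 1.15 * y[idx], y, seed = 4)
  expect_equal(biased$mean, 15)
  expect_equal(biased$sd, 0, tolerance = 1e-12)
  a <- validation_error_distribution(function(idx) y[idx] + 40, y, seed = 7)
  b <- validation_error_distribution(function(idx) y[idx] + 40, y, seed = 7)
  expect_identical(a, b)
  expect_error(validation_error_distribution(function(idx) y[idx], y, n_reps = 1),
               class = "wp_invalid_input")
  expect_error(validation_error_distribution(function(idx) y[idx], y[1:5]),
               class = "wp_invalid_input")
})
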