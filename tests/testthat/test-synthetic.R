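test_that("trajectories follow the incremental protocol staircase", {
  cfg <- cohort_config(rq1_time_mean = 6, rq1_time_sd = 0)
  set.seed(1)
  sim <- simulate_cpet_trajectory(age = 30, config = cfg)
  tr <- sim$trajectory
  expect_equal(sim$rq1_time, 6)
  # speed +1 km/h per minute before the slope phase, then held
  expect_equal(tr$speed[tr$time == 5], 8 + 5)
  expect_equal(tr$speed[tr$time == 0], 8)
  expect_true(all(tr$speed[tr$time >= 6] == 8 + 6))
  # slope still flat at the onset, +2% per stage afterwards
  expect_equal(tr$slope[tr$time <= 6], rep(0, 7))
  expect_equal(tr$slope[tr$time == 8], 4)
  # HR monotone, ending exactly at the age-predicted maximum
  expect_true(all(diff(tr$hr) >= 0))
  expect_equal(tr$hr[nrow(tr)], tanaka_hrmax(30), tolerance = 1e-9)
})

test_that("planted outcomes are the exact linear model at zero noise", {
  n <- 30
  Z <- matrix(rnorm(n * 3), n, 3, dimnames = list(NULL, c("a", "b", "c")))
  planted <- list(pp = list(intercept = 600, coefficients = c(a = 100, c = -50)),
                  mp = list(intercept = 450, coefficients = c(b = 80)))
  out <- simulate_want_outcomes(Z, planted, noise_sd = 0, seed = 2)
  expect_equal(out$pp, 600 + 100 * Z[, "a"] - 50 * Z[, "c"])
  expect_equal(out$mp, 450 + 80 * Z[, "b"])
  # a single planted weight makes outcome and feature perfectly correlated
  expect_equal(cor(out$mp, Z[, "b"]), 1)
  # zero weights collapse to the intercept
  flat <- simulate_want_outcomes(
    Z, list(pp = list(intercept = 644, coefficients = numeric(0)),
            mp = list(intercept = 475, coefficients = numeric(0))),
    noise_sd = 0, seed = 2)
  expect_equal(flat$pp, rep(644, n))
  expect_error(
    simulate_want_outcomes(Z, list(pp = list(intercept = 1, coefficients = c(zz = 1)),
                                   mp = planted$mp), 0, 1),
    "zz", class = "wp_not_found")
})

test_that("outcome noise has the configured spread", {
  Z <- matrix(0, 1000, 1, dimnames = list(NULL, "a"))
  planted <- list(pp = list(intercept = 600, coefficients = c(a = 0)),
                  mp = list(intercept = 450, coefficients = c(a = 0)))
  out <- simulate_want_outcomes(Z, planted, noise_sd = 40, seed = 5)
  expect_equal(sd(out$pp), 40, tolerance = 0.1)
  expect_equal(sd(out$mp), 40, tolerance = 0.1)
  # PP and MP noise streams are independent draws
  expect_lt(abs(cor(out$pp, out$mp)), 0.15)
})

test_that("cohort simulation is reproducible and respects its configuration", {
  cfg <- cohort_config(n_female = 12, n_male = 15)
  a <- simulate_cohort(cfg, seed = 9)
  b <- simulate_cohort(cfg, seed = 9)
  expect_equal(a, b, tolerance = 0)  # bit-identical given the seed
  expect_length(a, 27L)
  expect_equal(sum(vapply(a, function(s) s$sex == "female", logical(1))), 12L)
  expect_false(isTRUE(all.equal(a[[1]]$trajectory,
                                simulate_cohort(cfg, seed = 10)[[1]]$trajectory)))
  # every subject carries outcomes and an AT surrogate within the trajectory
  for (s in a[c(1, 14, 27)]) {
    expect_true(is.numeric(s$measured_pp) && is.numeric(s$measured_mp))
    expect_gte(s$at_time, s$trajectory$time[1])
    expect_lte(s$at_time, s$trajectory$time[nrow(s$trajectory)])
  }
  expect_error(cohort_config(n_female = 0, n_male = 0), class = "wp_invalid_input")
})

test_that("zero-noise cohorts reproduce the planted equation exactly", {
  cfg <- cohort_config(n_female = 15, n_male = 15, noise_sd = 0)
  co <- simulate_cohort(cfg, seed = 4)
  truth <- attr(co, "truth")
  feats <- derive_features(co, levels = cfg$planted_level)
  fm <- feature_matrix(feats, cfg$planted_level)
  X <- as.matrix(fm[, setdiff(names(fm), "subject_id")])
  z <- standardize_features(X[, names(truth$standardization$mean), drop = FALSE],
                            stats = truth$standardization)$z
  pp_expected <- truth$planted$pp$intercept +
    drop(z[, names(truth$planted$pp$coefficients)] %*% truth$planted$pp$coefficients)
  expect_equal(cohort_outcome <- vapply(co, function(s) s$measured_pp, numeric(1)),
               pp_expected, tolerance = 1e-12)
})

test_that("large-cohort demographics converge to the configured moments", {
  co <- simulate_cohort(cohort_config(n_female = 2150, n_male = 2850), seed = 11)
  sex <- vapply(co, function(s) s$sex, character(1))
  age <- vapply(co, function(s) s$age, numeric(1))
  mass <- vapply(co, function(s) s$body_mass, numeric(1))
  expect_equal(mean(age[sex == "female"]), 26, tolerance = 0.02)
  expect_equal(mean(age[sex == "male"]), 29, tolerance = 0.02)
  expect_equal(mean(mass[sex == "female"]), 60.9, tolerance = 0.02)
  expect_equal(mean(mass[sex == "male"]), 75.7, tolerance = 0.02)
})

test_that("noiseless end-to-end pipeline recovers planted raw-scale coefficients", {
  cfg <- cohort_config(n_female = 50, n_male = 50, noise_sd = 0)
  co <- simulate_cohort(cfg, seed = 6)
  truth <- attr(co, "truth")
  m <- train_power_model(co, "pp", level = cfg$planted_level, seed = 2)
  expect_setequal(m$selected_features, names(truth$planted$pp$coefficients))
  path <- m$diagnostics$train_adj_r2_path
  expect_equal(path[length(path)], 1, tolerance = 1e-9)
  # raw-scale (per-unit) coefficients are standardisation-frame invariant
  rec_raw <- m$coefficients / m$standardization$sd[m$selected_features]
  tru_raw <- truth$planted$pp$coefficients /
    truth$standardization$sd[names(truth$planted$pp$coefficients)]
  expect_equal(rec_raw[sort(names(rec_raw))], tru_raw[sort(names(tru_raw))],
               tolerance = 1e-6)
})
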