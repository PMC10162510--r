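# fixtures built in code: small deterministic subjects and brute-force oracles

# subject with HR rising linearly 100 -> 190 bpm over t = 0..10 min while
# speed rises 8 -> 18 km/h; optionally a slope phase from t = slope_from
linear_subject <- function(id = "L1", age = 26, mass = 60, slope_from = NULL,
                           at_time = NULL, pp = NULL, mp = NULL) {
  t <- 0:10
  slope <- rep(0, 11)
  if (!is.null(slope_from)) slope[t > slope_from] <- 2 * (t[t > slope_from] - slope_from)
  subject_profile(
    subject_id = id, age = age, sex = "female", body_mass = mass,
    trajectory = data.frame(time = t, speed = 8 + t, slope = slope, hr = 100 + 9 * t),
    at_time = at_time, measured_pp = pp, measured_mp = mp
  )
}

# subject running at constant speed on the flat, reaching its age-predicted
# HRmax exactly at t = 6 min (age 40 -> HRmax 180)
flat_subject <- function(id = "F1", mass = 60) {
  t <- 0:6
  subject_profile(
    subject_id = id, age = 40, sex = "male", body_mass = mass,
    trajectory = data.frame(time = t, speed = rep(10, 7), slope = rep(0, 7),
                            hr = 120 + 10 * t)
  )
}

# exhaustive single-step scan: the feature whose addition to `selected`
# minimises the calibration SSE (first index on ties)
brute_force_step <- function(X, y, selected, remaining) {
  sse <- vapply(remaining, function(j) {
    fit <- lm.fit(cbind(1, X[, c(selected, j), drop = FALSE]), y)
    if (fit$rank < length(selected) + 2L) Inf else sum(fit$residuals^2)
  }, numeric(1))
  remaining[which.min(sse)]
}

# exhaustive best-subset over all pairs (for the planted-pair oracle)
brute_force_best_pair <- function(X, y) {
  p <- ncol(X)
  best <- NULL
  best_sse <- Inf
  for (a in 1:(p - 1)) for (b in (a + 1):p) {
    fit <- lm.fit(cbind(1, X[, c(a, b)]), y)
    sse <- sum(fit$residuals^2)
    if (sse < best_sse) {
      best_sse <- sse
      best <- c(a, b)
    }
  }
  list(pair = best, sse = best_sse)
}
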