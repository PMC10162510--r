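#' Configuration of the synthetic cohort generator
#'
#' Defaults emulate the study cohort the models target: 40 women (age 26 +/- 4
#' y, mass 60.9 +/- 9.8 kg, height 163.8 +/- 6.4 cm) and 53 men (29 +/- 6 y,
#' 75.7 +/- 10 kg, 176.6 +/- 6.8 cm); an incremental treadmill protocol that
#' raises speed by 1 km/h every minute until the respiratory-quotient-1 event
#' and then the slope by 2% per stage; and Wingate outcomes generated from a
#' planted linear model on standardised derived features plus Gaussian noise.
#' The default planted models use the same feature families as the published
#' 85%-level equations (peak power: predicted VO2 in mL/min and mL/kg/min and
#' the slope x speed x time composite; mean power: predicted VO2, the two
#' VO2-at-threshold features and exercise time), with noise SD 40 W.
#'
#' Demographic normals are truncated at physiologic bounds (age 18-50 y,
#' mass 40-120 kg, height 145-210 cm) — generator policy, not cohort claims.
#'
#' @param n_female,n_male subject counts.
#' @param noise_sd SD of the Gaussian outcome noise, watts.
#' @param planted_level HRmax fraction whose features carry the planted model.
#' @param planted named list (`pp`, `mp`) of lists with `intercept` (watts)
#'   and `coefficients` (named, standardised scale).
#' @param start_speed treadmill speed after warm-up, km/h.
#' @param speed_increment km/h added per minute before the slope phase.
#' @param slope_increment percent grade added per stage.
#' @param rq1_time_mean,rq1_time_sd moments of the slope-phase onset, min.
#' @param slope_stages_range integer range of slope stages after onset.
#' @param hr_start_mean,hr_start_sd heart rate at test start, beats/min.
#' @param hr_jitter_sd SD of the HR ramp jitter, beats/min.
#' @param include_at_time record the slope-onset time as each subject's
#'   anaerobic-threshold surrogate (`at_time`)?
#' @return list of class `cohort_config`.
#' @export
cohort_config <- function(n_female = 40L, n_male = 53L,
                          noise_sd = 40,
                          planted_level = 0.85,
                          planted = list(
                            pp = list(intercept = 644, coefficients = c(
                              vo2_abs = 225, vo2_rel = -87, slope_speed_time = -26)),
                            mp = list(intercept = 475, coefficients = c(
                              vo2_abs = 154, vo2_at_rel = -93, time = 27,
                              vo2_at_abs = 6))
                          ),
                          start_speed = 8, speed_increment = 1,
                          slope_increment = 2,
                          rq1_time_mean = 8, rq1_time_sd = 2,
                          slope_stages_range = c(3L, 6L),
                          hr_start_mean = 110, hr_start_sd = 8,
                          hr_jitter_sd = 2,
                          include_at_time = TRUE) {
  cfg <- list(
    n_female = as.integer(n_female), n_male = as.integer(n_male),
    demographics = list(
      female = list(age = c(26, 4), mass = c(60.9, 9.8), height = c(163.8, 6.4)),
      male   = list(age = c(29, 6), mass = c(75.7, 10),  height = c(176.6, 6.8))
    ),
    bounds = list(age = c(18, 50), mass = c(40, 120), height = c(145, 210)),
    noise_sd = noise_sd, planted_level = planted_level, planted = planted,
    start_speed = start_speed, speed_increment = speed_increment,
    slope_increment = slope_increment,
    rq1_time_mean = rq1_time_mean, rq1_time_sd = rq1_time_sd,
    slope_stages_range = as.integer(slope_stages_range),
    hr_start_mean = hr_start_mean, hr_start_sd = hr_start_sd,
    hr_jitter_sd = hr_jitter_sd,
    include_at_time = isTRUE(include_at_time)
  )
  if (cfg$n_female < 0L || cfg$n_male < 0L || cfg$n_female + cfg$n_male < 1L) {
    wp_stop("cohort must contain at least one subject", "wp_invalid_input")
  }
  if (noise_sd < 0 || speed_increment <= 0 || slope_increment <= 0) {
    wp_stop("noise_sd must be >= 0; protocol increments must be positive",
            "wp_invalid_input")
  }
  class(cfg) <- "cohort_config"
  cfg
}

# truncated normal by rejection; bounds are generous so this terminates fast
#' @noRd
rtruncnorm1 <- function(mean, sd, lower, upper) {
  repeat {
    x <- stats::rnorm(1L, mean, sd)
    if (x >= lower && x <= upper) return(x)
  }
}

#' Simulate one incremental treadmill test trajectory
#'
#' Minute-resolution staircase: speed rises by `speed_increment` km/h each
#' minute until the drawn slope-phase onset, after which speed holds and the
#' slope rises by `slope_increment` percent per stage. Heart rate follows a
#' noisy linear ramp from the starting HR to the subject's age-predicted
#' HRmax at termination, made monotone by a running-maximum correction, so
#' every HR level up to 100% is crossed exactly once.
#'
#' @param age subject age, years (sets the terminal HR via [tanaka_hrmax()]).
#' @param config a [cohort_config()].
#' @return list with `trajectory` (data.frame `time`, `speed`, `slope`, `hr`)
#'   and `rq1_time` (the slope-phase onset, min). Uses the current RNG
#'   stream.
#' @export
simulate_cpet_trajectory <- function(age, config = cohort_config()) {
  rq1 <- max(3L, round(stats::rnorm(1L, config$rq1_time_mean, config$rq1_time_sd)))
  stages <- sample(seq(config$slope_stages_range[1L], config$slope_stages_range[2L]), 1L)
  total <- rq1 + stages
  t <- 0:total
  speed <- config$start_speed + config$speed_increment * pmin(t, rq1)
  slope <- config$slope_increment * pmax(0L, t - rq1)

  hrmax <- tanaka_hrmax(age)
  hr_start <- min(rtruncnorm1(config$hr_start_mean, config$hr_start_sd, 80, 140),
                  hrmax - 30)
  hr <- hr_start + (hrmax - hr_start) * t / total +
    c(0, stats::rnorm(total, 0, config$hr_jitter_sd))
  hr <- cummax(hr)
  hr <- pmin(hr, hrmax)
  hr[length(hr)] <- hrmax

  list(trajectory = data.frame(time = as.numeric(t), speed = speed,
                               slope = as.numeric(slope), hr = hr),
       rq1_time = as.numeric(rq1))
}

#' Plant Wingate outcomes on standardised features
#'
#' `outcome = intercept + sum(weight * z) + Normal(0, noise_sd)`, with
#' independent noise draws for peak and mean power.
#'
#' @param Z standardised feature matrix (subjects x features).
#' @param planted named list (`pp`, `mp`) with `intercept` and named
#'   `coefficients`; every coefficient name must be a column of `Z`.
#' @param noise_sd Gaussian noise SD, watts.
#' @param seed integer seed.
#' @return list with numeric vectors `pp` and `mp`, watts.
#' @export
simulate_want_outcomes <- function(Z, planted, noise_sd, seed = 1L) {
  Z <- as.matrix(Z)
  if (noise_sd < 0) wp_stop("`noise_sd` must be >= 0", "wp_invalid_input")
  draw <- function(spec, eps) {
    unknown <- setdiff(names(spec$coefficients), colnames(Z))
    if (length(unknown)) {
      wp_stop(paste0("unknown planted feature(s): ", paste(unknown, collapse = ", ")),
              "wp_not_found")
    }
    drop(spec$intercept + Z[, names(spec$coefficients), drop = FALSE] %*%
           spec$coefficients + eps)
  }
  with_local_seed(seed, {
    n <- nrow(Z)
    eps_pp <- stats::rnorm(n, 0, noise_sd)
    eps_mp <- stats::rnorm(n, 0, noise_sd)
    list(pp = draw(planted$pp, eps_pp), mp = draw(planted$mp, eps_mp))
  })
}

#' Simulate a synthetic cohort
#'
#' Draws demographics from truncated normals at the configured moments,
#' simulates an incremental treadmill trajectory per subject, derives the
#' candidate features at the planted level, standardises them cohort-wide,
#' and generates measured Wingate peak and mean power from the planted linear
#' model plus noise. Fully reproducible from `seed`.
#'
#' @param config a [cohort_config()].
#' @param seed integer root seed (substreams: `cohort`, `noise`).
#' @return list of [subject_profile()] objects with attribute `truth`
#'   (planted parameters, standardisation stats, planted level).
#' @export
simulate_cohort <- function(config = cohort_config(), seed = 1L) {
  stopifnot(inherits(config, "cohort_config"))
  n <- config$n_female + config$n_male
  sexes <- c(rep("female", config$n_female), rep("male", config$n_male))

  subjects <- with_local_seed(substream_seed(seed, "cohort"), {
    lapply(seq_len(n), function(i) {
      sex <- sexes[i]
      d <- config$demographics[[sex]]
      b <- config$bounds
      age <- rtruncnorm1(d$age[1], d$age[2], b$age[1], b$age[2])
      mass <- rtruncnorm1(d$mass[1], d$mass[2], b$mass[1], b$mass[2])
      height <- rtruncnorm1(d$height[1], d$height[2], b$height[1], b$height[2])
      sim <- simulate_cpet_trajectory(age, config)
      subject_profile(
        subject_id = sprintf("S%03d", i),
        age = age, sex = sex, body_mass = mass, body_height = height,
        trajectory = sim$trajectory,
        at_time = if (config$include_at_time) sim$rq1_time
      )
    })
  })

  feats <- derive_features(subjects, levels = config$planted_level)
  fm <- feature_matrix(feats, config$planted_level)
  X <- as.matrix(fm[, setdiff(names(fm), "subject_id")])
  rownames(X) <- fm$subject_id
  used <- unique(c(names(config$planted$pp$coefficients),
                   names(config$planted$mp$coefficients)))
  std <- standardize_features(X[, used, drop = FALSE])
  out <- simulate_want_outcomes(std$z, config$planted, config$noise_sd,
                                seed = substream_seed(seed, "noise"))

  for (i in seq_len(n)) {
    subjects[[i]]$measured_pp <- unname(out$pp[i])
    subjects[[i]]$measured_mp <- unname(out$mp[i])
  }
  attr(subjects, "truth") <- list(
    planted = config$planted,
    planted_level = config$planted_level,
    standardization = std$stats,
    noise_sd = config$noise_sd,
    seed = as.integer(seed)
  )
  subjects
}
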