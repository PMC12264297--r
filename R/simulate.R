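#' Configuration for the synthetic SAH cohort generator
#'
#' Defines the statistical structure of a simulated first-ICU-day cohort:
#' four trajectory archetypes (two low-mean at 9 mmHg, two high-mean at
#' 19 mmHg, the second archetype carrying the largest within-day fluctuation),
#' irregular sampling with occasional contiguous monitoring dropouts, simple
#' covariate distributions, and ICU mortality driven by the first-day mean ICP
#' through a logistic model.
#'
#' Each subject's latent trajectory is
#' \deqn{x(t) = \mu_a + z_i + g_a \sigma_a s_a(t) + d_i(t) + \epsilon}
#' where \eqn{\mu_a} is the archetype mean, \eqn{z_i} a per-subject level
#' offset with sd \code{mean_jitter_gain} \eqn{\times \sigma_a}, \eqn{s_a} a
#' fixed unit-amplitude 24-h profile (flat for archetypes I and III, sinusoidal
#' phases for II and IV) scaled by the shape gain \eqn{g_a} and the archetype
#' fluctuation scale \eqn{\sigma_a}, \eqn{d_i} a smooth random drift built
#' from three low-order sinusoid components, and \eqn{\epsilon} i.i.d.
#' measurement noise. Drift and noise sds are fixed fractions (0.6, 0.8) of
#' \eqn{\sigma_a} so their combined sd is \eqn{\sigma_a}.
#'
#' @param n_subjects number of subjects.
#' @param archetype_props length-4 membership probabilities; must be
#'   non-negative and sum to 1.
#' @param archetype_means length-4 archetype mean ICP, mmHg.
#' @param archetype_sds length-4 stochastic within-day fluctuation scale, mmHg.
#' @param archetype_shape_gains length-4 multipliers converting
#'   \code{archetype_sds} into the amplitude of the archetype's deterministic
#'   24-h profile (0 = flat trajectory).
#' @param mean_jitter_gain per-subject latent-mean sd as a fraction of the
#'   archetype sd.
#' @param sampling_rate mean number of measurements per hour (> 0).
#' @param regular_sampling if \code{TRUE}, one measurement exactly on each
#'   hour instead of Poisson-irregular times.
#' @param missing_block_prob probability a subject has one contiguous
#'   monitoring dropout.
#' @param missing_block_hours integer range (min, max) of dropout lengths in
#'   hours; the default includes blocks longer than 6 h so the downstream
#'   gap-exclusion rule is exercised.
#' @param mortality_intercept,beta_icpmean,beta_age,beta_gcs logistic
#'   coefficients of the ICU-death model.
#' @param beta_icpjump additional log-odds jump applied when the latent daily
#'   mean exceeds \code{icp_jump_at} (0 = no jump); used to plant a threshold
#'   effect for cut-point recovery studies.
#' @param icp_jump_at threshold (mmHg) for \code{beta_icpjump}.
#' @param censor_time_max maximum follow-up, hours; death times are uniform on
#'   (0, \code{censor_time_max}), survivors are censored at an ICU discharge
#'   time uniform on (24, \code{censor_time_max}).
#' @param seed integer seed; all generator output is reproducible given the
#'   config.
#'
#' @return an object of class \code{sim_config} (a validated list).
#' @export
sim_config <- function(n_subjects = 400,
                       archetype_props = c(0.62, 0.03, 0.10, 0.25),
                       archetype_means = c(9, 19, 19, 9),
                       archetype_sds = c(1, 2.5, 1, 1),
                       archetype_shape_gains = c(0, 6, 0, 9),
                       mean_jitter_gain = 0.5,
                       sampling_rate = 1.2,
                       regular_sampling = FALSE,
                       missing_block_prob = 0.15,
                       missing_block_hours = c(2L, 9L),
                       mortality_intercept = -3.5,
                       beta_icpmean = 0.25,
                       beta_age = 0.02,
                       beta_gcs = -0.15,
                       beta_icpjump = 0,
                       icp_jump_at = 14,
                       censor_time_max = 336,
                       seed = 1L) {
  cfg <- list(n_subjects = as.integer(n_subjects),
              archetype_props = archetype_props,
              archetype_means = archetype_means,
              archetype_sds = archetype_sds,
              archetype_shape_gains = archetype_shape_gains,
              mean_jitter_gain = mean_jitter_gain,
              sampling_rate = sampling_rate,
              regular_sampling = isTRUE(regular_sampling),
              missing_block_prob = missing_block_prob,
              missing_block_hours = as.integer(missing_block_hours),
              mortality_intercept = mortality_intercept,
              beta_icpmean = beta_icpmean,
              beta_age = beta_age,
              beta_gcs = beta_gcs,
              beta_icpjump = beta_icpjump,
              icp_jump_at = icp_jump_at,
              censor_time_max = censor_time_max,
              seed = as.integer(seed))
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  if (is.na(cfg$n_subjects) || cfg$n_subjects < 1)
    stop("configuration error: n_subjects must be a positive integer", call. = FALSE)
  p <- cfg$archetype_props
  if (length(p) != 4 || any(p < 0) || abs(sum(p) - 1) > 1e-8)
    stop("configuration error: archetype_props must be 4 non-negative values summing to 1",
         call. = FALSE)
  for (f in c("archetype_means", "archetype_sds", "archetype_shape_gains"))
    if (length(cfg[[f]]) != 4 || any(!is.finite(cfg[[f]])))
      stop("configuration error: ", f, " must be 4 finite values", call. = FALSE)
  if (any(cfg$archetype_sds < 0))
    stop("configuration error: archetype_sds must be non-negative", call. = FALSE)
  if (!is.finite(cfg$sampling_rate) || cfg$sampling_rate <= 0)
    stop("configuration error: sampling_rate must be positive", call. = FALSE)
  if (cfg$missing_block_prob < 0 || cfg$missing_block_prob > 1)
    stop("configuration error: missing_block_prob must be in [0, 1]", call. = FALSE)
  if (cfg$censor_time_max <= 24)
    stop("configuration error: censor_time_max must exceed 24 h", call. = FALSE)
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic ICP cohort configuration\n")
  cat(sprintf("  subjects: %d (seed %d)\n", x$n_subjects, x$seed))
  cat(sprintf("  archetype props: %s\n", paste(x$archetype_props, collapse = ", ")))
  cat(sprintf("  archetype means (mmHg): %s\n", paste(x$archetype_means, collapse = ", ")))
  cat(sprintf("  fluctuation sds (mmHg): %s\n", paste(x$archetype_sds, collapse = ", ")))
  invisible(x)
}

ARCHETYPE_LABELS <- c("I", "II", "III", "IV")

# fixed unit 24-h profiles; archetypes II and IV get sinusoids in quadrature
# so the two shaped archetypes are orthogonal in trajectory space
archetype_profile <- function(a, t_hours) {
  switch(a,
         rep(0, length(t_hours)),
         sin(2 * pi * t_hours / 24),
         rep(0, length(t_hours)),
         cos(2 * pi * t_hours / 24))
}

sim_origin <- function() as.POSIXct("2024-01-01 00:00:00", tz = "UTC")

#' Simulate irregular first-day ICP chart events
#'
#' Draws archetype membership, builds each subject's latent trajectory (see
#' \code{\link{sim_config}}), samples it at irregular (or exactly hourly)
#' times within the subject's first 24 ICU hours, and optionally removes one
#' contiguous block of measurements to emulate monitoring dropouts. Subjects
#' are admitted on consecutive days from a fixed origin so timestamps are
#' unambiguous.
#'
#' @param config a \code{\link{sim_config}}.
#' @return list with \code{events} (data.frame: \code{subject_id},
#'   \code{charttime} POSIXct UTC, \code{icp_mmHg}), \code{truth} (data.frame:
#'   \code{subject_id}, \code{archetype} I--IV, \code{latent_mean} mmHg), and
#'   \code{admissions} (data.frame: \code{subject_id}, \code{icu_intime}).
#' @export
simulate_trajectories <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  validate_sim_config(config)
  set.seed(config$seed)
  n <- config$n_subjects
  arch <- sample.int(4L, n, replace = TRUE, prob = config$archetype_props)
  jitter <- rnorm(n, 0, config$mean_jitter_gain * config$archetype_sds[arch])
  origin <- sim_origin()
  intime <- origin + (seq_len(n) - 1) * 86400

  ev <- vector("list", n)
  for (i in seq_len(n)) {
    a <- arch[i]
    if (config$regular_sampling) {
      t <- 0:23
    } else {
      m <- rpois(1, 24 * config$sampling_rate)
      t <- sort(runif(max(m, 1L), 0, 24))
    }
    sds <- config$archetype_sds[a]
    amp <- config$archetype_shape_gains[a] * sds
    b <- rnorm(3)
    drift <- sds * 0.6 / sqrt(1.5) *
      (b[1] * sin(2 * pi * t / 24) + b[2] * cos(2 * pi * t / 24) +
         b[3] * sin(4 * pi * t / 24))
    icp <- config$archetype_means[a] + jitter[i] + amp * archetype_profile(a, t) +
      drift + rnorm(length(t), 0, 0.8 * sds)
    # contiguous monitoring dropout
    if (runif(1) < config$missing_block_prob) {
      len <- sample(seq(config$missing_block_hours[1], config$missing_block_hours[2]), 1)
      start <- runif(1, 0, 24 - len)
      keep <- t < start | t >= start + len
      t <- t[keep]
      icp <- icp[keep]
    }
    ev[[i]] <- if (length(t)) data.frame(subject_id = i,
                                         charttime = intime[i] + round(t * 3600),
                                         icp_mmHg = icp) else NULL
  }
  events <- do.call(rbind, ev)
  rownames(events) <- NULL
  list(events = events,
       truth = data.frame(subject_id = seq_len(n),
                          archetype = ARCHETYPE_LABELS[arch],
                          latent_mean = config$archetype_means[arch] + jitter),
       admissions = data.frame(subject_id = seq_len(n), icu_intime = intime))
}

#' Simulate covariates and ICU outcomes for a synthetic cohort
#'
#' Draws baseline covariates from simple parametric distributions whose
#' location/scale mirror a typical adult SAH ICU cohort, then draws ICU death
#' from a logistic model in the latent daily mean ICP, age and minimum GCS
#' (plus an optional planted threshold jump). Death times are uniform on
#' (0, \code{censor_time_max}); survivors are censored at an ICU discharge
#' time uniform on (24, \code{censor_time_max}).
#'
#' The minimum GCS is generated to decrease with the latent ICP mean, making
#' it a genuine confounder of ICP-group comparisons; fluid balance increases
#' with the latent mean, emulating more aggressive fluid management at higher
#' ICP.
#'
#' @param truth data.frame from \code{\link{simulate_trajectories}} (one row
#'   per subject, with \code{latent_mean}).
#' @param config the same \code{\link{sim_config}}.
#' @param covariates optional pre-drawn covariate data.frame (must contain
#'   \code{subject_id} matching \code{truth}); drawn internally when NULL.
#' @return data.frame with one row per subject: covariates (\code{age},
#'   \code{gender}, \code{gcs_min}, \code{apsiii}, \code{oasis}, \code{sofa},
#'   \code{fluid_balance}), \code{icu_death} (0/1) and \code{time_hours}.
#' @export
simulate_outcomes <- function(truth, config, covariates = NULL) {
  stopifnot(inherits(config, "sim_config"))
  n <- nrow(truth)
  set.seed(config$seed + 1L)
  if (is.null(covariates)) {
    covariates <- data.frame(
      subject_id = truth$subject_id,
      age = pmin(95, pmax(18, round(rnorm(n, 58.8, 14.5)))),
      gender = ifelse(runif(n) < 0.58, "female", "male"),
      gcs_min = pmin(15, pmax(3, round(12 - 0.35 * (truth$latent_mean - 10) +
                                         rnorm(n, 0, 2.5)))),
      apsiii = pmax(0, round(rnorm(n, 52.8, 22.6))),
      oasis = pmax(0, round(rnorm(n, 37.6, 7.7))),
      sofa = pmin(24, pmax(0, round(rnorm(n, 5.2, 2.7)))),
      fluid_balance = round(500 + 80 * (truth$latent_mean - 10) + rnorm(n, 0, 900))
    )
  }
  if (!setequal(covariates$subject_id, truth$subject_id))
    stop("input error: covariate and truth subject sets differ", call. = FALSE)
  covariates <- covariates[match(truth$subject_id, covariates$subject_id), ]

  lp <- config$mortality_intercept +
    config$beta_icpmean * truth$latent_mean +
    config$beta_icpjump * (truth$latent_mean > config$icp_jump_at) +
    config$beta_age * covariates$age +
    config$beta_gcs * covariates$gcs_min
  death <- rbinom(n, 1, plogis(lp))
  time <- ifelse(death == 1,
                 runif(n, 0, config$censor_time_max),
                 runif(n, 24, config$censor_time_max))
  out <- cbind(covariates,
               data.frame(icu_death = death, time_hours = time))
  rownames(out) <- NULL
  out
}

#' Simulate a complete synthetic cohort
#'
#' Convenience wrapper running \code{\link{simulate_trajectories}} and
#' \code{\link{simulate_outcomes}}.
#'
#' @param config a \code{\link{sim_config}}.
#' @return list with \code{chartevents}, \code{cohort} (covariates + outcome +
#'   \code{icu_intime}), and \code{truth}.
#' @export
simulate_cohort <- function(config = sim_config()) {
  sim <- simulate_trajectories(config)
  cohort <- simulate_outcomes(sim$truth, config)
  cohort <- merge(cohort, sim$admissions, by = "subject_id", sort = TRUE)
  list(chartevents = sim$events, cohort = cohort, truth = sim$truth)
}

#' Simulate a confounded treatment-outcome cohort
#'
#' Small generator for validating the weighting estimators: two standard
#' normal covariates act as common causes of a binary treatment (logistic
#' assignment) and a binary outcome with a planted conditional odds ratio for
#' treatment. Useful for bias, coverage and balance studies where the true
#' propensity model is known.
#'
#' @param n subjects.
#' @param true_or planted conditional odds ratio of treatment on outcome
#'   (1 = null).
#' @param beta_conf confounder strength: coefficient of the first covariate in
#'   both the treatment and outcome models.
#' @param baseline_logit outcome model intercept.
#' @param seed integer seed.
#' @return data.frame with \code{z1}, \code{z2}, \code{treated},
#'   \code{outcome}, and the true propensity \code{ps_true}.
#' @export
simulate_confounded <- function(n, true_or = 1, beta_conf = 0.8,
                                baseline_logit = -1.5, seed = 1L) {
  set.seed(seed)
  z1 <- rnorm(n)
  z2 <- rnorm(n)
  ps <- plogis(-0.2 + beta_conf * z1 + 0.3 * z2)
  t <- rbinom(n, 1, ps)
  p_out <- plogis(baseline_logit + log(true_or) * t + beta_conf * z1 + 0.3 * z2)
  data.frame(z1 = z1, z2 = z2, treated = t, outcome = rbinom(n, 1, p_out),
             ps_true = ps)
}
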