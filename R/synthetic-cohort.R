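#' Configuration for the synthetic telemonitoring cohort generator
#'
#' The defaults emulate a 42-patient, ~6-month at-home telemonitoring study
#' of early-to-moderate Parkinson's disease: ages drawn from a normal(64.4,
#' 9.2) truncated to \[40, 90\], a two-thirds male majority, 120-150 visits
#' per patient over 180 days, a smooth per-patient motor-UPDRS trajectory
#' (uniform(8, 35) baseline, normal(0.02, 0.015) points/day slope) with
#' AR(1) visit-level noise, and acoustic measures linearly coupled to the
#' latent severity with multiplicative log-normal noise. HNR carries a
#' negative severity loading (voice quality degrades as motor impairment
#' rises); the jitter and shimmer families carry positive loadings.
#'
#' @param n_patients Number of patients.
#' @param visits_range Integer range (min, max) of visits per patient.
#' @param duration_days Length of the monitoring window in days.
#' @param age_mean,age_sd,age_range Truncated-normal age distribution.
#' @param male_fraction Probability that a patient is male.
#' @param baseline_range Uniform range for the latent baseline motor UPDRS.
#' @param slope_mean,slope_sd Normal distribution of the per-day UPDRS slope.
#' @param ar1_rho,noise_sd AR(1) autocorrelation and innovation scale of the
#'   visit-level UPDRS noise.
#' @param updrs_clip Clipping range applied to observed motor UPDRS.
#' @param total_offset_range Uniform range of the positive offset separating
#'   total from motor UPDRS.
#' @param voice_coupling Data frame with one row per acoustic feature and
#'   columns `feature`, `intercept`, `loading`, `noise_sd` (log-normal sdlog).
#'   `NULL` uses built-in values calibrated to the published cohort moments.
#' @param rng_seed Integer seed; the generator is fully reproducible.
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(n_patients = 42,
                          visits_range = c(120, 150),
                          duration_days = 180,
                          age_mean = 64.4, age_sd = 9.2,
                          age_range = c(40, 90),
                          male_fraction = 2 / 3,
                          baseline_range = c(8, 35),
                          slope_mean = 0.02, slope_sd = 0.015,
                          ar1_rho = 0.7, noise_sd = 1.0,
                          updrs_clip = c(0, 60),
                          total_offset_range = c(6, 12),
                          voice_coupling = NULL,
                          rng_seed = 20260926) {
  if (n_patients < 1) stop("validation error: n_patients >= 1", call. = FALSE)
  if (noise_sd < 0 || slope_sd < 0 || age_sd < 0) {
    stop("validation error: standard deviations must be >= 0", call. = FALSE)
  }
  if (male_fraction < 0 || male_fraction > 1) {
    stop("validation error: male_fraction in [0, 1]", call. = FALSE)
  }
  if (abs(ar1_rho) >= 1) {
    stop("validation error: |ar1_rho| < 1 required", call. = FALSE)
  }
  if (is.null(voice_coupling)) voice_coupling <- default_voice_coupling()
  need <- c("feature", "intercept", "loading", "noise_sd")
  if (!all(need %in% names(voice_coupling)) ||
      !setequal(voice_coupling$feature, uci_voice_columns)) {
    stop("validation error: voice_coupling must cover all 16 acoustic features",
         call. = FALSE)
  }
  structure(list(
    n_patients = n_patients, visits_range = visits_range,
    duration_days = duration_days, age_mean = age_mean, age_sd = age_sd,
    age_range = age_range, male_fraction = male_fraction,
    baseline_range = baseline_range, slope_mean = slope_mean,
    slope_sd = slope_sd, ar1_rho = ar1_rho, noise_sd = noise_sd,
    updrs_clip = updrs_clip, total_offset_range = total_offset_range,
    voice_coupling = voice_coupling, rng_seed = rng_seed
  ), class = "cohort_config")
}

# Intercepts sit at the published cohort means for a mid-severity patient
# (severity ~ 22 UPDRS points); loadings give jitter/shimmer a positive and
# HNR a negative association with severity, scaled so the induced
# between-patient spread is of the order of the published SDs.
default_voice_coupling <- function() {
  base <- c(
    "Jitter(%)" = 0.0062, "Jitter(Abs)" = 4.4e-05, "Jitter:RAP" = 0.003,
    "Jitter:PPQ5" = 0.0033, "Jitter:DDP" = 0.009, "Shimmer" = 0.034,
    "Shimmer(dB)" = 0.31, "Shimmer:APQ3" = 0.017, "Shimmer:APQ5" = 0.02,
    "Shimmer:APQ11" = 0.028, "Shimmer:DDA" = 0.051, "NHR" = 0.032,
    "HNR" = 21.72, "RPDE" = 0.54, "DFA" = 0.65, "PPE" = 0.22
  )
  # per-UPDRS-point sensitivity, as a fraction of the baseline level
  rel_loading <- c(
    "Jitter(%)" = 0.022, "Jitter(Abs)" = 0.022, "Jitter:RAP" = 0.022,
    "Jitter:PPQ5" = 0.022, "Jitter:DDP" = 0.022, "Shimmer" = 0.025,
    "Shimmer(dB)" = 0.025, "Shimmer:APQ3" = 0.025, "Shimmer:APQ5" = 0.025,
    "Shimmer:APQ11" = 0.025, "Shimmer:DDA" = 0.025, "NHR" = 0.030,
    "HNR" = -0.007, "RPDE" = 0.006, "DFA" = 0.002, "PPE" = 0.012
  )
  mid <- 22
  data.frame(
    feature = names(base),
    intercept = unname(base * (1 - rel_loading * mid)),
    loading = unname(base * rel_loading),
    noise_sd = rep(0.08, length(base)),
    stringsAsFactors = FALSE
  )
}

rtruncnorm1 <- function(n, mean, sd, lo, hi) {
  if (sd == 0) return(rep(mean, n))
  x <- rnorm(n, mean, sd)
  while (any(bad <- x < lo | x > hi)) x[bad] <- rnorm(sum(bad), mean, sd)
  x
}

#' Generate a synthetic telemonitoring cohort
#'
#' Draws per-patient demographics, irregular visit times, a latent linear
#' severity trajectory `s(t) = baseline + slope * t`, observed motor UPDRS
#' `clip(s(t) + AR(1) noise)`, total UPDRS as motor plus a positive offset,
#' and the 16 acoustic measures as
#' `intercept + loading * s(t) * exp(noise)`. Identical seeds reproduce
#' identical cohorts bit-for-bit.
#'
#' @param config A [cohort_config()].
#' @return A `telemon_cohort` with a `ground_truth` attribute (see
#'   [ground_truth()]).
#' @export
generate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$rng_seed)
  n <- config$n_patients
  ids <- sprintf("S%02d", seq_len(n))
  ages <- round(rtruncnorm1(n, config$age_mean, config$age_sd,
                            config$age_range[1], config$age_range[2]))
  sexes <- rbinom(n, 1, 1 - config$male_fraction)  # 0 = male, 1 = female
  baselines <- runif(n, config$baseline_range[1], config$baseline_range[2])
  slopes <- rnorm(n, config$slope_mean, config$slope_sd)
  vc <- config$voice_coupling
  vc <- vc[match(uci_voice_columns, vc$feature), ]

  cohort <- vector("list", n)
  for (i in seq_len(n)) {
    nv <- if (config$visits_range[1] == config$visits_range[2]) {
      config$visits_range[1]
    } else {
      sample(config$visits_range[1]:config$visits_range[2], 1)
    }
    tt <- sort(runif(nv, 0, config$duration_days))
    # enforce strictly increasing times (ties are measure-zero but guard)
    tt <- tt + seq(0, by = 1e-6, length.out = nv)
    sev <- baselines[i] + slopes[i] * tt
    eps <- numeric(nv)
    innov_sd <- config$noise_sd * sqrt(1 - config$ar1_rho^2)
    if (config$noise_sd > 0) {
      eps[1] <- rnorm(1, 0, config$noise_sd)
      for (k in seq_len(nv)[-1]) {
        eps[k] <- config$ar1_rho * eps[k - 1] + rnorm(1, 0, innov_sd)
      }
    }
    motor <- pmin(pmax(sev + eps, config$updrs_clip[1]), config$updrs_clip[2])
    offset <- runif(1, config$total_offset_range[1],
                    config$total_offset_range[2])
    total <- motor + offset
    voice <- matrix(0, nv, length(uci_voice_columns),
                    dimnames = list(NULL, uci_voice_columns))
    for (j in seq_along(uci_voice_columns)) {
      mu <- vc$intercept[j] + vc$loading[j] * sev
      noise <- exp(rnorm(nv, 0, vc$noise_sd[j]))
      voice[, j] <- mu * noise
    }
    visits <- data.frame(test_time = tt, motor_updrs = motor,
                         total_updrs = total, check.names = FALSE)
    visits <- cbind(visits, as.data.frame(voice, check.names = FALSE))
    cohort[[i]] <- structure(
      list(subject_id = ids[i], age = ages[i], sex = sexes[i],
           visits = visits),
      class = "patient_series"
    )
  }
  truth <- data.frame(subject_id = ids, baseline = baselines, slope = slopes,
                      stringsAsFactors = FALSE)
  structure(cohort, class = "telemon_cohort",
            sex_codes = c(male = 0, female = 1), ground_truth = truth)
}

#' Latent trajectory parameters of a synthetic cohort
#'
#' Returns the per-patient (baseline, slope) used by [generate_cohort()],
#' enabling parameter-recovery checks: on a noise-free cohort an ordinary
#' least-squares fit of motor UPDRS on test_time recovers these exactly.
#'
#' @param cohort A cohort produced by [generate_cohort()].
#' @return Data frame with columns `subject_id`, `baseline`, `slope`.
#' @export
ground_truth <- function(cohort) {
  truth <- attr(cohort, "ground_truth")
  if (is.null(truth)) {
    stop("cohort carries no ground truth (not generated by generate_cohort)",
         call. = FALSE)
  }
  truth
}
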