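#' Feature-engineering configuration
#'
#' Defaults follow the telemonitoring feature-engineering recipe: a
#' Savitzky-Golay denoiser (window 5 visits, quadratic), 3-visit trailing
#' windows for rolling mean/sd, 5-visit trailing windows for rolling
#' skewness/kurtosis, within-patient z-scores with stability constant
#' `eps = 0.01` and clipping at +/-5, a +/-0.5-point dead band for the
#' progression-rate category, and supervised windows of `T = 10` visits.
#'
#' @param savgol_window,savgol_polyorder Denoiser window (odd) and
#'   polynomial order.
#' @param roll_window_stats Trailing window for rolling mean/sd (visits).
#' @param roll_window_moments Trailing window for rolling skewness/kurtosis.
#' @param zscore_eps,zscore_clip Stability constant and symmetric clip for
#'   within-patient z-scores.
#' @param delta_threshold Dead band (UPDRS points) separating improving /
#'   stable / worsening visit-to-visit change.
#' @param sequence_length Supervised window length `T` in visits (>= 3).
#' @param causal_denoise If `TRUE`, the denoiser uses trailing-only fits so
#'   no smoothed value touches later visits; the default centred filter is
#'   confined to the input window of each supervised sample.
#' @param derivatives_on Compute velocity/acceleration from the `"denoised"`
#'   (default) or `"raw"` trace.
#' @param rolling_on Compute rolling statistics from the `"raw"` (default)
#'   or `"denoised"` trace.
#' @return A `feature_config` list.
#' @export
feature_config <- function(savgol_window = 5, savgol_polyorder = 2,
                           roll_window_stats = 3, roll_window_moments = 5,
                           zscore_eps = 0.01, zscore_clip = 5,
                           delta_threshold = 0.5, sequence_length = 10,
                           causal_denoise = FALSE,
                           derivatives_on = c("denoised", "raw"),
                           rolling_on = c("raw", "denoised")) {
  if (savgol_window %% 2 == 0 || savgol_window < 3) {
    stop("config error: savgol_window must be odd and >= 3", call. = FALSE)
  }
  if (savgol_polyorder >= savgol_window) {
    stop("config error: savgol_polyorder < savgol_window required",
         call. = FALSE)
  }
  if (zscore_eps <= 0) stop("config error: zscore_eps > 0", call. = FALSE)
  if (sequence_length < 3) {
    stop("config error: sequence_length >= 3", call. = FALSE)
  }
  structure(list(
    savgol_window = savgol_window, savgol_polyorder = savgol_polyorder,
    roll_window_stats = roll_window_stats,
    roll_window_moments = roll_window_moments,
    zscore_eps = zscore_eps, zscore_clip = zscore_clip,
    delta_threshold = delta_threshold, sequence_length = sequence_length,
    causal_denoise = causal_denoise,
    derivatives_on = match.arg(derivatives_on),
    rolling_on = match.arg(rolling_on)
  ), class = "feature_config")
}

#' Savitzky-Golay denoising of a visit series
#'
#' Local least-squares polynomial smoothing: each interior point is the
#' centre of a degree-`polyorder` fit over `window` neighbouring visits;
#' the first and last `window %/% 2` points come from the boundary window's
#' fit. A degree-2 filter therefore reproduces any quadratic series
#' exactly. Series shorter than the window are returned unchanged.
#'
#' @param series Numeric vector.
#' @param window Odd window length.
#' @param polyorder Polynomial order, less than `window`.
#' @param causal If `TRUE`, each point is the endpoint of a fit over the
#'   trailing `window` visits only (no look-ahead).
#' @return Numeric vector, same length as `series`.
#' @export
savgol_denoise <- function(series, window = 5, polyorder = 2,
                           causal = FALSE) {
  if (window %% 2 == 0) stop("config error: window must be odd",
                             call. = FALSE)
  if (polyorder >= window) stop("config error: polyorder < window",
                                call. = FALSE)
  n <- length(series)
  if (n < window) return(series)
  if (!causal) {
    return(as.numeric(signal::sgolayfilt(series, p = polyorder, n = window)))
  }
  out <- series
  for (i in seq_len(n)) {
    lo <- max(1, i - window + 1)
    idx <- lo:i
    if (length(idx) <= polyorder) next
    tt <- idx - i
    fit <- lm.fit(outer(tt, 0:polyorder, `^`), series[idx])
    out[i] <- fit$coefficients[1]
  }
  out
}

#' Velocity and acceleration of an irregularly sampled series
#'
#' First differences divided by the actual day gaps between visits
#' (velocity), and the same operator applied again (acceleration). The
#' first element of each is 0, there being no preceding visit.
#'
#' @param series Numeric vector.
#' @param times Strictly increasing visit times (days).
#' @return List with elements `velocity` and `acceleration`.
#' @export
temporal_derivatives <- function(series, times) {
  n <- length(series)
  stopifnot(length(times) == n)
  if (n > 1 && any(diff(times) <= 0)) {
    stop("degenerate input: times must be strictly increasing", call. = FALSE)
  }
  first_diff <- function(x) {
    if (length(x) < 2) return(rep(0, length(x)))
    c(0, diff(x) / diff(times))
  }
  vel <- first_diff(series)
  acc <- first_diff(vel)
  list(velocity = vel, acceleration = acc)
}

# central moments helper for a trailing window
.window_moment_stats <- function(w, which) {
  n <- length(w)
  switch(which,
    mean = mean(w),
    sd = if (n < 2) 0 else sd(w),
    skewness = {
      if (n < 3) return(0)
      m2 <- mean((w - mean(w))^2)
      if (m2 < .Machine$double.eps) return(0)
      g1 <- mean((w - mean(w))^3) / m2^1.5
      g1 * sqrt(n * (n - 1)) / (n - 2)
    },
    kurtosis = {
      if (n < 4) return(0)
      m2 <- mean((w - mean(w))^2)
      if (m2 < .Machine$double.eps) return(0)
      g2 <- mean((w - mean(w))^4) / m2^2 - 3
      ((n + 1) * g2 + 6) * (n - 1) / ((n - 2) * (n - 3))
    },
    stop("unknown statistic: ", which, call. = FALSE)
  )
}

#' Trailing rolling statistics
#'
#' Rolling mean, sample standard deviation (n-1), adjusted Fisher-Pearson
#' skewness or adjusted excess kurtosis over a trailing window ending at
#' each visit, with `min_periods = 1`: windows too short for a moment to be
#' defined yield 0. Trailing (rather than centred) windows keep every value
#' free of future-visit information.
#'
#' @param series Numeric vector.
#' @param window Window length, >= 2.
#' @param which One of `"mean"`, `"sd"`, `"skewness"`, `"kurtosis"`.
#' @return Numeric vector, same length as `series`.
#' @export
rolling_statistics <- function(series, window,
                               which = c("mean", "sd", "skewness",
                                         "kurtosis")) {
  which <- match.arg(which)
  stopifnot(window >= 2)
  n <- length(series)
  if (which %in% c("mean", "sd")) {
    # trailing sums via cumulative sums (lower moments vectorise cleanly)
    idx <- seq_len(n)
    lo <- pmax(1, idx - window + 1)
    nw <- idx - lo + 1
    c1 <- cumsum(series)
    s1 <- c1 - c(0, c1)[lo]
    if (which == "mean") return(s1 / nw)
    c2 <- cumsum(series^2)
    s2 <- c2 - c(0, c2)[lo]
    v <- (s2 - s1^2 / nw) / (nw - 1)
    out <- sqrt(pmax(v, 0))
    out[nw < 2] <- 0
    return(out)
  }
  vapply(seq_len(n), function(i) {
    .window_moment_stats(series[max(1, i - window + 1):i], which)
  }, numeric(1))
}

#' Within-patient z-scores with numerical stability
#'
#' `(x - mean) / (sd + eps)` with statistics over the patient's full series
#' (the panel-normalisation reading of "within-patient"), clipped to
#' `+/- clip`. A running-statistics variant that uses only visits up to
#' each index is available for strictly causal pipelines.
#'
#' @param series Numeric vector.
#' @param eps Stability constant added to the standard deviation.
#' @param clip Symmetric clipping bound.
#' @param causal If `TRUE`, mean and sd at index i use visits `1..i` only.
#' @return Numeric vector of clipped z-scores.
#' @export
within_patient_zscore <- function(series, eps = 0.01, clip = 5,
                                  causal = FALSE) {
  stopifnot(eps > 0)
  if (!causal) {
    s <- if (length(series) > 1) sd(series) else 0
    z <- (series - mean(series)) / (s + eps)
  } else {
    z <- vapply(seq_along(series), function(i) {
      w <- series[1:i]
      s <- if (i > 1) sd(w) else 0
      (series[i] - mean(w)) / (s + eps)
    }, numeric(1))
  }
  pmin(pmax(z, -clip), clip)
}

#' Composite voice indices
#'
#' The voice instability index is the mean of min-max-normalised jitter and
#' shimmer (normalised within the patient's series; a constant trace maps
#' to 0), and the voice quality ratio is `HNR / (NHR + 1e-6)`.
#'
#' @param jitter_pct,shimmer,hnr,nhr Numeric vectors over one patient's
#'   visits.
#' @return List with elements `instability_index` and `quality_ratio`.
#' @export
composite_indices <- function(jitter_pct, shimmer, hnr, nhr) {
  minmax <- function(x) {
    r <- max(x) - min(x)
    if (r < .Machine$double.eps) rep(0, length(x)) else (x - min(x)) / r
  }
  list(
    instability_index = (minmax(jitter_pct) + minmax(shimmer)) / 2,
    quality_ratio = hnr / (nhr + 1e-6)
  )
}

voice_transform_names <- c("raw", "denoised", "velocity", "acceleration",
                           "roll_mean", "roll_sd", "zscore", "roll_skew",
                           "roll_kurt")

#' Engineered voice feature block for one patient
#'
#' Expands each of the 16 base acoustic measures into nine transform
#' columns (raw, denoised, velocity, acceleration, rolling mean/sd,
#' within-patient z-score, rolling skewness/kurtosis) and appends the two
#' composite indices: 146 columns in the default manifest, in a fixed
#' order. All values are finite for any finite input, including one- and
#' two-visit series.
#'
#' @param series A `patient_series`.
#' @param config A [feature_config()].
#' @return Numeric matrix (visits x 146) with the manifest as column names.
#' @export
build_voice_features <- function(series, config = feature_config()) {
  v <- series$visits
  stopifnot(nrow(v) >= 1)
  times <- v$test_time
  cols <- vector("list", length(uci_voice_columns))
  for (j in seq_along(uci_voice_columns)) {
    x <- v[[uci_voice_columns[j]]]
    den <- savgol_denoise(x, config$savgol_window, config$savgol_polyorder,
                          causal = config$causal_denoise)
    der_src <- if (config$derivatives_on == "denoised") den else x
    der <- temporal_derivatives(der_src, times)
    roll_src <- if (config$rolling_on == "denoised") den else x
    cols[[j]] <- cbind(
      raw = x, denoised = den,
      velocity = der$velocity, acceleration = der$acceleration,
      roll_mean = rolling_statistics(roll_src, config$roll_window_stats,
                                     "mean"),
      roll_sd = rolling_statistics(roll_src, config$roll_window_stats, "sd"),
      zscore = within_patient_zscore(x, config$zscore_eps,
                                     config$zscore_clip),
      roll_skew = rolling_statistics(roll_src, config$roll_window_moments,
                                     "skewness"),
      roll_kurt = rolling_statistics(roll_src, config$roll_window_moments,
                                     "kurtosis")
    )
  }
  comp <- composite_indices(v[["Jitter(%)"]], v[["Shimmer"]],
                            v[["HNR"]], v[["NHR"]])
  out <- do.call(cbind, c(cols, list(cbind(
    instability_index = comp$instability_index,
    quality_ratio = comp$quality_ratio
  ))))
  manifest <- c(
    as.vector(t(outer(uci_voice_columns, voice_transform_names,
                      function(a, b) paste(a, b, sep = "__")))),
    "instability_index", "quality_ratio"
  )
  colnames(out) <- manifest
  stopifnot(all(is.finite(out)))
  out
}

#' Clinical progression feature block for one patient
#'
#' Nine per-visit columns computed from visit timing and *lagged* motor
#' UPDRS only, so no column at visit i touches the score at visit i or
#' later: days since first visit, visit number, inter-visit interval,
#' motor-UPDRS lag-1 and lag-2, their difference (delta), a trailing
#' 3-visit mean of delta, the disease stage of the lag-1 score, and a
#' progression-rate code (-1 improving / 0 stable / +1 worsening by the
#' configured dead band). Missing lags at the head of a series are imputed
#' with the patient's first observed score; the accompanying lag-validity
#' indicator is returned as an attribute.
#'
#' @param series A `patient_series`.
#' @param config A [feature_config()].
#' @return Numeric matrix (visits x 9) with a `lag_valid` attribute.
#' @export
build_clinical_features <- function(series, config = feature_config()) {
  v <- series$visits
  n <- nrow(v)
  stopifnot(n >= 1)
  y <- v$motor_updrs
  first_y <- y[1]
  lag1 <- if (n >= 2) c(first_y, y[1:(n - 1)]) else first_y
  lag2 <- if (n >= 3) c(first_y, first_y, y[1:(n - 2)]) else rep(first_y, n)
  delta <- lag1 - lag2
  trend3 <- rolling_statistics(delta, 3, "mean")
  stage_code <- match(classify_disease_stage(pmax(lag1, 0)),
                      c("Early", "Moderate", "Advanced")) - 1
  thr <- config$delta_threshold
  prog_code <- ifelse(delta < -thr, -1, ifelse(delta > thr, 1, 0))
  interval <- c(0, diff(v$test_time))
  out <- cbind(
    days_since_first = v$test_time - v$test_time[1],
    visit_number = seq_len(n),
    interval = interval,
    updrs_lag1 = lag1,
    updrs_lag2 = lag2,
    delta = delta,
    trend_3visit = trend3,
    stage_code = stage_code,
    progression_code = prog_code
  )
  attr(out, "lag_valid") <- cbind(lag1 = seq_len(n) > 1,
                                  lag2 = seq_len(n) > 2)
  out
}

# columns of the clinical block that are categorical codes (passed through
# unscaled by the robust scaler)
clinical_categorical_cols <- c(8L, 9L)

#' Demographic/temporal meta-feature block for one patient
#'
#' @param series A `patient_series`.
#' @return Numeric matrix (visits x 3): age, sex code, test_time.
#' @export
build_meta_features <- function(series) {
  n <- nrow(series$visits)
  cbind(age = rep(series$age, n), sex = rep(series$sex, n),
        test_time = series$visits$test_time)
}

#' Cut leakage-safe supervised windows from per-patient feature blocks
#'
#' For every target visit `i >= 3` (1-based), a window covers visits
#' `max(1, i - T + 1) .. i`, left-padded with zeros where the history is
#' shorter than `T`; the padding mask marks valid timesteps. The target is
#' the motor UPDRS at visit i. Voice and meta features at the target
#' timestep are contemporaneous measurements and are permitted; clinical
#' features use lagged scores only, so no feature cell depends on the
#' target-visit-or-later UPDRS.
#'
#' @param blocks List with elements `voice`, `clinical`, `meta` (matrices
#'   aligned to visits).
#' @param series The `patient_series` the blocks were built from.
#' @param config A [feature_config()] (supplies `sequence_length`).
#' @return List of `sequence_sample` objects: each has `subject_id`,
#'   `target_visit_index`, matrices `X_v`, `X_c`, `X_m` (T x D), `mask`
#'   (length T, 1 = valid) and scalar `y`. The text block `X_t` is attached
#'   downstream by the narrative pipeline.
#' @export
make_supervised_windows <- function(blocks, series,
                                    config = feature_config()) {
  Tlen <- config$sequence_length
  if (Tlen < 3) stop("config error: sequence_length >= 3", call. = FALSE)
  n <- nrow(series$visits)
  if (n < 3) return(list())
  lapply(3:n, function(i) {
    lo <- max(1, i - Tlen + 1)
    avail <- i - lo + 1
    pad <- Tlen - avail
    pad_rows <- function(M) {
      M <- M[lo:i, , drop = FALSE]
      if (pad > 0) M <- rbind(matrix(0, pad, ncol(M)), M)
      unname(M)
    }
    structure(list(
      subject_id = series$subject_id,
      target_visit_index = i,
      X_v = pad_rows(blocks$voice),
      X_c = pad_rows(blocks$clinical),
      X_m = pad_rows(blocks$meta),
      mask = c(rep(0, pad), rep(1, avail)),
      y = series$visits$motor_updrs[i]
    ), class = "sequence_sample")
  })
}
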