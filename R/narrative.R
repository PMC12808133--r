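#' Per-patient longitudinal statistics for the clinical narrative
#'
#' Computes the quantities the clinical-summary template reports: mean/sd
#' and least-squares per-visit slope of motor UPDRS, severity label (mild
#' <= 20 / moderate <= 40 / severe > 40 by mean score), progression pattern
#' (progressive / stable / improving with a +/-0.05 points-per-visit dead
#' band), symptom-variability label (high if SD > 5 else moderate), mean
#' jitter / shimmer / HNR with per-visit trend labels (increasing if the
#' slope exceeds 5% of the feature's patient mean per visit, else stable),
#' a vocal-impairment label from jitter/shimmer norm thresholds
#' (significant if jitter >= 0.01 or shimmer >= 0.06; mild if jitter <
#' 0.004 and shimmer < 0.02; else moderate), monitoring duration, number of
#' assessments and mean inter-visit interval.
#'
#' @param series A `patient_series`.
#' @param upto Last visit index to use (`Inf` = complete history, the
#'   default). In causal pipelines pass the target visit index so the
#'   narrative never sees later visits.
#' @param pattern_deadband Dead band (points/visit) for the pattern label.
#' @param variability_threshold SD threshold for "high" variability.
#' @param sex_codes Code-to-label mapping for the sex slot.
#' @return A `narrative_stats` list.
#' @export
compute_narrative_stats <- function(series, upto = Inf,
                                    pattern_deadband = 0.05,
                                    variability_threshold = 5,
                                    sex_codes = c(male = 0, female = 1)) {
  v <- series$visits
  n_all <- nrow(v)
  if (n_all < 1) stop("empty series", call. = FALSE)
  n <- min(n_all, upto)
  v <- v[seq_len(n), , drop = FALSE]
  y <- v$motor_updrs
  idx <- seq_len(n)
  ols_slope <- function(x) {
    if (length(x) < 2) return(0)
    unname(coef(lm.fit(cbind(1, idx), x))[2])
  }
  updrs_mean <- mean(y)
  updrs_sd <- if (n > 1) sd(y) else 0
  slope <- ols_slope(y)
  severity <- if (updrs_mean <= 20) "mild" else if (updrs_mean <= 40)
    "moderate" else "severe"
  pattern <- if (slope > pattern_deadband) "progressive" else
    if (slope < -pattern_deadband) "improving" else "stable"
  variability <- if (updrs_sd > variability_threshold) "high" else "moderate"
  jitter <- v[["Jitter(%)"]]
  shimmer <- v[["Shimmer"]]
  hnr <- v[["HNR"]]
  trend_label <- function(x) {
    s <- ols_slope(x)
    band <- 0.05 * abs(mean(x))
    list(slope = s, label = if (s > band) "increasing" else "stable")
  }
  jt <- trend_label(jitter)
  st <- trend_label(shimmer)
  jm <- mean(jitter); sm <- mean(shimmer)
  impairment <- if (jm >= 0.01 || sm >= 0.06) "significant" else
    if (jm < 0.004 && sm < 0.02) "mild" else "moderate"
  sex_label <- names(sex_codes)[match(series$sex, sex_codes)]
  structure(list(
    age = series$age, sex = sex_label,
    updrs_mean = updrs_mean, updrs_sd = updrs_sd, updrs_slope = slope,
    severity = severity, pattern = pattern, variability = variability,
    jitter_mean = jm, shimmer_mean = sm, hnr_mean = mean(hnr),
    jitter_trend = jt$label, jitter_slope = jt$slope,
    shimmer_trend = st$label, shimmer_slope = st$slope,
    impairment = impairment,
    duration_days = max(v$test_time) - min(v$test_time),
    n_assessments = n,
    mean_interval_days = if (n > 1)
      (max(v$test_time) - min(v$test_time)) / (n - 1) else 0
  ), class = "narrative_stats")
}

#' Render the clinical-summary narrative
#'
#' Instantiates the fixed clinical-presentation template with deterministic
#' number formatting: UPDRS mean/sd, HNR and interval to 1 decimal, the
#' per-visit slope to 2 decimals (with an upward/downward word carrying its
#' sign), jitter and shimmer to 4 decimals, duration and assessment count
#' as integers.
#'
#' @param stats A `narrative_stats` list.
#' @return A single summary string.
#' @export
render_summary <- function(stats) {
  f <- function(x, d) formatC(x, format = "f", digits = d)
  direction <- if (stats$updrs_slope >= 0) "upward" else "downward"
  expression_word <- if (stats$variability == "high") "variable" else
    "consistent"
  paste0(
    "Clinical presentation: ", stats$age, "-year-old ", stats$sex,
    " patient with Parkinson\u2019s disease under longitudinal",
    " telemonitoring. Disease severity: ", stats$severity,
    " (mean UPDRS: ", f(stats$updrs_mean, 1), ", SD: ",
    f(stats$updrs_sd, 1), "). Progression pattern: ", stats$pattern,
    " trajectory over ", round(stats$duration_days), " days with ",
    stats$n_assessments, " assessments, showing ", direction,
    " trend of ", f(abs(stats$updrs_slope), 2),
    " points per visit. Voice biomarkers indicate ", stats$impairment,
    " vocal impairment: jitter ", f(stats$jitter_mean, 4), " (",
    stats$jitter_trend, "), shimmer ", f(stats$shimmer_mean, 4),
    ", harmonics-to-noise ratio ", f(stats$hnr_mean, 1),
    " dB. Clinical monitoring shows ", stats$variability,
    " symptom variability, suggesting ", expression_word,
    " disease expression. Assessment frequency: ",
    f(stats$mean_interval_days, 1), " days per visit interval."
  )
}

#' Deterministic feature-hashing text encoder
#'
#' An offline embedding backend implementing the `text -> 768-dim` encoder
#' contract, built to emulate the geometry of a pretrained sentence
#' encoder: similar summaries map to nearby vectors, unrelated texts to
#' nearly orthogonal ones, and identical texts to identical vectors. Word
#' tokens are hashed to signed coordinates of a fixed-seed random
#' projection. Numeric tokens are not hashed discretely (which would make
#' every unseen value an unrelated direction); instead each number is
#' keyed by its preceding word ("UPDRS: 28.3" and "ratio 21.8" occupy
#' different blocks) and written as multi-scale sine/cosine features of
#' its value, so numerically close summaries stay close in embedding
#' space. The accumulated vector is L2-normalised. Any encoder exposing
#' `dim` and `encode(texts)` (an `n x dim` matrix) can be substituted,
#' e.g. a pretrained transformer sentence encoder.
#'
#' @param dim Embedding dimension (768 matches the sentence-encoder
#'   contract used by the model).
#' @param seed Hashing seed mixed into the token hash.
#' @return An encoder object.
#' @export
hashing_encoder <- function(dim = 768, seed = 1234) {
  force(dim); force(seed)
  num_scales <- c(0.002, 0.02, 0.2, 2, 20, 200)
  hash_token <- function(tok, salt) {
    bytes <- as.integer(charToRaw(tok))
    h <- (salt * 2654435761 + seed) %% 2147483647
    for (b in bytes) h <- (h * 31 + b) %% 2147483647
    h
  }
  encode_one <- function(text) {
    toks <- strsplit(gsub("[^a-z0-9.]+", " ", tolower(text)),
                     "[[:space:]]+")[[1]]
    toks <- toks[nzchar(toks)]
    v <- numeric(dim)
    prev <- ""
    for (tok in toks) {
      if (grepl("^[0-9]+(\\.[0-9]+)?$", tok)) {
        val <- as.numeric(tok)
        k0 <- hash_token(paste0(prev, "#num"), 3) %%
          (dim - 2 * length(num_scales))
        for (j in seq_along(num_scales)) {
          v[k0 + 2 * j - 1] <- v[k0 + 2 * j - 1] + sin(val / num_scales[j])
          v[k0 + 2 * j] <- v[k0 + 2 * j] + cos(val / num_scales[j])
        }
      } else {
        i <- hash_token(tok, 1) %% dim + 1
        s <- if (hash_token(tok, 2) %% 2 == 0) 1 else -1
        v[i] <- v[i] + s
      }
      prev <- tok
    }
    nrm <- sqrt(sum(v^2))
    if (nrm > 0) v / nrm else v
  }
  structure(list(
    name = "feature-hashing projector",
    dim = dim,
    encode = function(texts) {
      out <- t(vapply(texts, encode_one, numeric(dim)))
      rownames(out) <- NULL
      out
    }
  ), class = "text_encoder")
}

#' Embed a clinical summary
#'
#' @param text Non-empty summary string.
#' @param encoder An encoder object such as [hashing_encoder()].
#' @return A `narrative_embedding`: list with the 768-dim numeric vector
#'   `e` and the `source_text`.
#' @export
embed_summary <- function(text, encoder = hashing_encoder()) {
  stopifnot(is.character(text), length(text) == 1, nzchar(text))
  e <- encoder$encode(text)[1, ]
  if (length(e) != encoder$dim || length(e) != 768) {
    stop("contract error: encoder must produce 768-dimensional vectors",
         call. = FALSE)
  }
  if (any(!is.finite(e))) {
    stop("contract error: non-finite embedding entries", call. = FALSE)
  }
  structure(list(e = e, source_text = text), class = "narrative_embedding")
}

#' Tile an embedding across timesteps
#'
#' @param embedding A `narrative_embedding` (or bare numeric vector).
#' @param T Number of timesteps, >= 1.
#' @return A `T x length(e)` matrix whose rows all equal the embedding.
#' @export
tile_embedding <- function(embedding, T) {
  stopifnot(T >= 1)
  e <- if (inherits(embedding, "narrative_embedding")) embedding$e else
    embedding
  matrix(e, nrow = T, ncol = length(e), byrow = TRUE)
}
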