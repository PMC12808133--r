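#' Regression metrics
#'
#' MAE, MSE, RMSE and the coefficient of determination `R^2 = 1 -
#' SS_res/SS_tot` (SS_tot about the mean of `y`). A zero-variance target
#' leaves R^2 undefined; it is returned as `NA` with `r2_defined = FALSE`.
#'
#' @param y,yhat Observed and predicted values (equal nonzero length).
#' @return List with `MAE`, `MSE`, `RMSE`, `R2`, `r2_defined`.
#' @export
regression_metrics <- function(y, yhat) {
  stopifnot(length(y) == length(yhat), length(y) > 0)
  res <- y - yhat
  mse <- mean(res^2)
  ss_tot <- sum((y - mean(y))^2)
  r2_def <- ss_tot > 0
  list(MAE = mean(abs(res)), MSE = mse, RMSE = sqrt(mse),
       R2 = if (r2_def) 1 - sum(res^2) / ss_tot else NA_real_,
       r2_defined = r2_def)
}

#' Repeated patient-level k-fold assignments
#'
#' Each repetition freshly shuffles the patients (seed `seed + repetition`)
#' and partitions them into k folds of size `floor(n/k)` or `ceiling(n/k)`,
#' so every patient is tested exactly once per repetition and `repeats`
#' times overall. Window-level data never crosses patient boundaries.
#'
#' @param patient_ids Character vector of unique patient identifiers.
#' @param k Folds per repetition.
#' @param repeats Number of repetitions.
#' @param seed Base seed; repetition r uses `seed + r`.
#' @return Data frame with columns `repetition`, `fold`, `subject_id`.
#' @export
repeated_patient_kfold <- function(patient_ids, k = 5, repeats = 8,
                                   seed = 1) {
  patient_ids <- unique(as.character(patient_ids))
  n <- length(patient_ids)
  if (k > n) stop("k exceeds the number of patients", call. = FALSE)
  out <- list()
  for (r in seq_len(repeats)) {
    set.seed(seed + r)
    ord <- sample(patient_ids)
    # contiguous blocks of the shuffled order, sizes floor/ceiling(n/k)
    sizes <- rep(n %/% k, k) + c(rep(1, n %% k), rep(0, k - n %% k))
    fold_of <- rep(seq_len(k), times = sizes)
    out[[r]] <- data.frame(repetition = r, fold = fold_of,
                           subject_id = ord, stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Cross-validation run specification
#'
#' @param k,repeats Folds per repetition and number of repetitions.
#' @param seed Base seed for fold assignment and per-fold training seeds.
#' @param windows_per_patient Training windows kept per patient (evenly
#'   spaced over the visit sequence). Consecutive windows share all but one
#'   timestep, so a spaced subsample retains almost all of the training
#'   signal; evaluation always uses every test-patient window.
#' @param feature_config A [feature_config()].
#' @param narrative_mode,encoder Narrative pipeline options (see
#'   [build_feature_set()]).
#' @return A `cv_spec` list.
#' @export
cv_spec <- function(k = 5, repeats = 8, seed = 1,
                    windows_per_patient = 20,
                    val_windows_per_patient = 32,
                    feature_config = dcanet::feature_config(),
                    narrative_mode = "full_history",
                    encoder = hashing_encoder()) {
  structure(list(k = k, repeats = repeats, seed = seed,
                 windows_per_patient = windows_per_patient,
                 val_windows_per_patient = val_windows_per_patient,
                 feature_config = feature_config,
                 narrative_mode = narrative_mode, encoder = encoder),
            class = "cv_spec")
}

subsample_patient_windows <- function(fs, ids, per_patient) {
  unlist(lapply(ids, function(id) {
    idx <- which(fs$windows$subject_id == id)
    if (length(idx) > per_patient) {
      idx[unique(round(seq(1, length(idx), length.out = per_patient)))]
    } else idx
  }), use.names = FALSE)
}

# Train/evaluate one patient-level fold. Returns predictions and metrics.
run_fold <- function(fs, train_ids, test_ids, model_cfg, train_cfg,
                     fold_seed, windows_per_patient = Inf,
                     val_windows_per_patient = 32,
                     model_builder = NULL) {
  stopifnot(length(intersect(train_ids, test_ids)) == 0)
  scaler <- fit_scalers(fs, train_ids)
  sfs <- apply_scalers(fs, scaler)
  trn <- which(sfs$windows$subject_id %in% train_ids)
  tst <- which(sfs$windows$subject_id %in% test_ids)
  if (is.null(model_builder)) {
    model <- build_model(model_cfg, seed = fold_seed)
  } else {
    model <- model_builder(fold_seed)
  }
  tcfg <- train_cfg
  tcfg$train_windows_per_patient <- windows_per_patient
  tcfg$val_windows_per_patient <- val_windows_per_patient
  tcfg$rng_seed <- fold_seed
  fit <- train_model(model, sfs, trn, tcfg)
  yhat <- predict_model(fit$model, sfs, tst)
  y <- sfs$windows$y[tst]
  m <- regression_metrics(y, yhat)
  list(metrics = m, y = y, yhat = yhat, history = fit$history,
       model = fit$model)
}

fold_seed_for <- function(seed, rep, fold) {
  (seed + 7919 * rep + 104729 * fold) %% 2147483647L
}

#' Repeated patient-level cross-validation of the full pipeline
#'
#' For every fold: fits the robust scalers on the training patients only,
#' trains a freshly initialised network, and evaluates pooled predictions
#' over every window of the held-out patients. Metrics are aggregated over
#' folds as mean, sample sd, min, max, range, a t-based 95% confidence
#' interval and the coefficient of variation.
#'
#' @param cohort A `telemon_cohort`.
#' @param model_cfg A [model_config()].
#' @param train_cfg A [train_config()].
#' @param cv A [cv_spec()].
#' @param fs Optional pre-built feature set (e.g. to share across runs).
#' @param verbose Print per-fold progress.
#' @return A `cv_report`: list with `folds` (one row per fold: repetition,
#'   fold, MAE, MSE, RMSE, R2) and `summary` (per-metric aggregation).
#' @export
run_cv <- function(cohort, model_cfg = model_config(),
                   train_cfg = train_config(), cv = cv_spec(),
                   fs = NULL, verbose = FALSE) {
  if (is.null(fs)) {
    fcfg <- cv$feature_config
    fcfg$sequence_length <- model_cfg$sequence_length
    fs <- build_feature_set(cohort, fcfg, cv$narrative_mode, cv$encoder)
  }
  ids <- vapply(cohort, function(s) s$subject_id, character(1))
  assign_tab <- repeated_patient_kfold(ids, cv$k, cv$repeats, cv$seed)
  rows <- list()
  preds <- list()
  for (r in seq_len(cv$repeats)) {
    for (f in seq_len(cv$k)) {
      test_ids <- assign_tab$subject_id[assign_tab$repetition == r &
                                          assign_tab$fold == f]
      train_ids <- setdiff(ids, test_ids)
      res <- run_fold(fs, train_ids, test_ids, model_cfg, train_cfg,
                      fold_seed_for(cv$seed, r, f),
                      cv$windows_per_patient,
                      cv$val_windows_per_patient %||% 32)
      rows[[length(rows) + 1]] <- data.frame(
        repetition = r, fold = f,
        MAE = res$metrics$MAE, MSE = res$metrics$MSE,
        RMSE = res$metrics$RMSE, R2 = res$metrics$R2
      )
      preds[[length(preds) + 1]] <- data.frame(
        repetition = r, fold = f, y = res$y, yhat = res$yhat
      )
      if (verbose) {
        message(sprintf("rep %d fold %d: RMSE %.3f R2 %.4f", r, f,
                        res$metrics$RMSE, res$metrics$R2))
      }
    }
  }
  folds <- do.call(rbind, rows)
  predictions <- do.call(rbind, preds)
  # pooled test predictions per repetition (every patient held out once)
  pooled <- do.call(rbind, lapply(split(predictions,
                                        predictions$repetition),
                                  function(d) {
    m <- regression_metrics(d$y, d$yhat)
    data.frame(repetition = d$repetition[1], MAE = m$MAE, MSE = m$MSE,
               RMSE = m$RMSE, R2 = m$R2)
  }))
  rownames(pooled) <- NULL
  structure(list(folds = folds, summary = aggregate_cv(folds),
                 pooled = pooled, predictions = predictions),
            class = "cv_report")
}

#' Aggregate per-fold metrics into a cross-validation summary
#'
#' @param folds Data frame with columns `MAE`, `MSE`, `RMSE`, `R2`.
#' @return Data frame: one row per metric with mean, sd (sample, n-1),
#'   min, max, range, t-based 95% CI bounds and CV% (`sd/mean * 100`).
#' @export
aggregate_cv <- function(folds) {
  mets <- c("MAE", "MSE", "RMSE", "R2")
  do.call(rbind, lapply(mets, function(m) {
    x <- folds[[m]]
    n <- length(x)
    s <- if (n > 1) sd(x) else 0
    half <- if (n > 1) qt(0.975, n - 1) * s / sqrt(n) else 0
    data.frame(metric = m, mean = mean(x), sd = s, min = min(x),
               max = max(x), range = max(x) - min(x),
               ci_lo = mean(x) - half, ci_hi = mean(x) + half,
               cv_pct = if (mean(x) != 0) 100 * s / abs(mean(x)) else NA_real_)
  }))
}

#' Paired t-test on fold-wise metrics
#'
#' Classic paired t on the fold-wise differences. Identical samples (zero
#' variance of the differences) are flagged as exact ties with `t = 0`,
#' `p = 1` when the mean difference is zero.
#'
#' @param metric_a,metric_b Equal-length paired samples (n >= 2).
#' @return List with `t`, `p`, `df`, `mean_diff`, `tie`.
#' @export
paired_t_test <- function(metric_a, metric_b) {
  stopifnot(length(metric_a) == length(metric_b), length(metric_a) >= 2)
  d <- metric_a - metric_b
  if (sd(d) < 1e-14) {
    md <- mean(d)
    if (abs(md) < 1e-14) {
      return(list(t = 0, p = 1, df = length(d) - 1, mean_diff = 0,
                  tie = TRUE))
    }
    return(list(t = sign(md) * Inf, p = 0, df = length(d) - 1,
                mean_diff = md, tie = TRUE))
  }
  ht <- t.test(metric_a, metric_b, paired = TRUE)
  list(t = unname(ht$statistic), p = ht$p.value,
       df = unname(ht$parameter), mean_diff = unname(ht$estimate),
       tie = FALSE)
}

#' Kendall's coefficient of concordance (W)
#'
#' Agreement of m raters (folds) ranking k items (configurations), with
#' the standard mid-rank tie correction:
#' `W = 12 S / (m^2 (k^3 - k) - m sum(T_j))` where S is the sum of squared
#' deviations of the item rank sums and `T_j = sum(t^3 - t)` over the tie
#' groups of rater j.
#'
#' @param ranks `k x m` matrix: entry (i, j) is item i's rank (or raw
#'   score; scores are converted to mid-ranks) under rater j.
#' @return W in \[0, 1\].
#' @export
kendalls_w <- function(ranks) {
  ranks <- as.matrix(ranks)
  k <- nrow(ranks)
  m <- ncol(ranks)
  if (k < 2 || m < 2) {
    stop("degenerate input: need >= 2 items and >= 2 raters", call. = FALSE)
  }
  R <- apply(ranks, 2, function(x) rank(x, ties.method = "average"))
  Rsum <- rowSums(R)
  S <- sum((Rsum - mean(Rsum))^2)
  Tj <- apply(R, 2, function(x) {
    tt <- table(x)
    sum(tt^3 - tt)
  })
  denom <- m^2 * (k^3 - k) - m * sum(Tj)
  if (denom <= 0) return(1)
  12 * S / denom
}

#' Bland-Altman agreement statistics
#'
#' @param y,yhat Paired measurements (length >= 2).
#' @return List with `bias = mean(yhat - y)` and the 95% limits of
#'   agreement `bias +/- 1.96 sd(yhat - y)`.
#' @export
bland_altman <- function(y, yhat) {
  stopifnot(length(y) == length(yhat), length(y) >= 2)
  d <- yhat - y
  bias <- mean(d)
  s <- sd(d)
  list(bias = bias, loa_lower = bias - 1.96 * s, loa_upper = bias + 1.96 * s)
}

# The six standard modality configurations of the ablation study.
ablation_configurations <- list(
  "Clinical only" = c("clinical"),
  "Text only" = c("text"),
  "Clinical+Text" = c("clinical", "text"),
  "Clinical+Meta" = c("clinical", "meta"),
  "Clinical+Voice+Meta" = c("clinical", "voice", "meta"),
  "Full" = c("voice", "clinical", "meta", "text")
)

#' Modality ablation study under identical fold assignments
#'
#' Trains each requested modality configuration with the ablation
#' hyperparameter preset over the same repeated patient-level folds
#' (identical partitions and per-fold seeds across configurations); absent
#' modalities are removed from the encoders and the fusion softmax
#' re-normalises over the remainder. Reports per-configuration RMSE and
#' R^2 with the percent RMSE change versus the clinical-only baseline, and
#' the fold-wise rank matrix for [kendalls_w()].
#'
#' @param cohort A `telemon_cohort`.
#' @param cv A [cv_spec()].
#' @param configurations Named list of modality subsets; default the six
#'   standard configurations.
#' @param model_cfg,train_cfg Ablation presets by default.
#' @param fs Optional pre-built feature set.
#' @param verbose Print progress.
#' @return List with `table` (per-configuration summary), `folds`
#'   (per-configuration fold metrics), `rank_matrix` (configurations x
#'   folds, ranked by RMSE) and `kendalls_w`.
#' @export
ablation_runner <- function(cohort, cv = cv_spec(),
                            configurations = ablation_configurations,
                            model_cfg = NULL, train_cfg = NULL,
                            fs = NULL, verbose = FALSE) {
  bad <- setdiff(unlist(configurations),
                 c("voice", "clinical", "meta", "text"))
  if (length(bad) > 0) {
    stop("unknown modality in configuration: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  if (is.null(train_cfg)) train_cfg <- ablation_train_config()
  base_model_cfg <- model_cfg
  if (is.null(fs)) {
    fcfg <- cv$feature_config
    fs <- build_feature_set(cohort, fcfg, cv$narrative_mode, cv$encoder)
  }
  per_cfg <- list()
  for (cfg_name in names(configurations)) {
    mods <- configurations[[cfg_name]]
    mcfg <- if (is.null(base_model_cfg)) {
      ablation_model_config(
        modalities = mods,
        sequence_length = cv$feature_config$sequence_length
      )
    } else {
      mc <- base_model_cfg
      mc$modalities <- mods
      mc
    }
    if (verbose) message("configuration: ", cfg_name)
    report <- run_cv(cohort, mcfg, train_cfg, cv, fs = fs,
                     verbose = verbose)
    per_cfg[[cfg_name]] <- report
  }
  reports <- per_cfg
  per_cfg <- lapply(per_cfg, `[[`, "folds")
  rmse_mat <- do.call(rbind, lapply(per_cfg, function(f) f$RMSE))
  rank_matrix <- apply(rmse_mat, 2, function(x)
    rank(x, ties.method = "average"))
  rownames(rank_matrix) <- names(configurations)
  clin <- per_cfg[["Clinical only"]]
  tab <- do.call(rbind, lapply(names(per_cfg), function(nm) {
    f <- per_cfg[[nm]]
    pct <- if (!is.null(clin)) {
      100 * (mean(f$RMSE) - mean(clin$RMSE)) / mean(clin$RMSE)
    } else NA_real_
    data.frame(configuration = nm, RMSE_mean = mean(f$RMSE),
               RMSE_sd = sd(f$RMSE), R2_mean = mean(f$R2),
               R2_sd = sd(f$R2), pct_change_vs_clinical = pct,
               stringsAsFactors = FALSE)
  }))
  W <- if (length(per_cfg) >= 2 && ncol(rank_matrix) >= 2) {
    kendalls_w(rank_matrix)
  } else NA_real_
  list(table = tab, folds = per_cfg, rank_matrix = rank_matrix,
       kendalls_w = W, reports = reports)
}

#' Classical baseline comparison under identical folds
#'
#' Fits ridge regression (glmnet), gradient-boosted trees (xgboost), a
#' random forest (ranger) and a single-layer recurrent regressor on
#' flattened final-timestep features (voice + clinical + meta, optionally
#' text) with exactly the fold assignments of [repeated_patient_kfold()].
#' A failing baseline is recorded and does not abort the others.
#'
#' @param cohort A `telemon_cohort`.
#' @param cv A [cv_spec()].
#' @param include_text Give the baselines the text embeddings too.
#' @param baselines Subset of
#'   `c("ridge", "gradient_boosting", "random_forest", "simple_recurrent")`.
#' @param fs Optional pre-built feature set.
#' @param verbose Print progress.
#' @return List with `folds` (per baseline per fold metrics) and `summary`.
#' @export
baseline_harness <- function(cohort, cv = cv_spec(),
                             include_text = FALSE,
                             baselines = c("ridge", "gradient_boosting",
                                           "random_forest",
                                           "simple_recurrent"),
                             fs = NULL, verbose = FALSE) {
  baselines <- match.arg(baselines, several.ok = TRUE)
  if (is.null(fs)) {
    fs <- build_feature_set(cohort, cv$feature_config, cv$narrative_mode,
                            cv$encoder)
  }
  ids <- names(fs$patients)
  assign_tab <- repeated_patient_kfold(ids, cv$k, cv$repeats, cv$seed)
  rows <- list()
  for (r in seq_len(cv$repeats)) {
    for (f in seq_len(cv$k)) {
      test_ids <- assign_tab$subject_id[assign_tab$repetition == r &
                                          assign_tab$fold == f]
      train_ids <- setdiff(ids, test_ids)
      scaler <- fit_scalers(fs, train_ids)
      sfs <- apply_scalers(fs, scaler)
      trn <- subsample_patient_windows(sfs, train_ids,
                                       cv$windows_per_patient)
      tst <- which(sfs$windows$subject_id %in% test_ids)
      Xtr <- flatten_windows(sfs, trn, include_text)
      Xte <- flatten_windows(sfs, tst, include_text)
      ytr <- sfs$windows$y[trn]
      yte <- sfs$windows$y[tst]
      seed <- fold_seed_for(cv$seed, r, f)
      for (bl in baselines) {
        m <- tryCatch(
          fit_baseline(bl, Xtr, ytr, Xte, yte, sfs, trn, tst, seed),
          error = function(e) {
            warning("baseline ", bl, " failed on rep ", r, " fold ", f,
                    ": ", conditionMessage(e), call. = FALSE)
            NULL
          })
        if (is.null(m)) next
        rows[[length(rows) + 1]] <- data.frame(
          baseline = bl, repetition = r, fold = f, MAE = m$MAE,
          MSE = m$MSE, RMSE = m$RMSE, R2 = m$R2, stringsAsFactors = FALSE
        )
        if (verbose) {
          message(sprintf("rep %d fold %d %s: RMSE %.3f", r, f, bl,
                          m$RMSE))
        }
      }
    }
  }
  folds <- do.call(rbind, rows)
  summ <- do.call(rbind, lapply(split(folds, folds$baseline), function(d) {
    data.frame(baseline = d$baseline[1], MAE = mean(d$MAE),
               RMSE = mean(d$RMSE), RMSE_sd = sd(d$RMSE),
               R2 = mean(d$R2), stringsAsFactors = FALSE)
  }))
  rownames(summ) <- NULL
  list(folds = folds, summary = summ)
}

fit_baseline <- function(which, Xtr, ytr, Xte, yte, sfs, trn, tst, seed) {
  yhat <- switch(
    which,
    ridge = {
      if (!requireNamespace("glmnet", quietly = TRUE)) {
        stop("glmnet not available")
      }
      set.seed(seed)
      fit <- glmnet::cv.glmnet(Xtr, ytr, alpha = 0, nfolds = 5)
      as.numeric(predict(fit, Xte, s = "lambda.min"))
    },
    gradient_boosting = {
      if (!requireNamespace("xgboost", quietly = TRUE)) {
        stop("xgboost not available")
      }
      set.seed(seed)
      fit <- xgboost::xgboost(
        data = Xtr, label = ytr, nrounds = 150, eta = 0.1, max_depth = 4,
        objective = "reg:squarederror", verbose = 0, nthread = 1
      )
      as.numeric(predict(fit, Xte))
    },
    random_forest = {
      if (!requireNamespace("ranger", quietly = TRUE)) {
        stop("ranger not available")
      }
      dtr <- data.frame(y = ytr, Xtr)
      fit <- ranger::ranger(y ~ ., data = dtr, num.trees = 300,
                            seed = seed, num.threads = 1)
      predict(fit, data.frame(Xte))$predictions
    },
    simple_recurrent = {
      D <- ncol(sfs$patients[[1]]$voice) +
        ncol(sfs$patients[[1]]$clinical) + ncol(sfs$patients[[1]]$meta)
      model <- build_simple_recurrent(D, hidden_dim = 64, seed = seed)
      tcfg <- train_config(max_epochs = 30, early_stop_patience = 8,
                           rng_seed = seed)
      fit <- train_model(model, sfs, trn, tcfg)
      predict_model(fit$model, sfs, tst)
    },
    stop("unknown baseline: ", which)
  )
  regression_metrics(yte, yhat)
}
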