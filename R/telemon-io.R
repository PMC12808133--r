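#' @useDynLib dcanet, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats coef lm median pnorm dnorm qt rnorm runif rbinom sd
#'   quantile predict setNames cor t.test pt var
#' @importFrom utils read.csv write.csv head tail
#' @importFrom graphics plot abline
NULL

# The telemonitoring table dialect: 22 columns, in this order.
uci_voice_columns <- c(
  "Jitter(%)", "Jitter(Abs)", "Jitter:RAP", "Jitter:PPQ5", "Jitter:DDP",
  "Shimmer", "Shimmer(dB)", "Shimmer:APQ3", "Shimmer:APQ5", "Shimmer:APQ11",
  "Shimmer:DDA", "NHR", "HNR", "RPDE", "DFA", "PPE"
)
uci_columns <- c("subject#", "age", "sex", "test_time", "motor_UPDRS",
                 "total_UPDRS", uci_voice_columns)

norm_colname <- function(x) tolower(gsub("[[:space:]]", "", x))

#' Read a telemonitoring visit table
#'
#' Parses the standard Parkinson's telemonitoring CSV dialect: one row per
#' at-home voice recording with subject identifier, demographics, days since
#' recruitment, motor and total UPDRS, and 16 acoustic dysphonia measures.
#' Column matching is case- and whitespace-insensitive; column order in the
#' file is irrelevant.
#'
#' @param path Path to a CSV file with the 22 expected columns.
#' @param sex_codes Named integer vector mapping the stored 0/1 code to
#'   labels. The default follows the UCI convention (0 = male, 1 = female).
#' @return A `visit_table`: a data.frame with one row per visit, columns
#'   `subject_id`, `age`, `sex` (0/1 code), `test_time`, `motor_updrs`,
#'   `total_updrs` and the 16 acoustic measures under their standard names.
#' @export
read_telemonitoring_table <- function(path,
                                      sex_codes = c(male = 0, female = 1)) {
  if (!file.exists(path)) {
    stop("telemonitoring file not found: ", path, call. = FALSE)
  }
  raw <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  have <- norm_colname(names(raw))
  want <- norm_colname(uci_columns)
  missing <- uci_columns[!(want %in% have)]
  if (length(missing) > 0) {
    stop("schema error: missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  raw <- raw[, match(want, have), drop = FALSE]
  names(raw) <- uci_columns
  for (cn in setdiff(uci_columns, "subject#")) {
    v <- raw[[cn]]
    if (!is.numeric(v)) {
      vn <- suppressWarnings(as.numeric(v))
      bad <- which(is.na(vn) & !is.na(v))
      if (length(bad) > 0) {
        stop("parse error: non-numeric value in column '", cn,
             "' at data row ", bad[1], call. = FALSE)
      }
      raw[[cn]] <- vn
    }
  }
  if (any(!is.finite(raw[["motor_UPDRS"]]))) {
    stop("parse error: non-finite motor_UPDRS value", call. = FALSE)
  }
  if (any(!is.finite(raw[["test_time"]]))) {
    stop("parse error: non-finite test_time value", call. = FALSE)
  }
  out <- data.frame(
    subject_id = as.character(raw[["subject#"]]),
    age = raw[["age"]],
    sex = raw[["sex"]],
    test_time = raw[["test_time"]],
    motor_updrs = raw[["motor_UPDRS"]],
    total_updrs = raw[["total_UPDRS"]],
    check.names = FALSE, stringsAsFactors = FALSE
  )
  out <- cbind(out, raw[uci_voice_columns])
  attr(out, "sex_codes") <- sex_codes
  class(out) <- c("visit_table", "data.frame")
  out
}

#' Group visit records into per-patient series
#'
#' @param records A `visit_table` (or plain data.frame with the same
#'   columns) of visit records.
#' @return A `telemon_cohort`: a list of `patient_series`, ordered by
#'   ascending subject identifier. Each series holds `subject_id`, `age`,
#'   `sex`, and a `visits` data.frame sorted by `test_time`.
#' @export
build_patient_series <- function(records) {
  stopifnot(is.data.frame(records))
  ids <- sort(unique(as.character(records$subject_id)))
  cohort <- lapply(ids, function(id) {
    rows <- records[as.character(records$subject_id) == id, , drop = FALSE]
    if (length(unique(rows$age)) != 1 || length(unique(rows$sex)) != 1) {
      stop("consistency error: subject ", id,
           " has conflicting age or sex values", call. = FALSE)
    }
    rows <- rows[order(rows$test_time), , drop = FALSE]
    visits <- rows[, c("test_time", "motor_updrs", "total_updrs",
                       uci_voice_columns), drop = FALSE]
    rownames(visits) <- NULL
    structure(
      list(subject_id = id, age = rows$age[1], sex = rows$sex[1],
           visits = visits),
      class = "patient_series"
    )
  })
  structure(cohort, class = "telemon_cohort",
            sex_codes = attr(records, "sex_codes") %||%
              c(male = 0, female = 1))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Classify disease stage from a motor-UPDRS score
#'
#' Stages follow the conventional motor-UPDRS grid: Early for scores in
#' \[0, 20\], Moderate in (20, 40\], Advanced above 40. Closed-on-the-left
#' category bounds remove the gaps a printed integer grid ("0-20", "21-40")
#' would leave for continuous scores.
#'
#' @param updrs Motor-UPDRS score(s), finite and non-negative.
#' @return Character vector in `c("Early", "Moderate", "Advanced")`.
#' @export
classify_disease_stage <- function(updrs) {
  if (any(!is.finite(updrs)) || any(updrs < 0)) {
    stop("domain error: motor-UPDRS must be finite and >= 0", call. = FALSE)
  }
  ifelse(updrs <= 20, "Early", ifelse(updrs <= 40, "Moderate", "Advanced"))
}

#' Cohort demographic and voice-feature summary
#'
#' Computes the standard cohort description for a telemonitoring study:
#' patient counts, age and sex distribution, disease-stage counts (from each
#' patient's mean motor UPDRS by default), monitoring duration in months
#' (mean Gregorian month of 30.44 days), and per-feature voice statistics
#' averaged within patients first, then summarized across patients.
#'
#' @param cohort A `telemon_cohort`.
#' @param stage_from `"mean"` (default) stages each patient by mean motor
#'   UPDRS; `"baseline"` uses the first visit's score.
#' @return A `cohort_summary` list.
#' @export
cohort_summary <- function(cohort, stage_from = c("mean", "baseline")) {
  stage_from <- match.arg(stage_from)
  if (length(cohort) == 0) stop("domain error: empty cohort", call. = FALSE)
  sex_codes <- attr(cohort, "sex_codes") %||% c(male = 0, female = 1)
  ages <- vapply(cohort, function(s) s$age, numeric(1))
  sexes <- vapply(cohort, function(s) s$sex, numeric(1))
  stage_scores <- vapply(cohort, function(s) {
    if (stage_from == "mean") mean(s$visits$motor_updrs)
    else s$visits$motor_updrs[1]
  }, numeric(1))
  stages <- classify_disease_stage(stage_scores)
  stage_counts <- vapply(c("Early", "Moderate", "Advanced"),
                         function(st) sum(stages == st), numeric(1))
  durations <- vapply(cohort, function(s) {
    (max(s$visits$test_time) - min(s$visits$test_time)) / 30.44
  }, numeric(1))
  n <- length(cohort)
  per_patient_voice <- t(vapply(cohort, function(s) {
    colMeans(as.matrix(s$visits[, uci_voice_columns, drop = FALSE]))
  }, numeric(length(uci_voice_columns))))
  voice_means <- data.frame(
    feature = uci_voice_columns,
    mean = colMeans(per_patient_voice),
    sd = if (n > 1) apply(per_patient_voice, 2, sd) else rep(0, ncol(per_patient_voice)),
    row.names = NULL, stringsAsFactors = FALSE
  )
  structure(list(
    n_patients = n,
    n_records = sum(vapply(cohort, function(s) nrow(s$visits), numeric(1))),
    age_mean = mean(ages),
    age_sd = if (n > 1) sd(ages) else 0,
    n_male = sum(sexes == sex_codes[["male"]]),
    n_female = sum(sexes == sex_codes[["female"]]),
    stage_counts = stage_counts,
    duration_mean = mean(durations),
    duration_sd = if (n > 1) sd(durations) else 0,
    voice_means = voice_means
  ), class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf("Telemonitoring cohort: %d patients, %d recordings\n",
              x$n_patients, x$n_records))
  cat(sprintf("  Age (years): %.1f +/- %.1f\n", x$age_mean, x$age_sd))
  cat(sprintf("  Sex: %d male / %d female\n", x$n_male, x$n_female))
  cat(sprintf("  Stage: Early %d, Moderate %d, Advanced %d\n",
              x$stage_counts[["Early"]], x$stage_counts[["Moderate"]],
              x$stage_counts[["Advanced"]]))
  cat(sprintf("  Monitoring duration (months): %.1f +/- %.1f\n",
              x$duration_mean, x$duration_sd))
  sel <- x$voice_means[x$voice_means$feature %in%
                         c("HNR", "Jitter(%)", "Shimmer"), ]
  for (i in seq_len(nrow(sel))) {
    cat(sprintf("  %s: %.4f +/- %.4f\n", sel$feature[i], sel$mean[i],
                sel$sd[i]))
  }
  invisible(x)
}

#' Write a cohort back to the telemonitoring CSV dialect
#'
#' Emits the 22 columns in the canonical order at full float precision, so
#' that [read_telemonitoring_table()] inverts it.
#'
#' @param cohort A `telemon_cohort`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_telemonitoring_csv <- function(cohort, path) {
  rows <- lapply(cohort, function(s) {
    v <- s$visits
    data.frame(
      `subject#` = rep(s$subject_id, nrow(v)),
      age = rep(s$age, nrow(v)), sex = rep(s$sex, nrow(v)),
      test_time = v$test_time, motor_UPDRS = v$motor_updrs,
      total_UPDRS = v$total_updrs, v[, uci_voice_columns, drop = FALSE],
      check.names = FALSE, stringsAsFactors = FALSE
    )
  })
  tab <- if (length(rows) > 0) do.call(rbind, rows) else {
    as.data.frame(setNames(rep(list(numeric(0)), length(uci_columns)),
                           uci_columns), check.names = FALSE)
  }
  ok <- tryCatch({
    write.csv(tab, path, row.names = FALSE, quote = FALSE)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stop("cannot write to ", path, ": ",
                        conditionMessage(ok), call. = FALSE)
  invisible(path)
}

# Number of visits per series, used in several places.
series_lengths <- function(cohort) {
  vapply(cohort, function(s) nrow(s$visits), numeric(1))
}
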