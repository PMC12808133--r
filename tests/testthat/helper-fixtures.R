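# Shared fixtures: small synthetic cohorts and hand-built series.

small_cohort <- function(n_patients = 5, visits = c(12, 15), seed = 101,
                         ...) {
  generate_cohort(cohort_config(n_patients = n_patients,
                                visits_range = visits, rng_seed = seed,
                                ...))
}

# A hand-built two-visit-plus series with controllable UPDRS trace.
manual_series <- function(updrs, times = seq_along(updrs) * 7 - 7,
                          id = "P1", age = 65, sex = 0) {
  n <- length(updrs)
  voice <- matrix(0.01, n, length(dcanet:::uci_voice_columns),
                  dimnames = list(NULL, dcanet:::uci_voice_columns))
  voice[, "HNR"] <- 20
  voice[, "NHR"] <- 0.05
  visits <- data.frame(test_time = times, motor_updrs = updrs,
                       total_updrs = updrs + 8, check.names = FALSE)
  visits <- cbind(visits, as.data.frame(voice, check.names = FALSE))
  structure(list(subject_id = id, age = age, sex = sex, visits = visits),
            class = "patient_series")
}

cohort_from_series <- function(...) {
  structure(list(...), class = "telemon_cohort",
            sex_codes = c(male = 0, female = 1))
}

# tiny model/feature settings reused across network tests
tiny_model_setup <- function(seed = 7, n_patients = 4, visits = c(8, 10),
                             hidden = 16, Tlen = 5) {
  coh <- small_cohort(n_patients, visits, seed)
  fs <- build_feature_set(coh, feature_config(sequence_length = Tlen))
  sfs <- apply_scalers(fs, fit_scalers(fs))
  cfg <- model_config(hidden_dim = hidden, fusion_heads = 2,
                      encoder_heads = 2, sequence_length = Tlen)
  list(cohort = coh, fs = sfs, config = cfg,
       model = build_model(cfg, seed = seed))
}
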