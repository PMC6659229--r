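# Shared fixtures built in code: no stored data files.

linear_profile <- response_profile("linear")
default_var <- variance_components()
default_rule <- responder_rule()

# A small complete trial with CV and AE, fixed seed.
make_complete_trial <- function(n = 200, seed = 101, profile = linear_profile) {
  d <- simulate_trial(profile, n, default_var, seed = seed)
  d <- generate_cv(d)
  generate_ae(d)
}

# A masked trial under one dropout mechanism (cutoff calibrated on a small
# pilot for speed; unit tests do not depend on the exact achieved rate).
make_masked_trial <- function(n = 200, seed = 101, model_id = 1,
                              target = 0.30, pilot = 50) {
  d <- make_complete_trial(n, seed)
  spec <- dropout_spec(model_id, target, pilot_reps = pilot,
                       tolerance = 0.02)
  cutoff <- calibrate_cutoff(
    function(r) make_complete_trial(n, seed = 7000 + r), spec,
    seed = derive_test_seed(seed))
  mask <- apply_dropout(d, spec, cutoff, seed = seed + 1)
  list(complete = d, mask = mask, masked = apply_mask(d, mask),
       spec = spec, cutoff = cutoff)
}

# keep helper seeds clear of the package's internal stream derivation
derive_test_seed <- function(seed) (seed * 7919L) %% 2147480000L + 1L

# Hand-built trial_data from explicit columns (for boundary-case tests).
manual_trial <- function(df) {
  df$subject_id <- seq_len(nrow(df))
  attr(df, "profile") <- "linear"
  attr(df, "var") <- variance_components()
  class(df) <- c("trial_data", "data.frame")
  df
}
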