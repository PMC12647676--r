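# Shared fixtures, all generated in code.

small_registry <- function() load_montage_registry()

# A tiny deterministic cohort for direct-arithmetic tests.
tiny_cohort <- function(n = 12L) {
  data.frame(
    participant_id = sprintf("T%02d", seq_len(n)),
    age = seq(18, 87, length.out = n),
    gender = rep(c("male", "female"), length.out = n),
    head_circumference = seq(540, 600, length.out = n),
    cephalic_index = seq(75, 92, length.out = n),
    bmi = seq(19, 33, length.out = n),
    stringsAsFactors = FALSE)
}

# Random invertible affine (rotation + anisotropic scale + translation).
random_affine <- function(seed = 1L) {
  set.seed(seed)
  qrd <- qr(matrix(rnorm(9), 3, 3))
  rot <- qr.Q(qrd)
  a <- rot %*% diag(runif(3, 0.8, 1.2))
  t <- rbind(cbind(a, rnorm(3, sd = 10)), c(0, 0, 0, 1))
  t
}

# Zero-noise dataset: outcomes an exact affine function of the features.
zero_noise_dataset <- function(seed = 11L, n = 418L) {
  spec <- cohort_spec(n_participants = n, bmi_missing_rate = 0, seed = seed)
  truth <- default_ground_truth(noise_sd = 0)
  synthetic_dataset(spec, truth = truth, seed = seed)
}

# Standardized design matrix + truth outcome for model-recovery tests.
standardized_fixture <- function(seed = 2L, n = 418L) {
  spec <- cohort_spec(n_participants = n, bmi_missing_rate = 0, seed = seed)
  cohort <- generate_cohort(spec, seed = seed)
  params <- fit_standardizer(cohort)
  feats <- standardize_features(cohort, params)
  list(cohort = cohort, params = params, features = feats)
}
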