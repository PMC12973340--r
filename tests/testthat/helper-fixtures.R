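# Shared fixtures. The trained pipeline fixture is computed once per test run
# and reused by every test that needs a converged model.

# scaled-down study conditions: 60 parcels (5 networks per hemisphere),
# 60/20/20 healthy train/validation/test, 7 + 3 fine-tuning patients,
# 10 test patients
small_sim_spec <- function(seed = 11, ...) {
  simulation_spec(parcel_count = 60, networks_per_hemisphere = 5,
                  n_train = 60, n_val = 20, n_test = 20,
                  n_finetune_train = 7, n_finetune_val = 3,
                  n_patient_test = 10, seed = seed, ...)
}

# tiny cohort for fast pipeline smoke/determinism tests
tiny_sim_spec <- function(seed = 7, ...) {
  simulation_spec(parcel_count = 20, networks_per_hemisphere = 2,
                  n_train = 10, n_val = 4, n_test = 4,
                  n_finetune_train = 3, n_finetune_val = 2,
                  n_patient_test = 4, tumor_radius = 1, edema_radius = 1,
                  seed = seed, ...)
}

tiny_run_config <- function(seed = 3) {
  run_config(seed = seed, encoder_widths = c(32, 16), max_epochs = 25,
             patience = 25)
}

.fixtures <- new.env(parent = emptyenv())

# full pipeline at the scaled-down study conditions (300 epochs, reference
# architecture); trained once and shared across test files
trained_fixture <- function() {
  if (is.null(.fixtures$trained)) {
    spec <- small_sim_spec()
    cohort <- simulate_cohort(spec)
    config <- run_config(seed = 11, max_epochs = 300, patience = 300)
    result <- run_pipeline(cohort, spec$scheme, config)
    .fixtures$trained <- list(spec = spec, cohort = cohort, config = config,
                              result = result)
  }
  .fixtures$trained
}

# 6-parcel scheme with networks of sizes 3, 2 and 1 (small enough to
# enumerate every impairment pattern)
six_parcel_scheme <- function() {
  parcellation(tibble::tibble(
    parcel_id = paste0("p", 1:6),
    hemisphere = c("left", "left", "left", "right", "right", "right"),
    network = c("A", "A", "A", "B", "B", "C")))
}

# random symmetric zero-diagonal matrix
random_sym <- function(p, seed = 1) {
  set.seed(seed)
  m <- matrix(0, p, p)
  m[upper.tri(m)] <- rnorm(p * (p - 1) / 2)
  m + t(m)
}
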