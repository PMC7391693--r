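# Small cohort configurations shared across test files.

# Desk-scale cohort: full mutation layer, reduced expression/miRNA layers.
# Overrides in ... win over the desk-scale defaults.
small_cohort_config <- function(seed = 1, ...) {
  args <- utils::modifyList(
    list(n_expr_genes = 300, n_signature = 20, n_mirnas = 30,
         n_host_coupled = 8, seed = seed),
    list(...))
  do.call(cohort_config, args)
}

# Strong-recovery regime: an eight-gene driver signature mutated in 80% of
# short-lived and 5% of long-lived patients.
recovery_driver_rates <- function(n_drivers = 8) {
  data.frame(gene = paste0("DRV", seq_len(n_drivers)),
             p_short = rep(0.8, n_drivers),
             p_long = rep(0.05, n_drivers))
}

recovery_cohort_config <- function(seed = 1, ...) {
  small_cohort_config(seed = seed, driver_rates = recovery_driver_rates(), ...)
}

adjusted_rand_index <- function(a, b) {
  mclust::adjustedRandIndex(a, b)
}

# Tiny labeled survival table for hand-checked tests.
toy_survival <- function(times, events, ids = sprintf("P%02d", seq_along(times))) {
  as_survival_table(data.frame(patient_id = ids, time = times, event = events))
}
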