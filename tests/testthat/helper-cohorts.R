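# Shared cohorts, generated once per test run (the large one feeds several
# acceptance checks; regenerating it per block would dominate the runtime).

.cohort_cache <- new.env(parent = emptyenv())

default_cohort <- function() {
  if (is.null(.cohort_cache$default))
    .cohort_cache$default <- suppressWarnings(generate_cohort(cohort_config()))
  .cohort_cache$default
}

# 10,000 vessels per group, seed 42: the desk-scale recovery cohort
big_cohort <- function() {
  if (is.null(.cohort_cache$big)) {
    cfg <- cohort_config(seed = 42)
    .cohort_cache$big <- suppressWarnings(
      generate_cohort(cfg, n_fcl = 10000L, n_ncl = 10000L))
  }
  .cohort_cache$big
}
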