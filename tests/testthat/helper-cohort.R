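# The validation cohort used by the simulation-based acceptance checks:
# 19 subjects at the default phantom conditions, tracked at a reduced
# 1,000 samples per seed voxel. Built once per test run and shared.
.cohort_cache <- new.env(parent = emptyenv())

validation_cohort <- function() {
  if (!is.null(.cohort_cache$res)) return(.cohort_cache$res)
  cfg <- pipeline_config(
    phantom = phantom_config(rng_seed = 1L),
    tracking = tracking_params(n_samples = 1000L),
    n_subjects = 19L, rng_seed = 1L)
  .cohort_cache$res <- run_pipeline(cfg)
  .cohort_cache$res
}

cohort_truth_labels <- function(ph, clusters) {
  sc <- clusters$seed_coords
  ph$truth_labels[cbind(sc[, 1], sc[, 2], sc[, 3])]
}
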