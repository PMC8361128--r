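# Shared scaled-down synthetic cohorts, built once per test run. The suite
# uses 250 Hz sampling so the 16 ms reduction window spans 4 samples and the
# reduced series keeps its 500-sample structure.

.cohort_cache <- new.env(parent = emptyenv())

scaled_config <- function(effect, seed, n_adhd = 14, n_ctrl = 11,
                          trials = 6) {
  generator_config(n_adhd = n_adhd, n_ctrl = n_ctrl,
                   trials_per_subject = trials, sampling_hz = 250,
                   effect = effect, seed = seed)
}

cached_fm <- function(effect, seed) {
  key <- sprintf("%s_%d", effect, seed)
  if (is.null(.cohort_cache[[key]])) {
    gen <- generate_cohort(scaled_config(effect, seed))
    pp <- preprocess_cohort(gen$cohort)
    .cohort_cache[[key]] <- suppressMessages(build_feature_matrix(pp$cohort))
  }
  .cohort_cache[[key]]
}

strong_fm <- function() cached_fm("strong", 42)
null_fm <- function() cached_fm("null", 99)
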