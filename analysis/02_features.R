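#!/usr/bin/env Rscript
# Preprocess every trial (exclude >80%-missing trials, cubic-spline impute
# the rest, reduce with 16 ms block means) and build the subjects-by-
# features matrix: 22 custom dilation-metric features plus the 12 general
# time-series features, each computed per trial and averaged per subject.

library(pupilscreen)

cohort <- read_trials("results/trials.csv")
pp <- preprocess_cohort(cohort, window_ms = 16, max_missing_fraction = 0.8)
cat(sprintf("excluded %d trial(s) for missingness > 80%%\n", nrow(pp$dropped)))

n_red <- length(pp$cohort$subjects[[1]]$trials[[1]]$pupil)
cat(sprintf("reduced series length: %d samples at %g ms\n", n_red,
            pp$cohort$subjects[[1]]$trials[[1]]$sample_period_ms))

fm <- build_feature_matrix(pp$cohort)
write_feature_matrix(fm, "results/feature_matrix.csv")
cat(sprintf("feature matrix: %d subjects x %d features -> results/feature_matrix.csv\n",
            nrow(fm), length(feature_names(fm))))
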