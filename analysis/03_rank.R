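#!/usr/bin/env Rscript
# Rank every feature by a two-sided Mann-Whitney U test between the ADHD
# and control groups (descriptive ranking over the whole cohort; the
# classifier evaluation reselects features inside each CV fold with the
# ANOVA-F filter, so nothing here leaks into the metrics).

library(pupilscreen)

fm <- read_feature_matrix("results/feature_matrix.csv")
ranked <- rank_features(fm, method = "mann_whitney")
write_ranked_features(ranked, "results/ranked_features.csv")

cat("top 10 discriminative features (Mann-Whitney, two-sided):\n")
print(head(as.data.frame(ranked), 10), row.names = FALSE)
cat(sprintf("\n%d of %d features have p < 0.05\n",
            sum(ranked$p_value < 0.05), nrow(ranked)))
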