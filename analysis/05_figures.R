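#!/usr/bin/env Rscript
# The four figure families: group-mean time courses (size / velocity /
# acceleration), the distribution of the strongest scalar biomarker
# (pupil-size standard deviation) with its Mann-Whitney p-value, the
# RadViz class-separability projection of the top-ranked features, and the
# pooled nested-CV ROC curves.

library(pupilscreen)

dir.create("results/figures", showWarnings = FALSE, recursive = TRUE)

cohort <- read_trials("results/trials.csv")
pp <- preprocess_cohort(cohort)
fm <- read_feature_matrix("results/feature_matrix.csv")
ranked <- rank_features(fm)

group_mean_lineplot(pp$cohort, "size", "results/figures/group_mean_size.png")
group_mean_lineplot(pp$cohort, "velocity",
                    "results/figures/group_mean_velocity.png")
group_mean_lineplot(pp$cohort, "acceleration",
                    "results/figures/group_mean_acceleration.png")

feature_distribution_plot(fm, "size_std", "box",
                          "results/figures/size_std_box.png")
feature_distribution_plot(fm, "size_std", "violin",
                          "results/figures/size_std_violin.png")

proj <- radviz_project(fm, select_top_k(ranked, 9))
plot_radviz(proj, "results/figures/radviz_top9.png")

roc <- read.csv("results/roc.csv")
plot_roc_curves(roc, "results/figures/roc.png")

cat("figures written under results/figures/\n")
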