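#!/usr/bin/env Rscript
# Leakage-safe repeated nested ten-fold cross-validation: per outer fold,
# the 9 best features by the ANOVA-F filter (train rows only), inner 5-fold
# grid search maximizing AUROC, refit, score the held-out fold. 10
# repetitions per classifier keep this desk-fast; the half-width printed is
# the standard error over repetitions.

library(pupilscreen)

fm <- read_feature_matrix("results/feature_matrix.csv")

roc_all <- list()
for (clf in c("svm", "logistic_regression", "naive_bayes")) {
  rep <- nested_cv(fm, classifier_spec(clf), outer_folds = 10, k_select = 9,
                   repetitions = 10, seed = 20260919)
  print(rep)
  write_evaluation_report(rep, sprintf("results/evaluation_%s.json", clf))
  roc_all[[clf]] <- cbind(classifier = clf, rep$roc_points)
}
write.csv(do.call(rbind, roc_all), "results/roc.csv", row.names = FALSE)
cat("wrote per-classifier evaluation JSON and results/roc.csv\n")
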