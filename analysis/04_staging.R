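#!/usr/bin/env Rscript
# Softening-stage classification: day-0 difference spectra -> PCA ->
# firmness tertile labels -> five-fold cross-validated linear SVM.

suppressPackageStartupMessages(library(kiwitrts))

study <- read_study_fixture("results/study")
study$trps <- lapply(study$trps, savitzky_golay_smooth)

for (cond in c("shelf", "cold")) {
  st <- stage_condition(study, cond, k = 3L, folds = 5L, seed = 1L)
  cat(sprintf("%s: components %s (cum. contribution %.1f%%), pooled accuracy %.1f%%\n",
              cond, paste(st$selected_components, collapse = ","),
              100 * sum(st$pca$explained_variance_ratio[st$selected_components]),
              100 * st$report$overall_accuracy))
  print(st$report$confusion_matrix)
  write.csv(as.data.frame(st$report$confusion_matrix),
            sprintf("results/confusion_%s.csv", cond),
            row.names = FALSE, quote = FALSE)
  jsonlite::write_json(
    list(condition = cond, selected_components = st$selected_components,
         class_thresholds = st$class_thresholds,
         fold_accuracies = st$report$fold_accuracies,
         overall_accuracy = st$report$overall_accuracy),
    sprintf("results/staging_%s.json", cond), auto_unbox = TRUE, digits = NA)
}
cat("staging outputs written under results/\n")
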