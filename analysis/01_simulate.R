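#!/usr/bin/env Rscript
# Generate the default synthetic two-condition storage study and write it as
# a plain-text fixture under results/study/.

suppressPackageStartupMessages(library(kiwitrts))

cfg <- study_config(seed = 1L)
study <- generate_study(cfg)
dir.create("results", showWarnings = FALSE)
unlink("results/study", recursive = TRUE)
write_fixture(study, "results/study")

tot <- vapply(study$trps, function(p) sum(p$counts), numeric(1))
cat(sprintf("study: %d records (%d fruit x %d/%d days x 2 conditions)\n",
            nrow(study$records), cfg$n_samples,
            length(cfg$shelf_days), length(cfg$cold_days)))
cat(sprintf("per-TRP totals: %.2e - %.2e photons (reference %.0e)\n",
            min(tot), max(tot), cfg$total_counts))
cat(sprintf("day-0 latent mu_s': %.2f - %.2f mm^-1; firmness %.1f - %.1f N/cm2\n",
            min(study$truth$mu_s_prime[study$truth$day == 0]),
            max(study$truth$mu_s_prime[study$truth$day == 0]),
            min(study$records$firmness_N_cm2), max(study$records$firmness_N_cm2)))
cat("fixture written to results/study/\n")
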