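#!/usr/bin/env Rscript
# Stage 1 — simulate the study design: a log-normal ranked inoculum of 200
# features under a random taxonomy, 16 media with per-feature survival and
# growth bias, and one cultured print per medium at realistic read depths.
# Writes the profiles, metadata and ground truth used by all later stages.

library(cultureval)

out <- "results"
dir.create(out, showWarnings = FALSE)

truth <- simulate_inoculum(
  n_features = 200,
  media = sprintf("M%02d", 1:16),
  lognormal_sigma = 1.5,
  survival_prob = 0.5,
  bias_sdlog = 0.5,
  seed = 20260101
)
study <- simulate_print_study(truth, seed = 20260102)

write_profile(truth$profile, file.path(out, "inoculum.tsv"))
write_profile(study$prints, file.path(out, "prints.tsv"))
write.table(study$meta, file.path(out, "meta.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(data.frame(feature = names(truth$abundance),
                       abundance = truth$abundance, truth$survival,
                       check.names = FALSE),
            file.path(out, "truth.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)

depths <- colSums(study$prints$counts)
cat(sprintf("Simulated %d features on %d media; print depths %d-%d reads.\n",
            length(truth$abundance), length(truth$media),
            min(depths), max(depths)))
cat(sprintf("Features culturable on >=1 medium: %d/%d.\n",
            sum(rowSums(truth$survival) > 0), nrow(truth$survival)))
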