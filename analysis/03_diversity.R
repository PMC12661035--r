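#!/usr/bin/env Rscript
# Stage 3 — alpha diversity of the print arrays after rarefaction, plus a
# sample-based accumulation curve at the genus level.

library(cultureval)

prints <- read_profile("results/prints.tsv")

depth <- min(6070, min(colSums(prints$counts)))
rare <- rarefy_profile(prints, depth = depth, seed = 20260103)
tab <- diversity_table(rare, m = 100)
write.table(tab, "results/diversity.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat(sprintf("Diversity of %d samples rarefied to %d reads:\n", nrow(tab), depth))
print(tab[, c("sample_id", "S", "H_prime", "J_prime", "one_minus_lambda",
              "N1", "N2", "ES_m", "goods_coverage")], row.names = FALSE)

acc <- accumulation_curve(prints, level = "genus", n_perm = 999,
                          seed = 20260104)
write.table(acc, "results/genus_accumulation.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat(sprintf("\nGenus accumulation: %0.1f genera after 1 sample, %0.0f after %d.\n",
            acc$mean[1], acc$mean[nrow(acc)], nrow(acc)))
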