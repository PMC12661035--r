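#!/usr/bin/env Rscript
# Stage 2 — score how well the cultured prints recover the inoculum:
# recovery fractions across abundance cut-offs, enriched features, the
# class-level shift tests, and the cell input/output ratio bound.

library(cultureval)

inoc <- read_profile("results/inoculum.tsv", units = "relative")
prints <- to_relative(read_profile("results/prints.tsv"))
meta <- read_sample_meta("results/meta.tsv")

cuts <- c(0.001, 0.005, 0.01, 0.05)
rows <- lapply(cuts, function(cut) {
  rep <- recovered_fraction(inoc, prints, meta = meta, inoc_cutoff = cut)
  data.frame(cutoff = cut, eligible = length(rep$eligible),
             recovered = length(rep$recovered), fraction = rep$fraction)
})
tab <- do.call(rbind, rows)
write.table(tab, "results/recovery_by_cutoff.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("Recovery by inoculum abundance cut-off:\n")
print(tab, row.names = FALSE)

enr <- enriched_features(inoc, prints, detect_cutoff = 0.001)
cat(sprintf("\n%d features below the 0.1%% inoculum detection limit were\n",
            length(enr)),
    "enriched above it by culture.\n")

# class-level shifts between inoculum replicates and prints need multiple
# inoculum samples; with a single inoculum we compare prints between the
# first and second half of the media panel as a demonstration
cls_prints <- to_relative(aggregate_taxa(read_profile("results/prints.tsv"),
                                         "class"))
half <- ncol(cls_prints$counts) %/% 2
shift <- class_shift_test(cls_prints$counts[, 1:half],
                          cls_prints$counts[, (half + 1):ncol(cls_prints$counts)])
write.table(shift, "results/class_shifts.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat(sprintf("\nClass shift tests: %d/%d classes significant after Bonferroni.\n",
            sum(shift$p_adjusted < 0.05), nrow(shift)))

io <- estimate_io_ratio()
cat(sprintf("\nCell input/output ratio bound: %.1e (volume factor %g).\n",
            io$ratio, io$volume_factor))
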