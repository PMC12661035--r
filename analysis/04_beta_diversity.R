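#!/usr/bin/env Rscript
# Stage 4 — beta diversity of the print arrays: max-standardized,
# fourth-root transformed Bray-Curtis similarities, UPGMA clustering cut at
# 60% similarity, a 2-D non-metric MDS, and the class vector overlay.

library(cultureval)

prints <- read_profile("results/prints.tsv")
rel <- to_relative(prints)

m <- standardize_transform(rel)  # standardize by max, then fourth root
sim <- bray_curtis(m)
write.table(round(sim$sim, 3), "results/bray_curtis.tsv", sep = "\t",
            quote = FALSE)

dend <- upgma(sim)
clusters <- flat_clusters(dend, threshold_similarity = 60)
dendrogram_newick(dend, "results/upgma.nwk")
cat(sprintf("UPGMA: %d clusters at 60%% similarity (merges %0.1f-%0.1f).\n",
            length(unique(clusters)), min(dend$merge_similarity),
            max(dend$merge_similarity)))

ord <- nmds(100 - sim$sim, ndim = 2, n_restarts = 20, seed = 20260105)
cat(sprintf("nMDS 2D-stress: %0.3f over %d restarts.\n", ord$stress,
            ord$n_restarts))

cls <- to_relative(aggregate_taxa(prints, "class"))
overlay <- vector_overlay(ord, t(cls$counts))
write.table(data.frame(sample = rownames(ord$points), ord$points,
                       cluster = clusters),
            "results/nmds_points.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(overlay, "results/nmds_class_vectors.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("Strongest class-axis correlation:\n")
print(overlay[which.max(overlay$length), ], row.names = FALSE)
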