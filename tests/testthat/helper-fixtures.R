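# Shared fixture builders and independent brute-force oracles.

# Small profile built in code: 5 features, 3 samples, 2 genera / 2 classes.
toy_profile <- function() {
  counts <- matrix(
    c(10L, 5L, 0L,
      3L,  4L, 2L,
      0L,  1L, 7L,
      6L,  0L, 1L,
      2L,  2L, 2L),
    nrow = 5, byrow = TRUE,
    dimnames = list(paste0("f", 1:5), c("s1", "s2", "s3"))
  )
  lineage <- rbind(
    c("Bacteria", "P1", "C1", "O1", "F1", "G1", "f1"),
    c("Bacteria", "P1", "C1", "O1", "F1", "G1", "f2"),
    c("Bacteria", "P1", "C2", "O2", "F2", "G2", "f3"),
    c("Bacteria", "P2", "C3", "O3", "F3", "G3", "f4"),
    c("Bacteria", "P2", "C3", "O3", "F3", "G4", "f5")
  )
  rownames(lineage) <- rownames(counts)
  taxon_profile(counts, lineage, units = "reads")
}

random_profile <- function(n_features, n_samples, seed, max_count = 50) {
  set.seed(seed)
  counts <- matrix(rpois(n_features * n_samples, max_count / 4),
                   n_features, n_samples,
                   dimnames = list(sprintf("f%03d", seq_len(n_features)),
                                   sprintf("s%02d", seq_len(n_samples))))
  counts[sample(length(counts), length(counts) %/% 3)] <- 0L
  counts[1, colSums(counts) == 0] <- 1L  # no all-zero sample
  taxon_profile(counts, NULL, units = "reads")
}

random_community <- function(seed, n = 30, lambda = 8) {
  set.seed(seed)
  counts <- rpois(n, lambda)
  if (all(counts == 0)) counts[1] <- 1L
  counts
}

# Independent pairwise-loop Bray-Curtis similarity (0-100).
oracle_bray <- function(m) {
  n <- nrow(m)
  s <- matrix(100, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i != j) {
      s[i, j] <- 100 * (1 - sum(abs(m[i, ] - m[j, ])) / sum(m[i, ] + m[j, ]))
    }
  }
  s
}

# Hand UPGMA on a similarity matrix: returns merge similarities in order.
oracle_upgma_merges <- function(sim) {
  clusters <- as.list(seq_len(nrow(sim)))
  merges <- numeric(0)
  while (length(clusters) > 1) {
    best <- c(NA, NA); best_val <- -Inf
    for (i in seq_len(length(clusters) - 1)) {
      for (j in (i + 1):length(clusters)) {
        val <- mean(sim[clusters[[i]], clusters[[j]]])
        if (val > best_val) { best_val <- val; best <- c(i, j) }
      }
    }
    merges <- c(merges, best_val)
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  merges
}

# All permutations of 1..n (small n only).
all_perms <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (p in all_perms(n - 1L)) {
    for (k in seq_len(n)) {
      out[[length(out) + 1L]] <- append(p, n, after = k - 1L)
    }
  }
  out
}

# Exclusive membership-pattern tally for UpSet counts.
oracle_upset <- function(sets) {
  features <- sort(unique(unlist(sets)))
  pat <- vapply(features, function(f) {
    paste(names(sets)[vapply(sets, function(s) f %in% s, logical(1))],
          collapse = "&")
  }, character(1))
  table(pat)
}
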