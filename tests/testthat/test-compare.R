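test_that("standardize/transform follows the max-then-fourth-root recipe", {
  counts <- matrix(c(1L, 2L, 4L, 0L, 0L, 0L, 16L, 16L, 16L), nrow = 3,
                   byrow = TRUE,
                   dimnames = list(c("f1", "f2", "f3"), c("s1", "s2", "s3")))
  p <- taxon_profile(counts, NULL, units = "reads")
  m <- standardize_transform(p, transform = "none")
  expect_equal(unname(m[, "f1"]), c(0.25, 0.5, 1))
  expect_equal(unname(m[, "f2"]), c(0, 0, 0))  # all-zero row untouched
  m4 <- standardize_transform(p, variable_standardize = "none")
  expect_equal(unname(m4[, "f3"]), rep(2, 3))  # fourth root of 16
  ident <- standardize_transform(p, "none", "none")
  expect_equal(unname(ident), unname(t(counts + 0)))
})

test_that("Bray-Curtis similarity has the right identities and oracle values", {
  expect_equal(bray_curtis(rbind(a = c(1, 2), b = c(1, 2)))$sim["a", "b"], 100)
  expect_equal(bray_curtis(rbind(a = c(1, 0), b = c(0, 1)))$sim["a", "b"], 0)
  set.seed(81)
  m <- matrix(runif(10 * 6), 10, 6)
  s <- bray_curtis(m)$sim
  expect_true(max(abs(s - oracle_bray(m))) <= 1e-10)
  expect_equal(s, t(s))
  expect_true(all(diag(s) == 100))
  expect_true(all(s >= 0 & s <= 100))
})

test_that("a pair of all-zero samples gets an undefined similarity sentinel", {
  m <- rbind(a = c(1, 2), b = c(0, 0), c = c(0, 0))
  s <- suppressWarnings(bray_curtis(m))$sim
  expect_true(is.na(s["b", "c"]))
  expect_equal(s["b", "b"], 100)
})

test_that("UPGMA reproduces the hand agglomeration and oracle merges", {
  sim <- matrix(100, 3, 3, dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  sim["A", "B"] <- sim["B", "A"] <- 98
  sim["A", "C"] <- sim["C", "A"] <- 92
  sim["B", "C"] <- sim["C", "B"] <- 94
  dend <- upgma(structure(list(sim = sim, samples = rownames(sim)),
                          class = "similarity_matrix"))
  expect_equal(dend$merge_similarity, c(98, 93))  # (A,B) at 98, C at (92+94)/2
  # oracle agreement on a random case
  set.seed(82)
  m <- matrix(runif(8 * 5), 8, 5)
  bc <- bray_curtis(m)
  got <- upgma(bc)$merge_similarity
  expect_equal(got, oracle_upgma_merges(bc$sim), tolerance = 1e-10)
  expect_true(all(diff(got) <= 1e-10))  # merge similarities non-increasing
})

test_that("flat clusters cut the dendrogram at the similarity threshold", {
  m <- rbind(a = c(5, 0, 0), b = c(5, 0, 0), c = c(0, 5, 0))
  bc <- bray_curtis(m)
  dend <- upgma(bc)
  expect_equal(unname(flat_clusters(dend, 60)), c(1, 1, 2))
  # identical samples: one cluster at similarity 100
  same <- bray_curtis(rbind(a = c(1, 1), b = c(1, 1)))
  expect_equal(max(upgma(same)$merge_similarity), 100)
  expect_equal(length(unique(flat_clusters(upgma(same), 60))), 1L)
  # a threshold above every merge similarity isolates every sample
  dist_rows <- rbind(a = c(5, 1, 0), b = c(3, 2, 1), c = c(0, 1, 5))
  dend2 <- upgma(bray_curtis(dist_rows))
  expect_equal(length(unique(flat_clusters(dend2, 99.99))), 3L)
  nwk <- dendrogram_newick(dend)
  expect_match(nwk, "^\\(")
})

test_that("nMDS recovers perfectly embeddable configurations with ~zero stress", {
  set.seed(83)
  pts <- matrix(rnorm(8 * 2), 8, 2)
  d <- as.matrix(dist(pts))
  ord <- nmds(d, ndim = 2, n_restarts = 4, seed = 1)
  expect_lte(ord$stress, 1e-3)
  # collinear points in 1-D
  line <- matrix(c(0, 1, 2.5, 4), ncol = 1)
  ord1 <- nmds(as.matrix(dist(line)), ndim = 1, n_restarts = 4, seed = 1)
  expect_lte(ord1$stress, 1e-3)
  expect_error(nmds(matrix(c(0, 1, 2, 0), 2, 2)), "symmetric")
})

test_that("nMDS stress descends monotonically and matches vegan's optimum", {
  set.seed(84)
  m <- matrix(runif(9 * 12), 9, 12)
  d <- 100 - bray_curtis(m)$sim
  ord <- nmds(d, ndim = 2, n_restarts = 6, seed = 2)
  expect_true(all(diff(ord$trace) <= 1e-12))
  expect_gte(ord$stress, 0)
  # at least as good an optimum as the reference implementation, same ballpark
  ref <- vegan::monoMDS(as.dist(d), k = 2, model = "global")
  expect_lte(ord$stress, ref$stress + 0.01)
  expect_lt(abs(ord$stress - ref$stress), 0.05)
})

test_that("vector overlays are axis correlations with expected symmetries", {
  set.seed(85)
  pts <- prcomp(matrix(rnorm(12 * 2), 12, 2))$x  # uncorrelated axes
  ord <- structure(list(points = pts, stress = 0), class = "ordination_result")
  vars <- cbind(v_axis = pts[, 1], v_noise = rnorm(12))
  ov <- vector_overlay(ord, vars)
  expect_equal(ov$r_axis1[1], 1, tolerance = 1e-12)
  expect_lt(abs(ov$r_axis2[1]), 1e-9)
  flipped <- vector_overlay(ord, -vars)
  expect_equal(flipped$r_axis1, -ov$r_axis1)
  expect_equal(flipped$length, ov$length)
  expect_warning(vector_overlay(ord, cbind(const = rep(1, 12))), "constant")
  # independent variables stay inside the permutation null band
  null_r <- replicate(500, cor(sample(pts[, 1]), pts[, 2]))
  expect_lt(abs(ov$r_axis2[2]), quantile(abs(null_r), 0.999))
})

test_that("pts[, 1] correlated variable separates from pure noise by length", {
  set.seed(86)
  pts <- matrix(rnorm(20 * 2), 20, 2)
  ord <- structure(list(points = pts, stress = 0), class = "ordination_result")
  ov <- vector_overlay(ord, cbind(signal = pts[, 1] + rnorm(20, 0, 0.1),
                                  noise = rnorm(20)))
  expect_gt(ov$length[1], ov$length[2])
})
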