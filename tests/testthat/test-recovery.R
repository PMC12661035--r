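rel_profile <- function(abund, sample = "s") {
  counts <- matrix(abund, ncol = length(sample),
                   dimnames = list(names(abund) %||%
                                     paste0("f", seq_along(abund)), sample))
  taxon_profile(counts, NULL, units = "relative")
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("recovered fraction matches the worked set enumeration", {
  inoc <- rel_profile(c(A = 0.50, B = 0.30, C = 0.15, D = 0.04, E = 0.01))
  # prints contain A and C above threshold, B diluted below it
  pr <- rel_profile(c(A = 0.55, B = 0.001, C = 0.40, D = 0.004, E = 0.045))
  rep <- recovered_fraction(inoc, pr, inoc_cutoff = 0.05, print_cutoff = 0.01)
  expect_setequal(rep$eligible, c("A", "B", "C"))
  expect_setequal(rep$recovered, c("A", "C"))
  expect_equal(rep$fraction, 2 / 3)
})

test_that("self-recovery is total and empty eligibility is an NA sentinel", {
  inoc <- rel_profile(c(A = 0.6, B = 0.3, C = 0.1))
  for (cut in c(0.001, 0.05, 0.09)) {
    expect_equal(recovered_fraction(inoc, inoc, inoc_cutoff = cut)$fraction, 1)
  }
  rep <- recovered_fraction(inoc, inoc, inoc_cutoff = 0.9)
  expect_true(is.na(rep$fraction))
  expect_length(rep$eligible, 0)
})

test_that("inoculum pooling modes differ as documented", {
  counts <- cbind(i1 = c(A = 0.02, B = 0.98), i2 = c(A = 0.001, B = 0.999))
  inoc <- taxon_profile(counts, NULL, units = "relative")
  pr <- rel_profile(c(A = 0.5, B = 0.5))
  any_mode <- recovered_fraction(inoc, pr, inoc_cutoff = 0.015, pooling = "any")
  mean_mode <- recovered_fraction(inoc, pr, inoc_cutoff = 0.015, pooling = "mean")
  expect_true("A" %in% any_mode$eligible)    # reaches 2% in one sample
  expect_false("A" %in% mean_mode$eligible)  # mean is 1.05%
})

test_that("recovery is monotone as print samples accumulate", {
  truth <- simulate_inoculum(60, media = paste0("M", 1:6), seed = 51)
  st <- simulate_print_study(truth, seed = 52)
  rel <- to_relative(st$prints)
  fr <- vapply(1:6, function(k) {
    sub <- subset_samples(rel, sample_ids(rel)[1:k])
    recovered_fraction(truth$profile, sub)$fraction
  }, numeric(1))
  expect_true(all(diff(fr) >= -1e-12))
})

test_that("enrichment detection matches a brute-force double loop", {
  set.seed(61)
  n <- 50
  inoc <- matrix(runif(n * 2), n, 2); inoc <- sweep(inoc, 2, colSums(inoc), "/")
  rownames(inoc) <- paste0("f", 1:n); colnames(inoc) <- c("i1", "i2")
  pr <- matrix(runif(n * 3), n, 3); pr <- sweep(pr, 2, colSums(pr), "/")
  rownames(pr) <- paste0("f", 1:n); colnames(pr) <- c("p1", "p2", "p3")
  pi <- taxon_profile(inoc, NULL, units = "relative")
  pp <- taxon_profile(pr, NULL, units = "relative")
  cut <- 0.02
  got <- enriched_features(pi, pp, detect_cutoff = cut)
  manual <- character()
  for (f in paste0("f", 1:n)) {
    below_all <- all(inoc[f, ] < cut)
    detected <- any(pr[f, ] >= cut)
    if (below_all && detected) manual <- c(manual, f)
  }
  expect_setequal(got, manual)
  # print-only features are enriched; abundant inoculum features are not
  expect_true(all(manual %in% got))
})

test_that("Mann-Whitney exact path reproduces enumeration closed forms", {
  mw <- mann_whitney(c(1, 2, 3), c(4, 5, 6))
  expect_equal(mw$U, 0)
  expect_equal(mw$p, 0.1)  # 2 / choose(6, 3)
  expect_equal(mw$method, "exact")
  # identical groups: U at its mean, p = 1
  mwi <- mann_whitney(c(1, 2, 3), c(1, 2, 3))
  expect_equal(mwi$p, 1)
  # constant data in both groups
  expect_equal(mann_whitney(rep(2, 4), rep(2, 5))$p, 1)
})

test_that("exact path agrees with wilcox.test on tie-free data", {
  set.seed(71)
  for (i in 1:10) {
    x <- rnorm(5); y <- rnorm(6) + 0.5
    mine <- mann_whitney(x, y)
    ref <- wilcox.test(x, y, exact = TRUE)
    expect_equal(mine$p, ref$p.value, tolerance = 1e-12)
    expect_equal(mine$U, unname(ref$statistic))
  }
})

test_that("exact and normal-approximation paths agree at group size 8", {
  set.seed(72)
  deltas <- vapply(1:20, function(i) {
    x <- rnorm(8); y <- rnorm(8) + runif(1, 0, 1)
    abs(mann_whitney(x, y, exact_max = 8)$p -
          mann_whitney(x, y, exact_max = 0)$p)
  }, numeric(1))
  expect_lt(mean(deltas), 0.01)
  expect_lt(max(deltas), 0.02)
})

test_that("class shift tests apply Bonferroni over the classes tested", {
  set.seed(73)
  k <- 11
  a <- matrix(runif(k * 4), k, dimnames = list(paste0("c", 1:k), NULL))
  b <- matrix(runif(k * 4), k, dimnames = list(paste0("c", 1:k), NULL))
  res <- class_shift_test(a, b)
  expect_equal(res$p_adjusted, pmin(1, res$p * k))
  # identical groups: adjusted p = 1 everywhere
  same <- class_shift_test(a, a)
  expect_true(all(same$p_adjusted == 1))
  expect_error(class_shift_test(a[, 1, drop = FALSE], b), ">= 2 samples")
})

test_that("activity coverage sums the covered genera per sample", {
  act <- matrix(c(0.6, 0.3, 0.1, 0.6, 0.3, 0.1), nrow = 3,
                dimnames = list(c("g1", "g2", "g3"), c("s1", "s2")))
  cov <- activity_coverage(c("g1", "g3"), act)
  expect_equal(unname(cov$per_sample), c(0.7, 0.7))
  expect_equal(cov$mean, 0.7)
  expect_equal(activity_coverage(c("g1", "g2", "g3"), act)$mean, 1)
  expect_equal(activity_coverage(character(), act)$mean, 0)
  expect_message(activity_coverage(c("g1", "ghost"), act), "ghost")
  # invariant to genus and sample order
  perm <- act[c(3, 1, 2), c(2, 1)]
  expect_equal(activity_coverage(c("g3", "g1"), perm)$mean, 0.7)
  # mean-profile mode coincides for unit-sum columns
  expect_equal(activity_coverage(c("g1", "g3"), act, mode = "mean_profile")$mean,
               0.7)
})

test_that("the input/output cell ratio bound reproduces the worked example", {
  io <- estimate_io_ratio(2e1, 2e2, 2e9, r_print = 0.5, r_ref = 5)
  expect_equal(io$volume_factor, 1e3)
  expect_equal(io$scaled_output, 2e6)
  expect_equal(io$ratio, 1e-4)
  # equal radii: no volume scaling
  same <- estimate_io_ratio(2e1, 2e2, 2e9, r_print = 5, r_ref = 5)
  expect_equal(same$ratio, 2e2 / 2e9)
  expect_error(estimate_io_ratio(r_ref = 0), "positive")
})
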