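make_raw <- function(n = 50, seed = 1) {
  set.seed(seed)
  spectrum(seq(900, by = 2, length.out = n), rnorm(n))
}

test_that("baseline correction zeroes a pure line and the endpoints", {
  w <- seq(1000, 1200, by = 4)
  s <- spectrum(w, 2 * w + 5)
  b <- baseline_correct(s)
  expect_equal(b$a, rep(0, length(w)))
  r <- baseline_correct(make_raw())
  expect_equal(r$a[1], 0)
  expect_equal(r$a[length(r$a)], 0)
  expect_identical(r$stage, "baseline_corrected")
  expect_error(baseline_correct(r), "raw")
})

test_that("baseline correction is idempotent on already-corrected values", {
  r <- baseline_correct(make_raw(seed = 2))
  again <- baseline_correct(spectrum(r$w, r$a))  # same values re-fed as raw
  expect_equal(again$a, r$a, tolerance = 1e-12)
})

test_that("vector normalization yields unit power and zero mean", {
  b <- baseline_correct(make_raw(seed = 3))
  v <- vector_normalize(b)
  expect_lt(abs(sum(v$a^2) - 1), 1e-12)
  expect_lt(abs(mean(v$a)), 1e-12)
  expect_identical(v$stage, "normalized")
  # scale invariance
  v5 <- vector_normalize(spectrum(b$w, 5 * b$a, stage = "baseline_corrected"))
  expect_equal(v5$a, v$a, tolerance = 1e-12)
  # hand computation: centered (1, 0, -1) normalizes to (1, 0, -1)/sqrt(2)
  h <- vector_normalize(spectrum(1:3, c(1, 0, -1), stage = "baseline_corrected"))
  expect_equal(h$a, c(1, 0, -1) / sqrt(2))
  expect_error(vector_normalize(spectrum(1:3, c(2, 2, 2),
                                         stage = "baseline_corrected")),
               "constant")
  expect_error(vector_normalize(make_raw()), "baseline-corrected")
})

test_that("the preprocessing pipeline is ramp- and scale-invariant", {
  set.seed(4)
  for (i in 1:20) {
    n <- sample(20:200, 1)
    w <- seq(900, 1800, length.out = n)
    a <- rnorm(n)
    base <- preprocess_spectra(spectrum(w, a))
    ramped <- preprocess_spectra(
      spectrum(w, runif(1, 0.5, 4) * a + runif(1, -1, 1) * w + rnorm(1)))
    expect_equal(ramped$a, base$a, tolerance = 1e-10)
  }
})

test_that("region slicing respects bounds and grid arithmetic", {
  w <- seq(524, 4000, by = 2)
  s <- spectrum_set(w, matrix(rnorm(2 * length(w)), ncol = 2))
  fp <- slice_region(s, "fingerprint")
  expect_equal(length(fp$w), 451)  # 900..1800 inclusive at 2 cm-1 step
  expect_true(all(fp$w >= 900 & fp$w <= 1800))
  expect_identical(fp$region, "fingerprint")
  ch <- slice_region(s, "ch")
  expect_true(all(ch$w >= 2800 & ch$w <= 3000))
  full <- slice_region(s, c(0, 5000))
  expect_equal(full$w, s$w)
  expect_error(slice_region(s, c(10, 20)), "fewer than 3")
  both <- slice_regions(s, c("fingerprint", "ch"))
  expect_equal(length(both$w), length(fp$w) + length(ch$w))
})

test_that("covariance PCA matches an SVD oracle and reconstructs the data", {
  set.seed(5)
  A <- matrix(rnorm(30 * 8), 30, 8)  # 30 points x 8 spectra
  set <- spectrum_set(seq_len(30), A, stage = "normalized")
  pca <- spectra_pca(set)
  X <- t(A)
  Xc <- scale(X, center = TRUE, scale = FALSE)
  sv <- svd(Xc)
  ref_eval <- sv$d^2 / (nrow(X) - 1)
  expect_equal(pca$sdev^2, ref_eval[seq_along(pca$sdev)], tolerance = 1e-8)
  for (j in seq_len(ncol(pca$scores))) {
    expect_equal(abs(cor(pca$scores[, j], sv$u[, j] * sv$d[j])), 1,
                 tolerance = 1e-8)
  }
  # loadings orthonormal, explained fractions non-increasing, scores uncorrelated
  expect_equal(crossprod(pca$loadings), diag(ncol(pca$loadings)),
               tolerance = 1e-10, ignore_attr = TRUE)
  expect_true(all(diff(pca$explained) <= 1e-12))
  cv <- cov(pca$scores)
  expect_lt(max(abs(cv[upper.tri(cv)])), 1e-8)
  # full-rank reconstruction
  recon <- pca$scores %*% t(pca$loadings)
  expect_equal(recon, Xc, tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("one-directional variation loads entirely on PC1", {
  t_vals <- seq(-2, 2, length.out = 9)
  dir <- rnorm(15)
  A <- t(outer(t_vals, dir))  # points x spectra
  set <- spectrum_set(seq_len(15), A, stage = "normalized")
  pca <- spectra_pca(set, n_components = 3)
  expect_equal(pca$explained[1], 1, tolerance = 1e-12)
  expect_error(spectra_pca(spectrum_set(1:15, A[, 1, drop = FALSE])), "2 spectra")
})

test_that("two-class Fisher direction matches the closed form and MASS", {
  set.seed(6)
  n <- 30
  X <- cbind(rnorm(n, rep(c(0, 3), each = n / 2), 0.7), rnorm(n, 0, 2))
  labels <- rep(c("a", "b"), each = n / 2)
  model <- fit_lda(X, labels, regularization = "none")
  mu_a <- colMeans(X[labels == "a", ]); mu_b <- colMeans(X[labels == "b", ])
  W <- crossprod(sweep(X[labels == "a", ], 2, mu_a)) +
       crossprod(sweep(X[labels == "b", ], 2, mu_b))
  closed <- solve(W, mu_a - mu_b)
  dir <- model$scaling[, 1]
  cosang <- abs(sum(closed * dir)) / (sqrt(sum(closed^2)) * sqrt(sum(dir^2)))
  expect_equal(cosang, 1, tolerance = 1e-8)
  ref <- MASS::lda(X, grouping = labels)
  expect_equal(as.character(predict(ref)$class), lda_predict(model, X))
})

test_that("separated 1-D classes classify perfectly; coincident means do not", {
  set.seed(7)
  X <- matrix(c(rnorm(20, 0, 0.1), rnorm(20, 10, 0.1)), ncol = 1)
  labels <- rep(c("lo", "hi"), each = 20)
  model <- fit_lda(X, labels, regularization = "none")
  expect_equal(mean(lda_predict(model, X) == labels), 1)
  # coincident class means: between-scatter (hence eigenvalues) ~ 0
  set.seed(8)
  Y <- matrix(rnorm(80), 40, 2)
  same <- fit_lda(Y, rep(c("a", "b"), 20), regularization = "none")
  Ymeans <- apply(Y, 2, function(col) tapply(col, rep(c("a", "b"), 20), mean))
  expect_lt(same$eigenvalues[1],
            fit_lda(Y + 10 * cbind(rep(c(0, 1), 20), 0),
                    rep(c("a", "b"), 20),
                    regularization = "none")$eigenvalues[1] / 10)
  expect_true(all(same$eigenvalues >= 0))
})

test_that("singular within-class scatter demands explicit regularization", {
  set.seed(9)
  X <- matrix(rnorm(6 * 50), 6, 50)  # more variables than observations
  labels <- rep(c("a", "b"), 3)
  expect_error(fit_lda(X, labels, regularization = "none"), "singular")
  m <- fit_lda(X, labels)  # pca_reduce default works
  expect_lte(ncol(m$scaling), 1)
  mr <- fit_lda(X, labels, regularization = "ridge")
  expect_equal(ncol(mr$scaling), 1)
})

test_that("cross-validation on separable synthetic spectra is perfect", {
  truth <- spectrum_truth(paste0("c", 1:5), disjoint = TRUE, noise_sd = 1e-3,
                          seed = 10)
  set <- simulate_spectra(truth, n_per_class = 8, seed = 11)
  prep <- slice_regions(preprocess_spectra(set), c("fingerprint", "ch"))
  rep5 <- cross_validate(prep, k = 5, seed = 12)
  expect_equal(rep5$accuracy, 1)
  expect_equal(sum(diag(rep5$confusion)) / sum(rep5$confusion), rep5$accuracy)
  expect_equal(unname(rowSums(rep5$confusion)), rep(8L, 5))
  expect_lt(rep5$ci[["lower"]], 1)
  expect_equal(rep5$ci[["upper"]], 1, tolerance = 1e-9)
  expect_lte(ncol(rep5$ld_scores), 4)  # at most classes - 1 axes
  expect_error(cross_validate(spectrum_set(prep$w, prep$A,
                                           labels = rep("x", 40),
                                           stage = "normalized")),
               "2 classes")
})

test_that("permuted labels drive accuracy to chance level", {
  truth <- spectrum_truth(paste0("c", 1:5), disjoint = TRUE, noise_sd = 1e-3,
                          seed = 13)
  set <- simulate_spectra(truth, n_per_class = 8, seed = 14)
  prep <- slice_regions(preprocess_spectra(set), c("fingerprint", "ch"))
  accs <- vapply(1:10, function(s) {
    set.seed(100 + s)
    shuffled <- spectrum_set(prep$w, prep$A, labels = sample(prep$labels),
                             stage = "normalized")
    suppressWarnings(cross_validate(shuffled, k = 5, seed = s)$accuracy)
  }, numeric(1))
  n_total <- 40 * 10
  band <- qbinom(c(0.005, 0.995), n_total, 0.2) / n_total
  expect_gte(mean(accs), band[1])
  expect_lte(mean(accs), band[2])
})

test_that("accuracy degrades on average as spectral noise grows", {
  mean_acc <- function(noise) {
    mean(vapply(1:6, function(s) {
      truth <- spectrum_truth(paste0("c", 1:4), disjoint = FALSE,
                              noise_sd = noise, seed = 200 + s)
      set <- simulate_spectra(truth, n_per_class = 6, seed = 300 + s)
      prep <- slice_regions(preprocess_spectra(set), c("fingerprint", "ch"))
      suppressWarnings(cross_validate(prep, k = 3, seed = s)$accuracy)
    }, numeric(1)))
  }
  accs <- vapply(c(0.001, 0.05, 0.2), mean_acc, numeric(1))
  expect_true(accs[1] >= accs[2] && accs[2] >= accs[3] - 0.05)
})

test_that("spectra read back from text files match what was written", {
  truth <- spectrum_truth(c("a", "b"), seed = 15)
  set <- simulate_spectra(truth, n_per_class = 2, wavenumber_range = c(800, 3100),
                          step = 8, seed = 16)
  f <- withr::local_tempfile(fileext = ".tsv")
  df <- data.frame(wavenumber = set$w, set$A, check.names = FALSE)
  write.table(df, f, sep = "\t", quote = FALSE, row.names = FALSE)
  back <- read_spectra(f, labels = set$labels)
  expect_equal(back$A, set$A, tolerance = 1e-6, ignore_attr = TRUE)
  expect_equal(back$w, set$w)
})
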