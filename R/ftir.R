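# FT-IR spectra: containers, the baseline-correction / vector-normalization
# preprocessing pipeline, region slicing, covariance PCA, Fisher LDA and
# cross-validated classification.
#
# Preprocessing follows the two-step scheme used for ATR-FTIR microbial
# fingerprints: (i) subtract the straight line through the spectrum's two
# endpoints (slope = (a_n - a_1)/(w_n - w_1), offset = a_1 - slope * w_1,
# a'_k = a_k - (w_k * slope + offset)), then (ii) mean-center and divide by
# the Euclidean norm so the squared components of the normalized spectrum
# a''' sum to exactly 1.  The pipeline is therefore invariant to any added
# linear ramp and to positive intensity scaling.

SPECTRUM_STAGES <- c("raw", "baseline_corrected", "normalized")

FTIR_REGIONS <- list(fingerprint = c(900, 1800), ch = c(2800, 3000))

#' Construct a single spectrum
#'
#' @param w Strictly monotone wavenumber grid (cm-1), length >= 3.
#' @param a Absorbance values aligned to `w`.
#' @param label Optional class label.
#' @param stage Processing stage (default `"raw"`).
#' @return A `spectrum` object.
#' @export
spectrum <- function(w, a, label = NULL, stage = "raw") {
  stage <- match.arg(stage, SPECTRUM_STAGES)
  if (length(w) != length(a) || length(w) < 3) {
    stop("`w` and `a` must have equal length >= 3")
  }
  dw <- diff(w)
  if (!(all(dw > 0) || all(dw < 0))) stop("wavenumber grid must be strictly monotone")
  structure(list(w = as.numeric(w), a = as.numeric(a),
                 label = label, stage = stage),
            class = "spectrum")
}

#' Construct a spectrum set on a common grid
#'
#' @param w Strictly monotone wavenumber grid.
#' @param A Absorbance matrix, grid points x spectra.
#' @param labels Optional class labels, one per spectrum.
#' @param stage Processing stage shared by all member spectra.
#' @param region Optional region tag (set by [slice_region()]).
#' @return A `spectrum_set` object.
#' @export
spectrum_set <- function(w, A, labels = NULL, stage = "raw", region = NULL) {
  stage <- match.arg(stage, SPECTRUM_STAGES)
  A <- as.matrix(A)
  if (nrow(A) != length(w)) stop("grid length must match nrow(A)")
  if (length(w) < 3) stop("grid must have >= 3 points")
  if (!is.null(labels) && length(labels) != ncol(A)) {
    stop("one label per spectrum required")
  }
  if (is.null(colnames(A))) colnames(A) <- paste0("s", seq_len(ncol(A)))
  structure(list(w = as.numeric(w), A = A,
                 labels = if (is.null(labels)) NULL else as.character(labels),
                 stage = stage, region = region),
            class = "spectrum_set")
}

#' @export
print.spectrum_set <- function(x, ...) {
  cat(sprintf("spectrum_set: %d spectra x %d points [%g, %g] cm-1, stage %s\n",
              ncol(x$A), length(x$w), min(x$w), max(x$w), x$stage))
  invisible(x)
}

#' Read spectra from text files
#'
#' Two dialects: a two-column file (wavenumber, absorbance; header optional)
#' per spectrum, or a wide TSV whose first column is the wavenumber and each
#' further column one spectrum.
#'
#' @param path File path (wide) or character vector of paths (two-column).
#' @param labels Optional class labels, one per spectrum.
#' @return A `spectrum_set` (stage `"raw"`).  Spectra read from separate
#'   two-column files are linearly interpolated onto the first file's grid
#'   when grids differ, with a message.
#' @export
read_spectra <- function(path, labels = NULL) {
  read_one <- function(p) {
    df <- utils::read.delim(p, header = FALSE, comment.char = "#",
                            stringsAsFactors = FALSE)
    if (suppressWarnings(is.na(as.numeric(df[1, 1])))) df <- df[-1, ]
    list(w = as.numeric(df[[1]]), a = as.numeric(df[[2]]))
  }
  if (length(path) == 1L) {
    df <- utils::read.delim(path, header = TRUE, comment.char = "#",
                            check.names = FALSE, stringsAsFactors = FALSE)
    if (ncol(df) >= 3L) {
      w <- as.numeric(df[[1]])
      A <- as.matrix(df[, -1, drop = FALSE])
      return(spectrum_set(w, A, labels = labels))
    }
    one <- read_one(path)
    return(spectrum_set(one$w, matrix(one$a, ncol = 1), labels = labels))
  }
  specs <- lapply(path, read_one)
  w <- specs[[1]]$w
  A <- vapply(specs, function(s) {
    if (length(s$w) == length(w) && all(s$w == w)) return(s$a)
    message("interpolating spectrum onto the common grid")
    stats::approx(s$w, s$a, xout = w, rule = 2)$y
  }, numeric(length(w)))
  spectrum_set(w, A, labels = labels)
}

#' Baseline-correct a spectrum or spectrum set
#'
#' Subtracts the straight line through the first and last grid point, so the
#' corrected spectrum is exactly zero at both endpoints.  Requires raw-stage
#' input; re-application is a no-op by construction (second-pass slope and
#' offset are zero).
#'
#' @param x A `spectrum` or `spectrum_set` with stage `"raw"`.
#' @return The object with stage `"baseline_corrected"`.
#' @export
baseline_correct <- function(x) UseMethod("baseline_correct")

baseline_vec <- function(w, a) {
  n <- length(w)
  if (w[n] == w[1]) stop("degenerate grid: w_n equals w_1")
  slope <- (a[n] - a[1]) / (w[n] - w[1])
  offset <- a[1] - slope * w[1]
  a - (w * slope + offset)
}

#' @export
baseline_correct.spectrum <- function(x) {
  if (x$stage != "raw") stop("baseline correction requires a raw spectrum")
  spectrum(x$w, baseline_vec(x$w, x$a), label = x$label,
           stage = "baseline_corrected")
}

#' @export
baseline_correct.spectrum_set <- function(x) {
  if (x$stage != "raw") stop("baseline correction requires raw spectra")
  A <- apply(x$A, 2L, function(a) baseline_vec(x$w, a))
  dimnames(A) <- dimnames(x$A)
  spectrum_set(x$w, A, labels = x$labels, stage = "baseline_corrected",
               region = x$region)
}

#' Vector-normalize a spectrum or spectrum set
#'
#' Mean-centers the baseline-corrected spectrum and divides by its Euclidean
#' norm, so the squared components of the result sum to 1.  Together with
#' [baseline_correct()] this removes additive linear ramps and positive
#' intensity scaling.
#'
#' @param x A `spectrum` or `spectrum_set` with stage
#'   `"baseline_corrected"`.
#' @return The object with stage `"normalized"`.
#' @export
vector_normalize <- function(x) UseMethod("vector_normalize")

normalize_vec <- function(a, id = "spectrum") {
  centered <- a - mean(a)
  nrm <- sqrt(sum(centered^2))
  if (nrm == 0) stop("constant spectrum cannot be normalized: ", id)
  centered / nrm
}

#' @export
vector_normalize.spectrum <- function(x) {
  if (x$stage != "baseline_corrected") {
    stop("vector normalization requires a baseline-corrected spectrum")
  }
  spectrum(x$w, normalize_vec(x$a), label = x$label, stage = "normalized")
}

#' @export
vector_normalize.spectrum_set <- function(x) {
  if (x$stage != "baseline_corrected") {
    stop("vector normalization requires baseline-corrected spectra")
  }
  A <- vapply(seq_len(ncol(x$A)), function(j) {
    normalize_vec(x$A[, j], id = colnames(x$A)[j])
  }, numeric(nrow(x$A)))
  dimnames(A) <- dimnames(x$A)
  spectrum_set(x$w, A, labels = x$labels, stage = "normalized",
               region = x$region)
}

#' Apply the full preprocessing pipeline
#'
#' Baseline correction followed by vector normalization, in that order.
#'
#' @param x A raw `spectrum` or `spectrum_set`.
#' @return The normalized object.
#' @export
preprocess_spectra <- function(x) vector_normalize(baseline_correct(x))

#' Slice a spectral analysis region
#'
#' Inclusive slice on wavenumber.  Named regions: `"fingerprint"`
#' (900-1800 cm-1) and `"ch"` (2800-3000 cm-1, CH stretching).
#'
#' @param x A `spectrum` or `spectrum_set`.
#' @param region `"fingerprint"`, `"ch"`, or numeric `c(lo, hi)` bounds.
#' @return The sliced object, region tag recorded (sets only).
#' @export
slice_region <- function(x, region) {
  if (is.character(region)) {
    tag <- match.arg(region, names(FTIR_REGIONS))
    bounds <- FTIR_REGIONS[[tag]]
  } else {
    bounds <- sort(as.numeric(region))
    tag <- paste0(bounds[1], "-", bounds[2])
  }
  keep <- x$w >= bounds[1] & x$w <= bounds[2]
  if (sum(keep) < 3) stop("region [", bounds[1], ", ", bounds[2],
                          "] intersects the grid in fewer than 3 points")
  if (inherits(x, "spectrum")) {
    return(spectrum(x$w[keep], x$a[keep], label = x$label, stage = x$stage))
  }
  spectrum_set(x$w[keep], x$A[keep, , drop = FALSE], labels = x$labels,
               stage = x$stage, region = tag)
}

#' Concatenate two spectral regions of the same set
#'
#' The classification pipeline uses both fingerprint and CH regions; this
#' stacks their point rows into one feature block.
#'
#' @param set A `spectrum_set`.
#' @param regions Character or list of bounds, passed to [slice_region()].
#' @return A `spectrum_set` over the concatenated (still monotone) grid.
#' @export
slice_regions <- function(set, regions = c("fingerprint", "ch")) {
  parts <- lapply(regions, function(r) slice_region(set, r))
  w <- unlist(lapply(parts, `[[`, "w"))
  A <- do.call(rbind, lapply(parts, `[[`, "A"))
  spectrum_set(w, A, labels = set$labels, stage = set$stage,
               region = paste(vapply(parts, function(p) p$region %||% "",
                                     character(1)), collapse = "+"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Covariance-based PCA of a spectrum set
#'
#' Eigendecomposition of the covariance matrix of the spectra (observations
#' = spectra, variables = grid points); no correlation scaling.
#'
#' @param set A `spectrum_set`, normally at stage `"normalized"`.
#' @param n_components Number of components to keep (default
#'   `min(n_spectra - 1, n_points)`).
#' @return A list of class `spectra_pca`: `scores` (spectra x components),
#'   `loadings` (points x components, orthonormal), `sdev`, `explained`
#'   (variance fractions), `center`, `labels`.
#' @export
spectra_pca <- function(set, n_components = NULL) {
  X <- t(set$A)  # spectra x points
  if (nrow(X) < 2) stop("PCA needs at least 2 spectra")
  maxc <- min(nrow(X) - 1L, ncol(X))
  if (is.null(n_components)) n_components <- maxc
  if (n_components > maxc) stop("n_components exceeds min(n_spectra - 1, n_points)")
  center <- colMeans(X)
  Xc <- sweep(X, 2L, center)
  cv <- crossprod(Xc) / (nrow(X) - 1L)
  eg <- eigen(cv, symmetric = TRUE)
  ev <- pmax(eg$values, 0)
  keep <- seq_len(n_components)
  loadings <- eg$vectors[, keep, drop = FALSE]
  scores <- Xc %*% loadings
  colnames(loadings) <- colnames(scores) <- paste0("PC", keep)
  rownames(scores) <- rownames(X)
  structure(list(scores = scores, loadings = loadings,
                 sdev = sqrt(ev[keep]),
                 explained = ev[keep] / sum(ev),
                 eigenvalues = ev,
                 center = center, labels = set$labels),
            class = "spectra_pca")
}

#' Fit a multi-class Fisher linear discriminant model
#'
#' Maximizes the generalized Rayleigh quotient of between- to within-class
#' scatter; discriminant axes are scaled so the pooled within-class variance
#' along each axis is 1, making nearest-class-mean assignment in
#' discriminant space Mahalanobis-equivalent (uniform priors).
#'
#' When the within-class scatter is singular — the usual regime for spectra,
#' with more grid points than spectra — choose a regularization:
#' `"pca_reduce"` first projects onto the smallest set of principal
#' components explaining at least `var_kept` of the variance; `"ridge"`
#' adds `lambda` to the within-scatter diagonal.
#'
#' @param x A `spectrum_set` (stage `"normalized"`), or a numeric matrix of
#'   observations x variables (e.g., PCA scores).
#' @param labels Class labels (taken from the set if omitted).
#' @param regularization `"pca_reduce"` (default), `"ridge"` or `"none"`.
#' @param var_kept Variance fraction kept under `"pca_reduce"`
#'   (default 0.99).
#' @param lambda Ridge added to the within-scatter diagonal (default 1e-6
#'   of its mean diagonal).
#' @return A list of class `lda_model`: `scaling` (variables x axes),
#'   `means` (class means in discriminant space), `eigenvalues`, plus the
#'   projection used.
#' @export
fit_lda <- function(x, labels = NULL,
                    regularization = c("pca_reduce", "ridge", "none"),
                    var_kept = 0.99, lambda = NULL) {
  regularization <- match.arg(regularization)
  if (inherits(x, "spectrum_set")) {
    if (is.null(labels)) labels <- x$labels
    X <- t(x$A)
  } else {
    X <- as.matrix(x)
  }
  if (is.null(labels)) stop("class labels required")
  labels <- as.character(labels)
  classes <- sort(unique(labels))
  if (length(classes) < 2) stop("need >= 2 classes")
  tab <- table(labels)
  if (any(tab < 2)) stop("every class needs >= 2 training observations")

  center <- colMeans(X)
  proj <- NULL
  if (regularization == "pca_reduce") {
    Xc <- sweep(X, 2L, center)
    sv <- svd(Xc)
    var_frac <- cumsum(sv$d^2) / sum(sv$d^2)
    k <- which(var_frac >= var_kept)[1]
    k <- min(max(k, length(classes) - 1L), sum(sv$d > 1e-10 * sv$d[1]))
    proj <- sv$v[, seq_len(k), drop = FALSE]
    X <- Xc %*% proj
    center0 <- center
    center <- rep(0, ncol(X))
  }

  p <- ncol(X)
  mu <- colMeans(X)
  W <- matrix(0, p, p)
  B <- matrix(0, p, p)
  for (cl in classes) {
    Xi <- X[labels == cl, , drop = FALSE]
    mi <- colMeans(Xi)
    Xi <- sweep(Xi, 2L, mi)
    W <- W + crossprod(Xi)
    B <- B + nrow(Xi) * tcrossprod(mi - mu)
  }
  n <- nrow(X)
  Wc <- W / (n - length(classes))  # pooled within-class covariance

  if (regularization == "ridge") {
    if (is.null(lambda)) lambda <- 1e-6 * mean(diag(Wc))
    Wc <- Wc + diag(lambda, p)
  }
  # whiten by the within-class covariance, then diagonalize between-scatter
  ew <- eigen(Wc, symmetric = TRUE)
  if (regularization == "none" && any(ew$values < 1e-10 * max(ew$values))) {
    stop("within-class scatter is singular; choose regularization = ",
         "\"pca_reduce\" or \"ridge\"")
  }
  vals <- pmax(ew$values, 1e-12 * max(ew$values))
  Wmh <- ew$vectors %*% diag(1 / sqrt(vals), p) %*% t(ew$vectors)
  Bt <- Wmh %*% (B / (n - length(classes))) %*% Wmh
  eb <- eigen(Bt, symmetric = TRUE)
  naxes <- min(length(classes) - 1L, p)
  scaling <- Wmh %*% eb$vectors[, seq_len(naxes), drop = FALSE]
  colnames(scaling) <- paste0("LD", seq_len(naxes))

  Z <- X %*% scaling  # X is already in the (possibly PCA-reduced) space
  means <- do.call(rbind, lapply(classes, function(cl) {
    colMeans(Z[labels == cl, , drop = FALSE])
  }))
  rownames(means) <- classes

  structure(list(scaling = scaling, means = means, classes = classes,
                 eigenvalues = pmax(eb$values[seq_len(naxes)], 0),
                 proj = proj,
                 center0 = if (is.null(proj)) NULL else center0,
                 train_scores = Z, train_labels = labels),
            class = "lda_model")
}

#' Project observations into a fitted discriminant space
#'
#' @param model An `lda_model`.
#' @param x A `spectrum_set` or numeric matrix matching the training
#'   variables.
#' @return Matrix of LD coordinates.
#' @export
lda_project <- function(model, x) {
  X <- if (inherits(x, "spectrum_set")) t(x$A) else as.matrix(x)
  if (!is.null(model$proj)) {
    X <- sweep(X, 2L, model$center0) %*% model$proj
  }
  X %*% model$scaling
}

#' Classify observations with a fitted LDA model
#'
#' Nearest class mean in discriminant space (uniform priors).
#'
#' @param model An `lda_model`.
#' @param x A `spectrum_set` or numeric matrix.
#' @return Character vector of predicted class labels.
#' @export
lda_predict <- function(model, x) {
  Z <- lda_project(model, x)
  d2 <- outer(rowSums(Z^2), rowSums(model$means^2), `+`) -
    2 * Z %*% t(model$means)
  model$classes[max.col(-d2, ties.method = "first")]
}

#' Cross-validated classification of a spectrum set
#'
#' Stratified, seeded k-fold (or leave-one-out) cross-validation of the
#' Fisher LDA classifier; pooled out-of-fold predictions give the accuracy,
#' its Wilson 95% confidence interval, and the confusion matrix.
#'
#' @param set A `spectrum_set` at stage `"normalized"` with labels.
#' @param scheme `"kfold"` (default) or `"loo"`.
#' @param k Number of folds (default 5).
#' @param seed Integer seed for fold assignment.
#' @param ... Passed to [fit_lda()].
#' @return A list of class `classifier_report`: `accuracy`, `ci` (Wilson
#'   95%), `confusion` (true x predicted), `predictions`, `folds`, and
#'   `ld_scores` from a final full-data fit.
#' @export
cross_validate <- function(set, scheme = c("kfold", "loo"), k = 5,
                           seed = NULL, ...) {
  scheme <- match.arg(scheme)
  labels <- set$labels
  if (is.null(labels)) stop("spectrum set carries no class labels")
  if (length(unique(labels)) < 2) stop("need >= 2 classes")
  n <- ncol(set$A)
  folds <- integer(n)
  if (scheme == "loo") {
    folds <- seq_len(n)
    k <- n
  } else {
    if (min(table(labels)) < k) {
      warning("some class has fewer members than k; folds stratified as ",
              "evenly as the class sizes allow")
    }
    folds <- with_seed(seed, {
      f <- integer(n)
      for (cl in unique(labels)) {
        idx <- sample(which(labels == cl))
        f[idx] <- rep_len(seq_len(k), length(idx))
      }
      f
    })
  }
  pred <- character(n)
  for (fold in sort(unique(folds))) {
    test <- folds == fold
    model <- fit_lda(t(set$A[, !test, drop = FALSE]), labels[!test], ...)
    pred[test] <- lda_predict(model, t(set$A[, test, drop = FALSE]))
  }
  classes <- sort(unique(labels))
  confusion <- table(factor(labels, classes), factor(pred, classes),
                     dnn = c("true", "predicted"))
  accuracy <- sum(diag(confusion)) / n
  full <- fit_lda(set, labels, ...)
  structure(list(accuracy = accuracy, ci = wilson_ci(sum(diag(confusion)), n),
                 confusion = confusion,
                 predictions = data.frame(id = colnames(set$A), true = labels,
                                          predicted = pred, fold = folds,
                                          stringsAsFactors = FALSE),
                 ld_scores = full$train_scores),
            class = "classifier_report")
}

#' Wilson score interval for a binomial proportion
#'
#' @param x Number of successes.
#' @param n Number of trials.
#' @param conf Confidence level (default 0.95).
#' @return Named vector `c(lower, upper)`.
#' @export
wilson_ci <- function(x, n, conf = 0.95) {
  z <- stats::qnorm(1 - (1 - conf) / 2)
  p <- x / n
  denom <- 1 + z^2 / n
  center <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  c(lower = max(0, center - half), upper = min(1, center + half))
}
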