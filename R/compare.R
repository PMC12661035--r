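# Beta diversity: standardization/transformation, Bray-Curtis similarity on
# the 0-100 scale, group-average (UPGMA) clustering with similarity-cut
# flat clusters, Kruskal non-metric MDS, and Pearson vector overlays.
#
# Pipeline order is standardize -> transform -> Bray-Curtis, and the
# functions enforce it by operating on the standardized matrix.

#' Standardize and transform a profile for beta-diversity analysis
#'
#' Variables (features) are divided by their maximum across samples, then
#' fourth-root transformed elementwise — the conventional pretreatment
#' before Bray-Curtis on community data.  All-zero feature rows are left as
#' zeros.
#'
#' @param profile A `taxon_profile` (either unit).
#' @param variable_standardize `"max"` (default) or `"none"`.
#' @param transform `"fourth_root"` (default) or `"none"`.
#' @return A samples x features numeric matrix ready for [bray_curtis()].
#' @export
standardize_transform <- function(profile,
                                  variable_standardize = c("max", "none"),
                                  transform = c("fourth_root", "none")) {
  variable_standardize <- match.arg(variable_standardize)
  transform <- match.arg(transform)
  m <- profile$counts + 0
  if (variable_standardize == "max") {
    mx <- apply(m, 1L, max)
    nz <- mx > 0
    m[nz, ] <- m[nz, , drop = FALSE] / mx[nz]
  }
  if (transform == "fourth_root") m <- m^0.25
  t(m)  # samples x features
}

#' Bray-Curtis similarity matrix (0-100 scale)
#'
#' `S(x, y) = 100 * (1 - sum|x - y| / sum(x + y))` for every sample pair.
#' Computed through [vegan::vegdist()].  A pair of all-zero samples has
#' undefined similarity (`NA` sentinel).
#'
#' @param m Samples x features non-negative matrix (e.g., from
#'   [standardize_transform()]).
#' @return A list of class `similarity_matrix`: `sim` (symmetric matrix,
#'   diagonal 100) and `samples`.
#' @export
bray_curtis <- function(m) {
  m <- as.matrix(m)
  if (any(m < 0)) stop("Bray-Curtis needs non-negative values")
  if (is.null(rownames(m))) rownames(m) <- paste0("s", seq_len(nrow(m)))
  zero <- rowSums(m) == 0
  d <- as.matrix(vegan::vegdist(m, method = "bray"))
  sim <- 100 * (1 - d)
  diag(sim) <- 100
  if (any(zero)) {
    sim[zero, zero] <- NA_real_
    diag(sim) <- 100
  }
  structure(list(sim = sim, samples = rownames(m)),
            class = "similarity_matrix")
}

#' Group-average (UPGMA) hierarchical clustering of a similarity matrix
#'
#' Agglomerates the most similar pair first; inter-cluster similarity is
#' the unweighted average over all cross pairs (average linkage on the
#' 100 - S dissimilarity, via [stats::hclust()]).
#'
#' @param sim A `similarity_matrix`.
#' @return A list of class `upgma_dendrogram`: `hclust` (the fitted tree),
#'   `merge_similarity` (similarity at each merge, non-increasing),
#'   `samples`.
#' @export
upgma <- function(sim) {
  s <- sim$sim
  if (nrow(s) < 2) stop("clustering needs >= 2 samples")
  if (any(is.na(s))) stop("similarity matrix contains undefined entries")
  d <- stats::as.dist(100 - s)
  hc <- stats::hclust(d, method = "average")
  structure(list(hclust = hc, merge_similarity = 100 - hc$height,
                 samples = sim$samples),
            class = "upgma_dendrogram")
}

#' Cut a UPGMA dendrogram at a similarity threshold
#'
#' Samples joined at or above `threshold_similarity` share a cluster
#' (default 60, the conventional arbitrary cut).
#'
#' @param dendrogram An `upgma_dendrogram`.
#' @param threshold_similarity Similarity in \[0, 100\].
#' @return Named integer vector of cluster memberships.
#' @export
flat_clusters <- function(dendrogram, threshold_similarity = 60) {
  stats::cutree(dendrogram$hclust, h = 100 - threshold_similarity)
}

#' Export a UPGMA dendrogram as a Newick string
#'
#' @param dendrogram An `upgma_dendrogram`.
#' @param path Optional file to write to.
#' @return The Newick string, invisibly if written to file.
#' @export
dendrogram_newick <- function(dendrogram, path = NULL) {
  phy <- ape::as.phylo(dendrogram$hclust)
  if (is.null(path)) return(ape::write.tree(phy))
  ape::write.tree(phy, file = path)
  invisible(ape::write.tree(phy))
}

#' Non-metric multidimensional scaling (Kruskal stress-1)
#'
#' Minimizes Kruskal's stress-1,
#' `sqrt(sum((d - dhat)^2) / sum(d^2))`, where `d` are configuration
#' distances and `dhat` the monotone (pool-adjacent-violators) regression
#' of `d` on the input dissimilarities, by steepest descent with
#' backtracking line search (stress never increases within a restart).
#' The first start is the classical-scaling (principal coordinates)
#' configuration; the remaining `n_restarts - 1` are random.  The best
#' configuration over restarts is returned.
#'
#' @param dissim Symmetric non-negative dissimilarity matrix (e.g.,
#'   `100 - similarity`).
#' @param ndim Embedding dimension (default 2).
#' @param n_restarts Number of starts (default 20).
#' @param max_iter Iterations per restart (default 200).
#' @param tol Relative stress-decrease convergence tolerance (default 1e-7).
#' @param seed Integer seed for the random starts.
#' @return A list of class `ordination_result`: `points` (samples x ndim),
#'   `stress`, `n_restarts`, `trace` (stress per iteration of the winning
#'   restart).
#' @export
nmds <- function(dissim, ndim = 2, n_restarts = 20, max_iter = 200,
                 tol = 1e-7, seed = NULL) {
  d <- as.matrix(dissim)
  if (!isTRUE(all.equal(d, t(d), tolerance = 1e-8))) {
    stop("dissimilarity matrix must be symmetric")
  }
  if (any(d < 0)) stop("dissimilarities must be non-negative")
  n <- nrow(d)
  if (is.null(rownames(d))) rownames(d) <- paste0("s", seq_len(n))
  lower <- d[lower.tri(d)]

  starts <- with_seed(seed, {
    inits <- vector("list", n_restarts)
    cmd <- suppressWarnings(stats::cmdscale(stats::as.dist(d), k = ndim))
    if (ncol(cmd) == ndim) inits[[1]] <- cmd
    for (i in seq_len(n_restarts)) {
      if (is.null(inits[[i]])) {
        inits[[i]] <- matrix(stats::rnorm(n * ndim), n, ndim)
      }
    }
    inits
  })

  best <- NULL
  for (X0 in starts) {
    fit <- kruskal_descent(lower, X0, max_iter = max_iter, tol = tol)
    if (is.null(best) || fit$stress < best$stress) best <- fit
  }
  rownames(best$points) <- rownames(d)
  structure(list(points = best$points, stress = best$stress,
                 n_restarts = n_restarts, trace = best$trace),
            class = "ordination_result")
}

# One nMDS restart: steepest descent on stress-1 with fixed-disparity
# gradient and a backtracking step guaranteeing monotone descent.
kruskal_descent <- function(lower_d, X, max_iter, tol) {
  n <- nrow(X)
  stress_of <- function(X) {
    dist_conf <- as.vector(stats::dist(X))
    dhat <- numeric(length(dist_conf))
    # primary tie treatment: within tied input dissimilarities the fit may
    # follow the configuration, so sort by (d, dist) before PAVA
    o <- order(lower_d, dist_conf)
    dhat[o] <- stats::isoreg(dist_conf[o])$yf
    list(stress = sqrt(sum((dist_conf - dhat)^2) / sum(dist_conf^2)),
         dist = dist_conf, dhat = dhat)
  }
  cur <- stress_of(X)
  trace <- cur$stress
  step <- 0.2
  for (it in seq_len(max_iter)) {
    if (cur$stress < 1e-12) break
    # gradient of stress-1 w.r.t. coordinates at fixed disparities
    S2 <- sum((cur$dist - cur$dhat)^2)
    T2 <- sum(cur$dist^2)
    G <- matrix(0, n, ncol(X))
    k <- 1L
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        dij <- cur$dist[k]
        if (dij > 1e-12) {
          coef <- cur$stress * ((dij - cur$dhat[k]) / S2 - dij / T2) / dij
          diffv <- X[i, ] - X[j, ]
          G[i, ] <- G[i, ] + coef * diffv
          G[j, ] <- G[j, ] - coef * diffv
        }
        k <- k + 1L
      }
    }
    gnorm <- sqrt(sum(G^2))
    if (gnorm < 1e-14) break
    xnorm <- sqrt(sum(X^2)) + 1e-12
    improved <- FALSE
    for (half in 0:20) {
      Xn <- X - (step / gnorm) * xnorm * G
      cand <- stress_of(Xn)
      if (cand$stress < cur$stress) {
        rel <- (cur$stress - cand$stress) / max(cur$stress, 1e-12)
        X <- Xn
        cur <- cand
        improved <- TRUE
        step <- step * 1.2
        trace <- c(trace, cur$stress)
        if (rel < tol) improved <- NA  # converged
        break
      }
      step <- step / 2
    }
    if (!isTRUE(improved)) break
  }
  list(points = scale(X, center = TRUE, scale = FALSE), stress = cur$stress,
       trace = trace)
}

#' Pearson vector overlay for an ordination
#'
#' Correlates each variable with the ordination axes; the vector endpoint
#' `(r1, r2, ...)` scaled by `scale_const` is the conventional biplot
#' arrow.  Constant variables get a zero-length vector with a warning.
#'
#' @param ord An `ordination_result`.
#' @param variables Samples x variables matrix, rows aligned with
#'   `ord$points`.
#' @param scale_const Plotting scale constant (default 1).
#' @return A data frame with one row per variable: correlations with each
#'   axis, and `length` (Euclidean norm of the correlation vector).
#' @export
vector_overlay <- function(ord, variables, scale_const = 1) {
  V <- as.matrix(variables)
  if (nrow(V) != nrow(ord$points)) stop("variables rows must match samples")
  axes <- ord$points
  out <- t(apply(V, 2L, function(v) {
    if (stats::sd(v) == 0) {
      warning("constant variable mapped to zero-length vector")
      return(rep(0, ncol(axes)))
    }
    apply(axes, 2L, function(a) stats::cor(v, a))
  }))
  colnames(out) <- paste0("r_axis", seq_len(ncol(axes)))
  df <- as.data.frame(out * scale_const)
  df$variable <- colnames(V) %||% paste0("v", seq_len(ncol(V)))
  df$length <- sqrt(rowSums(out^2)) * scale_const
  df[, c("variable", colnames(out), "length")]
}
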