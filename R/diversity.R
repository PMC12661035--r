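# Alpha diversity: the full PRIMER-style DIVERSE record plus sample-based
# accumulation curves.

#' Alpha-diversity suite for one sample
#'
#' Computes the full record of richness, evenness, dominance and Hill-number
#' indices for a single vector of feature counts:
#' \itemize{
#'   \item `S` feature count (Hill number N0); `N` total reads
#'   \item `d` Margalef richness, (S-1)/ln N
#'   \item `J_prime` Pielou evenness, H'/ln S
#'   \item `brillouin` Brillouin diversity, (ln N! - sum ln n_i!)/N
#'   \item `fisher_alpha` solving S = alpha * ln(1 + N/alpha)
#'   \item `H_prime` Shannon entropy, natural log
#'   \item `one_minus_lambda` 1 - sum p_i^2 (Simpson)
#'   \item `one_minus_lambda_prime` unbiased Simpson,
#'     1 - sum n_i(n_i-1) / (N(N-1))
#'   \item Hill numbers `N1 = exp(H')`, `N2 = 1/sum p^2`, `N_inf = 1/p_max`
#'     and the ratios `N10 = N1/S`, `N10_prime = (N1-1)/(S-1)`,
#'     `N21 = N2/N1`, `N21_prime = (N2-1)/(N1-1)`
#'   \item `ES_m` Hurlbert's expected feature count in a random subsample of
#'     `m` reads (hypergeometric, via log-gamma)
#'   \item `goods_coverage` 1 - singletons/N
#' }
#'
#' Quantities undefined for a one-feature sample (`J_prime`, `N10_prime`,
#' `N21_prime`) and `one_minus_lambda_prime` at N = 1 are reported as `NA`
#' (explicit undefined sentinel).  Shannon uses log base e.
#'
#' @param counts Non-negative integer vector of feature counts, at least one
#'   positive.
#' @param m Subsample size for Hurlbert rarefaction `ES_m` (default 100, the
#'   ES(100) convention); capped at `N` with a warning if larger.
#' @return A one-row data frame with the fields above.
#' @export
diversity_suite <- function(counts, m = 100) {
  if (!is.numeric(counts) || any(!is.finite(counts)) || any(counts < 0)) {
    stop("`counts` must be finite and non-negative")
  }
  if (any(abs(counts - round(counts)) > 1e-9)) {
    stop("`counts` must be integers (read counts)")
  }
  counts <- round(counts)
  n <- counts[counts > 0]
  if (length(n) == 0L) stop("all-zero count vector")
  N <- sum(n)
  S <- length(n)
  p <- n / N

  H_prime <- -sum(p * log(p))
  d <- if (N > 1) (S - 1) / log(N) else NA_real_
  J_prime <- if (S > 1) H_prime / log(S) else NA_real_
  brillouin <- (lgamma(N + 1) - sum(lgamma(n + 1))) / N
  lambda <- sum(p^2)
  lambda_prime <- if (N > 1) sum(n * (n - 1)) / (N * (N - 1)) else NA_real_
  N1 <- exp(H_prime)
  N2 <- 1 / lambda
  N_inf <- 1 / max(p)
  N10 <- N1 / S
  N10_prime <- if (S > 1) (N1 - 1) / (S - 1) else NA_real_
  N21 <- N2 / N1
  N21_prime <- if (N1 > 1 + 1e-12) (N2 - 1) / (N1 - 1) else NA_real_

  if (m > N) {
    warning("ES subsample size m = ", m, " exceeds sample total N = ", N,
            "; using m = N")
    m <- N
  }
  singletons <- sum(n == 1)

  data.frame(
    S = S, N = N, d = d, J_prime = J_prime, brillouin = brillouin,
    fisher_alpha = fisher_alpha(S, N), H_prime = H_prime,
    one_minus_lambda = 1 - lambda,
    one_minus_lambda_prime = if (is.na(lambda_prime)) NA_real_ else 1 - lambda_prime,
    N1 = N1, N2 = N2, N_inf = N_inf,
    N10 = N10, N10_prime = N10_prime, N21 = N21, N21_prime = N21_prime,
    ES_m = hurlbert_es(n, m), es_m_size = m,
    goods_coverage = 1 - singletons / N
  )
}

#' Alpha-diversity table for every sample of a profile
#'
#' @param profile A `taxon_profile` with read units.
#' @param m Hurlbert subsample size, as in [diversity_suite()].
#' @return A data frame, one row per sample, with a `sample_id` column.
#' @export
diversity_table <- function(profile, m = 100) {
  if (profile$units != "reads") stop("diversity indices need read counts")
  rows <- lapply(sample_ids(profile), function(s) {
    cbind(sample_id = s, diversity_suite(profile$counts[, s], m = m))
  })
  do.call(rbind, rows)
}

#' Fisher's log-series alpha
#'
#' Solves `S = alpha * ln(1 + N/alpha)` by bracketed root finding on
#' `[1e-8, 1e8]` (the defining function is monotone in alpha).  When every
#' individual is its own feature (S = N) no finite alpha exists and `Inf`
#' is returned.
#'
#' @param S Number of features.
#' @param N Number of individuals (reads).
#' @param tol Root tolerance (default 1e-10).
#' @return Fisher's alpha.
#' @export
fisher_alpha <- function(S, N, tol = 1e-10) {
  if (S >= N) return(Inf)
  f <- function(a) a * log1p(N / a) - S
  stats::uniroot(f, lower = 1e-8, upper = 1e8, tol = tol)$root
}

#' Hurlbert rarefaction ES(m)
#'
#' Expected number of features in a random without-replacement subsample of
#' `m` individuals: `sum_i [1 - C(N - n_i, m) / C(N, m)]`, evaluated through
#' log-gamma for numerical safety.
#'
#' @param counts Positive feature counts (zeros allowed, ignored).
#' @param m Subsample size, `1 <= m <= sum(counts)`.
#' @return Expected feature count, `<= min(S, m)`.
#' @export
hurlbert_es <- function(counts, m) {
  n <- counts[counts > 0]
  N <- sum(n)
  if (m < 1 || m > N) stop("m must be in [1, N]")
  term <- ifelse(N - n < m, 0,
                 exp(lchoose(N - n, m) - lchoose(N, m)))
  sum(1 - term)
}

#' Sample-based feature accumulation curve
#'
#' Averages, over random permutations of sample order, the cumulative number
#' of unique features observed as samples are added.
#'
#' @param profile A `taxon_profile`.
#' @param level Optional rank to aggregate to first.
#' @param n_perm Number of sample-order permutations (default 999).
#' @param seed Integer seed.
#' @return A data frame with `n_samples`, `mean`, `sd` of cumulative unique
#'   features; the final mean equals the total unique feature count.
#' @export
accumulation_curve <- function(profile, level = NULL, n_perm = 999,
                               seed = NULL) {
  if (!is.null(level)) profile <- aggregate_taxa(profile, level)
  ns <- ncol(profile$counts)
  if (ns < 2L) stop("accumulation needs at least 2 samples")
  if (n_perm < 1) stop("n_perm must be >= 1")
  present <- profile$counts > 0
  curves <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      ord <- sample.int(ns)
      seen <- rep(FALSE, nrow(present))
      out <- integer(ns)
      for (k in seq_len(ns)) {
        seen <- seen | present[, ord[k]]
        out[k] <- sum(seen)
      }
      out
    }, integer(ns))
  })
  data.frame(
    n_samples = seq_len(ns),
    mean = rowMeans(curves),
    sd = apply(curves, 1L, stats::sd)
  )
}
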