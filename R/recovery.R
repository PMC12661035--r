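# Recovery scoring of cultured prints against their inoculum, enrichment
# detection, class-shift tests, activity coverage, and the cell
# input/output ratio bound.

#' Score recovery of inoculum features by cultured prints
#'
#' A feature is *eligible* if its relative abundance reaches `inoc_cutoff`
#' in the inoculum group — by default in ANY inoculum sample (the inclusive
#' pooled reading); `pooling = "mean"` uses the mean inoculum abundance
#' instead.  It is *recovered* if it is eligible and reaches `print_cutoff`
#' in at least one print sample.  The fraction |recovered| / |eligible| is
#' the recovery statistic; per-medium recovered subsets are reported when
#' the metadata carries medium labels.
#'
#' @param inoculum A relative-unit `taxon_profile` of inoculum samples.
#' @param prints A relative-unit `taxon_profile` of print samples.
#' @param meta Optional sample metadata (see [read_sample_meta()]) used to
#'   split prints by medium.
#' @param level Optional rank to aggregate both profiles to first (requires
#'   read units on input in that case — aggregate before converting).
#' @param inoc_cutoff Inoculum eligibility threshold in \[0, 1) (default
#'   0.01, the 1% convention).
#' @param print_cutoff Print detection threshold; defaults to
#'   `inoc_cutoff` (symmetric thresholds).
#' @param pooling `"any"` (default) or `"mean"` inoculum pooling.
#' @return A list of class `recovery_report`: `eligible`, `recovered`,
#'   `fraction` (`NA` sentinel when no feature is eligible), `per_medium`,
#'   `enriched` (features below `print_cutoff` everywhere in the inoculum
#'   but detected in prints), and the thresholds used.
#' @export
recovered_fraction <- function(inoculum, prints, meta = NULL, level = NULL,
                               inoc_cutoff = 0.01,
                               print_cutoff = inoc_cutoff,
                               pooling = c("any", "mean")) {
  pooling <- match.arg(pooling)
  if (!is.null(level)) {
    if (inoculum$units == "reads") inoculum <- to_relative(aggregate_taxa(inoculum, level))
    else inoculum <- aggregate_taxa(inoculum, level)
    if (prints$units == "reads") prints <- to_relative(aggregate_taxa(prints, level))
    else prints <- aggregate_taxa(prints, level)
  }
  if (inoculum$units != "relative" || prints$units != "relative") {
    stop("both profiles must be in relative units (or pass `level` with reads)")
  }
  if (inoc_cutoff < 0 || inoc_cutoff >= 1) stop("inoc_cutoff must be in [0, 1)")

  inoc_ab <- if (pooling == "any") {
    apply(inoculum$counts, 1L, max)
  } else {
    rowMeans(inoculum$counts)
  }
  eligible <- names(inoc_ab)[inoc_ab >= inoc_cutoff]

  print_max <- apply(prints$counts, 1L, max)
  detected <- names(print_max)[print_max >= print_cutoff]
  recovered <- intersect(eligible, detected)

  per_medium <- NULL
  if (!is.null(meta)) {
    pm <- meta[meta$sample_id %in% sample_ids(prints) & !is.na(meta$medium), ]
    media <- unique(pm$medium)
    per_medium <- lapply(media, function(md) {
      ids <- pm$sample_id[pm$medium == md]
      if (!length(ids)) {
        warning("medium ", md, " has zero print samples")
        return(character())
      }
      mx <- apply(prints$counts[, ids, drop = FALSE], 1L, max)
      intersect(eligible, names(mx)[mx >= print_cutoff])
    })
    names(per_medium) <- media
  }

  below <- apply(inoculum$counts, 1L, max) < print_cutoff
  enriched <- union(
    intersect(feature_ids(inoculum)[below], detected),
    setdiff(detected, feature_ids(inoculum))
  )

  structure(list(
    eligible = eligible, recovered = recovered,
    fraction = if (length(eligible)) length(recovered) / length(eligible)
               else NA_real_,
    per_medium = per_medium, enriched = enriched,
    inoc_cutoff = inoc_cutoff, print_cutoff = print_cutoff,
    pooling = pooling
  ), class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat(sprintf(
    "recovery_report: %d/%d eligible features recovered (%s) at cutoffs %g/%g\n",
    length(x$recovered), length(x$eligible),
    if (is.na(x$fraction)) "undefined" else sprintf("%.1f%%", 100 * x$fraction),
    x$inoc_cutoff, x$print_cutoff))
  invisible(x)
}

#' Features enriched by culture beyond the inoculum detection limit
#'
#' Features below `detect_cutoff` (or absent) in every inoculum sample but
#' at or above it in at least one print sample — the "below detection but
#' successfully enriched" set.
#'
#' @param inoculum,prints Relative-unit `taxon_profile`s.
#' @param detect_cutoff Detection threshold (default 0.001).
#' @return Character vector of enriched feature ids.
#' @export
enriched_features <- function(inoculum, prints, detect_cutoff = 0.001) {
  print_max <- apply(prints$counts, 1L, max)
  detected <- names(print_max)[print_max >= detect_cutoff]
  inoc_max <- apply(inoculum$counts, 1L, max)
  below <- names(inoc_max)[inoc_max < detect_cutoff]
  union(intersect(below, detected), setdiff(detected, names(inoc_max)))
}

#' Mann-Whitney U class-shift tests with Bonferroni adjustment
#'
#' For each class (row), compares its relative abundances between two
#' sample groups with a two-sided Mann-Whitney U test.  Both groups of
#' size <= `exact_max` use exact enumeration over all group assignments
#' (tie-aware); larger groups use the tie-corrected, continuity-corrected
#' normal approximation.  Adjusted p values are Bonferroni
#' (`min(1, n_classes * p)`).
#'
#' @param group_a,group_b Numeric matrices, classes x samples, with matching
#'   rownames (classes).
#' @param exact_max Use exact enumeration when both groups have at most this
#'   many samples (default 8).
#' @return A data frame with `class`, `U`, `p`, `p_adjusted`, `method`.
#' @export
class_shift_test <- function(group_a, group_b, exact_max = 8) {
  group_a <- as.matrix(group_a)
  group_b <- as.matrix(group_b)
  if (is.null(rownames(group_a)) || !identical(rownames(group_a),
                                               rownames(group_b))) {
    stop("groups must share identical class rownames")
  }
  if (ncol(group_a) < 2 || ncol(group_b) < 2) {
    stop("each group needs >= 2 samples")
  }
  classes <- rownames(group_a)
  res <- lapply(classes, function(cl) {
    mw <- mann_whitney(group_a[cl, ], group_b[cl, ], exact_max = exact_max)
    data.frame(class = cl, U = mw$U, p = mw$p, method = mw$method,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$p_adjusted <- pmin(1, out$p * length(classes))
  out[, c("class", "U", "p", "p_adjusted", "method")]
}

#' Two-sided Mann-Whitney U test (exact or normal approximation)
#'
#' The U statistic counts pairs where x exceeds y, ties counting 1/2.  The
#' exact path enumerates all C(n1 + n2, n1) group assignments of the pooled
#' data and computes the two-sided tail of |U - n1 n2 / 2|; it is exact in
#' the presence of ties.  The approximate path delegates to
#' [stats::wilcox.test()] (tie-corrected variance, continuity correction).
#' Data constant across both groups gives p = 1.
#'
#' @param x,y Numeric vectors (the two groups).
#' @param exact_max Exact enumeration when both lengths are <= this.
#' @return A list with `U`, `p`, `method`.
#' @export
mann_whitney <- function(x, y, exact_max = 8) {
  n1 <- length(x); n2 <- length(y)
  U <- u_statistic(x, y)
  if (stats::var(c(x, y)) == 0) {
    return(list(U = U, p = 1, method = "degenerate"))
  }
  if (n1 <= exact_max && n2 <= exact_max) {
    pooled <- c(x, y)
    idx <- utils::combn(n1 + n2, n1)
    devs <- apply(idx, 2L, function(sel) {
      abs(u_statistic(pooled[sel], pooled[-sel]) - n1 * n2 / 2)
    })
    obs <- abs(U - n1 * n2 / 2)
    p <- mean(devs >= obs - 1e-12)
    return(list(U = U, p = p, method = "exact"))
  }
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, alternative = "two.sided", exact = FALSE,
                       correct = TRUE)
  )
  list(U = U, p = min(1, wt$p.value), method = "normal")
}

# U = number of (x, y) pairs with x > y, ties counting 1/2.
u_statistic <- function(x, y) {
  r <- rank(c(x, y))
  sum(r[seq_along(x)]) - length(x) * (length(x) + 1) / 2
}

#' Transcriptional-activity coverage of an isolate collection
#'
#' Per sample, the summed relative activity of the genera present in the
#' isolate set; the mean over samples is the headline "fraction of average
#' transcriptional activity covered" statistic.  `mode = "mean_profile"`
#' instead averages the activity profile over samples first and sums the
#' covered genera of that mean profile.
#'
#' @param isolate_genera Character vector of genus names in the collection.
#'   Genera absent from the activity table are logged via `message()` and
#'   contribute 0.
#' @param activity Genus x sample matrix of relative activities (columns
#'   sum to 1).
#' @param mode `"per_sample"` (default) or `"mean_profile"`.
#' @return A list: `per_sample` named vector of covered fractions and
#'   `mean` (identical under both modes when columns sum to 1; kept for
#'   the two stated conventions).
#' @export
activity_coverage <- function(isolate_genera, activity,
                              mode = c("per_sample", "mean_profile")) {
  mode <- match.arg(mode)
  activity <- as.matrix(activity)
  if (any(abs(colSums(activity) - 1) > 1e-6)) {
    stop("activity columns must each sum to 1")
  }
  unknown <- setdiff(isolate_genera, rownames(activity))
  if (length(unknown)) {
    message("isolate genera absent from activity table (contribute 0): ",
            paste(unknown, collapse = ", "))
  }
  hit <- rownames(activity) %in% isolate_genera
  per_sample <- colSums(activity[hit, , drop = FALSE])
  mean_cov <- if (mode == "per_sample") {
    mean(per_sample)
  } else {
    sum(rowMeans(activity)[hit])
  }
  list(per_sample = per_sample, mean = mean_cov, mode = mode)
}

#' Upper bound on the cell input/output ratio of printed colonies
#'
#' Scales a reference colony's cell yield by the cube of the radius ratio
#' (sphere volumes) and divides the maximal droplet input by that scaled
#' output.
#'
#' @param input_cells_min,input_cells_max Cells per printed droplet
#'   (defaults 2e1 and 2e2, the microscopy estimate).
#' @param reference_output Cells per reference colony (default 2e9).
#' @param r_print,r_ref Colony radii in the same units (defaults 0.5 and
#'   5 mm).
#' @return A list: `ratio` (the upper bound, input_max / scaled output),
#'   `volume_factor` ((r_ref/r_print)^3), `scaled_output`.
#' @export
estimate_io_ratio <- function(input_cells_min = 2e1, input_cells_max = 2e2,
                              reference_output = 2e9,
                              r_print = 0.5, r_ref = 5) {
  for (nm in c("input_cells_min", "input_cells_max", "reference_output",
               "r_print", "r_ref")) {
    check_number(get(nm), nm, positive = TRUE)
  }
  if (input_cells_min > input_cells_max) stop("input range inverted")
  scaled_output <- reference_output * (r_print / r_ref)^3
  list(ratio = input_cells_max / scaled_output,
       volume_factor = (r_ref / r_print)^3,
       scaled_output = scaled_output)
}
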