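# Synthetic communities, prints, activity profiles and FT-IR spectra with
# known ground truth.  The generator emulates the structure of a
# laser-printed culturomics study: a log-normal ranked inoculum under a
# multi-level taxonomy, hard per-medium survival plus soft growth bias,
# multinomial read sampling at realistic depths, and class-structured
# infrared spectra (Gaussian peak mixtures over a linear baseline).

# Per-sample sequencing depths observed in the emulated study.
DEFAULT_DEPTH_RANGE <- c(6640L, 26728L)

#' Simulate an inoculum community with known truth
#'
#' True relative abundances are log-normal draws, ranked and normalized, so
#' `lognormal_sigma = 0` gives a perfectly even community.  Lineages are
#' assigned by recursive random branching: each rank level splits every
#' parent taxon into `branching[rank]` children, and features are attached
#' to random genus-level leaves.  Per-medium culturability is a Bernoulli
#' survival indicator per feature; growth bias is an independent log-normal
#' multiplier.
#'
#' @param n_features Number of features (>= 2).
#' @param media Character vector of medium labels (may be empty).
#' @param lognormal_sigma Dispersion of the log-normal rank-abundance curve
#'   (default 1.5, a typical host-associated community shape).
#' @param branching Named integer vector of children per rank for
#'   phylum..genus (default `c(phylum = 4, class = 2, order = 2,
#'   family = 2, genus = 3)`).
#' @param culturable_prob Probability a feature is culturable at all
#'   (default 0.85); unculturable features fail on every medium, the
#'   hard-to-culture fraction of real communities.
#' @param survival_prob Probability a culturable feature grows on a given
#'   medium (default 0.5).
#' @param bias_sdlog Log-sd of the growth-bias multiplier (default 0.5);
#'   0 disables soft bias.
#' @param seed Integer seed.
#' @return A list of class `community_truth`: `profile` (single-sample
#'   relative `taxon_profile` named `inoculum`), `abundance` (named true
#'   abundances, sum 1), `lineage`, `survival` (features x media 0/1
#'   matrix), `bias` (features x media positive matrix).
#' @export
simulate_inoculum <- function(n_features, media = character(),
                              lognormal_sigma = 1.5,
                              branching = c(phylum = 4, class = 2, order = 2,
                                            family = 2, genus = 3),
                              culturable_prob = 0.85,
                              survival_prob = 0.5, bias_sdlog = 0.5,
                              seed = NULL) {
  if (n_features < 2) stop("need at least 2 features")
  with_seed(seed, {
    ab <- exp(stats::rnorm(n_features, 0, lognormal_sigma))
    ab <- sort(ab, decreasing = TRUE)
    ab <- ab / sum(ab)
    ids <- sprintf("sp%03d", seq_len(n_features))
    names(ab) <- ids

    lineage <- random_lineages(n_features, branching)
    rownames(lineage) <- ids
    lineage[, "species"] <- ids

    nm <- length(media)
    survival <- matrix(1L, n_features, nm, dimnames = list(ids, media))
    bias <- matrix(1, n_features, nm, dimnames = list(ids, media))
    if (nm > 0) {
      # two-level model: unculturable features fail everywhere; culturable
      # ones survive per medium independently
      culturable <- stats::rbinom(n_features, 1L, culturable_prob)
      survival[] <- culturable * stats::rbinom(n_features * nm, 1L,
                                               survival_prob)
      # a medium growing nothing at all is not a realistic design
      viable <- which(culturable == 1L)
      if (!length(viable)) viable <- seq_len(n_features)
      for (j in seq_len(nm)) {
        if (all(survival[, j] == 0)) {
          survival[viable[sample.int(length(viable), 1L)], j] <- 1L
        }
      }
      if (bias_sdlog > 0) {
        bias[] <- stats::rlnorm(n_features * nm, 0, bias_sdlog)
      }
    }

    counts <- matrix(ab, ncol = 1, dimnames = list(ids, "inoculum"))
    profile <- taxon_profile(counts, lineage, units = "relative")
    structure(list(profile = profile, abundance = ab, lineage = lineage,
                   survival = survival, bias = bias, media = media),
              class = "community_truth")
  })
}

# Hierarchical lineages by recursive random branching.  Parent taxa are
# labelled by rank initial + index path, giving unique names per level.
random_lineages <- function(n_features, branching) {
  ranks <- c("phylum", "class", "order", "family", "genus")
  if (!all(ranks %in% names(branching))) {
    stop("`branching` must name counts for: ", paste(ranks, collapse = ", "))
  }
  lin <- matrix(NA_character_, n_features, length(TAXONOMY_RANKS))
  colnames(lin) <- TAXONOMY_RANKS
  lin[, "domain"] <- "Bacteria"
  path <- rep("", n_features)
  for (r in ranks) {
    child <- sample.int(branching[[r]], n_features, replace = TRUE)
    path <- paste0(path, "_", child)
    lin[, r] <- paste0(substr(r, 1, 1), path)
  }
  lin
}

#' Simulate a cultured print from a community truth
#'
#' Post-culture composition is proportional to truth abundance x survival x
#' bias, renormalized; reads are then a single multinomial draw of size
#' `depth`.
#'
#' @param truth A `community_truth` from [simulate_inoculum()].
#' @param medium A medium label defined in `truth`.
#' @param depth Read depth; default drawn uniformly from the realistic
#'   per-sample range 6,640-26,728.
#' @param sample_id Sample name for the output column.
#' @param seed Integer seed.
#' @return A one-sample `taxon_profile` with read units; column total
#'   equals `depth` exactly.
#' @export
simulate_print <- function(truth, medium, depth = NULL,
                           sample_id = paste0("print_", medium), seed = NULL) {
  if (!medium %in% truth$media) stop("medium not defined in truth: ", medium)
  with_seed(seed, {
    if (is.null(depth)) {
      depth <- sample(seq(DEFAULT_DEPTH_RANGE[1], DEFAULT_DEPTH_RANGE[2]), 1L)
    }
    q <- truth$abundance * truth$survival[, medium] * truth$bias[, medium]
    if (sum(q) == 0) stop("all features killed by medium ", medium)
    q <- q / sum(q)
    reads <- stats::rmultinom(1L, size = depth, prob = q)
    dimnames(reads) <- list(names(truth$abundance), sample_id)
    taxon_profile(reads, truth$lineage, units = "reads")
  })
}

#' Simulate genus-level relative transcriptional activity
#'
#' Each sample's activity profile is a Dirichlet draw (gamma normalization)
#' with concentration `concentration * length(genera)` spread evenly, so
#' columns sum to 1 and the expected activity is uniform across genera.
#'
#' @param genera Character vector of genus names.
#' @param concentration Per-genus Dirichlet concentration (default 1).
#' @param n_samples Number of samples.
#' @param seed Integer seed.
#' @return A genera x samples matrix whose columns each sum to 1.
#' @export
simulate_activity <- function(genera, concentration = 1, n_samples = 1,
                              seed = NULL) {
  check_number(concentration, "concentration", positive = TRUE)
  with_seed(seed, {
    k <- length(genera)
    m <- matrix(stats::rgamma(k * n_samples, shape = concentration, rate = 1),
                nrow = k,
                dimnames = list(genera, paste0("sample", seq_len(n_samples))))
    if (k == 1L) m[] <- 1
    sweep(m, 2L, colSums(m), `/`)
  })
}

#' Default class-structured spectral truth
#'
#' Draws, per class, random Gaussian peak centers inside the fingerprint
#' (900-1800 cm-1) and CH-stretching (2800-3000 cm-1) regions with random
#' widths and heights.  With `disjoint = TRUE` each class gets its own
#' private set of candidate peak positions so class templates do not
#' overlap — the separable design used for classifier sanity checks.
#'
#' @param classes Character vector of class labels.
#' @param n_peaks Peaks per class per region (default 4 fingerprint, 2 CH).
#' @param disjoint Give classes non-overlapping peak positions.
#' @param noise_sd Absorbance noise standard deviation (default 0.01).
#' @param baseline_slope_range,baseline_offset_range Uniform ranges for the
#'   random linear baseline.
#' @param scale_range Uniform range for the per-spectrum intensity scale.
#' @param seed Integer seed.
#' @return A list of class `spectrum_truth` with per-class peak tables and
#'   the nuisance-parameter ranges.
#' @export
spectrum_truth <- function(classes, n_peaks = c(fingerprint = 4, ch = 2),
                           disjoint = FALSE, noise_sd = 0.01,
                           baseline_slope_range = c(-2e-5, 2e-5),
                           baseline_offset_range = c(-0.02, 0.02),
                           scale_range = c(0.7, 1.3), seed = NULL) {
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  regions <- list(fingerprint = c(900, 1800), ch = c(2800, 3000))
  with_seed(seed, {
    peaks <- lapply(seq_along(classes), function(ci) {
      do.call(rbind, lapply(names(regions), function(rg) {
        b <- regions[[rg]]
        k <- n_peaks[[rg]]
        if (disjoint) {
          # carve the region into one private band per class
          width <- diff(b) / length(classes)
          b <- b[1] + c(ci - 1, ci) * width
        }
        data.frame(region = rg,
                   center = stats::runif(k, b[1] + 0.05 * diff(b),
                                         b[2] - 0.05 * diff(b)),
                   width = stats::runif(k, 8, 25),
                   height = stats::runif(k, 0.3, 1))
      }))
    })
    names(peaks) <- classes
    structure(list(classes = classes, peaks = peaks, regions = regions,
                   noise_sd = noise_sd,
                   baseline_slope_range = baseline_slope_range,
                   baseline_offset_range = baseline_offset_range,
                   scale_range = scale_range),
              class = "spectrum_truth")
  })
}

#' Evaluate a class template on a wavenumber grid
#'
#' @param truth A `spectrum_truth`.
#' @param class Class label.
#' @param w Wavenumber grid.
#' @return Numeric vector of template absorbances.
#' @export
class_template <- function(truth, class, w) {
  pk <- truth$peaks[[class]]
  if (is.null(pk)) stop("unknown class: ", class)
  out <- numeric(length(w))
  for (i in seq_len(nrow(pk))) {
    out <- out + pk$height[i] * exp(-0.5 * ((w - pk$center[i]) / pk$width[i])^2)
  }
  out
}

#' Simulate a labelled FT-IR spectrum set
#'
#' Each spectrum is `template x scale + (slope * w + offset) + noise` with
#' per-spectrum uniform scale/baseline draws and Gaussian noise, on a common
#' wavenumber grid.
#'
#' @param truth A `spectrum_truth`.
#' @param n_per_class Spectra per class.
#' @param wavenumber_range Grid bounds in cm-1 (default 525-4000, the full
#'   recorded range); must cover both analysis regions.
#' @param step Grid step in cm-1 (default 2).
#' @param seed Integer seed.
#' @return A `spectrum_set` (stage `"raw"`) with class labels.
#' @export
simulate_spectra <- function(truth, n_per_class = 8,
                             wavenumber_range = c(525, 4000), step = 2,
                             seed = NULL) {
  w <- seq(wavenumber_range[1], wavenumber_range[2], by = step)
  for (rg in names(truth$regions)) {
    b <- truth$regions[[rg]]
    if (sum(w >= b[1] & w <= b[2]) < 3) {
      stop("wavenumber grid excludes the ", rg, " analysis region")
    }
  }
  with_seed(seed, {
    labels <- rep(truth$classes, each = n_per_class)
    A <- vapply(labels, function(cl) {
      tmpl <- class_template(truth, cl, w)
      scale <- stats::runif(1, truth$scale_range[1], truth$scale_range[2])
      slope <- stats::runif(1, truth$baseline_slope_range[1],
                            truth$baseline_slope_range[2])
      offset <- stats::runif(1, truth$baseline_offset_range[1],
                             truth$baseline_offset_range[2])
      tmpl * scale + slope * w + offset +
        stats::rnorm(length(w), 0, truth$noise_sd)
    }, numeric(length(w)))
    colnames(A) <- sprintf("%s_r%02d", labels,
                           stats::ave(seq_along(labels), labels,
                                      FUN = seq_along))
    spectrum_set(w, A, labels = labels, stage = "raw")
  })
}

#' Simulate a full print study design
#'
#' Convenience wrapper: one inoculum plus one print per medium, each at its
#' own depth, with matching sample metadata.
#'
#' @param truth A `community_truth` with at least one medium.
#' @param depths Optional per-medium read depths (recycled); default random
#'   in the realistic range.
#' @param donor Donor label for the metadata.
#' @param seed Integer seed.
#' @return A list: `prints` (multi-sample read `taxon_profile`), `meta`
#'   (sample metadata data frame covering inoculum + prints).
#' @export
simulate_print_study <- function(truth, depths = NULL, donor = "D1",
                                 seed = NULL) {
  if (length(truth$media) == 0) stop("truth defines no media")
  with_seed(seed, {
    if (is.null(depths)) {
      depths <- sample(seq(DEFAULT_DEPTH_RANGE[1], DEFAULT_DEPTH_RANGE[2]),
                       length(truth$media), replace = TRUE)
    }
    depths <- rep_len(depths, length(truth$media))
    mats <- lapply(seq_along(truth$media), function(i) {
      simulate_print(truth, truth$media[i], depth = depths[i])$counts
    })
    counts <- do.call(cbind, mats)
    prints <- taxon_profile(counts, truth$lineage, units = "reads")
    meta <- data.frame(
      sample_id = c("inoculum", colnames(counts)),
      role = c("inoculum", rep("print", length(truth$media))),
      donor = donor,
      medium = c(NA_character_, truth$media),
      atmosphere = "anaerobic",
      stringsAsFactors = FALSE
    )
    list(prints = prints, meta = meta)
  })
}
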