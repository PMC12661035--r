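# Taxon profiles: the universal community object and its I/O.
#
# A `taxon_profile` holds a features x samples count (or relative-abundance)
# matrix together with a full taxonomy lineage per feature.  Lineages use a
# fixed rank order and explicit "unclassified-at-<rank>" sentinels so that
# aggregation at any rank is total.

#' Fixed taxonomy rank order, domain to terminal level
#'
#' The terminal rank ("species") holds the finest label available: a species
#' name, an OTU id, or an ASV id.
#' @export
TAXONOMY_RANKS <- c("domain", "phylum", "class", "order", "family",
                    "genus", "species")

unclassified_sentinel <- function(rank) paste0("unclassified-at-", rank)

is_sentinel <- function(x) startsWith(x, "unclassified-at-")

#' Construct a taxon profile
#'
#' @param counts Non-negative numeric matrix, features x samples, with unique
#'   rownames (feature ids) and unique colnames (sample ids).
#' @param lineage Character matrix, features x `length(TAXONOMY_RANKS)`,
#'   rownames matching `counts`.  Missing entries (`NA` or `""`) are replaced
#'   by the rank's "unclassified-at-<rank>" sentinel, except the terminal
#'   rank which defaults to the feature id.
#' @param units `"reads"` (integer counts) or `"relative"` (columns sum to 1).
#' @return A `taxon_profile` object.
#' @export
taxon_profile <- function(counts, lineage, units = c("reads", "relative")) {
  units <- match.arg(units)
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("`counts` must carry feature ids as rownames and sample ids as colnames")
  }
  if (anyDuplicated(rownames(counts))) stop("duplicate feature id in profile")
  if (anyDuplicated(colnames(counts))) stop("duplicate sample id in profile")
  if (any(!is.finite(counts)) || any(counts < 0)) {
    stop("counts must be finite and non-negative")
  }
  lineage <- fill_lineage(lineage, rownames(counts))
  if (units == "reads") {
    if (any(abs(counts - round(counts)) > 1e-9)) {
      stop("read-unit counts must be integers")
    }
    storage.mode(counts) <- "integer"
  } else {
    storage.mode(counts) <- "double"
    csums <- colSums(counts)
    if (any(abs(csums - 1) > 1e-9)) {
      stop("relative-unit columns must each sum to 1")
    }
  }
  structure(list(counts = counts, lineage = lineage, units = units),
            class = "taxon_profile")
}

# Normalize a lineage matrix: fixed rank columns, sentinel filling, terminal
# rank defaulting to the feature id.
fill_lineage <- function(lineage, feature_ids) {
  nr <- length(TAXONOMY_RANKS)
  if (is.null(lineage)) {
    lineage <- matrix(NA_character_, length(feature_ids), nr)
    rownames(lineage) <- feature_ids
  }
  lineage <- as.matrix(lineage)
  if (ncol(lineage) > nr) stop("lineage has more columns than taxonomy ranks")
  if (ncol(lineage) < nr) {
    pad <- matrix(NA_character_, nrow(lineage), nr - ncol(lineage))
    lineage <- cbind(lineage, pad)
  }
  colnames(lineage) <- TAXONOMY_RANKS
  if (is.null(rownames(lineage))) rownames(lineage) <- feature_ids
  lineage <- lineage[feature_ids, , drop = FALSE]
  for (j in seq_len(nr - 1L)) {
    miss <- is.na(lineage[, j]) | lineage[, j] == ""
    lineage[miss, j] <- unclassified_sentinel(TAXONOMY_RANKS[j])
  }
  term <- nr
  miss <- is.na(lineage[, term]) | lineage[, term] == ""
  lineage[miss, term] <- feature_ids[miss]
  lineage
}

#' @export
print.taxon_profile <- function(x, ...) {
  cat(sprintf("taxon_profile: %d features x %d samples (%s units)\n",
              nrow(x$counts), ncol(x$counts), x$units))
  invisible(x)
}

#' @export
dim.taxon_profile <- function(x) dim(x$counts)

#' Feature and sample ids of a profile
#' @param profile A `taxon_profile`.
#' @return Character vector of ids.
#' @export
feature_ids <- function(profile) rownames(profile$counts)

#' @rdname feature_ids
#' @export
sample_ids <- function(profile) colnames(profile$counts)

#' Subset a profile by sample ids
#' @param profile A `taxon_profile`.
#' @param samples Sample ids to keep (order preserved).
#' @param drop_empty Drop features with zero total in the kept samples.
#' @return A `taxon_profile`.
#' @export
subset_samples <- function(profile, samples, drop_empty = FALSE) {
  missing <- setdiff(samples, sample_ids(profile))
  if (length(missing)) {
    stop("unknown sample id(s): ", paste(missing, collapse = ", "))
  }
  counts <- profile$counts[, samples, drop = FALSE]
  if (drop_empty) {
    keep <- rowSums(counts) > 0
    counts <- counts[keep, , drop = FALSE]
  }
  taxon_profile(counts, profile$lineage[rownames(counts), , drop = FALSE],
                units = profile$units)
}

#' Read a wide feature table
#'
#' Parses a UTF-8, tab-separated table: first column feature id, second
#' column a semicolon-delimited lineage string (domain first), remaining
#' columns one numeric column per sample.  Lines starting with `#` are
#' comments.  Missing lineage entries are sentinel-filled.
#'
#' @param path File path.
#' @param units `"reads"` (default, integer counts) or `"relative"` for
#'   tables of relative abundances whose columns sum to 1.
#' @return A `taxon_profile` with the requested units.
#' @export
read_profile <- function(path, units = c("reads", "relative")) {
  units <- match.arg(units)
  raw <- utils::read.delim(path, header = TRUE, comment.char = "#",
                           check.names = FALSE, stringsAsFactors = FALSE,
                           colClasses = "character", fileEncoding = "UTF-8")
  if (ncol(raw) < 3L) stop("feature table needs id, lineage and >=1 sample column")
  ids <- raw[[1L]]
  if (anyDuplicated(ids)) {
    stop("parse error: duplicate feature id '",
         ids[duplicated(ids)][1L], "'")
  }
  lin_strings <- strsplit(raw[[2L]], ";", fixed = TRUE)
  nr <- length(TAXONOMY_RANKS)
  lineage <- t(vapply(lin_strings, function(v) {
    v <- trimws(v)
    if (length(v) > nr) stop("lineage deeper than the fixed rank order")
    c(v, rep(NA_character_, nr - length(v)))
  }, character(nr)))
  rownames(lineage) <- ids
  num <- as.matrix(raw[, -(1:2), drop = FALSE])
  suppressWarnings(storage.mode(num) <- "double")
  if (any(is.na(num))) stop("parse error: non-numeric or ragged count cell")
  if (any(num < 0)) stop("validation error: negative count")
  rownames(num) <- ids
  taxon_profile(num, lineage, units = units)
}

#' Write a wide feature table
#'
#' Inverse of [read_profile()]; the lineage column joins ranks with `;`.
#'
#' @param profile A `taxon_profile`.
#' @param path Output file path.
#' @export
write_profile <- function(profile, path) {
  lin <- apply(profile$lineage, 1L, paste, collapse = ";")
  df <- data.frame(feature_id = feature_ids(profile),
                   lineage = lin,
                   profile$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a sample metadata table
#'
#' Tab-separated with header `sample_id  role  donor  medium  atmosphere`.
#' `role` must be one of inoculum / print / isolate_set; `medium` may be
#' empty (inocula).
#'
#' @param path File path.
#' @return A data frame with one row per sample.
#' @export
read_sample_meta <- function(path) {
  meta <- utils::read.delim(path, header = TRUE, comment.char = "#",
                            stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  required <- c("sample_id", "role", "donor", "medium", "atmosphere")
  if (!all(required %in% names(meta))) {
    stop("sample metadata must have columns: ", paste(required, collapse = ", "))
  }
  bad <- setdiff(meta$role, c("inoculum", "print", "isolate_set"))
  if (length(bad)) stop("unknown sample role(s): ", paste(bad, collapse = ", "))
  if (anyDuplicated(meta$sample_id)) stop("duplicate sample_id in metadata")
  meta$medium[is.na(meta$medium) | meta$medium == ""] <- NA_character_
  meta
}

#' Aggregate a profile to a taxonomic rank
#'
#' Features sharing the same lineage prefix down to `level` are summed; the
#' output feature ids are the prefix strings (ranks joined by `;`).  Column
#' totals are conserved exactly.
#'
#' @param profile A `taxon_profile`.
#' @param level A rank name from [TAXONOMY_RANKS].
#' @return A `taxon_profile` at the requested rank.
#' @export
aggregate_taxa <- function(profile, level) {
  idx <- match(level, TAXONOMY_RANKS)
  if (is.na(idx)) stop("unknown rank name: ", level)
  prefix <- apply(profile$lineage[, seq_len(idx), drop = FALSE], 1L,
                  paste, collapse = ";")
  groups <- unique(prefix)
  counts <- rowsum(profile$counts + 0, group = prefix, reorder = FALSE)
  counts <- counts[groups, , drop = FALSE]
  lineage <- profile$lineage[match(groups, prefix), seq_len(idx), drop = FALSE]
  lineage <- cbind(lineage,
                   matrix(NA_character_, length(groups),
                          length(TAXONOMY_RANKS) - idx))
  rownames(counts) <- groups
  rownames(lineage) <- groups
  # deeper ranks are meaningless after aggregation; sentinel-fill them, with
  # the terminal slot carrying the aggregated id so re-aggregation is stable
  taxon_profile(counts, lineage, units = profile$units)
}

#' Convert read counts to relative abundances
#'
#' @param profile A `taxon_profile`.  Applying it to a relative profile is
#'   the identity.
#' @return A `taxon_profile` with `units = "relative"`.
#' @export
to_relative <- function(profile) {
  if (profile$units == "relative") return(profile)
  totals <- colSums(profile$counts)
  if (any(totals == 0)) {
    stop("zero-total sample column(s): ",
         paste(sample_ids(profile)[totals == 0], collapse = ", "))
  }
  rel <- sweep(profile$counts + 0, 2L, totals, `/`)
  taxon_profile(rel, profile$lineage, units = "relative")
}

#' Rarefy a profile to a fixed read depth
#'
#' Each sample is subsampled to exactly `depth` reads without replacement
#' (multivariate hypergeometric draw).  Samples whose total is below `depth`
#' are dropped with a warning, mirroring the exclusion of low-depth samples
#' rather than failing the whole table.
#'
#' @param profile A `taxon_profile` with read units.
#' @param depth Target reads per sample (default 6070).
#' @param seed Integer seed for reproducibility.
#' @return A rarefied `taxon_profile`; every column sums to `depth`.
#' @export
rarefy_profile <- function(profile, depth = 6070, seed = NULL) {
  if (profile$units != "reads") stop("rarefaction needs read units")
  check_number(depth, "depth", positive = TRUE)
  depth <- as.integer(depth)
  totals <- colSums(profile$counts)
  low <- totals < depth
  if (all(low)) stop("no sample reaches the rarefaction depth")
  if (any(low)) {
    warning("dropping sample(s) below depth ", depth, ": ",
            paste(sample_ids(profile)[low], collapse = ", "))
  }
  keep <- which(!low)
  out <- with_seed(seed, {
    vapply(keep, function(j) {
      n <- profile$counts[, j]
      if (sum(n) == depth) return(as.integer(n))
      picked <- sample.int(sum(n), depth)
      breaks <- cumsum(n)
      tabulate(findInterval(picked, breaks, left.open = TRUE) + 1L,
               nbins = length(n))
    }, integer(nrow(profile$counts)))
  })
  rownames(out) <- feature_ids(profile)
  colnames(out) <- sample_ids(profile)[keep]
  taxon_profile(out, profile$lineage, units = "reads")
}
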