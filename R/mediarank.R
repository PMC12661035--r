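# Media complementarity: per-medium recovered-feature sets, greedy stepwise
# panel ranking, exclusive UpSet intersection counts, and cumulative
# coverage curves.

#' Per-medium recovered-feature sets
#'
#' Runs [recovered_fraction()] restricted to each medium's print samples,
#' returning the covered sets against the shared eligible universe.
#'
#' @param inoculum Relative-unit inoculum `taxon_profile`.
#' @param prints Relative-unit print `taxon_profile`.
#' @param meta Sample metadata with medium labels for the print samples.
#' @param inoc_cutoff,print_cutoff,pooling As in [recovered_fraction()].
#' @return A list of class `media_coverage`: `sets` (medium -> recovered
#'   feature set), `universe` (eligible inoculum features).
#' @export
coverage_sets <- function(inoculum, prints, meta, inoc_cutoff = 0.01,
                          print_cutoff = inoc_cutoff,
                          pooling = c("any", "mean")) {
  pooling <- match.arg(pooling)
  rep_all <- recovered_fraction(inoculum, prints, meta = meta,
                                inoc_cutoff = inoc_cutoff,
                                print_cutoff = print_cutoff,
                                pooling = pooling)
  if (is.null(rep_all$per_medium)) stop("metadata carries no medium labels")
  structure(list(sets = rep_all$per_medium, universe = rep_all$eligible,
                 pooled_recovered = rep_all$recovered),
            class = "media_coverage")
}

#' Build a media coverage object from explicit sets
#'
#' @param sets Named list, medium -> character vector of covered features.
#' @param universe Character vector of eligible features (default: union of
#'   the sets).
#' @return A `media_coverage`.
#' @export
media_coverage <- function(sets, universe = NULL) {
  if (is.null(names(sets)) || any(names(sets) == "")) {
    stop("`sets` must be a named list of media")
  }
  if (is.null(universe)) universe <- sort(unique(unlist(sets)))
  extra <- setdiff(unlist(sets), universe)
  if (length(extra)) stop("set member(s) outside the universe: ",
                          paste(utils::head(extra, 3), collapse = ", "))
  structure(list(sets = lapply(sets, unique), universe = universe,
                 pooled_recovered = sort(unique(unlist(sets)))),
            class = "media_coverage")
}

#' Greedy stepwise media ranking by complementarity
#'
#' Starting from `base`, each step adds the medium covering the most
#' not-yet-covered features; ties break lexicographically on the medium
#' label.  All media are placed.
#'
#' @param cov A `media_coverage`.
#' @param base Starting medium label (must be in `cov`).
#' @return A data frame with `step`, `medium`, `gain` (new features), and
#'   `cumulative` (covered count after the step).
#' @export
greedy_rank <- function(cov, base) {
  media <- names(cov$sets)
  if (!base %in% media) stop("base medium not in coverage: ", base)
  covered <- unique(cov$sets[[base]])
  out <- data.frame(step = 1L, medium = base, gain = length(covered),
                    cumulative = length(covered), stringsAsFactors = FALSE)
  remaining <- setdiff(media, base)
  while (length(remaining)) {
    gains <- vapply(remaining, function(md) {
      length(setdiff(cov$sets[[md]], covered))
    }, integer(1))
    ord <- order(-gains, remaining)  # max gain, then lexicographic label
    pick <- remaining[ord[1]]
    covered <- union(covered, cov$sets[[pick]])
    out <- rbind(out, data.frame(step = nrow(out) + 1L, medium = pick,
                                 gain = gains[ord[1]],
                                 cumulative = length(covered),
                                 stringsAsFactors = FALSE))
    remaining <- setdiff(remaining, pick)
  }
  rownames(out) <- NULL
  out
}

#' Exhaustively optimal media panel of a given size
#'
#' Searches all panels of `size` media containing `base` for the maximal
#' union coverage — quantifies the greedy gap on small designs.
#'
#' @param cov A `media_coverage` with at most 12 media.
#' @param base Starting medium included in every panel.
#' @param size Panel size including the base.
#' @return A list: `media` (best panel, lexicographically first among
#'   ties), `covered` (union size).
#' @export
exhaustive_rank <- function(cov, base, size) {
  media <- names(cov$sets)
  if (length(media) > 12) stop("exhaustive search limited to <= 12 media")
  if (!base %in% media) stop("base medium not in coverage: ", base)
  others <- sort(setdiff(media, base))
  if (size < 1 || size > length(media)) stop("invalid panel size")
  best <- NULL
  combos <- if (size == 1) matrix(character(), 0, 1) else
    utils::combn(others, size - 1L)
  eval_panel <- function(panel) length(unique(unlist(cov$sets[panel])))
  if (size == 1) {
    return(list(media = base, covered = eval_panel(base)))
  }
  for (j in seq_len(ncol(combos))) {
    panel <- c(base, combos[, j])
    val <- eval_panel(panel)
    if (is.null(best) || val > best$covered) {
      best <- list(media = panel, covered = val)
    }
  }
  best
}

#' Exclusive UpSet intersection counts
#'
#' For every non-empty media combination, the number of features covered by
#' exactly those media (UpSet semantics); the counts partition the union of
#' all sets.
#'
#' @param cov A `media_coverage` with at most 20 media.
#' @return A data frame with `combination` (media labels joined by `&`),
#'   `degree` (number of media in the combination), `count`; only observed
#'   (nonzero) combinations are listed.
#' @export
upset_counts <- function(cov) {
  media <- names(cov$sets)
  if (length(media) > 20) {
    stop("more than 20 media; filter the panel before UpSet counting")
  }
  features <- sort(unique(unlist(cov$sets)))
  if (!length(features)) {
    return(data.frame(combination = character(), degree = integer(),
                      count = integer()))
  }
  membership <- vapply(media, function(md) features %in% cov$sets[[md]],
                       logical(length(features)))
  membership <- matrix(membership, nrow = length(features),
                       dimnames = list(features, media))
  pattern <- apply(membership, 1L, function(row) {
    paste(media[row], collapse = "&")
  })
  tab <- table(pattern)
  out <- data.frame(combination = names(tab),
                    degree = lengths(strsplit(names(tab), "&", fixed = TRUE)),
                    count = as.integer(tab), stringsAsFactors = FALSE)
  out[order(-out$count, out$combination), , drop = FALSE]
}

#' Cumulative coverage curve along a media ordering
#'
#' @param cov A `media_coverage`.
#' @param order Character vector, a permutation of the media labels.
#' @return A data frame with `step`, `medium`, `covered` (count) and
#'   `fraction` of the universe (`NA` sentinel if the universe is empty).
#' @export
cumulative_curve <- function(cov, order) {
  media <- names(cov$sets)
  if (!setequal(order, media) || length(order) != length(media)) {
    stop("`order` must be a permutation of the media labels")
  }
  covered <- character()
  rows <- lapply(seq_along(order), function(k) {
    covered <<- union(covered, cov$sets[[order[k]]])
    data.frame(step = k, medium = order[k], covered = length(covered),
               fraction = if (length(cov$universe)) {
                 length(covered) / length(cov$universe)
               } else NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
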