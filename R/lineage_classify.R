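#' Classify a TF from its two lineage scores
#'
#' Applies the grouping criteria on the trimmed-mean internal Z-scores
#' \code{Z_ad} (adenocarcinoma) and \code{Z_NE} (NEPC):
#' \itemize{
#'   \item \code{SHARED}: \code{Z_ad > theta} and \code{Z_NE > theta} —
#'     moderate-to-high expression in both lineages;
#'   \item \code{AD}: \code{Z_ad - Z_NE > theta} and \code{Z_NE < theta} —
#'     preferential expression in adenocarcinoma;
#'   \item \code{NE}: \code{Z_ad < theta} and \code{Z_NE - Z_ad > theta} —
#'     preferential expression in NEPC;
#'   \item \code{UNCLASSIFIED} otherwise.
#' }
#' Inequalities are strict, so scores exactly at the threshold fall into
#' \code{UNCLASSIFIED}; for any \code{theta > 0} the three named predicates
#' are pairwise mutually exclusive. The default \code{theta = 0.2}
#' corresponds to roughly 20 normalized reads, in line with common
#' low-abundance filtering practice, and may be adapted to the platform.
#'
#' @param z_ad,z_ne numeric vectors of lineage scores (recycled together).
#' @param theta positive classification threshold, default 0.2.
#' @return character vector of categories.
#' @export
#' @examples
#' classify_tf(c(0.5, 0.5, 0.1, 0.2), c(0.5, 0.1, 0.5, 0.2))
classify_tf <- function(z_ad, z_ne, theta = 0.2) {
  if (!is.numeric(theta) || length(theta) != 1L || !is.finite(theta) ||
      theta <= 0)
    stop("theta must be a single positive number")
  if (!all(is.finite(z_ad)) || !all(is.finite(z_ne)))
    stop("non-finite lineage score(s)")
  ifelse(z_ad > theta & z_ne > theta, "SHARED",
  ifelse(z_ad - z_ne > theta & z_ne < theta, "AD",
  ifelse(z_ad < theta & z_ne - z_ad > theta, "NE", "UNCLASSIFIED")))
}

#' Classify every TF of a group-score table
#'
#' @param table group-score table from [group_scores()].
#' @param theta positive classification threshold, default 0.2.
#' @return the input table with a \code{category} column appended; attribute
#'   \code{"counts"} holds the per-category tally and \code{"theta"} the
#'   threshold used.
#' @export
classify_all <- function(table, theta = 0.2) {
  if (!is.data.frame(table) || nrow(table) == 0L)
    stop("empty score table")
  table$category <- classify_tf(table$Z_ad, table$Z_NE, theta)
  counts <- table(factor(table$category,
                         levels = c("SHARED", "AD", "NE", "UNCLASSIFIED")))
  message("classified ", nrow(table), " TFs: ",
          paste(names(counts), as.integer(counts), sep = "=", collapse = ", "))
  structure(table, counts = counts, theta = theta)
}

#' Extract the three TF sets from a classification
#'
#' @param cls classified table from [classify_all()].
#' @return named list of symbol vectors: \code{SHARED}, \code{AD}, \code{NE}.
#' @export
classification_sets <- function(cls) {
  lapply(stats::setNames(nm = c("SHARED", "AD", "NE")),
         function(g) cls$tf[cls$category == g])
}

#' Consolidate TF classifications across cohorts
#'
#' Intersects, per category, the TF lists obtained independently in each
#' cohort — the cross-cohort overlap step that finalizes the TF gene sets.
#' TFs missing from any cohort's scored universe cannot be confirmed in every
#' cohort and are reported as dropped.
#'
#' @param classifications list (length >= 2) of classified tables from
#'   [classify_all()], one per cohort; optionally named by cohort id.
#' @return list with \code{sets} (named list \code{SHARED}/\code{AD}/\code{NE}
#'   of intersected symbol vectors, sorted), \code{per_cohort_sizes} (matrix of
#'   per-cohort set sizes) and \code{dropped} (TFs not scored in every cohort).
#' @export
consolidate <- function(classifications) {
  if (!is.list(classifications) || length(classifications) < 2L)
    stop("consolidation needs >= 2 cohorts; with a single cohort use ",
         "classification_sets() directly")
  if (is.null(names(classifications)))
    names(classifications) <- paste0("cohort", seq_along(classifications))
  universes <- lapply(classifications, function(cl) cl$tf)
  common <- Reduce(intersect, universes)
  dropped <- setdiff(unique(unlist(universes)), common)
  per <- lapply(classifications, classification_sets)
  sets <- lapply(stats::setNames(nm = c("SHARED", "AD", "NE")), function(g)
    sort(Reduce(intersect, lapply(per, `[[`, g))))
  sizes <- vapply(per, function(p) lengths(p)[c("SHARED", "AD", "NE")],
                  integer(3))
  list(sets = sets, per_cohort_sizes = sizes, dropped = dropped)
}

#' Rank TFs within each lineage category
#'
#' Orders each category by its defining score, descending: \code{AD} by
#' \code{Z_ad}, \code{NE} by \code{Z_NE}, \code{SHARED} by
#' \code{min(Z_ad, Z_NE)}. With several cohorts the per-cohort trimmed-mean
#' scores are averaged first. Ties break alphabetically by symbol.
#'
#' @param sets named list of symbol vectors (\code{SHARED}, \code{AD},
#'   \code{NE}) — e.g. [classification_sets()] output or the \code{sets}
#'   element of [consolidate()].
#' @param tables one group-score table, or a list of them (one per cohort).
#' @return named list of ordered symbol vectors.
#' @export
rank_within_lineage <- function(sets, tables) {
  if (is.data.frame(tables)) tables <- list(tables)
  score_of <- function(tfs, col) {
    per_cohort <- lapply(tables, function(tb) {
      i <- match(tfs, tb$tf)
      if (anyNA(i))
        stop("missing score for TF(s): ",
             paste(tfs[is.na(i)], collapse = ", "))
      tb[[col]][i]
    })
    rowMeans(matrix(unlist(per_cohort), nrow = length(tfs)))
  }
  order_by <- function(tfs, key) {
    if (length(tfs) == 0L) return(character(0))
    tfs[order(-key, tfs, method = "radix")]
  }
  list(
    SHARED = order_by(sets$SHARED, pmin(score_of(sets$SHARED, "Z_ad"),
                                        score_of(sets$SHARED, "Z_NE"))),
    AD = order_by(sets$AD, score_of(sets$AD, "Z_ad")),
    NE = order_by(sets$NE, score_of(sets$NE, "Z_NE")))
}
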