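#' Internal Z trajectories over an ordered time series
#'
#' Scores an ordered series of expression profiles (e.g. a patient-derived
#' xenograft transdifferentiation series: baseline, post-castration 8 and 12
#' weeks, relapse). Internal Z-scores are computed per sample within each
#' timepoint's matrix; a timepoint with replicate samples is summarized by the
#' trimmed mean, a single-sample timepoint by the value itself. All matrices
#' are reduced to the intersection of their catalog-subset gene universes;
#' dropped genes are reported.
#'
#' @param series ordered list of expression matrices (genes in rows), named by
#'   timepoint id; unnamed lists get ids \code{T0, T1, ...}.
#' @param catalog optional symbol vector; when supplied each matrix is
#'   subset with [subset_by_catalog()] first.
#' @param log2_transform passed to [compute_internal_z()].
#' @param trim_total trim fraction for replicate timepoints, default 0.2.
#' @return numeric matrix, TFs in rows and timepoints in columns, with
#'   attribute \code{"dropped"} (genes absent from some timepoint).
#' @export
series_scores <- function(series, catalog = NULL, log2_transform = TRUE,
                          trim_total = 0.2) {
  if (!is.list(series) || length(series) < 3L)
    stop("need an ordered series of at least 3 timepoints")
  if (is.null(names(series)) || !all(nzchar(names(series))))
    names(series) <- paste0("T", seq_along(series) - 1L)
  if (!is.null(catalog))
    series <- lapply(series, function(m) subset_by_catalog(m, catalog)$matrix)
  if (any(vapply(series, ncol, 0L) == 0L)) stop("empty timepoint matrix")
  genes <- Reduce(intersect, lapply(series, rownames))
  if (length(genes) < 2L) stop("fewer than 2 genes shared across timepoints")
  dropped <- setdiff(unique(unlist(lapply(series, rownames))), genes)
  ts <- vapply(series, function(m) {
    z <- compute_internal_z(m[genes, , drop = FALSE],
                            log2_transform = log2_transform)
    apply(z, 1L, function(v) trimmed_mean(v, trim_total))
  }, numeric(length(genes)))
  rownames(ts) <- genes
  attr(ts, "dropped") <- dropped
  ts
}

#' Mean trajectory of a TF set
#'
#' Unweighted arithmetic mean of a gene set's internal Z trajectories at each
#' timepoint — e.g. the average AD-TF and NE-TF curves whose crossing defines
#' the transdifferentiation phases.
#'
#' @param tf_set character vector of symbols (or a gene-set list with a
#'   \code{members} element).
#' @param ts timepoint score matrix from [series_scores()].
#' @return named numeric vector (one value per timepoint) with attribute
#'   \code{"coverage"} (members found / total).
#' @export
set_trajectory <- function(tf_set, ts) {
  if (is.list(tf_set)) tf_set <- tf_set$members
  tf_set <- unique(normalize_symbols(tf_set))
  hit <- tf_set[tf_set %in% rownames(ts)]
  if (length(hit) == 0L) stop("gene set disjoint from scored TFs")
  traj <- colMeans(ts[hit, , drop = FALSE])
  attr(traj, "coverage") <- list(found = length(hit), total = length(tf_set))
  traj
}

#' Phase segmentation of a transdifferentiation series
#'
#' Labels each timepoint from the AD-set and NE-set trajectories:
#' \code{ADENO_LIKE} when only the adenocarcinoma program is active
#' (\code{ad >= theta}, \code{ne < theta}), \code{NE_LIKE} when only the
#' neuroendocrine program is (\code{ne >= theta}, \code{ad < theta}), and
#' \code{DORMANT} when both are suppressed. Both programs active at once is
#' not a state the model admits and raises an error naming the timepoint.
#' The de-/re-differentiation phases of the three-phase view are the
#' transitions between consecutive labels, reported alongside.
#'
#' @param ad_traj,ne_traj trajectories over identical timepoints
#'   ([set_trajectory()]).
#' @param theta positive threshold, default 0.2.
#' @return named character vector of phase labels per timepoint with attribute
#'   \code{"transitions"} (e.g. \code{"T0->T1: ADENO_LIKE->DORMANT"}).
#' @export
assign_phases <- function(ad_traj, ne_traj, theta = 0.2) {
  if (theta <= 0) stop("theta must be positive")
  if (length(ad_traj) != length(ne_traj) ||
      (!is.null(names(ad_traj)) && !identical(names(ad_traj), names(ne_traj))))
    stop("trajectories must share timepoints")
  both <- ad_traj >= theta & ne_traj >= theta
  if (any(both))
    stop("both lineage programs above threshold at timepoint(s): ",
         paste(if (is.null(names(ad_traj))) which(both)
               else names(ad_traj)[both], collapse = ", "))
  phase <- ifelse(ad_traj >= theta, "ADENO_LIKE",
           ifelse(ne_traj >= theta, "NE_LIKE", "DORMANT"))
  names(phase) <- names(ad_traj)
  tp <- if (is.null(names(phase))) as.character(seq_along(phase))
        else names(phase)
  trans <- if (length(phase) > 1L)
    paste0(tp[-length(tp)], "->", tp[-1L], ": ",
           phase[-length(phase)], "->", phase[-1L])
  else character(0)
  structure(phase, transitions = trans, theta = theta)
}

#' Screen for dormant TFs
#'
#' Flags TFs with heightened weighted expression at the dormant timepoint
#' relative to both terminal stages: a TF is flagged iff its score at the
#' dormant timepoint exceeds an absolute floor (\code{Z_dormant > theta_floor})
#' and exceeds every terminal-stage score by a margin
#' (\code{Z_dormant - Z_t > delta} for each terminal timepoint \code{t}).
#' By default the dormant timepoint is the third of four (castration 12 weeks)
#' and the terminals are the first and last (baseline and relapse); the
#' 8-week timepoint participates only if listed explicitly.
#'
#' @param ts timepoint score matrix from [series_scores()].
#' @param dormant_tp dormant timepoint id (default: third column).
#' @param terminal_tps terminal timepoint ids (default: first and last
#'   columns).
#' @param delta required margin over each terminal, default 0.2.
#' @param theta_floor absolute floor on the dormant score, default 0.2.
#' @return data frame of flagged TFs ranked by descending dormant score:
#'   \code{tf}, \code{Z_dormant}, one \code{margin_<tp>} column per terminal;
#'   attribute \code{"params"} records the thresholds and timepoints.
#' @export
screen_dormant <- function(ts, dormant_tp = colnames(ts)[3L],
                           terminal_tps = colnames(ts)[c(1L, ncol(ts))],
                           delta = 0.2, theta_floor = 0.2) {
  if (delta <= 0) stop("delta must be positive")
  if (!dormant_tp %in% colnames(ts))
    stop("unknown dormant timepoint: ", dormant_tp)
  if (!all(terminal_tps %in% colnames(ts)))
    stop("unknown terminal timepoint(s): ",
         paste(setdiff(terminal_tps, colnames(ts)), collapse = ", "))
  if (dormant_tp %in% terminal_tps)
    stop("dormant timepoint cannot also be terminal: ", dormant_tp)
  zd <- ts[, dormant_tp]
  margins <- zd - ts[, terminal_tps, drop = FALSE]
  keep <- zd > theta_floor & apply(margins > delta, 1L, all)
  res <- data.frame(tf = rownames(ts)[keep], Z_dormant = zd[keep],
                    row.names = NULL)
  for (tp in terminal_tps) res[[paste0("margin_", tp)]] <- margins[keep, tp]
  res <- res[order(-res$Z_dormant, res$tf, method = "radix"), , drop = FALSE]
  rownames(res) <- NULL
  structure(res, params = list(dormant_tp = dormant_tp,
                               terminal_tps = terminal_tps,
                               delta = delta, theta_floor = theta_floor))
}
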