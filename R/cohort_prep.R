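#' Default lineage marker panels
#'
#' The AR-axis panel (AR and the PSA gene KLK3) marks adenocarcinoma; the
#' NE-axis panel (CHGA and CD56/NCAM1) marks the neuroendocrine phenotype.
#' Both are user-overridable wherever panels are accepted.
#'
#' @return named list with character vectors \code{ar_axis} and \code{ne_axis}.
#' @export
default_panels <- function() {
  list(ar_axis = c("AR", "KLK3"), ne_axis = c("CHGA", "NCAM1"))
}

#' Per-sample marker-panel score
#'
#' Mean internal Z-score of the panel's genes present in the matrix, per
#' sample. Computing on internal Z (rather than raw expression) makes the
#' selection inherit the method's per-sample scale invariance. Panel genes
#' absent from the matrix are reported via the \code{"coverage"} attribute.
#'
#' @param z internal Z matrix ([compute_internal_z()]).
#' @param panel character vector of marker gene symbols.
#' @return named numeric vector of per-sample scores with attribute
#'   \code{"coverage"} (list: \code{found}, \code{missing}).
#' @export
panel_score <- function(z, panel) {
  panel <- unique(normalize_symbols(panel))
  hit <- panel[panel %in% rownames(z)]
  if (length(hit) == 0L)
    stop("no panel gene present in matrix: ", paste(panel, collapse = ", "))
  s <- colMeans(z[hit, , drop = FALSE])
  attr(s, "coverage") <- list(found = hit, missing = setdiff(panel, hit))
  s
}

#' Assign lineage labels from marker-panel scores
#'
#' Selects clean lineage samples: \code{ADENO} (AR+/NE-) when the AR-axis
#' score is at least the threshold and the NE-axis score is below it;
#' \code{NEPC} (AR-/NE+) in the mirrored case; every other sample — double
#' positive or double negative — is \code{EXCLUDED} from downstream group
#' scoring.
#'
#' @param ar_scores,ne_scores named per-sample scores over identical samples
#'   (see [panel_score()]).
#' @param theta_sel selection threshold, default 0 (the sign of the internal
#'   Z panel score).
#' @return named character vector sample -> \code{ADENO}/\code{NEPC}/
#'   \code{EXCLUDED}, with attribute \code{"params"}.
#' @export
assign_lineage <- function(ar_scores, ne_scores, theta_sel = 0) {
  if (is.null(names(ar_scores)) || is.null(names(ne_scores)))
    stop("score vectors must be named by sample id")
  if (!setequal(names(ar_scores), names(ne_scores)))
    stop("score vectors cover different samples: ",
         paste(c(setdiff(names(ar_scores), names(ne_scores)),
                 setdiff(names(ne_scores), names(ar_scores))), collapse = ", "))
  ne_scores <- ne_scores[names(ar_scores)]
  lab <- ifelse(ar_scores >= theta_sel & ne_scores < theta_sel, "ADENO",
         ifelse(ne_scores >= theta_sel & ar_scores < theta_sel, "NEPC",
                "EXCLUDED"))
  structure(stats::setNames(lab, names(ar_scores)),
            groups = c("ADENO", "NEPC", "EXCLUDED"),
            params = list(theta_sel = theta_sel))
}

#' Panel-based sample selection on an expression matrix
#'
#' Convenience wrapper: computes internal Z, scores both marker panels and
#' assigns lineage labels.
#'
#' @param m expression matrix (genes in rows).
#' @param panels list with \code{ar_axis} and \code{ne_axis} symbol vectors;
#'   default [default_panels()].
#' @param theta_sel selection threshold, default 0.
#' @param log2_transform passed to [compute_internal_z()].
#' @return labels as from [assign_lineage()].
#' @export
select_samples <- function(m, panels = default_panels(), theta_sel = 0,
                           log2_transform = TRUE) {
  z <- compute_internal_z(m, log2_transform = log2_transform)
  assign_lineage(panel_score(z, panels$ar_axis),
                 panel_score(z, panels$ne_axis), theta_sel)
}
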