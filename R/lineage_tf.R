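#' Fit a lineage TF profile to a two-lineage cohort
#'
#' The package's main entry point. Given a gene-by-sample expression matrix,
#' it (1) subsets to the TF catalog, (2) computes per-sample internal
#' Z-scores, (3) selects clean lineage samples via marker panels when no
#' labels are supplied, (4) computes trimmed-mean lineage scores \code{Z_ad}
#' and \code{Z_NE} per TF, and (5) classifies every TF as \code{SHARED},
#' \code{AD}, \code{NE} or \code{UNCLASSIFIED}.
#'
#' @param x numeric expression matrix (genes in rows, samples in columns) or
#'   a path readable by [read_expression_matrix()].
#' @param labels optional named sample -> group vector with groups
#'   \code{ADENO}/\code{NEPC} (and optionally \code{EXCLUDED}); when
#'   \code{NULL}, labels are derived from the marker panels via
#'   [assign_lineage()].
#' @param catalog optional TF catalog (symbol vector or path for
#'   [read_catalog()]); \code{NULL} scores every gene in the matrix.
#' @param theta classification threshold on the trimmed-mean internal Z,
#'   default 0.2.
#' @param trim total trim fraction for the group means, default 0.2 (drop the
#'   top and bottom 10\% per group).
#' @param log2_transform apply \code{log2(x + 1)} before standardization,
#'   default \code{TRUE}.
#' @param panels marker panels for sample selection, default
#'   [default_panels()].
#' @param theta_sel selection threshold on panel scores, default 0.
#' @return object of class \code{"lineage_tf"}: a list with \code{scores}
#'   (classified group-score table), \code{sets} (the three TF sets),
#'   \code{ranked} (per-category rankings), \code{z} (internal Z matrix),
#'   \code{labels}, \code{missing} (catalog symbols absent from the matrix),
#'   \code{params} and \code{call}.
#' @seealso [classify_all()], [group_scores()], [compute_internal_z()]
#' @export
#' @examples
#' sim <- simulate_cohort(seed = 1)
#' fit <- lineage_tf(sim$matrix, labels = sim$labels)
#' fit
#' head(coef(fit))
lineage_tf <- function(x, labels = NULL, catalog = NULL, theta = 0.2,
                       trim = 0.2, log2_transform = TRUE,
                       panels = default_panels(), theta_sel = 0) {
  cl <- match.call()
  if (is.character(x) && length(x) == 1L) x <- read_expression_matrix(x)
  if (is.character(catalog) && length(catalog) == 1L &&
      file.exists(catalog)) catalog <- read_catalog(catalog)
  missing_syms <- character(0)
  if (!is.null(catalog)) {
    sub <- subset_by_catalog(x, catalog)
    x <- sub$matrix
    missing_syms <- sub$missing
  }
  z <- compute_internal_z(x, log2_transform = log2_transform)
  if (is.null(labels)) {
    labels <- assign_lineage(panel_score(z, panels$ar_axis),
                             panel_score(z, panels$ne_axis), theta_sel)
  } else {
    unknown <- setdiff(names(labels), colnames(z))
    if (length(unknown))
      stop("label(s) for unknown sample(s): ",
           paste(unknown, collapse = ", "))
  }
  tab <- group_scores(z, labels, trim_total = trim)
  cls <- classify_all(tab, theta = theta)
  sets <- classification_sets(cls)
  structure(list(scores = cls, sets = sets,
                 ranked = rank_within_lineage(sets, cls),
                 z = z, labels = labels, missing = missing_syms,
                 params = list(theta = theta, trim = trim,
                               log2_transform = log2_transform,
                               theta_sel = theta_sel, panels = panels),
                 call = cl),
            class = "lineage_tf")
}

#' @export
print.lineage_tf <- function(x, ...) {
  cat("Lineage TF profile (internal Z-score method)\n")
  cat("  call: ", deparse(x$call), "\n", sep = "")
  n <- table(factor(x$labels, levels = c("ADENO", "NEPC", "EXCLUDED")))
  cat(sprintf("  samples: %d ADENO, %d NEPC, %d excluded\n",
              n[["ADENO"]], n[["NEPC"]], n[["EXCLUDED"]]))
  cnt <- attr(x$scores, "counts")
  cat(sprintf("  TFs scored: %d (theta = %g, trim = %g, transform = %s)\n",
              nrow(x$scores), x$params$theta, x$params$trim,
              if (x$params$log2_transform) "log2(x+1)" else "none"))
  cat(sprintf("  sets: %d SHARED, %d AD, %d NE, %d unclassified\n",
              cnt[["SHARED"]], cnt[["AD"]], cnt[["NE"]],
              cnt[["UNCLASSIFIED"]]))
  invisible(x)
}

#' @export
summary.lineage_tf <- function(object, n_top = 10L, ...) {
  structure(list(fit = object, n_top = n_top), class = "summary.lineage_tf")
}

#' @export
print.summary.lineage_tf <- function(x, ...) {
  print(x$fit)
  for (g in c("AD", "NE", "SHARED")) {
    top <- utils::head(x$fit$ranked[[g]], x$n_top)
    cat(sprintf("  top %s: %s\n", g, paste(top, collapse = ", ")))
  }
  invisible(x)
}

#' @describeIn lineage_tf matrix of the two lineage scores per TF
#'   (rows named by TF, columns \code{Z_ad}, \code{Z_NE}).
#' @param object,... method arguments.
#' @export
coef.lineage_tf <- function(object, ...) {
  m <- as.matrix(object$scores[, c("Z_ad", "Z_NE")])
  rownames(m) <- object$scores$tf
  m
}

#' @describeIn lineage_tf scatter of \code{Z_ad} vs \code{Z_NE} colored by
#'   category, with the classification boundaries at \code{theta}.
#' @export
plot.lineage_tf <- function(x, ...) {
  s <- x$scores
  cols <- c(SHARED = "#7570b3", AD = "#1b9e77", NE = "#d95f02",
            UNCLASSIFIED = "grey70")
  graphics::plot(s$Z_ad, s$Z_NE, col = cols[s$category], pch = 16,
                 xlab = expression(Z[ad]), ylab = expression(Z[NE]), ...)
  graphics::abline(h = x$params$theta, v = x$params$theta, lty = 3)
  graphics::abline(0, 1, lty = 3, col = "grey50")
  graphics::legend("topleft", legend = names(cols), col = cols, pch = 16,
                   bty = "n", cex = 0.8)
  invisible(x)
}

#' @describeIn lineage_tf assign lineage labels to new samples with the
#'   fitted marker panels and selection threshold (\code{newdata}: expression
#'   matrix over at least the panel genes).
#' @param newdata expression matrix of new samples (genes in rows).
#' @export
predict.lineage_tf <- function(object, newdata, ...) {
  z <- compute_internal_z(newdata,
                          log2_transform = object$params$log2_transform)
  assign_lineage(panel_score(z, object$params$panels$ar_axis),
                 panel_score(z, object$params$panels$ne_axis),
                 object$params$theta_sel)
}
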