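#' Per-sample mean and standard deviation over catalog genes
#'
#' For each sample (column), the arithmetic mean and the sample standard
#' deviation (n-1 denominator) across all scored genes — the normalizing
#' constants of the internal Z-score.
#'
#' @param m numeric expression matrix, genes in rows (at least 2).
#' @return data frame with columns \code{sample}, \code{mean}, \code{sd} and
#'   \code{degenerate} (\code{TRUE} where \code{sd == 0}).
#' @export
column_stats <- function(m) {
  if (!is.matrix(m) || nrow(m) < 2L)
    stop("need a matrix with at least 2 gene rows")
  mu <- colMeans(m)
  s <- apply(m, 2L, stats::sd)
  data.frame(sample = colnames(m), mean = mu, sd = s,
             degenerate = s == 0, row.names = NULL)
}

#' Internal Z-score matrix
#'
#' Standardizes every expression value against the mean and sample standard
#' deviation of all scored genes *within the same sample*:
#' \eqn{z_i = (x_i - \bar{x}) / s}. Because each sample is its own reference,
#' samples are comparable without any cross-sample normalization, and the
#' scores are invariant to positive per-sample scale factors.
#'
#' @param m numeric matrix (genes in rows, samples in columns), catalog-subset.
#' @param log2_transform apply \code{log2(x + 1)} first (default \code{TRUE};
#'   on raw linear-scale expression the per-sample sd is dominated by a few
#'   extreme genes).
#' @param drop_degenerate drop zero-variance columns with a warning instead of
#'   erroring.
#' @return matrix of internal Z-scores with the input dim names; every column
#'   has mean 0 and sample sd 1. Attribute \code{"provenance"} records the
#'   transform applied.
#' @export
#' @examples
#' m <- matrix(c(1, 2, 3, 2, 4, 6), nrow = 3,
#'             dimnames = list(c("A", "B", "C"), c("s1", "s2")))
#' compute_internal_z(m, log2_transform = FALSE)
compute_internal_z <- function(m, log2_transform = TRUE,
                               drop_degenerate = FALSE) {
  if (!is.matrix(m) || nrow(m) < 2L || ncol(m) < 1L)
    stop("need a non-empty matrix with at least 2 gene rows")
  if (!all(is.finite(m))) stop("non-finite expression value(s)")
  if (log2_transform) {
    if (any(m < 0)) stop("negative values are incompatible with log2(x + 1)")
    m <- log2(m + 1)
  }
  s <- apply(m, 2L, stats::sd)
  deg <- which(s == 0)
  if (length(deg)) {
    if (!drop_degenerate)
      stop("zero-variance column(s): ",
           paste(colnames(m)[deg], collapse = ", "),
           " (use drop_degenerate = TRUE to drop them)")
    warning("dropping ", length(deg), " zero-variance column(s): ",
            paste(colnames(m)[deg], collapse = ", "))
    m <- m[, -deg, drop = FALSE]
    s <- s[-deg]
  }
  z <- sweep(sweep(m, 2L, colMeans(m)), 2L, s, "/")
  attr(z, "provenance") <- list(
    transform = if (log2_transform) "log2(x+1)" else "none",
    n_genes = nrow(z))
  z
}

#' Trimmed mean with spreadsheet (Excel TRIMMEAN) semantics
#'
#' Mean after discarding \code{floor(n * trim_total / 2)} values from each end
#' of the sorted vector — i.e. the total excluded count is rounded down to the
#' nearest even integer, exactly as the Excel \code{TRIMMEAN(range, trim_total)}
#' function computes it. With \code{trim_total = 0.2} this drops the top and
#' bottom 10\% of values.
#'
#' @param values numeric vector (non-empty, finite).
#' @param trim_total total fraction to exclude, in \code{[0, 1)}; default 0.2.
#' @return the trimmed mean, with attribute \code{"k"} = number of values
#'   excluded from each end.
#' @export
#' @examples
#' trimmed_mean(c(1:9, 100), 0.2)  # drops 1 and 100 -> 5.5
trimmed_mean <- function(values, trim_total = 0.2) {
  if (length(values) == 0L) stop("empty input to trimmed_mean")
  if (!is.numeric(values) || !all(is.finite(values)))
    stop("trimmed_mean needs finite numeric values")
  if (!is.numeric(trim_total) || length(trim_total) != 1L ||
      trim_total < 0 || trim_total >= 1)
    stop("trim_total must be in [0, 1)")
  n <- length(values)
  k <- trim_count(n, trim_total)
  v <- sort(values)
  structure(mean(v[(k + 1L):(n - k)]), k = k)
}

#' @rdname trimmed_mean
#' @param n number of values.
#' @return \code{trim_count}: the integer count excluded per end,
#'   \code{floor(n * trim_total / 2)}.
#' @export
trim_count <- function(n, trim_total = 0.2) {
  as.integer(floor(n * trim_total / 2))
}

#' Trimmed-mean lineage scores per TF
#'
#' For every TF (row of the internal Z matrix), computes the trimmed-mean
#' internal Z over the samples of each lineage group — \code{Z_ad} over
#' adenocarcinoma samples and \code{Z_NE} over NEPC samples — excluding the
#' top and bottom 10\% of values per group (at the default trim) to damp
#' high-dispersion samples. Samples labelled \code{EXCLUDED} are ignored.
#'
#' @param z internal Z matrix from [compute_internal_z()].
#' @param labels named character vector sample -> group; groups \code{"ADENO"},
#'   \code{"NEPC"} and optionally \code{"EXCLUDED"} (see [assign_lineage()]).
#' @param trim_total total trim fraction, default 0.2.
#' @return data frame with one row per TF: \code{tf}, \code{Z_ad}, \code{Z_NE},
#'   group sizes \code{n_ad}, \code{n_NE}, per-end trim counts \code{k_ad},
#'   \code{k_NE} and retained counts \code{S_ad}, \code{S_NE}.
#' @export
group_scores <- function(z, labels, trim_total = 0.2) {
  labels <- labels[names(labels) %in% colnames(z)]
  ad <- names(labels)[labels == "ADENO"]
  ne <- names(labels)[labels == "NEPC"]
  if (length(ad) == 0L) stop("group empty after exclusions: ADENO")
  if (length(ne) == 0L) stop("group empty after exclusions: NEPC")
  row_tm <- function(cols) apply(z[, cols, drop = FALSE], 1L,
                                 function(v) trimmed_mean(v, trim_total))
  k_ad <- trim_count(length(ad), trim_total)
  k_ne <- trim_count(length(ne), trim_total)
  data.frame(tf = rownames(z),
             Z_ad = row_tm(ad), Z_NE = row_tm(ne),
             n_ad = length(ad), n_NE = length(ne),
             k_ad = k_ad, k_NE = k_ne,
             S_ad = length(ad) - 2L * k_ad, S_NE = length(ne) - 2L * k_ne,
             row.names = NULL)
}
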