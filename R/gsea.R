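#' Rank genes by a two-class differential metric
#'
#' Builds the ranked list underlying two-class GSEA. The default
#' \code{signal_to_noise} metric is \eqn{(\mu_A - \mu_B) / (\sigma_A +
#' \sigma_B)} with each group standard deviation floored at
#' \eqn{0.2 |\mu|} of its group (the classic GSEA-desktop variance floor);
#' \code{difference_of_means} is \eqn{\mu_A - \mu_B} and admits single-sample
#' groups. Ordering is by descending score with stable alphabetical
#' tie-breaking, so rankings are reproducible across platforms.
#'
#' @param m expression matrix (genes in rows); typically the whole
#'   transcriptome, not a catalog subset.
#' @param labels named sample -> group vector; samples outside the two
#'   compared groups are ignored.
#' @param metric \code{"signal_to_noise"} (default) or
#'   \code{"difference_of_means"}.
#' @param groups length-2 character vector (A, B); positive scores mean
#'   higher in A. Defaults to the first two declared groups of \code{labels}.
#' @return data frame \code{gene}, \code{score}, ordered descending;
#'   attributes \code{"metric"} and \code{"groups"}.
#' @export
rank_metric <- function(m, labels,
                        metric = c("signal_to_noise", "difference_of_means"),
                        groups = NULL) {
  metric <- match.arg(metric)
  if (is.null(groups))
    groups <- setdiff(attr(labels, "groups") %||% unique(labels),
                      "EXCLUDED")[1:2]
  if (length(groups) != 2L || anyNA(groups))
    stop("need exactly two phenotype groups")
  a <- intersect(colnames(m), names(labels)[labels == groups[1L]])
  b <- intersect(colnames(m), names(labels)[labels == groups[2L]])
  if (length(a) == 0L || length(b) == 0L)
    stop("phenotype group without samples in matrix")
  if (metric == "signal_to_noise" && (length(a) < 2L || length(b) < 2L))
    stop("signal_to_noise needs >= 2 samples per phenotype; ",
         "use metric = 'difference_of_means'")
  mu_a <- rowMeans(m[, a, drop = FALSE])
  mu_b <- rowMeans(m[, b, drop = FALSE])
  if (metric == "signal_to_noise") {
    sd_a <- pmax(apply(m[, a, drop = FALSE], 1L, stats::sd), 0.2 * abs(mu_a))
    sd_b <- pmax(apply(m[, b, drop = FALSE], 1L, stats::sd), 0.2 * abs(mu_b))
    denom <- sd_a + sd_b
    score <- ifelse(denom > 0, (mu_a - mu_b) / denom, 0)
  } else {
    score <- mu_a - mu_b
  }
  ord <- order(-score, rownames(m), method = "radix")
  structure(data.frame(gene = rownames(m)[ord], score = score[ord],
                       row.names = NULL),
            metric = metric, groups = groups)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Weighted Kolmogorov-Smirnov enrichment score
#'
#' Walks the ranked list accumulating a running sum: set members (hits)
#' increment by \eqn{|score|^{p}} normalized by the total over hits, misses
#' decrement by \eqn{1 / (N - N_{hit})}. The enrichment score (ES) is the
#' signed maximum deviation from zero; with \code{p_weight = 0} this is the
#' classic Kolmogorov-Smirnov statistic, with the default \code{p_weight = 1}
#' hits are weighted by their metric magnitude.
#'
#' @param ranked ranked list from [rank_metric()] (data frame \code{gene},
#'   \code{score}) or a named numeric vector already in descending order.
#' @param members character vector of set member symbols (or a gene-set list
#'   with a \code{members} element).
#' @param p_weight hit-weight exponent, default 1.
#' @return list: \code{es}, \code{running} (length-N profile),
#'   \code{leading_edge} (member symbols at or before the positive peak, or at
#'   or after the negative peak), \code{peak} (peak position).
#' @export
enrichment_score <- function(ranked, members, p_weight = 1) {
  if (is.data.frame(ranked)) {
    genes <- ranked$gene; score <- ranked$score
  } else {
    genes <- names(ranked); score <- as.numeric(ranked)
  }
  if (is.list(members)) members <- members$members
  members <- unique(normalize_symbols(members))
  hit <- genes %in% members
  n <- length(genes); n_hit <- sum(hit)
  if (n_hit == 0L) stop("gene set disjoint from ranked universe")
  if (n_hit == n) stop("gene set covers the whole ranked universe")
  w <- abs(score[hit])^p_weight
  if (sum(w) == 0) w <- rep(1, n_hit)  # all-zero hit scores: uniform weights
  step <- numeric(n)
  step[hit] <- w / sum(w)
  step[!hit] <- -1 / (n - n_hit)
  running <- cumsum(step)
  peak <- which.max(abs(running))
  es <- running[peak]
  le <- if (es >= 0) genes[seq_len(peak)][hit[seq_len(peak)]]
        else genes[peak:n][hit[peak:n]]
  list(es = es, running = running, leading_edge = le, peak = peak)
}

# metric scores for one label assignment; returns ranked data.frame
.ranked_for <- function(m, samples, is_a, metric, genes_sorted = TRUE) {
  a <- samples[is_a]; b <- samples[!is_a]
  mu_a <- rowMeans(m[, a, drop = FALSE])
  mu_b <- rowMeans(m[, b, drop = FALSE])
  if (metric == "signal_to_noise") {
    sd_a <- pmax(apply(m[, a, drop = FALSE], 1L, stats::sd), 0.2 * abs(mu_a))
    sd_b <- pmax(apply(m[, b, drop = FALSE], 1L, stats::sd), 0.2 * abs(mu_b))
    denom <- sd_a + sd_b
    score <- ifelse(denom > 0, (mu_a - mu_b) / denom, 0)
  } else score <- mu_a - mu_b
  ord <- order(-score, rownames(m), method = "radix")
  list(genes = rownames(m)[ord], score = score[ord])
}

.es_only <- function(genes, score, member_flag_by_gene, p_weight) {
  hit <- member_flag_by_gene[genes]
  n <- length(genes); n_hit <- sum(hit)
  w <- abs(score[hit])^p_weight
  if (sum(w) == 0) w <- rep(1, n_hit)
  step <- numeric(n)
  step[hit] <- w / sum(w)
  step[!hit] <- -1 / (n - n_hit)
  running <- cumsum(step)
  running[which.max(abs(running))]
}

#' Two-class GSEA with permutation significance
#'
#' Self-contained two-class gene set enrichment analysis: ranks the whole
#' matrix with [rank_metric()], computes each set's weighted-KS enrichment
#' score, and calibrates it against a permutation null. Phenotype permutation
#' (the default) reshuffles sample labels, preserving gene-gene correlation;
#' when the requested number of permutations exceeds the number of distinct
#' label assignments the null is enumerated exhaustively, and when too few
#' distinct assignments exist the procedure falls back to gene-set
#' permutation (random same-size sets) with a warning.
#'
#' The normalized enrichment score is \code{NES = ES / mean(|null ES| of
#' matching sign)}; the nominal p-value is the fraction of same-sign null ES
#' at least as extreme; the FDR q-value follows the pooled-normalized-null
#' procedure of canonical GSEA (ratio of the null and observed tail fractions
#' of NES, pooled across sets, capped at 1). A set is conventionally called
#' significantly enriched at \code{q < 0.25}.
#'
#' @inheritParams rank_metric
#' @param sets named list of gene sets (symbol vectors, or gene-set lists from
#'   [read_gmt()]).
#' @param n_perm number of permutations (>= 10), default 1000.
#' @param perm_type \code{"phenotype"} (default) or \code{"gene_set"}.
#' @param seed integer seed making the permutation null reproducible.
#' @param p_weight hit-weight exponent, default 1.
#' @return data frame per set: \code{set}, \code{size}, \code{es}, \code{nes},
#'   \code{p}, \code{fdr_q}, \code{le_size}, \code{n_perm}; attributes
#'   \code{"leading_edges"} (named list) and \code{"params"}.
#' @export
gsea <- function(m, labels, sets, n_perm = 1000,
                 perm_type = c("phenotype", "gene_set"), seed = NULL,
                 metric = c("signal_to_noise", "difference_of_means"),
                 p_weight = 1, groups = NULL) {
  perm_type <- match.arg(perm_type)
  metric <- match.arg(metric)
  if (n_perm < 10L) stop("n_perm must be >= 10")
  if (length(sets) == 0L) stop("empty gene-set list")
  if (!is.null(seed)) set.seed(seed)
  sets <- lapply(sets, function(s) {
    if (is.list(s)) s <- s$members
    unique(normalize_symbols(s))
  })
  if (is.null(names(sets)) || !all(nzchar(names(sets))))
    stop("gene sets must be named")

  if (is.null(groups))
    groups <- setdiff(attr(labels, "groups") %||% unique(labels),
                      "EXCLUDED")[1:2]
  ranked <- rank_metric(m, labels, metric = metric, groups = groups)
  universe <- ranked$gene
  flags <- lapply(sets, function(s) {
    f <- stats::setNames(universe %in% s, universe)
    if (!any(f)) stop("gene set disjoint from ranked universe")
    if (all(f)) stop("gene set covers the whole ranked universe")
    f
  })
  obs <- lapply(sets, function(s) enrichment_score(ranked, s, p_weight))
  es_obs <- vapply(obs, `[[`, 0, "es")

  a <- intersect(colnames(m), names(labels)[labels == groups[1L]])
  b <- intersect(colnames(m), names(labels)[labels == groups[2L]])
  samples <- c(a, b)
  msub <- m[, samples, drop = FALSE]

  if (perm_type == "phenotype") {
    n_distinct <- choose(length(samples), length(a))
    if (n_distinct < n_perm) {
      warning("only ", n_distinct, " distinct label assignments for ",
              length(samples), " samples; falling back to gene_set ",
              "permutation")
      perm_type <- "gene_set"
    }
  }

  if (perm_type == "phenotype") {
    n_distinct <- choose(length(samples), length(a))
    if (n_distinct <= n_perm) {
      combs <- utils::combn(length(samples), length(a))
      assign_a <- lapply(seq_len(ncol(combs)), function(j) {
        f <- logical(length(samples)); f[combs[, j]] <- TRUE; f
      })
    } else {
      assign_a <- lapply(seq_len(n_perm), function(j) {
        f <- logical(length(samples))
        f[sample.int(length(samples), length(a))] <- TRUE
        f
      })
    }
    null_es <- vapply(assign_a, function(is_a) {
      rk <- .ranked_for(msub, samples, is_a, metric)
      vapply(names(sets), function(nm)
        .es_only(rk$genes, rk$score, flags[[nm]], p_weight), 0)
    }, numeric(length(sets)))
  } else {
    sizes <- vapply(flags, sum, 0L)
    null_es <- vapply(seq_len(n_perm), function(j) {
      vapply(seq_along(sets), function(k) {
        f <- stats::setNames(logical(length(universe)), universe)
        f[sample.int(length(universe), sizes[k])] <- TRUE
        .es_only(ranked$gene, ranked$score, f, p_weight)
      }, 0)
    }, numeric(length(sets)))
  }
  null_es <- matrix(null_es, nrow = length(sets),
                    dimnames = list(names(sets), NULL))
  n_perm_eff <- ncol(null_es)

  norm_one <- function(es, null) {
    pos <- null[null >= 0]; neg <- null[null < 0]
    if (es >= 0) {
      if (length(pos) == 0L) return(NA_real_)
      es / mean(pos)
    } else {
      if (length(neg) == 0L) return(NA_real_)
      es / abs(mean(neg))
    }
  }
  nes <- vapply(seq_along(sets),
                function(k) norm_one(es_obs[k], null_es[k, ]), 0)
  null_nes <- t(vapply(seq_along(sets), function(k) {
    null <- null_es[k, ]
    pos <- null[null >= 0]; neg <- null[null < 0]
    mp <- if (length(pos)) mean(pos) else NA_real_
    mn <- if (length(neg)) abs(mean(neg)) else NA_real_
    ifelse(null >= 0, null / mp, null / mn)
  }, numeric(n_perm_eff)))

  p <- vapply(seq_along(sets), function(k) {
    null <- null_es[k, ]
    if (es_obs[k] >= 0) {
      same <- null[null >= 0]
      if (length(same) == 0L) return(0)
      mean(same >= es_obs[k])
    } else {
      same <- null[null < 0]
      if (length(same) == 0L) return(0)
      mean(same <= es_obs[k])
    }
  }, 0)

  pool <- null_nes[is.finite(null_nes)]
  fdr_q <- vapply(seq_along(sets), function(k) {
    s <- nes[k]
    if (!is.finite(s)) return(NA_real_)
    if (s >= 0) {
      n_pos <- sum(pool >= 0)
      num <- if (n_pos) sum(pool >= s) / n_pos else 0
      den <- sum(nes[is.finite(nes)] >= s) / max(1L, sum(nes >= 0,
                                                         na.rm = TRUE))
    } else {
      n_neg <- sum(pool < 0)
      num <- if (n_neg) sum(pool <= s) / n_neg else 0
      den <- sum(nes[is.finite(nes)] <= s) / max(1L, sum(nes < 0,
                                                          na.rm = TRUE))
    }
    min(1, num / den)
  }, 0)

  res <- data.frame(set = names(sets),
                    size = vapply(flags, sum, 0L),
                    es = es_obs, nes = nes, p = p, fdr_q = fdr_q,
                    le_size = vapply(obs, function(o)
                      length(o$leading_edge), 0L),
                    n_perm = n_perm_eff, row.names = NULL)
  structure(res,
            leading_edges = lapply(obs, `[[`, "leading_edge"),
            params = list(metric = metric, p_weight = p_weight,
                          perm_type = perm_type, seed = seed,
                          groups = groups))
}
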