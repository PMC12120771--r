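#' Simulate a two-lineage expression cohort with known ground truth
#'
#' Generates a linear-scale gene-by-sample matrix emulating a mixed
#' adenocarcinoma/NEPC cohort. On the log2 scale every gene gets a baseline
#' \code{Normal(mu_b, 1)}; planted AD-TFs add \code{delta} in ADENO samples
#' only, planted NE-TFs add \code{delta} in NEPC samples only, and planted
#' SHARED-TFs add \code{delta} in all samples; i.i.d. \code{Normal(0, sigma)}
#' noise is added, and each sample is multiplied by an independent positive
#' scale factor \code{exp(Normal(0, sigma_s))} on the linear scale (the
#' nuisance the internal Z-score is designed to cancel). The marker-panel
#' genes (AR, KLK3 up in ADENO; CHGA, NCAM1 up in NEPC) are included as
#' members of the planted lineage sets so panel-based sample selection runs
#' end-to-end.
#'
#' Per-sample scale factors are drawn after all other quantities, so two runs
#' with the same seed and different \code{sigma_s} share every other draw.
#'
#' @param n_genes total genes, default 300.
#' @param n_ad,n_ne samples per lineage (>= 4), defaults 30 and 20.
#' @param n_planted named integer vector, sizes of the planted \code{AD},
#'   \code{NE} and \code{SHARED} sets (defaults 20/20/20).
#' @param delta planted effect in log2 units, default 2.
#' @param sigma log2-scale noise sd, default 0.5.
#' @param sigma_s sd of the log per-sample scale factor, default 0.3.
#' @param mu_b mean log2 baseline, default 8.
#' @param seed integer seed.
#' @return list: \code{matrix} (linear-scale expression), \code{labels}
#'   (true sample -> ADENO/NEPC), \code{truth} (planted symbol sets and the
#'   generation parameters).
#' @export
simulate_cohort <- function(n_genes = 300, n_ad = 30, n_ne = 20,
                            n_planted = c(AD = 20, NE = 20, SHARED = 20),
                            delta = 2, sigma = 0.5, sigma_s = 0.3,
                            mu_b = 8, seed = NULL) {
  if (n_ad < 4L || n_ne < 4L) stop("need n_ad >= 4 and n_ne >= 4")
  n_planted <- n_planted[c("AD", "NE", "SHARED")]
  if (anyNA(n_planted)) stop("n_planted needs AD, NE and SHARED entries")
  if (any(n_planted < 2L)) stop("planted sets need >= 2 genes each")
  if (n_genes < sum(n_planted) + 20L)
    stop("n_genes must be >= planted total + 20")
  if (sigma < 0 || sigma_s < 0) stop("sigma and sigma_s must be >= 0")
  if (!is.null(seed)) set.seed(seed)

  panels <- default_panels()
  ad_set <- c(panels$ar_axis,
              sprintf("ADTF%03d", seq_len(n_planted[["AD"]] - 2L)))
  ne_set <- c(panels$ne_axis,
              sprintf("NETF%03d", seq_len(n_planted[["NE"]] - 2L)))
  sh_set <- sprintf("SHTF%03d", seq_len(n_planted[["SHARED"]]))
  if (length(intersect(ad_set, ne_set)) || length(intersect(ad_set, sh_set)) ||
      length(intersect(ne_set, sh_set)))
    stop("planted sets overlap")
  genes <- c(ad_set, ne_set, sh_set,
             sprintf("BGTF%04d", seq_len(n_genes - sum(n_planted))))
  samples <- c(sprintf("AD%02d", seq_len(n_ad)),
               sprintf("NE%02d", seq_len(n_ne)))
  grp <- c(rep("ADENO", n_ad), rep("NEPC", n_ne))

  b <- stats::rnorm(n_genes, mu_b, 1)
  names(b) <- genes
  # marker genes are lineage-exclusive (e.g. CHGA is off in adenocarcinoma):
  # centred baseline so the planted effect puts them high in their own
  # lineage and clearly low in the other — without this, panel-based sample
  # selection sees spurious double positives
  b[c(panels$ar_axis, panels$ne_axis)] <- mu_b - delta / 2
  logm <- matrix(b, n_genes, n_ad + n_ne) +
    matrix(stats::rnorm(n_genes * (n_ad + n_ne), 0, sigma), n_genes)
  dimnames(logm) <- list(genes, samples)
  logm[ad_set, grp == "ADENO"] <- logm[ad_set, grp == "ADENO"] + delta
  logm[ne_set, grp == "NEPC"] <- logm[ne_set, grp == "NEPC"] + delta
  logm[sh_set, ] <- logm[sh_set, ] + delta
  scale_f <- exp(stats::rnorm(n_ad + n_ne, 0, sigma_s))
  m <- 2^logm * rep(scale_f, each = n_genes)

  list(matrix = m,
       labels = structure(stats::setNames(grp, samples),
                          groups = c("ADENO", "NEPC")),
       truth = list(AD = ad_set, NE = ne_set, SHARED = sh_set,
                    params = list(n_genes = n_genes, n_ad = n_ad,
                                  n_ne = n_ne, delta = delta, sigma = sigma,
                                  sigma_s = sigma_s, mu_b = mu_b,
                                  seed = seed),
                    scale_factors = stats::setNames(scale_f, samples)))
}

#' Simulate a four-timepoint transdifferentiation series with planted
#' dormant TFs
#'
#' Emulates the structure of a baseline -> castration (8w, 12w) -> relapse
#' xenograft series: planted AD-TFs are high only at the first timepoint,
#' planted NE-TFs only at the last, and planted dormant TFs only at the
#' dormant timepoint (third of four). Planted genes follow deterministic
#' centred profiles — log2 level \code{mu_b + delta_planted} at their "on"
#' timepoint and \code{mu_b + delta_planted - delta} elsewhere — so their
#' internal Z sits near \code{+delta_planted} when on, with an on/off margin
#' of \code{delta}; background genes get a \code{Normal(mu_b, 1)} baseline
#' constant over time. Per-timepoint profiles carry small
#' \code{Normal(0, sigma)} noise (the series emulates averaged reference
#' profiles per timepoint, not cohort-level biological variation) and
#' per-sample scale factors, drawn last as in [simulate_cohort()].
#'
#' @param n_genes total genes, default 300.
#' @param n_planted named sizes of the planted \code{AD}, \code{NE} and
#'   \code{DORMANT} sets (defaults 20/20/20).
#' @param delta on/off margin in log2 units (> 0), default 2.
#' @param delta_planted height of the "on" level above the cohort mean in
#'   log2 units (> 0), default 1.
#' @param sigma log2 noise sd, default 0.05.
#' @param sigma_s sd of log per-sample scale factors, default 0.3.
#' @param n_rep samples per timepoint, default 1.
#' @param timepoints timepoint ids, default \code{T0..T3}.
#' @param mu_b mean log2 baseline, default 8.
#' @param seed integer seed.
#' @return list: \code{series} (named list of linear-scale matrices, in
#'   time order) and \code{truth} (planted sets, on-timepoints, parameters).
#' @export
simulate_time_series <- function(n_genes = 300,
                                 n_planted = c(AD = 20, NE = 20, DORMANT = 20),
                                 delta = 2, delta_planted = 1,
                                 sigma = 0.05, sigma_s = 0.3, n_rep = 1,
                                 timepoints = c("T0", "T1", "T2", "T3"),
                                 mu_b = 8, seed = NULL) {
  if (delta <= 0 || delta_planted <= 0)
    stop("delta and delta_planted (planted margins) must be > 0")
  n_planted <- n_planted[c("AD", "NE", "DORMANT")]
  if (anyNA(n_planted)) stop("n_planted needs AD, NE and DORMANT entries")
  if (n_genes < sum(n_planted) + 20L)
    stop("n_genes must be >= planted total + 20")
  if (length(timepoints) < 3L) stop("need >= 3 timepoints")
  if (n_rep < 1L) stop("need >= 1 sample per timepoint")
  if (!is.null(seed)) set.seed(seed)

  ad_set <- sprintf("ADTF%03d", seq_len(n_planted[["AD"]]))
  ne_set <- sprintf("NETF%03d", seq_len(n_planted[["NE"]]))
  do_set <- sprintf("DOTF%03d", seq_len(n_planted[["DORMANT"]]))
  genes <- c(ad_set, ne_set, do_set,
             sprintf("BGTF%04d", seq_len(n_genes - sum(n_planted))))
  n_tp <- length(timepoints)
  # dormant timepoint: second-to-last (castration 12w in a 4-point series),
  # the middle point in a 3-point series
  on_tp <- c(AD = timepoints[1L], NE = timepoints[n_tp],
             DORMANT = timepoints[if (n_tp >= 4L) n_tp - 1L else 2L])

  b <- stats::rnorm(n_genes, mu_b, 1)
  names(b) <- genes
  off <- mu_b + delta_planted - delta
  b[c(ad_set, ne_set, do_set)] <- off

  profiles <- vapply(timepoints, function(tp) {
    lv <- b
    if (tp == on_tp[["AD"]]) lv[ad_set] <- mu_b + delta_planted
    if (tp == on_tp[["NE"]]) lv[ne_set] <- mu_b + delta_planted
    if (tp == on_tp[["DORMANT"]]) lv[do_set] <- mu_b + delta_planted
    lv
  }, numeric(n_genes))

  noise <- array(stats::rnorm(n_genes * n_rep * n_tp, 0, sigma),
                 dim = c(n_genes, n_rep, n_tp))
  scale_f <- matrix(exp(stats::rnorm(n_rep * n_tp, 0, sigma_s)), n_rep, n_tp)
  series <- lapply(seq_len(n_tp), function(t) {
    logm <- matrix(profiles[, t], n_genes, n_rep) + noise[, , t]
    m <- 2^logm * rep(scale_f[, t], each = n_genes)
    dimnames(m) <- list(genes,
                        if (n_rep == 1L) timepoints[t]
                        else paste0(timepoints[t], "r", seq_len(n_rep)))
    m
  })
  names(series) <- timepoints

  list(series = series,
       truth = list(AD = ad_set, NE = ne_set, DORMANT = do_set,
                    on_timepoints = on_tp,
                    params = list(n_genes = n_genes, delta = delta,
                                  delta_planted = delta_planted,
                                  sigma = sigma, sigma_s = sigma_s,
                                  n_rep = n_rep, timepoints = timepoints,
                                  mu_b = mu_b, seed = seed)))
}

#' Precision and recall of a recovered set against planted truth
#'
#' @param called character vector of symbols called by the pipeline.
#' @param truth character vector of planted symbols.
#' @return named numeric vector \code{precision}, \code{recall}.
#' @export
recovery_stats <- function(called, truth) {
  tp <- length(intersect(called, truth))
  c(precision = if (length(called)) tp / length(called) else NA_real_,
    recall = if (length(truth)) tp / length(truth) else NA_real_)
}
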