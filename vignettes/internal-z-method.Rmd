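---
title: "The internal Z-score method for lineage TF profiling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The internal Z-score method for lineage TF profiling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tflens)
```

## The model

`tflens` profiles transcription-factor (TF) expression in a two-lineage
cohort — developed for prostatic adenocarcinoma (ADENO) versus
treatment-induced neuroendocrine prostate cancer (NEPC), but generic.
Its core statistic is the *internal Z-score*: within each sample, every
catalog TF's expression is standardized against the mean and sample
standard deviation (n − 1 denominator) of all catalog TFs *in that same
sample*,

$$ z_i = \frac{x_i - \bar{x}}{s}. $$

The assumptions this rests on are deliberately weak: expression values are
non-negative, pre-normalized within each sample (counts-per-library, FPKM,
TPM or array intensity), and comparable *within* a sample up to a monotone
scale. Nothing is assumed about comparability *across* samples — any
positive per-sample scale factor cancels exactly, which is the point: the
statistic measures where a TF sits in its own sample's expression
hierarchy, so samples from different platforms or library sizes can be
scored independently and only their scores combined.

Per TF, each lineage's score is a trimmed mean of the internal Z over that
lineage's samples, and the two scores $(Z_{ad}, Z_{NE})$ are thresholded
into four categories:

* **SHARED** — $Z_{ad} > \theta$ and $Z_{NE} > \theta$;
* **AD** — $Z_{ad} - Z_{NE} > \theta$ and $Z_{NE} < \theta$;
* **NE** — $Z_{ad} < \theta$ and $Z_{NE} - Z_{ad} > \theta$;
* **UNCLASSIFIED** — everything else.

For any $\theta > 0$ the three named predicates are pairwise exclusive
(SHARED needs $Z_{NE} > \theta$ while AD needs $Z_{NE} < \theta$; AD needs
$Z_{ad} > Z_{NE} + \theta$ while NE needs the reverse; SHARED needs
$Z_{ad} > \theta$ while NE needs $Z_{ad} < \theta$), so with the explicit
UNCLASSIFIED remainder the partition is total — a property the test suite
asserts over random score pairs. Classification lists from independent
cohorts are consolidated by per-category intersection, which is
order-invariant and monotone (adding a cohort can only shrink a set).

## Tunable parameters

* `theta` (default **0.2**, dimensionless internal-Z units): the
  classification threshold, on the same scale in every cohort because the
  scores are standardized. The default corresponds to roughly 20 normalized
  reads in a typical RNA-seq library — the usual low-abundance filtering
  region — so "high" means reliably expressed, not merely detectable. It is
  a descriptive cut, not a significance level, and should be re-examined per
  platform.
* `trim` (default **0.2** total): the trimmed-mean fraction,
  spreadsheet-`TRIMMEAN` semantics — $k = \lfloor 0.1\,n \rfloor$ samples
  dropped from each end after sorting, $S = n - 2k$ retained. At group sizes
  below 10 no trimming occurs ($k = 0$); a single-sample group returns the
  value itself, which is what makes single-graft timepoints scoreable.
* `log2_transform` (default **TRUE**): apply $\log_2(x+1)$ before
  standardization. On the raw linear scale the within-sample standard
  deviation is dominated by a handful of extreme genes and every z is
  compressed toward 0; the log scale spreads the hierarchy. The flag is
  recorded in output provenance. Scale-factor invariance is *exact* without
  the transform and approximate (through $\log_2(x+1) \approx \log_2 x + c$
  for the expression ranges involved) with it.
* `theta_sel` (default **0**): sample-selection threshold on marker-panel
  scores. Selection demands AR-axis ≥ threshold and NE-axis < threshold (or
  the mirror image); double-positive and double-negative samples are
  excluded rather than guessed. The default panels — AR axis {AR, KLK3},
  NE axis {CHGA, NCAM1} — are the classic immuno-markers of the two
  lineages (PSA and CD56 by their gene symbols) and are fully overridable.
* `delta` and `theta_floor` (defaults **0.2** each): the dormancy screen
  flags a TF when its score at the dormant timepoint exceeds `theta_floor`
  *and* exceeds the score at every terminal timepoint by more than `delta`.
  The defaults reuse the classification threshold so "dormant-high" means
  the same thing as "lineage-high".

## Numerical and design choices

* Trim-count rounding follows the spreadsheet convention (total excluded
  count rounded down to the nearest even integer) because that is the
  reference implementation the scores are defined against; the suite checks
  exact agreement with an independent sort-and-slice oracle for
  $n \in 1..50$.
* Inequalities at exactly $\theta$ are strict; boundary ties fall to
  UNCLASSIFIED. Deterministic and conservative.
* Zero-variance samples (constant expression across the catalog) are a hard
  error by default — silently dropping a sample changes cohort composition;
  `drop_degenerate = TRUE` opts into dropping with a warning.
* Internal Z is computed for *all* samples regardless of labels; excluded
  samples simply do not contribute to group trimmed means. Standardization
  is strictly within-sample, so a sample's score cannot depend on who else
  is in the cohort.
* Gene symbols are upper-cased and whitespace-stripped, with no
  alias-database resolution (deterministic and offline); duplicate gene
  rows are collapsed by their arithmetic mean, the order-independent choice
  for multi-probe arrays.
* Ranking within a category uses the defining score (AD by $Z_{ad}$, NE by
  $Z_{NE}$, SHARED by $\min(Z_{ad}, Z_{NE})$), averaging per-cohort scores
  when several cohorts are supplied; ties break alphabetically so rankings
  are platform-stable.
* The longitudinal phase labels attach to timepoints (ADENO_LIKE, DORMANT,
  NE_LIKE from the mean AD-set and NE-set trajectories); the
  de-/re-differentiation phases of the three-phase view are the transitions
  between consecutive labels and are reported alongside. Both programs
  simultaneously above threshold is rejected as an error rather than
  silently labelled. The second castration timepoint of a four-point series
  participates in the dormancy screen only if listed explicitly — the
  default compares the 12-week dormant point against baseline and relapse
  only.

## The two-class GSEA validator

Derived sets are validated with a self-contained two-class GSEA: genes are
ranked by signal-to-noise $(\mu_A - \mu_B)/(\sigma_A + \sigma_B)$ with each
$\sigma$ floored at $0.2\,|\mu|$ of its group (the classic desktop-tool
variance floor; `difference_of_means` is available for single-sample
groups), the enrichment score is the signed maximum of the weighted-KS
running sum (hit weight $|r|^p$, default $p = 1$), and significance comes
from phenotype permutation: NES is the ES normalized by the mean same-sign
null ES, the nominal p is the same-sign null tail fraction, and FDR q
follows the pooled-normalized-null procedure, with the conventional
q < 0.25 significance rule. When the requested permutation count exceeds
the number of distinct label assignments the null is enumerated
exhaustively (the suite checks exact agreement with an enumeration oracle
on a 4 + 4 design); when too few assignments exist the procedure falls back
to gene-set permutation with a warning. All randomness is seed-driven and
results are bit-reproducible.

## What the synthetic generator emulates — and what it does not

`simulate_cohort()` draws per-gene log2 baselines $\mathcal{N}(\mu_b, 1)$,
adds an effect $\Delta$ (default 2) to planted AD-TFs in ADENO samples
only, to planted NE-TFs in NEPC samples only, and to planted SHARED-TFs
everywhere, then adds $\mathcal{N}(0, \sigma)$ noise (default 0.5) and
multiplies each sample by $e^{\mathcal{N}(0, \sigma_s)}$ (default 0.3) on
the linear scale. Defaults: 300 genes, 30 + 20 samples, 20 planted TFs per
category — planted fractions of the same order as real TF catalogs. The
four marker genes are planted with centred, lineage-exclusive profiles
(high in their own lineage, low in the other), mirroring the mutual
exclusivity that makes AR/NE immuno-phenotyping usable for sample selection
in the first place. Scale factors are drawn after all other quantities, so
runs with the same seed and different $\sigma_s$ share every other draw —
that is what lets the suite test the scale-invariance claim end-to-end.

`simulate_time_series()` emulates a four-timepoint transdifferentiation
series. Planted genes follow deterministic centred profiles (on-level
$\mu_b + \delta_{planted}$ at their single "on" timepoint, off-level
$\delta$ lower elsewhere; AD on at baseline, NE on at relapse, dormant on
at the 12-week point), with small per-timepoint noise (default sd 0.05 on
the log2 scale). The series is modelled as *averaged reference profiles* —
one representative profile per timepoint of a single xenograft line — not
as a cohort; between-patient biological variation is intentionally absent,
which is why exact recovery of the planted dormant set is an appropriate
expectation there and not in the cohort setting.

Two honest gaps between the generator and real data follow from this
design. First, the cohort generator's random gene baselines mean a planted
"lineage-specific" gene can happen to sit above the sample average in the
opposite lineage too — real lineage TFs are usually repressed in the other
lineage. Second, threshold classification carries no error control: with
noise sd 0.5 and 20–30 samples per group, a few percent of null genes
exceed a between-group score difference of 0.2 by chance. Both effects are
visible in the planted-recovery numbers the acceptance script reports, and
both temper what passing tests show about real cohorts: the pipeline's
*mechanics* (normalization, trimming, classification algebra, scale
invariance, screen predicates) are verified exactly, while its *operating
characteristics* on any particular dataset depend on that dataset's effect
sizes and noise, and should be checked against known marker genes as the
threshold guidance above suggests.

## Problem sizes

The test suite and acceptance script run on 300-gene, 50-sample cohorts,
four-timepoint series, and GSEA with 1000 permutations on 200–300-gene
universes — sizes chosen so the whole battery, including 1000-vector
trimmed-mean oracles and exhaustive permutation enumeration, completes in a
few minutes on a single core while still exercising every code path a
full-size cohort would.

## Known limitations

* The classification is descriptive; no multiplicity-corrected inference is
  attached to set membership. Use the GSEA validator (or orthogonal data)
  to assess a derived set.
* Symbol handling is string-normalization only; catalogs and matrices using
  different alias conventions must be reconciled upstream.
* Cross-cohort consolidation intersects symbol sets; it does not model
  cohort-specific power, so a TF missed in one underpowered cohort is
  dropped even if strongly supported in others.
* CLS phenotype files carry no sample identifiers; the caller must supply
  the matrix column order, and mismatches are only detectable by count.
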