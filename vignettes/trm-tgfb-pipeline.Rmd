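---
title: "Methods: differential expression, signature overlap and GSEA for TGF-β imprinting"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: differential expression, signature overlap and GSEA for TGF-β imprinting}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trmsig)
```

`trmsig` analyses a genes × samples FPKM matrix from a four-condition
CD8⁺ T-cell stimulation experiment (Untreated, TGFb, IL2, IL2_TGFb × 3
replicates) and asks whether the TGF-β response recapitulates the
tissue-resident memory (TRM) transcriptional program: first by direct
differential expression, then by directional concordance with a 35-gene
TRM core signature, and finally by gene set enrichment against
tissue-specific TRM gene sets. This vignette is the package's account of
each model, its assumptions, and the choices made where the design was
genuinely open.

## Preprocessing

The pipeline consumes FPKM, never read counts, and applies exactly the
order filter → log₂ → standardise:

* **Filter** (`filter_low_expression`): keep genes with *mean* FPKM
  across all samples > 0.3. The threshold is the conventional
  expressed-gene cutoff in FPKM units. A gene "expressed in most samples
  but silent in one" should survive a low-expression filter, so the mean
  rule is the default; the stricter every-sample rule is available via
  `rule = "all_samples"`.
* **Log transform** (`log2_transform`): `log2(FPKM + 1)`. The
  pseudocount of 1 keeps zeros at zero and is the most common
  convention; it is validated to be positive whenever zeros are present.
* **Standardise** (`standardise`): per-gene z-scores across samples.
  Zero-variance genes have no defined z-score; they are mapped to
  all-zero rows, flagged in the `zero_variance` attribute, and dropped
  from PCA and clustering input.

## Differential expression: a moderated t for n = 3

With three replicates per condition, per-gene variance estimates are
unstable; the package uses a moderated two-sample *t* on log₂(FPKM+1)
with shrinkage toward a global prior:

$$\tilde s_g^2 = \frac{d_0 s_0^2 + d\, s_g^2}{d_0 + d}, \qquad
  d_0 = 4,\; s_0^2 = \operatorname{median}_g s_g^2,$$

with $s_g^2$ the pooled two-group variance on $d = n_A + n_B - 2$ df,
and $t_g$ referred to Student's *t* with $d_0 + d$ df. This is a fully
specified, calibrated stand-in for count-level dispersion modelling:
the original study's count-based test cannot be applied to FPKM-only
input, and the downstream stages consume only the DE list, log₂FC and
FDR, not the test internals. The suite verifies type-I error of the raw
P-values on a null simulation (observed rate must fall in [0.03, 0.07]
at nominal 0.05) and >0.9 power for planted |log₂FC| = 2 effects.

Direction calls are `up`/`down` only when the BH-adjusted P is below α
*and* log₂FC is strictly signed; a significant gene with log₂FC exactly 0
stays `ns`. BH adjustment is delegated to `stats::p.adjust(method =
"BH")` behind `bh_adjust()`, which validates the inputs; tests compare it
against an exhaustive min-over-tails computation.

## Directional signature overlap and its bootstrap null

The overlap statistic counts signature genes that are significantly DE
*in the annotated direction* (`directional_overlap`); each signature
gene is labelled concordant / discordant / not-DE / not-measured, so
the familiar pie-style percentages fall out of the per-gene table.

Significance (`bootstrap_enrichment`) uses a label-resampling null: draw
k and m gene labels with replacement from the universe, deduplicate each
draw, intersect, repeat B = 10,000 times, and report the add-one tail
$(1 + \#\{o_b \ge o_{obs}\})/(B+1)$. Numerical choices:

* **Deduplication.** A multiset intersection of gene lists is
  ill-defined, so each with-replacement draw is reduced to its unique
  labels before intersecting. For k, m ≪ N duplicates are rare and the
  null matches the hypergeometric upper tail within Monte-Carlo error
  (verified on a parameter grid in the tests).
* **Add-one estimator.** Keeps P strictly positive at finite B; at
  B = 10,000 the floor is ≈ 1×10⁻⁴, consistent with reporting
  "P < 0.001" for overwhelming overlaps.
* **Direction handling.** The null draws are direction-blind while the
  observed statistic is direction-constrained, which is conservative
  (roughly half of random same-gene collisions would also match
  direction). This mirrors the published procedure; a direction-aware
  null (draws inherit direction labels resampled from the signature and
  the DE calls) is available via `mode = "direction_aware"`.
* **Universe.** Default is the expressed-gene universe after filtering
  (the ~10,941-gene analogue); `run_pipeline(universe = "annotated")`
  switches to the full input matrix (the annotated-genome analogue used
  by GO tooling). The published procedure does not state which universe
  the bootstrap drew from; the default is the more conservative,
  smaller one.
* **Discreteness.** The overlap count is an integer, and the ≥ tail
  includes ties, so at small k·m/N the estimator is visibly
  super-uniform; the calibration test therefore uses wide draws where
  ties are rare.

## GSEA

`run_gsea` is an implementation, not a wrapper: Signal2Noise ranking,
weighted running-sum ES, permutation null, NES, nominal P, pooled-NES
FDR q, and the standard significance rule (nominal P < 0.05 and
q < 0.25; minimum post-restriction set size 15).

* **Metric.** $r_g = (\mu_A - \mu_B)/(\sigma_A + \sigma_B)$ with each σ
  floored at max(0.2·|μ|, 0.2). The floor prevents near-constant genes
  from taking extreme ranks. The metric is computed on log₂ FPKM by
  default: per-gene standardisation forces every row to unit overall
  variance, which distorts the within-group σ's the metric depends on,
  so the standardised matrix — while accepted — is not the default
  metric input.
* **ES.** Weight exponent p = 1, the standard weighted scheme.
  $P_{hit}$ accumulates $|r_g|^p/N_R$ at member positions, $P_{miss}$
  accumulates $1/(N - N_h)$ elsewhere; ES is the signed extreme of
  $P_{hit} - P_{miss}$, with the positive extreme taken on an exact tie.
  Ranking ties are broken by lexicographic gene id, making runs
  reproducible across platforms. A closed-form $O(N_h)$ evaluation from
  member positions is used inside permutation loops; tests pin both
  paths to an exhaustive running-sum oracle (≤ 1e−12) and to an
  independent external implementation.
* **Null.** A 3v3 phenotype permutation admits only
  $\binom{6}{3}/2 = 10$ distinct splits and a 6v6 contrast 462 — far
  fewer than the 100,000 label permutations a large design would
  support. Phenotype mode therefore enumerates distinct splits
  exhaustively when possible and refuses to run with fewer than 10; the
  default null is `gene_set` mode (random member sets of matched size
  from the ranked universe), which supports arbitrary permutation
  counts. This is a documented divergence from the published
  label-permutation procedure, forced by the design size.
* **P, NES, q.** Nominal P is the side-matched add-one tail; NES divides
  ES by the mean |null ES| of the same sign; q follows the pooled-NES
  procedure (every null ES normalised by its set's same-sign null mean,
  pooled; q = null tail fraction / observed tail fraction, capped at 1,
  monotonised so a more extreme NES never has a larger q). A set whose
  same-sign null is empty is flagged rather than silently dropped.

## The synthetic generator

`simulate_expression` emulates the 12-sample study design in log₂
space: per-gene baseline ~ N(3, 1.5²) log₂-FPKM units; a TGF-β effect
δ_g in a fraction 0.08 of genes, up-regulated with probability 0.6
(the study observed mostly up-regulated responses), with
|δ| ~ 0.5 + Exponential(mean 1.5) log₂ units; an independent IL-2
effect with the same magnitude model and unbiased sign (IL-2 is treated
as a nuisance pro-survival factor, not an interaction); replicate noise
N(0, 0.35²); and FPKM = max(2^signal − 1, 0). Choices worth noting:

* **Log-normal noise, not negative binomial:** the pipeline consumes
  FPKM and never counts, so noise is modelled on the scale every
  downstream stage uses.
* **Effect floor 0.5:** keeps "responsive" separated from replicate
  noise so that recovery tests are stable at n = 3.
* **Published effect-size distributions are unavailable;** the
  magnitudes here are plausible defaults, not estimates.

The signature generator plants `round(0.6 × 35) = 21` concordant
members (responsive genes whose δ sign matches their annotation, split
between the 30 up and 5 down slots in proportion) and fills the rest
with non-responsive genes. The gene-set generator plants five sets from
up-regulated and five from down-regulated responsive genes (size 50)
plus two negative-control sets from non-responsive genes.

What the generator does *not* emulate: gene–gene correlation, GC or
length biases, count-level sampling noise, isoform structure, or any in
vivo tissue biology. Passing tests therefore demonstrate that the
statistical machinery is correct and calibrated under the stated
generative model — not that the biological conclusions of any particular
dataset are right.

## Exploratory stage and a deliberate deviation

PCA is computed on the sample-by-sample covariance of the standardised
matrix; variance fractions are pinned to a direct eigendecomposition in
the tests. Clustering defaults to Ward linkage on a precomputed
Chebyshev ("maximum") dissimilarity between sample profiles — the
combination named for the study's dendrogram. Ward on a non-Euclidean
dissimilarity is formally heuristic; merge heights are asserted
monotone only for Euclidean input.

One design decision was reversed after implementation. The planted
treatment separation *cannot* be read from the full standardised matrix
with the Chebyshev metric: the metric is a max statistic, per-gene
standardisation makes every null gene's z-profile noise of unit scale
regardless of the noise level, and the extreme of ~10⁴ null z-differences
(≈ 4–6) always exceeds the bounded contribution of a clean 6v6 treatment
split (≤ ≈ 2.2). The package therefore evaluates the two-group
separation on the samples' profiles over the top 30 common DE genes
(ranked by mean |log₂FC| across the three TGF-β comparisons, the
construction of the study's supplementary heatmap), where the same
Ward/maximum method separates treated from untreated samples perfectly.
Both the full-matrix dendrogram and the top-DE purity are reported.

## Problem sizes and runtime

The shipped tests run the full default design (11,000 genes, 12
samples) for the headline GSEA and recovery checks, and smaller designs
(400–2,500 genes) for calibration loops: 1,000 bootstrap-calibration
trials at B = 199, 100 null gene sets at 250 permutations, and 10,000
bootstraps for the published overlap configuration. These sizes were
chosen so the whole suite completes in well under a minute while keeping
every Monte-Carlo band at 3 standard errors.

## Known limitations

* The moderated t is a stand-in, not a reimplementation, of
  count-level DE; absolute DE counts on real data will differ from the
  original tooling's.
* Bootstrap and GSEA P-values are Monte-Carlo estimates with add-one
  floors of 1/(B+1) and 1/(n_perm+1).
* Phenotype-mode GSEA on small designs is under-powered by construction
  (few distinct splits) and is retained for fidelity, not inference.
* The generator's independence assumptions (genes independent, IL-2 and
  TGF-β effects drawn independently) make calibration results
  optimistic relative to correlated real transcriptomes.
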