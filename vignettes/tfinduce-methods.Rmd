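---
title: "Models and methods behind tfinduce"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind tfinduce}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tfinduce)
```

This vignette documents the statistical models, the synthetic-data
generator, the numerical conventions, and the design choices the package
makes where more than one reasonable option existed. It states no result
that the test suite or `scripts/acceptance.R` does not itself compute.

## The experimental design being modelled

Each ESC line carries one Tet-Off transgenic TF. Culturing without
doxycycline induces the TF ("induced", Dox−); parallel wells kept in Dox
are the control. Expression is measured on log-scale intensity arrays, so
all analysis operates on log10 intensities, and the per-gene response to a
TF is a *logratio*: the difference between the mean log-intensity of
induced and control replicates. Fold change is `10^|logratio|`.

Two normalization steps precede testing:

* **Control-channel normalization** (`normalize_to_control()`): for a
  two-channel array *i* with induced channel *x* and control channel *c*,
  `x' = x - c + Median(c)`, the median over the array's features.
  Subtracting the paired control removes feature-level effects common to
  both channels; adding the array median restores the intensity scale.
  When `c` is constant the operation is the identity.
* **Batch normalization** (`batch_normalize()`): when combining arrays
  hybridized in different batches, each gene's values are shifted
  additively (log scale) within each batch so the gene's batch median
  equals its global median, defined as the median of per-batch medians.
  After the shift, per-gene medians agree exactly across batches; this is
  asserted, to machine precision, in the tests. Additive shifts (not
  scaling) are used because the data are already on the log scale.

## Significance testing with few replicates

The screen's standard design has three induced and three control wells.
With group variances estimated from three values, a classical per-gene
test is fragile: its t-statistic has ~4 degrees of freedom, and the
variance estimate itself is noisy enough that genuine 2-fold responses are
frequently missed once the Benjamini–Hochberg threshold adapts to the
sparse discoveries. We quantified this during development: with
`noise_sd = 0.05` and exact 2-fold planted effects, a Welch test with BH
recovers under 10% of planted genes, an operating point at which the
screen's headline counts would be meaningless.

The default test is therefore the **limma moderated t**: per-gene
variances are shrunk toward a common empirical-Bayes prior, which at
homogeneous noise approaches a known-variance z-test and restores power
while keeping false discoveries controlled (the null-calibration check in
the acceptance suite runs 20 complete-null simulations and measures the
realized false-discovery proportion). The classical test remains available
as `compute_induction_profile(..., method = "welch")`, with a variance
floor of 1e-4 guarding against literal zero-variance degeneracy. The same
moderated machinery backs the per-cell atlas test (a one-sample contrast
of a tissue's median-centred replicates against zero, df = replicates − 1
before moderation).

Responder calling uses inclusive thresholds: FDR ≤ 0.05 **and** fold
≥ 1.5. A gene at exactly fold 1.5 with FDR exactly 0.05 is a responder.

**PCA of profiles** (`pca_profiles()`) takes the TF × gene logratio matrix
restricted to genes significant in at least one profile (otherwise the
dominant principal directions describe noise), centres it, and fixes the
sign of each component so its largest-magnitude gene loading is positive —
`prcomp()` output is otherwise sign-ambiguous and not reproducible across
platforms.

## Tissue-atlas correlation

The atlas is reduced to `A_gt = mean(log10 tissue t) − median over tissues
of the tissue means`, so each gene's values are centred on its cross-tissue
median (per-gene median of `A` is 0 by construction). Atlas significance
uses FDR ≤ 0.05 and fold ≥ 2 — stricter than the induction side because
expression differences between adult tissues are much larger than
induction responses.

Correlations are Pearson, over one **shared gene universe** used for every
cell of the TF × tissue matrix: genes significant for at least one TF in
the induction data *and* for at least one tissue in the atlas. The
per-cell alternative (intersecting each pair's own significant sets) was
rejected because it gives every cell a different universe and therefore
non-comparable z-values; a single universe matches the convention of
reporting one shared gene count for the whole matrix.

Significance is the Fisher transform `z = atanh(r)·sqrt(n − 3)`, the
standard normal deviate for a correlation under independence. `|z|` is
capped at 50 so that degenerate `r → ±1` cells stay finite; with `n < 4`
the transform is undefined and z is set to 0 with a warning. Cells with
`|z| < 2` are treated as non-significant (white in the heatmap). Note the
null quantile is nominal: label permutation leaves ~95.4% of cells below
`|z| = 2` in expectation, so the permutation check in the acceptance suite
sits close to its threshold by construction.

Row and column orders come from average-linkage hierarchical clustering on
the correlation distance (1 − Pearson correlation between rows, resp.
columns, of the r matrix). No manual re-ordering is attempted.

## PAGE on expression quartiles

Gene-set enrichment uses the parametric PAGE statistic
`z = (Sm − mu)·sqrt(m)/delta`, applied separately to the top 25% of genes
by logratio (direction "up") and the bottom 25% (direction "down");
quartile size is `ceiling(0.25·N)` and boundary ties are broken by gene id
for determinism.

The background (mu, delta) defaults to the **analyzed fraction itself**.
With scores truncated to a quartile, a whole-distribution background is
selection-biased: any random set's in-quartile members have extreme scores
by construction, so E[z] ≫ 0 and the null is wrong (we measured z up to ~6
for uniformly drawn sets). With the within-quartile background, a
uniformly drawn set is a genuine draw from the background and E[z] = 0;
the Monte-Carlo check in the tests verifies z against a 10,000-draw
resampling null to |Δz| < 0.15. `background = "all"` remains available
for untruncated score vectors, where it is the classical PAGE choice.

One-sided p-values (upper tail for "up", lower for "down") are BH-adjusted
across sets within each pass. Sets with fewer than `m_min = 5` members
among the analyzed genes are flagged untested rather than scored — the
normal approximation for `Sm` is not trustworthy below that, and the
threshold is deliberately small so that the two bound-gene classes of
`binding_enrichment_test()` are almost always testable.

## Peak annotation

Score filtering keeps peaks with `score >= min_score` ("filtering out
peaks with low scores (< T)" retains the threshold value itself).
Cross-sample matching treats peaks as matching when they overlap by at
least 1 bp and groups them into connected components of the overlap graph
(a chain A–B, B–C is one component even if A and C do not touch): the most
permissive deterministic reading of "matching peaks", implemented with
IRanges and checked against a brute-force graph-traversal oracle. A
consensus peak is emitted per component spanning at least `min_samples`
distinct samples; its interval is the union of members, its score the
member maximum.

Transcript scoring uses the peak **midpoint** (the conventional reference
when no summit is recorded; narrowPeak summits can be supplied by reading
with `score_col` and adjusting coordinates upstream), unstranded absolute
distance, and `S = symbol_score / max(d, 1 kb)` with `symbol_score` 3 for
valid gene symbols and 1 for clone/predicted symbols. Candidates lie
within 50 kb; the best-scoring transcript is assigned, a second only if
its score strictly exceeds 25% of the best; score ties resolve to the
lexicographically smaller transcript id. Classes are half-open and
disjoint: promoter `d < 500`, enhancer `500 ≤ d < 50000`. A gene bound by
both a promoter-class and an enhancer-class peak belongs to both sets.

## EPFP target calling

Direct-target calling conditions on binding: the candidate set is the
bound genes, ranked by ascending p from the induction profile, and
`EPFP(rank r) = cummin over ranks ≥ r of p(r)·n/r` — a step-up q-value
computed **within the candidate subset**. Restricting the null to
candidates matches the framing "which bound genes are regulated"; the
genome-wide alternative is available via `genomewide = TRUE`. The
implementation is independent of `stats::p.adjust` and is checked against
both that and a literal step-up enumeration to 1e-12. A gene is a
regulated target when EPFP ≤ 0.5, fold ≥ 1.5, and its logratio sign
matches the requested direction (default upregulation, the direction in
which promoter/enhancer binding is expected to act for an induced TF).

Rank plots sort genes by logratio (descending, ties by gene id) and report
the proportion of bound genes in every 300-gene window, fully sliding
(step 1); the window, not the step, is the resolution-determining choice.

## The synthetic-data generator

`simulate_experiment()` and friends generate the exact study design:
`reps_per_condition = 3` induced and control wells per TF, log10
intensities. Defaults, and why:

| parameter | default | rationale |
|---|---|---|
| baseline | N(2.5, 0.7) | plausible log10 microarray intensity scale; cancels from all logratio-based analysis |
| `frac_affected` | 0.05 | a typical TF moves a few percent of the transcriptome |
| effect magnitude | `effect_floor + Exp`, `effect_floor = log10(1.5)`, mean `effect_loc = log10(2)` | planted effects clear the calling threshold yet include borderline genes; `effect_floor = log10(2)` reproduces the "all effects at least 2-fold" recovery condition |
| `noise_sd` | 0.05 | replicate SD on log10 scale (~12% CV), typical for technical microarray replicates |
| `n_tissues` | `n_tfs + 2` | every TF aligns to a distinct tissue with spare unaligned tissues |
| `alignment_strength` | 1.5 | aligned tissue shifts = 1.5 × planted effects, so most shifts clear the atlas' 2-fold bar |
| `frac_marker` | 0.05 | unaligned tissues get their own significant marker genes, as real atlases do |
| `frac_bound` | 0.5 | half of a TF's upregulated effect genes receive a planted peak |
| `peak_width_bp` | 400 | typical TF ChIP-seq peak width |
| `promoter_frac` | 0.5 | balanced exercise of both distance classes |
| genome layout | 100 genes/chromosome, TSS every 200 kb | attribution is unambiguous unless deliberately confounded; 20% of transcripts get `symbol_score = 1` to exercise the 3-vs-1 rule |

Planted peaks are placed with midpoints at most 450 bp (promoter) or
600–45 000 bp (enhancer) from the TSS and replicated with ±20 bp jitter in
all peak samples, so class bands survive consensus-building with margin;
decoy peaks sit exactly between genes (100 kb from the nearest TSS) and
occur in a single sample each, so they are removed both by cross-sample
matching and by the 50 kb annotation window. Every generator derives its
RNG stream from `seed` plus a fixed offset, so identical configurations
produce identical outputs regardless of call order.

**What the generator does not emulate**: probe-level physics (dye bias,
spatial artifacts, saturation), probe-to-gene collapsing, correlated
gene-gene noise, sequencing reads, genuine regulatory cascades
(indirectly regulated genes), or annotation ambiguity from overlapping
transcripts. Passing the recovery tests therefore demonstrates the
*pipeline's* correctness on data satisfying its model, not robustness to
every failure mode of real arrays.

## Problem sizes and numerical conventions

The verification suite uses 2000-gene simulations with 3+3 replicates (20
seeds for null calibration, 3 for effect recovery), 20 seeds of 1000-gene
simulations for enrichment separation, 10 for target recall, 1000 random
peaks × 500 transcripts for the annotation oracle, and a 10,000-draw
resampling null for PAGE — sizes at which every Monte-Carlo bound in the
tests has comfortable margin while the whole suite runs in well under a
minute per module.

Degenerate inputs are handled explicitly: zero-variance genes (variance
floor / moderation), `r → ±1` (z cap at 50), `n < 4` correlations (z = 0
with warning), sets below `m_min` (untested flag), peaks with no
transcript within 50 kb (unannotated, absent from output), empty candidate
sets (empty tibbles, not errors), and atlases with single replicates
(all-significant with warning, as no test is possible). All boundary
comparisons mirror the stated rules: FDR/fold/EPFP thresholds inclusive,
the 25% second-transcript rule strict, class bands half-open.

## Known limitations

* The moderated test assumes roughly exchangeable per-gene variances; with
  strongly heteroskedastic noise its advantage shrinks (the Welch option
  exists for that case, at a real cost in power at 3+3).
* The "significant in both datasets" universe is one defensible reading;
  per-cell universes would give different z-values.
* EPFP-within-candidates follows the target-calling framing; it is a
  documented choice, not the only reading of expected-false-positive
  control.
* Peak–transcript distance is midpoint-based and unstranded; summit-based
  distances require summit offsets upstream of `assign_peaks()`.
* The atlas correlation treats genes as independent when converting r to
  z; co-expressed gene blocks inflate |z| somewhat, which is why the
  heatmap's z = 2 cut should be read as a display threshold, not a
  calibrated family-wise error rate.
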