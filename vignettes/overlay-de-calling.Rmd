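---
title: "Overlay DE calling: model, calibration and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Overlay DE calling: model, calibration and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scatterde)
```

## The model

`scatterde` calls differential expression from the geometry of
scatter plots rather than from a parametric count model. Its null
hypothesis is embodied by a point cloud: plot a condition's replicate 1
against replicate 2 in log10(TPM) and every gene lands near the
diagonal, with a spread that summarizes technical, operator and culture
variability. The alternative is read off the same axes: a gene whose
condition-1 vs condition-2 point falls outside everything the replicate
cloud can produce has changed more than replicates ever disagree.

Concretely, for a two-condition comparison with two replicates each:

1. **Normalization.** Counts become TPM (`tpm_normalize()`): per sample,
   count/length-in-kb rescaled so each sample sums to 10⁶. Overlay
   geometry operates on `log10(max(TPM, floor))` with `floor = 1e-3`
   TPM, which keeps unobserved genes finite and far below the filtered
   range.
2. **Clouds.** The null cloud pools both conditions' replicate pairs
   (2m points for m genes). Each gene also gets four between-condition
   points, one per replicate pairing (r1/r1, r1/r2, r2/r1, r2/r2).
3. **Overlap.** Dots are disks of radius `dot_size` (log10-TPM units);
   two dots overlap when their centers are within `2 * dot_size`
   (touching counts; Euclidean by default, Chebyshev optional). A gene
   is DE at that size iff all four of its between-condition points are
   uncovered by the whole cloud. Genes are not excluded from the cloud
   when testing themselves — a gene with identical expression everywhere
   coincides with its own cloud points and can never be DE.
4. **Calibration.** Per-gene expression noise between samples j and k is
   the squared coefficient of variation
   `eta2 = 2 (x_j - x_k)^2 / (x_j + x_k)^2`, computed on **linear** TPM
   (logs would distort the CV interpretation) and averaged over genes.
   The replicate baseline averages this over the two within-condition
   replicate pairs. Sweeping the dot size over a grid
   (`default_dot_grid()`: 0.001–0.009 by 0.001, plus 0.015), the non-DE
   set's between-condition noise starts far below the baseline (tiny
   dots throw every ordinarily noisy gene into the DE set) and rises
   toward it as growing dots absorb those genes back. The working size
   is the first grid size whose non-DE noise reaches the baseline.
5. **Refinement (optional).** A kernel density over the replicate cloud
   assigns each gene the probability that its between-condition point
   belongs to the cloud; p and fold-change cutoffs then prune the
   overlay calls (`de_pvalues()`, `apply_cutoffs()`).

### Assumptions

- Two usable replicates per condition. With more, the best-correlated
  pair is chosen (`select_replicate_pair()`, Pearson on
  `log10(TPM + floor)` over all genes); analyses of additional pairs can
  be run separately and are not merged automatically.
- Cross-sample TPM comparison is meaningful, i.e. the global
  transcriptional budget is roughly conserved. TPM is compositional;
  a large unbalanced shift moves *every* gene off the diagonal and is
  indistinguishable from widespread DE by this method.
- Replicate scatter is representative of null variability at every
  expression level. There is no mean–variance model; the cloud itself
  is the model.

## Tunable parameters

| Parameter | Units | Default | Notes |
|---|---|---|---|
| `dot_size` | log10(TPM) | calibrated | the only real tuning knob; larger = more conservative |
| grid | log10(TPM) | 0.001–0.009, 0.015 | sweep range for calibration |
| `floor` | TPM | 1e-3 | log-transform clamp; keeps zeros finite |
| filter threshold | TPM | fitted | lower-tail density crossing, or a fixed value (e.g. TPM > 2) |
| filter rule | — | `mean` | gene kept if mean TPM over all samples exceeds the threshold; `all`/`any` available |
| `metric` | — | euclidean | disk glyphs; `chebyshev` treats glyphs as squares |
| `noise_mode` | — | `mean` | per-gene noise averaged over genes; `sum` provided because the total-noise formulation is also in use, but reported replicate levels (~0.05) are only consistent with an average |
| bandwidth | log10(TPM) | Silverman | `h_d = sd_d * n^(-1/6)` per dimension; `plugin` = univariate Sheather–Jones per dimension |
| `p_mode` | — | `cdf` | lower-orthant CDF; `two_sided`, `hdr` alternatives |
| `p_cutoff`, `fold_cutoff` | —, ratio | none | only ever remove overlay calls |

## The synthetic generator

`synth_config()` / `generate_counts()` emulate the statistical shape of
real count tables: a lognormal baseline of relative expression
(`meanlog 2.5`, `sdlog 1.2`, giving a median around 10² TPM over five
decades), multiplicative lognormal replicate noise with CV 15% (bulk
replicate CVs typically run 5–20%), 200 of 2000 genes carrying 4–8-fold
changes, gene lengths uniform in 500–3000 bp, and multinomial read
sampling to a 5-million-read library so counting noise enters exactly as
in sequencing. With `replicate_cv = 0` expected counts are emitted
directly, so replicates are bit-identical — useful for degenerate-case
tests. All randomness flows from one mandatory seed.

Two design points deserve explanation:

- **Mass balance** (`balance_mass = TRUE`). Because TPM columns each sum
  to 10⁶, injecting fold changes whose total expression mass is
  unbalanced shifts every non-DE gene's TPM by the mass ratio — at the
  default settings an unbalanced injection would move the whole diagonal
  by ~20% and swamp the replicate-noise calibration with a
  library-composition artifact. Directions are therefore assigned by a
  greedy partition that keeps the DE genes' total mass conserved, which
  (with folds ≥ 4) necessarily yields more down- than up-regulated
  genes. Set `balance_mass = FALSE` to study the compositional artifact
  itself; `direction_prob` is honored in that mode.
- **What it does not emulate:** gene–gene correlation, batch effects,
  isoform-level length changes, overdispersion beyond the lognormal ×
  multinomial composition, or datasets whose global output genuinely
  changes. Passing tests on this generator therefore demonstrate the
  geometry and calibration logic, not robustness to compositional or
  batch artifacts in real data.

## Numerical and design choices

- **Overlap predicate.** Exact thresholding of center distances at
  `2 * dot_size` (`<=`, so touching overlaps). The indexed path buckets
  cloud points into cells of side `2 * dot_size` and inspects the 3×3
  neighborhood; it is contractually identical to the brute-force scan
  and tested as such. Sweeps reuse one nearest-distance computation per
  combination, so DE sets are nested across dot sizes by construction.
- **Symmetrized cloud.** Replicate labels are arbitrary, so the null
  cloud enters overlap tests in both axis orientations. This makes DE
  sets invariant to replicate relabeling and to condition order, which
  single-orientation clouds violate at coverage boundaries.
- **Dot-size selection direction.** The non-DE noise curve increases
  with dot size from below the baseline, so "comparable to the replicate
  baseline" is operationalized as the *first size at or above* it. When
  the curve never reaches the baseline — common when calibration is
  nearly perfect, since the full non-DE mean and the baseline estimate
  the same quantity — the largest (most conservative) grid size is used
  and flagged.
- **Distribution fits.** Lognormal and Pareto (location fixed at the
  sample minimum) have closed-form MLEs; Weibull, log-logistic and Burr
  XII are optimized by BFGS on log-parameters from method-of-moments
  starts, making every fit deterministic. AIC ties break toward fewer
  parameters, then alphabetically. Fitting uses linear TPM of non-zero
  values only (all candidate families have positive support).
- **Lower-tail threshold.** "Where the low-expression excess ends" is
  made precise as the first sign change of (empirical − fitted) density
  below the fitted mode, both evaluated in log10 space (empirical:
  Gaussian kernel, Silverman's rule-of-thumb bandwidth; fitted: change
  of variables `g(y) = f(10^y) 10^y ln 10`), on a 1024-point grid with
  the crossing placed at the midpoint of the bracketing grid interval.
  No crossing means nothing is filtered. On data the fitted family
  describes well the crossing location is essentially arbitrary noise —
  usually harmless (near the minimum) but occasionally mid-tail — so a
  fixed threshold is preferable when no low-expression contamination is
  expected; the spec of the bundled calibration study does exactly that
  (TPM > 2).
- **KDE p-values.** The density is a mixture of 2m axis-aligned Gaussian
  kernels on the concatenated replicate vectors; the `cdf` mode is the
  literal lower-orthant integral, computable in closed form as a mean of
  products of normal CDFs. That integral flags only the lower-left tail,
  so `two_sided` and `hdr` modes are provided; `hdr` is
  `P(f(X) <= f(x))`, near 1 deep inside the cloud and near 0 outside,
  estimated from a seeded Monte-Carlo sample shared across genes. The
  evaluated point is the replicate-1 pairing by default; `combos="max"`
  takes the most conservative of all four.
- **Degenerate inputs.** Zero-variance samples refuse to fit; genes with
  zero expression in both members of a pair are errors in the public
  noise API but carry no information in sweeps, where they are excluded
  from noise aggregates (they sit at the log floor and are always
  covered). Empty DE or non-DE sets yield `NA` noise entries, which the
  selector skips.
- **PCA trajectories.** Samples are observations, genes are centered,
  unscaled variables; per-subset analyses refit the PCA on that subset
  rather than projecting a global fit. The PC1 sign is fixed by forcing
  the anchor time's mean score non-positive.

## Problem sizes

The test suite and acceptance script run the calibration study at 2000
genes with 200 DE genes, oracle-equivalence checks on 100 instances of
200 genes, monotonicity over 20 instances of 200 genes, and
distribution-fit recovery on 100 seeded trials of 2000 draws — sizes at
which every geometric result is also verifiable by brute force in the
suite itself.

## Known limitations

- Only two replicates per condition enter any one comparison; the
  method has no notion of within-condition dispersion beyond the chosen
  pair.
- Calls are binary per dot size; the KDE probability is a refinement,
  not a ranking that orders the overlay calls (uncovered genes
  typically saturate near p = 0 in `cdf` mode).
- No multiple-testing correction is applied to the optional p cutoff.
- The `cdf` p-value's one-tailed orientation treats strongly
  down-regulated genes (lower-left of the cloud) as the small-p tail;
  use `two_sided` or `hdr` when direction-neutral pruning is wanted.
- Compositional shifts in real data (global transcriptional
  amplification or shutdown) move the whole between-condition scatter
  off the diagonal and inflate calls; the generator's `balance_mass =
  FALSE` mode reproduces this failure mode for study.
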