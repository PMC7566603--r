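# scatterde

Overlay-based differential-expression (DE) calling for bulk and
single-cell RNA-seq count matrices.

## The idea

Plot a condition's two replicates against each other in log10(TPM) space
and you see how far apart two measurements of the *same* transcriptome
fall — the replicate scatter cloud is an empirical null for "no change".
Now plot condition 1 against condition 2 on the same axes: genes whose
between-condition point is **not covered** by any replicate-cloud dot have
moved further than replicate variability can explain. `scatterde` turns
that picture into a caller:

- Dots are disks of radius *s* (the **dot size**) in log10(TPM) data
  units; a point is covered when its center lies within *2s* of a cloud
  point. With two replicates per condition there are four
  replicate-by-condition pairings, and a gene is called DE only if it is
  uncovered in **all four**. Because replicate labels are arbitrary, the
  cloud is used in both axis orientations, making calls invariant to
  replicate relabeling and condition order.
- The dot size is the method's single tuning parameter. It is calibrated
  against transcriptome-wide **expression noise**, the squared coefficient
  of variation between two samples:

  η²ᵢ = σ²ᵢ / μ²ᵢ = 2 (xᵢⱼ − xᵢₖ)² / (xᵢⱼ + xᵢₖ)²

  computed per gene *i* on linear TPM and averaged over genes. Replicate
  pairs put this around 0.02–0.05; between-condition pairs exceed it
  exactly because of DE genes. Sweeping *s* over a grid, the noise of the
  *non-DE* set rises toward the replicate baseline; the working dot size
  is the first grid size at which it reaches the baseline (falling back,
  with a warning, to the largest size when it never does).
- Lowly expressed, noise-dominated genes are removed first: candidate
  distributions (lognormal, Pareto, Burr XII, log-logistic, Weibull) are
  fitted to the transcriptome-wide TPM distribution by maximum
  likelihood, the family with minimal AIC wins, and the cutoff is the
  lower-tail crossing between the empirical and fitted densities (or a
  fixed TPM threshold you supply).
- Optionally, each gene gets a probability of belonging to the replicate
  cloud from a 2D Gaussian kernel density estimate over the 2m replicate
  points (diagonal bandwidth; Silverman's rule or per-dimension
  Sheather–Jones), evaluated as the lower-orthant CDF, a two-sided
  variant, or a highest-density-region probability; p and fold-change
  cutoffs can then refine the overlay calls.

A seeded synthetic generator (`synth_config()` / `generate_counts()`)
produces count matrices with lognormal baselines, multiplicative
replicate noise, mass-balanced injected fold changes and ground-truth
labels, so the whole pipeline is testable without downloads.

## Worked example

```r
library(scatterde)

sim <- generate_counts(synth_config(m = 1000, n_de = 100, seed = 8))
tpm <- tpm_normalize(sim$counts, sim$gene_lengths) |>
  filter_low_expression(2)

baseline <- replicate_noise_baseline(tpm, sim$design, c("c1", "c2"))
round(baseline, 4)
#> [1] 0.0228

sw <- sweep_dot_sizes(tpm, sim$design, "c1", "c2")
as.data.frame(sw) |> head(4)
#>   dot_size de_count de_noise nonde_noise
#> 1    0.001      727    0.159      0.0172
#> 2    0.002      371    0.291      0.0197
#> 3    0.003      207    0.500      0.0213
#> 4    0.004      143    0.710      0.0220

ds <- select_dot_size(sw, baseline)   # warns: baseline never reached,
as.numeric(ds)                        # falls back to the largest size
#> [1] 0.015

ov <- overlay_de(tpm, sim$design, "c1", "c2", as.numeric(ds))
glance(ov)
#>   dot_size de_count n_genes metric
#> 1    0.015      103    1000 euclidean

truth_evaluation(tidy(ov), sim$truth)
#>   sensitivity    fdr precision  tp  fp  fn  tn
#> 1           1 0.0291     0.971 100   3   0 897
```

The sweep shows the method's signature behavior: DE counts fall as dots
grow, the DE set's between-condition noise is ~30–40× the non-DE set's,
and the non-DE noise climbs toward the replicate baseline (0.0228). At
the calibrated size all 100 injected genes are recovered with 3 false
positives. `autoplot(sw, baseline = baseline)` and `autoplot(ov)` draw
the calibration curve and the overlay scatter; `run_pipeline()` executes
the same steps from count/length/design files (or tibbles) and writes
`de_genes.tsv`, `sweep.tsv`, `noise.tsv`, `fit.json`, `manifest.json`
and `overlay.svg` to an output directory. A thin CLI wrapper lives at
`inst/cli/scatterde.R`.

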