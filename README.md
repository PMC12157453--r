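# surfdeliv

Quantitative surface-delivery metrics from per-cell fluorescence data.

## The problem

Whether a membrane protein actually reaches the plasma membrane is a
prerequisite question for studying adhesion molecules, channels,
receptors and transporters in heterologous cells — and one that simple
"is there staining?" inspection answers poorly, because surface
delivery is heterogeneous across cells and confounded by expression
level. The standard experiment expresses the protein with an
extracellular epitope tag plus an intracellular fluorescent protein
(FP), stains live cells with a membrane-impermeant fluorescent antibody
(Ab), and records per-cell mean intensities `FPcell` (expression) and
`Abcell` (surface-exposed protein), by microscopy with segmentation
masks or by flow cytometry.

surfdeliv turns those per-cell measurements into three complementary
metrics, computed per sample and biological replicate over transfected,
non-saturated cells:

* **f+** — the fraction of transfected cells whose `Abcell` exceeds a
  surface-stain threshold: population penetrance of surface delivery.
* **Ab̄** — the mean `Abcell` (negatives included), proportional to the
  average surface concentration; optionally normalized to a
  positive-control sample.
* **Esurface** — the slope of the least-squares line through
  `(log FPbin, log Abbin)`, where cells are grouped into shared
  expression bins: a dose-response exponent. `Esurface = 1` means
  surface protein scales proportionally with expression; `0` means no
  expression dependence (the retained phenotype). Being a log-log
  slope, it is invariant to rescaling of either channel and thereby
  normalizes for expression differences between constructs.

Both gating thresholds are the 0.995 empirical quantile of pooled
control cells — mock-transfected cells for the `FPcell` threshold,
cells expressing an untagged construct for the `Abcell` threshold — so
the expected false-positive fraction at each gate is below 0.005.

The package also includes the replicate-level statistical comparisons
used with these metrics (one-/two-tailed Welch, Dunnett many-to-one,
Tukey all-pairs, Pearson), a logicle display transform for histograms,
differential-conservation scoring of alignment columns by
Kullback–Leibler divergence between two sequence groups (e.g.
trafficking vs. non-trafficking isoforms), synthetic-data generators
with planted ground truth, and file I/O (TIFF images/masks, per-cell
CSV, aligned FASTA, a minimal FCS 3.0/3.1 reader).

## Worked example

Simulate a surface-trafficking sample (planted dose-response exponent
`k = 0.8`) and a retained null sample, three replicates each, derive
thresholds from simulated mock/untagged controls, and fit:

```r
library(surfdeliv)

cells <- do.call(rbind, lapply(1:3, function(r) rbind(
  simulate_cell_table("surface_high", paste0("r", r), 4000, seed = 10 + r)$cells,
  simulate_cell_table("retained_null", paste0("r", r), 4000,
                      stained_fraction = 0, seed = 20 + r)$cells)))
ctl <- simulate_controls(n_cells = 8000, seed = 30)

fit <- surface_delivery(cells,
                       thresholds = list(mock_fp = ctl$mock$fp_cell,
                                         untagged_ab = ctl$untagged$ab_cell),
                       bin_mode = "equal_count", reference = "surface_high")
summary(fit)
```

```
Per-sample surface-delivery metrics (replicate mean +/- SD)
     sample_id n_replicates  f_plus f_plus_sd ab_mean ab_mean_sd e_surface
 retained_null            3 0.00285  0.000688   0.151      0.262    0.0999
  surface_high            3 0.63731  0.012297  85.133      3.805    0.8066
 e_surface_sd ab_mean_norm
      0.08520      0.00178
      0.00487      1.00000
```

The trafficking sample shows two thirds of transfected cells stained
(`f_plus = 0.64`) and recovers the planted exponent
(`e_surface = 0.81` vs. the true 0.8); the null sample sits at the
false-positive floor (`f_plus = 0.003`, below the 0.005 gate bound)
with `e_surface` near 0 — surface signal independent of expression.
`ab_mean_norm` expresses each sample's mean surface signal relative to
the positive control. A replicate-level comparison:

```r
e <- coef(fit)
welch_t(e[grep("surface_high", names(e))], e[grep("retained_null", names(e))],
        tails = "one", direction = "greater",
        comparison = "surface_high vs retained_null")
```

```
                     comparison statistic       df     p_value tails method
1 surface_high vs retained_null  14.34352 2.013077 0.002349953   one  welch
```

`plot(fit)` draws the per-replicate binned dose-response curves with
their fitted power laws on log-log axes.

## Command line

A thin wrapper over the same functions lives at `inst/cli/surfdeliv`:

```sh
Rscript inst/cli/surfdeliv simulate --out demo --seed 1
Rscript inst/cli/surfdeliv quantify --images demo/images --out cells.csv
Rscript inst/cli/surfdeliv metrics  --cells demo/cells.csv --out out \
                                    --config demo/config.yaml
Rscript inst/cli/surfdeliv compare  --metrics out/metrics.csv \
                                    --control retained_null --out tests.csv
Rscript inst/cli/surfdeliv conservation --alignment demo/alignment.fasta \
                                    --groups demo/groups.csv --out kldiv.csv
```

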