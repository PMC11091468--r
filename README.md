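# regionmarkers

Screens marker genes for dissected brain regions from bulk RNA-seq counts.
Given a gene × sample count matrix, gene lengths, and a design table
assigning each library to a region (the default scheme is the six-region
teleost dissection: OBT, Hy, OT, Ce, Mo, RB), the package

1. computes **FPKM**: `FPKM(g,s) = count(g,s) · 10⁹ / (length(g) · N_s)`
   with `N_s` the library's column sum;
2. tests each region against the pooled rest with a **negative-binomial
   conditional exact test** (common dispersion φ, variance μ + φμ²,
   double-tail p-values, Benjamini–Hochberg FDR);
3. calls a gene **region-highly expressed** when adjusted p < 0.05, the
   25th percentile of its FPKM in the target region strictly exceeds the
   90th percentile over all other samples pooled, and its region mean
   FPKM ≥ 1;
4. calls it **region-specifically expressed** when additionally
   `(mean FPKM in region + ε) / (max other region mean + ε) ≥ 10`
   (ε = 0.01 FPKM; max can be swapped for mean);
5. ranks each region's **top-3 markers** by that ratio;
6. profiles **cell-type marker panels** (bundled neurotransmitter-neuron
   and non-neuronal panels) and user-supplied receptor families across
   regions; and
7. computes **qPCR relative expression** by the 2^−ΔΔCt method for
   validation.

A synthetic-data generator (`simulate_counts()`) produces experiments with
the same 6 × 3 structure and a known spiked-marker truth, so every stage is
verifiable without deposited sequencing data; `evaluate_recovery()` scores
the screen against that truth. The bundled
`inst/extdata/published_marker_fpkm.tsv` carries a published 18-marker ×
6-region FPKM table used for worked-example tests.

## Worked example

The `analysis/` scripts run the whole pipeline on a simulated study
(2000 genes, 6 regions × 3 replicates, φ = 0.1, 10 spiked markers per
region at fold 20):

```sh
Rscript analysis/01_simulate_data.R
Rscript analysis/02_fpkm.R
Rscript analysis/03_differential_expression.R
Rscript analysis/04_marker_screen.R
Rscript analysis/05_marker_panels.R
Rscript analysis/06_qpcr_validation.R
```

`04_marker_screen.R` prints, for example:

```
  Ce   highly:   10  specific:   9  markers: g1776, g0273, g0840
  Mo   highly:   14  specific:  10  markers: g1052, g0323, g0721
  RB   highly:   12  specific:  10  markers: g0876, g0668, g1694
Recovery vs truth: sensitivity 0.967, precision 1.000
```

i.e. each region's highly/specific set sizes, its top-3 markers, and how
the specific sets compare with the spiked ground truth: 58 of 60 spiked
genes were recovered in their assigned region and every specific call was
a true spike. Per-region tables land under `results/screen/`
(`highly_<region>.tsv`, `specific_<region>.tsv` with per-gene ratios,
`markers.tsv`, `summary.json`).

On the published 18-marker table, `05_marker_panels.R` confirms that all
18 candidate markers peak in their assigned region and that the
glycinergic marker *slc6a5* peaks in the medulla oblongata:

```
Published markers peaking in their assigned region: 18 / 18
Glycinergic marker slc6a5 peaks in: Mo
```

In R directly:

```r
library(regionmarkers)
sim  <- simulate_counts(sim_config(seed = 1L))
sets <- run_screen_pipeline(sim$counts, sim$lengths, sim$design)
evaluate_recovery(sim$truth, sets)[c("sensitivity", "precision")]
#> $sensitivity  0.9833333
#> $precision    1
```

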