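---
title: "Methods: screening brain-region marker genes from bulk RNA-seq counts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: screening brain-region marker genes from bulk RNA-seq counts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Teleost brains are dissected into a handful of macroscopic regions — here
the telencephalon plus olfactory bulbs (OBT), hypothalamus (Hy), optic
tectum (OT), cerebellum (Ce), medulla oblongata (Mo), and the remaining
brain (RB) — and profiled by bulk RNA-seq with a few replicates per region.
The analysis question is: which genes are reliable markers of a region,
i.e. expressed consistently and much more strongly there than anywhere
else? `regionmarkers` implements that screen end to end, from a raw
gene × sample count matrix to ranked marker lists, together with the
downstream profiling of cell-type marker panels and a qPCR
relative-expression calculator used to validate candidates.

Because the deposited sequencing data of any particular study is not needed
to verify the *method*, the package ships a synthetic-data generator that
produces experiments with the same structure and a known ground truth, and
the whole pipeline is tested against that truth.

## Expression units: FPKM

Counts are normalized to fragments per kilobase of transcript per million
mapped fragments,

FPKM(g, s) = count(g, s) · 10⁹ / (length(g) · N_s),

with `N_s` the library size of sample `s`. The library size is the raw
column sum of the count matrix — no TMM or upper-quartile step — because
the screen is defined on FPKM and adding a second normalization would
change its thresholds silently; `compute_fpkm()` exposes a `lib_sizes`
argument as the hook for alternatives. Whether "library size" should be
total or uniquely mapped fragments is a data-processing question upstream
of this package; whatever produced the counts defines it. The identity
`sum_g FPKM(g, s) · length_kb(g) = 10⁶` holds for every sample and is
asserted in the test suite at 10⁻⁶ relative tolerance. Genes present in
the counts but missing from the length table are a hard error, never
silently dropped, since a drop would corrupt that identity.

## Differential expression: a conditional NB exact test

Each region is tested against all remaining samples pooled as one group.
Counts are modelled negative-binomially with a single common dispersion φ
(variance μ + φμ²; φ = 0 is Poisson). The test is a conditional two-sided
exact test in the style of the classic edgeR exact test:

1. counts are linearly scaled to the geometric mean of the library sizes
   and rounded half-to-even (the rounding rule is fixed so results are
   bit-reproducible);
2. group sums `S_a`, `S_b` are formed; a sum of n i.i.d. NB(μ, φ) is
   exactly NB(nμ, φ/n) under this parameterization;
3. conditional on `T = S_a + S_b`, with the common mean estimated as
   μ = T/(n_a + n_b), the two-sided p-value sums the probabilities of all
   splits `(s, T − s)` that are no more probable than the observed one
   ("double tail"), with ties included at a relative tolerance of 10⁻⁷ —
   the same convention as the exact binomial test, to which the procedure
   reduces exactly when φ = 0 and group sizes are equal.

All-zero genes return p = 1 by convention so they can never be called
differential. Multiple testing is controlled by Benjamini–Hochberg
adjustment across genes (`stats::p.adjust`). Note that BH is *not*
idempotent — re-adjusting an adjusted vector inflates it again (e.g.
(0.1, 0.5) → (0.2, 0.5) → (0.4, 0.5)) — so the package never re-adjusts
derived quantities; the properties the suite asserts are the step-up
closed forms, componentwise dominance over raw p-values, and monotonicity
on the sorted scale.

The common dispersion is estimated by a method-of-moments rule chosen for
transparency over efficiency: per gene, each group with ≥ 2 replicates
contributes `(s² − m̄)/m̄²` from its within-group mean and variance on
library-size-scaled counts; the contributions are combined per gene with
degrees-of-freedom weights, clamped at zero, and the estimate is the
median over genes. On data simulated at φ = 0.1 with the study design
(3 target vs 15 rest samples) it recovers ≈ 0.09; the residual downward
bias is the familiar skewness of small-sample variance estimates and is
covered by the estimator's recovery test band. The null behaviour of the
full test, with the dispersion estimated from the data, is checked
directly: on a 2000-gene null simulation the raw p < 0.05 fraction sits
near 0.055, and the empirical p-value CDF never exceeds uniform by more
than a small one-sided KS distance.

## The two-step screen

**Step 1 — region-highly expressed.** Gene g is highly expressed in
region r when all three hold:

* adjusted p-value of the region-vs-rest test < `alpha` (default 0.05);
* the 25th percentile of g's FPKM across r's replicates strictly exceeds
  the 90th percentile of g's FPKM across *all* non-r samples pooled;
* mean FPKM in r ≥ 1.

The percentile is computed by linear interpolation at fractional rank
h = (n − 1)·q/100 on the sorted values — the default convention of the
major numeric libraries. With only three replicates the pass/fail outcome
is genuinely sensitive to the percentile definition, which is why it is
fixed in code rather than configurable. "All other regions" is read as one
pooled population (15 values in the 6 × 3 design), not as per-region
percentiles, and the comparison is strict. The FPKM ≥ 1 floor applies to
the region mean; applying it per replicate would interact with the
percentile condition in an untestable way.

**Step 2 — region-specifically expressed.** A highly expressed gene is
specific to r when its specificity ratio

(mean FPKM in r + ε) / (AGG over other regions of per-region mean FPKM + ε)

reaches `fold_threshold` (default 10). ε = 0.01 FPKM: published marker
tables contain exact zeros, so a pseudocount is mandatory, and 0.01 sits
below the smallest nonzero value such tables print (0.02). The aggregation
AGG defaults to the maximum over the other regions' means — the strictest
reading of "10-fold higher than other regions" — with a mean mode offered
because published marker calls are not always consistent with the strict
reading: in the bundled 18-marker reference table, five of the published
markers (viaat, pax7, dmbx1a, prph, slc6a5) have a maximum-other ratio
between 2 and 10 and fail the strict rule, while 13/18 pass. The package
makes no claim to reproduce those borderline calls; both modes are exposed
and reported.

**Markers.** Each region's markers are its `top_k` (default 3) specific
genes by descending ratio, with ties broken by descending target-region
mean FPKM and then lexicographic gene id, so selection is deterministic.

A structural consequence asserted in the tests: markers ⊆ specific ⊆
highly per region, and under max-aggregation with a threshold above 1 no
gene can be specific to two regions.

### Scale behaviour

FPKM, both percentile conditions, the expression floor and the fold rule
are exactly invariant to multiplying every count in every library by a
common positive integer. The DE gate is not, and cannot be: a deeper
experiment is genuinely more informative, the conditional lattice and the
moment estimator's Poisson correction both change with depth, so genes
whose adjusted p-value sits at the `alpha` boundary may enter or leave the
*highly* sets when all counts are doubled. Genes that pass the 10-fold
rule are never boundary cases in practice, so the specific and marker sets
are stable under global rescaling; that is the invariance the test suite
asserts.

## Cell-type panels and receptor families

`profile_panel()` scores a panel (cell type → marker gene list) by the
unweighted sum of per-region mean FPKM over the panel's genes — matching
the "total expression of a family" convention — and reports each type's
top region and full region ranking; a mean-per-gene mode supports
comparisons across panels of unequal size. Two panels are bundled: seven
neurotransmitter-type neuron markers (glutamatergic *slc17a6a/b*,
GABAergic *gad1/2*, glycinergic *slc6a5*, dopaminergic *th/th2*,
serotonergic *tph2*, noradrenergic *dbh/dbh-like*, cholinergic
*chata/chata-like*) and five non-neuronal cell types (oligodendrocytes,
microglia, endothelial cells, radial astrocytes, neuroprogenitors), with
duplicate annotations represented as separate `-1`/`-2` gene ids within
one type. Receptor-family gene lists vary by genome annotation, so no
receptor panel is bundled; `aggregate_receptor_expression()` applies the
same computation to user-supplied families. Panel genes missing from the
expression matrix are warned about and reported, never silently zeroed; an
entry with no matched gene is dropped with a warning, and a panel with no
matched gene at all is an error.

## qPCR relative expression

`ddct_relative_expression()` implements the 2^−ΔΔCt method: per sample
ΔCt = Ct_target − Ct_reference; per region ΔΔCt = mean ΔCt(region) − mean
ΔCt(calibrator); relative expression 2^−ΔΔCt, so the calibrator region is
exactly 1. ΔCt values are averaged per region before differencing (the
common convention); per-replicate values 2^−(ΔCt − calibrator mean) supply
the reported SD. The calibrator has no default and is always echoed in the
output, because the choice sets the absolute scale: without knowing a
study's calibrator only rank patterns across regions are comparable.
Amplification efficiency is fixed at 2; efficiency-corrected variants are
out of scope.

## The synthetic experiment

`simulate_counts()` emulates the 6-region × 3-replicate design: 2000
genes; baseline expected FPKM log-normal with meanlog log(10) and sdlog
1.5 (median 10 FPKM with a realistic heavy right tail), rescaled by one
constant so the FPKM conservation identity holds; gene lengths uniform on
500–5000 bp; 10 spiked genes per region whose expected FPKM is multiplied
by 20 in their assigned region only; expected counts obtained by inverting
the FPKM formula at a 10⁶-fragment target library and then renormalized
per sample to that target (sequencing depth is set by the run, not by
tissue expression); counts drawn NB with φ = 0.1, the same
mean–dispersion parameterization the DE test assumes, so recovery tests
are internally consistent.

Two generator details matter and were chosen once:

* **Spike eligibility.** Spiked genes are drawn only from genes holding at
  most 0.1% of the expected library (the mean share is 1/n_genes = 0.05%).
  Spiking a gene that already dominates the library rewrites the sample's
  composition: every other gene's FPKM in that region drops, and the
  nominal fold is no longer the fold realized in FPKM — the truth labels
  would be wrong. Real markers can be extremely abundant, but a recovery
  benchmark needs its declared truth to be true.
* **Seeding.** One integer seed governs everything; each stage (lengths,
  baselines, spike assignment, counts) derives its own sub-seed, so runs
  are fully reproducible and stages are insulated from each other. Adding
  genes perturbs draws within a stage but not across stages.

What the generator deliberately does **not** emulate: batch effects,
correlated gene modules, mean-dependent (trended) dispersion, partially
shared two-region markers, and read-level artefacts. Passing the recovery
tests therefore demonstrates that the screen's logic and thresholds behave
as designed under the model it assumes — not that the thresholds are
optimal for any particular real data set.

`evaluate_recovery()` compares the specific sets against the spiked truth:
sensitivity is the fraction of spikes found in their assigned region's
specific set; precision the fraction of specific calls that are true
spikes of that region; a run with no calls at all reports precision 1 with
an explicit zero-call flag. At the generator defaults the pipeline reaches
sensitivity and precision ≥ 0.9; at fold 2 sensitivity drops sharply,
which the suite uses to confirm the thresholds actually bind.

## Problem sizes and numerical choices

The packaged analyses and tests run the full design at 2000 genes and
10⁶-fragment libraries for the headline checks (type-I error, marker
recovery) and a 600-gene / 2·10⁵-fragment version of the same design for
the structural property checks, which keeps the whole suite under a couple
of minutes on one core without changing any screen threshold. Exact-test
correctness is verified by brute-force enumeration over all two-group
splits with totals up to 30 at φ ∈ {0, 0.05, 0.5} (tolerance 10⁻¹⁰), and
the percentile routine against the library quantile reference on 1000
random cases (tolerance 10⁻¹²). Probability sums in the exact test are
computed in log space and normalized, so totals in the tens of thousands
are handled without underflow.

## Known limitations

* The common-dispersion moment estimator is deliberately simple; it is
  mildly downward-biased at three replicates, and the exact test with an
  estimated dispersion is slightly liberal at this design (null p < 0.05
  fraction ≈ 0.055 rather than 0.05). Tagwise or trended dispersion and
  quasi-likelihood frameworks are out of scope.
* The screen is defined on FPKM with library size = column sum; strong
  compositional shifts between regions (one transcript dominating one
  region) will depress apparent fold changes, as in any FPKM-based
  analysis.
* Region-vs-rest is the only contrast; pairwise region comparisons are not
  implemented.
* The published-table worked examples treat printed region means as the
  expression matrix (one pseudo-sample per region); replicate-level
  behaviour of those genes is not recoverable from a printed table.
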