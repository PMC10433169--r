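---
title: "Methods: characterizing doubled-haploid panels from recurrent selection"
author: "dhpanel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: characterizing doubled-haploid panels from recurrent selection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dhpanel)
```

## The problem

Long-term recurrent selection reshapes a breeding population: allele
frequencies drift and respond to selection, diversity erodes, linkage
disequilibrium (LD) builds up, and the genomes of the original founders are
progressively diluted or lost. `dhpanel` quantifies these signatures in
panels of doubled-haploid (DH) lines sampled from different cycles of such a
program — the motivating setting is a maize synthetic founded from 16 inbred
lines and advanced through ~17 selection cycles, with DH lines extracted
from the base population (C0), from the advanced cycle (C17), and from an
intermated C0 x C17 cross, alongside the surviving progenitor lines.

Because real panels of this kind are rarely redistributable, the package
pairs every analysis with a forward-in-time simulator of the breeding scheme
that produces genotypes **with known truth** (founder-of-origin of every
allele), so each estimator can be validated by recovery of simulated truth.

## The data container

`GenotypePanel` holds an individuals x markers dosage matrix (0/1/2 copies
of the counted allele, `NA` missing), a marker map (chromosome, bp, cM) and
one group label per individual. Dosages are oriented to the panel-wide minor
allele; all downstream statistics are invariant to that orientation.

## The simulator

* **Founders.** 16 fully inbred lines; marker allele configurations follow
  a 1/j-weighted spectrum over the number of carrier founders, with 15% of
  markers carrying an allele private to a single founder (pool frequency
  1/16 = 6.25%).
* **Meiosis.** Haldane model: per chromosome, crossover count is Poisson
  with mean map-length/100, positions uniform on the cM scale, no
  interference. Founder-origin labels recombine with the alleles, giving
  the truth track.
* **Scheme.** Founders are intermated into C0 (default 200 individuals) and
  random-mated through 5 maintenance generations (the real base
  population's maintenance history is unrecorded; 5 generations of size 200
  is a placeholder choice, configurable). Each selection cycle evaluates
  `cycle_pop_size` individuals on an additive trait (`trait_n_qtl` marker
  QTL, heritability `trait_h2`, default 0.3) and recombines the top
  `selection_fraction`. The default 0.05 of 200 recombines ~10 parents per
  cycle — the order of the historical program — and over 17 cycles erodes
  expected heterozygosity by a factor comparable to the published panel.
  With `selection_fraction = 1` the process is pure drift, used for the
  Wright-Fisher calibration tests. Reciprocal selection against a tester is
  deliberately simplified to within-population truncation selection: only
  the selected population is analyzed, and drift plus directional selection
  reproduce the relevant genomic signatures.
* **DH derivation.** One recombinant gamete per line, doubled; residual
  heterozygosity is injected as a per-call homozygote-to-heterozygote error
  (default rate 0.013, matching the ~1.3% observed in real DH panels).
* **What it does not emulate.** Genotyping missingness patterns, allele
  ascertainment bias of a genotyping platform, structural variation,
  crossover interference, and the reciprocal tester population. Tests that
  pass on simulated panels therefore validate the estimators under a clean
  neutral-plus-selection model, not the full messiness of real assay data.

## Statistics

**Diversity.** Per locus, minor allele frequency from gene-copy counts and
unbiased expected heterozygosity
\(H_{exp} = \frac{n}{n-1}(1 - \sum_i p_i^2)\), where *n* is the number of
non-missing gene copies (2 x genotyped individuals). We read "number of
observed alleles" as gene copies rather than distinct alleles — the latter
would make the correction factor a constant and lose the small-sample
unbiasedness the estimator exists for. Group summaries re-estimate
frequencies within groups (re-orienting the minor allele per group so group
MAF is always at most 0.5; a switch keeps the panel-wide orientation
instead), and standard errors are computed over loci, which matches the
magnitude of published per-group tables at tens of thousands of loci.
Heterozygous calls in DH lines are treated as genuine calls, since the
analyses deliberately run on un-imputed data.

**Differentiation.** Pairwise Euclidean distance over dosage vectors uses
loci non-missing in both individuals; the default output is the per-locus
RMS form sqrt(SSQ/L) so that pairs with different missingness are
comparable (the raw form is available — published distance tables use an
unstated normalization, so both are provided). UPGMA uses size-weighted
averaging (`hclust` "average") and serializes to Newick. Weir-Cockerham
F_ST is implemented from the two-population variance components a (among
populations), b (among individuals within), c (within individuals), using
observed heterozygote proportions — DH data simply make the c component
nearly zero. Per-locus estimates may be negative and are retained; the
multi-locus estimate is the ratio of summed components, not the mean of
per-locus ratios, which would be biased. The top 1% of per-locus values are
flagged for Manhattan-style scans, with a deterministic earlier-position
tie-break.

**Structure.** Centered-IBS kinship is K = ZZ'/s with Z the column-centered
dosage matrix and s the summed per-locus variance; this makes the average
self-kinship exactly 1, and the constant is recorded in the output so any
other scaling is recoverable. Missing calls are mean-imputed *only* for
kinship/PCA (these linear-algebra steps need a total matrix; diversity and
F_ST statistics stay un-imputed). The kinship distribution's "equal to 0"
bin uses a tolerance of |k| <= 0.005 — floating-point kinship is never
exactly zero, and 0.005 is half a unit of the one-decimal reporting
precision used in the literature. PCA eigen-decomposes the same centered
matrix in individual space, so kinship eigenvectors and PC scores coincide
up to scaling (a tested identity). The number of informative PCs is chosen
by a profile-likelihood BIC: retained eigenvalues keep their values, the
residual spectrum is pooled isotropically, and the parameter count
k(d_eff + 1) - k(k-1)/2 caps the dimension d_eff at the matrix rank —
without the cap, marker counts in the tens of thousands would make the
penalty dominate and always select one component. The literature names BIC
without a formula; this definition is isolated in one function. Only PCA is
implemented; a discriminant step on the retained PCs is a documented
extension point, since the source analyses are ambiguous about whether one
was used.

**LD decay.** r² is the squared Pearson correlation of dosage vectors
(composite LD — valid without phase; DH lines are near-homozygous so it
coincides with haplotypic LD up to rare heterozygous calls), with a
two-sided Fisher exact p-value from the 2x2 homozygote-class table. The
decay curve is the Hill-Weir drift-equilibrium expectation
\[
E(r^2) = \frac{10 + C}{(2+C)(11+C)}
\left(1 + \frac{(3+C)(12 + 12C + C^2)}{n(2+C)(11+C)}\right), \quad C = \rho d,
\]
fitted by nonlinear least squares over the pair table with three fixed
restarts; n is the group's line count (each DH line contributes one
effective haplotype). The decay distance is the smallest distance where the
fitted curve drops to r² = 0.1 — a common convention; the threshold is not
fixed by the source analyses and is configurable, and every reported
distance carries it in metadata — solved by bisection to 1 bp. Two
numerical caveats are deliberate design choices: the search range extends
to 1e4/ρ because the curve approaches its 1/n asymptote slowly; and the
`max_pairs` cap thins pairs *systematically along the distance axis* rather
than uniformly at random, because the fitted constant is identified mostly
by the scarce short-distance pairs and uniform subsampling destabilizes it.
On drift-simulated panels whose empirical r²-distance relation is nearly
flat, ρ is intrinsically weakly identified (bootstrap CV can approach
100%+); decay *orderings* between groups remain robust and are what the
tests assert.

**IBD segments and founder contributions.** Each DH line is compared with
each progenitor under a two-state (IBD / non-IBD) hidden Markov model along
each chromosome. Transitions between consecutive markers leave a state with
probability 1 - exp(-d_cM / L), with L the state's expected tract length
(defaults: 5 cM in IBD, 50 cM outside, hence a stationary IBD prior of
1/11). Emissions reduce the two near-homozygous calls to allele classes:
under non-IBD the classes are independent draws at the panel allele
frequency; under IBD they share one allele lineage, with a genotyping-error
rate (default 0.01) absorbing mismatches; heterozygous and missing calls
are uninformative (equal likelihood under both states). This is an order-0
emission model — site independence given the state. The program that
inspired it conditions emissions on previous loci to model background LD;
here the error parameter absorbs that miscalibration, the simulation-truth
recovery tests quantify the cost (marker-level recall and precision above
90% for planted 5-cM segments at realistic marker density), and
higher-order emissions are an extension point. Posteriors come from the
scaled forward-backward algorithm (C++ kernel, verified against exhaustive
path enumeration). Segments are maximal runs with posterior strictly above
0.70, kept only if they span at least 350 kb and at least 11 markers
("more than 10") — the filters that suppress segments created by occasional
genotyping errors. Contributions credit every marker inside a line's
segments to the segment's progenitor; where segments from several
progenitors overlap, the highest mean posterior wins and exact ties split
equally — an explicit rule chosen so that per-progenitor percentages plus
the non-IBD percentage always account for exactly 100% of markers
(published analyses leave overlap handling unstated). Emission allele
frequencies are estimated from the combined genotyped panel, the standard
reference-population choice.

**QC.** Markers are filtered on missing rate (> 10% removed), monomorphism,
duplicate call vectors (identical including the missing pattern; first
occurrence kept — the published filter is named but not defined, so this
definition is explicit and also collapses physical-position duplicates),
and lines are screened at 8.8% heterozygosity, the level at which a line is
no longer credible as an inbred. All filters are idempotent.

## Pipeline and reproducibility

`runPipeline()` executes simulate → QC → diversity → F_ST/distances/UPGMA →
kinship/PCA → LD → IBD from a validated configuration (YAML, key=value file
or list; unknown keys are rejected with a nearest-key suggestion). One
global seed fans out deterministically to per-stage child seeds, so a run
is byte-reproducible and stages can be toggled without changing the seeds
of the others. Numeric TSV output is fixed at 6 significant digits for byte
stability; a JSON manifest records versions, seeds, per-stage status and
every file written.

## Problem sizes used in the tests

The test suite runs the full machinery at reduced scale chosen to keep a
complete run in the order of a minute while preserving the study's
structure: typically 2 chromosomes of 120 cM with 200-700 markers,
populations of 40-50, 17 cycles recombining ~10 selected parents, and 20-25
DH lines per group (the layout checks use the full 15/132/170/185 group
sizes at small marker counts). Marker density for the IBD recovery checks
(~7 markers/cM) matches the density of the real 10,344-marker data set.
Truth-recovery criteria at these scales: planted-segment recall/precision
above 90%, founder-contribution correlations with simulated truth above
0.8 in every group, and the four drift-series orderings (H_exp, F_ST, LD
decay, total IBD) each holding in at least 9 of 10 seeded replicates.

## Known limitations

* The HMM's order-0 emissions over-call IBD in regions of strong background
  LD; the segment length/marker filters and the error parameter compensate
  at the tested densities.
* The Hill-Weir constant is unstable on panels with little LD signal; use
  the decay distance comparisons, not the raw constant, across groups.
* The simulator's constant cM/Mb map and interference-free meiosis ignore
  recombination-rate heterogeneity, so physical segment-length
  distributions are smoother than in real genomes.
* Euclidean distances are not on the scale of any particular published
  table (the normalization there is unstated); within-analysis comparisons
  are unaffected.
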