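---
title: "Methods: cross-platform 5hmC quantification in hydroxycall"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cross-platform 5hmC quantification in hydroxycall}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hydroxycall)
```

## The measurement model

Conventional bisulphite treatment (Bis) converts unmodified cytosines to
uracil but leaves both 5-methylcytosine (5mC) and
5-hydroxymethylcytosine (5hmC) intact, so the retained-cytosine fraction
reads out total modification, 5modC = 5mC + 5hmC. Oxidative bisulphite
(OxBis) first oxidises 5hmC to 5-formylcytosine, which then converts like
an unmodified base, so OxBis reads out 5mC alone. The per-CpG 5hmC level
is the subtraction of the two readouts.

At a CpG with coverage $N$, the retained count is modelled binomially,
$NC \sim \mathrm{Binomial}(N, p)$, with
$p_{\mathrm{Bis}} = p_{5mC} + p_{5hmC}$ and
$p_{\mathrm{OxBis}} = p_{5mC}$. The caller estimates
$\Delta = \hat p_{\mathrm{Bis}} - \hat p_{\mathrm{OxBis}}$ and tests
$\Delta = 0$ with the two-sample proportion test (a 2x2 chi-square with
Yates continuity correction, identical to `prop.test()`; the correction
can be switched off). A CpG is significantly hydroxymethylated when the
two-sided p-value is below `alpha` (default 0.05) **and** $\Delta > 0$ —
a one-sided side condition on a two-sided test, which is why the realised
type-I error under a 5hmC-free truth is roughly `alpha`/2. No
multiple-testing correction is applied at this stage by default (the
whole-genome rule operates on raw p-values); a BH option exists.

CpGs with less than `min_cov` (default 10) coverage in *either* library
are never tested.

### Region averaging

Averaging noisy per-CpG subtractions over a region uses asymmetric
discard/impute rules: significant CpGs contribute $\Delta$;
non-significant CpGs with $0 \le \Delta \le 0.10$ are imputed to zero
(indistinguishable from no 5hmC); non-significant CpGs with
$\Delta > 0.10$ are discarded (too large to be noise around zero yet not
supported statistically, typically low coverage); any $\Delta < 0$ is
discarded as chemically impossible. The average runs over contributing
CpGs only — the discard rules remove CpGs from the denominator by
construction. The boundary $\Delta = 0.10$ imputes rather than discards
(the printed rules use strict inequalities on both sides, leaving the
boundary open; imputation is the conservative choice). A region with no
contributing CpG is flagged undefined rather than given a value.

### Power

`power_two_proportion()` wraps `power.prop.test()`, the standard normal
approximation for the *uncorrected* two-sample proportion test. When we
validate it against Monte-Carlo rejection rates of the package's own
test we therefore disable the continuity correction in the simulation;
with Yates correction on, the realised power at e.g. (0.8, 0.7, n = 60)
is ~0.18 against a closed-form 0.24, which is a property of the
correction, not an error in either computation.

## The synthetic-data generator

No sequencing data accompany the package; every analysis is exercised on
synthetic inputs with the statistical structure the methods assume, plus
ground truth for recovery tests.

* **Methylome truth** (`simulate_methylome()`): CpG positions on one
  chromosome with geometric-like spacing (mean 100 bp), feature labels
  drawn in runs of 25 CpGs (chromatin states are segments, not i.i.d.
  labels), and per-feature levels from beta distributions. The defaults
  put the highest 5hmC at enhancers (mean 0.25) and gene bodies (0.15),
  and deplete CpG islands and active TSSes (0.02), mirroring the somatic
  5hmC landscape; quiescent chromatin is heavily 5mC-methylated. The
  5mC level is drawn as a beta fraction of the non-5hmC mass, so
  $p_{5mC} + p_{5hmC} \le 1$ holds by construction. These beta-mixture
  defaults are a modelling choice — the generator emulates marginal level
  distributions and segment structure, not sequence composition,
  replication timing or real chromatin-state inference, so passing tests
  demonstrate statistical correctness of the pipeline, not biological
  fidelity of any particular genome.
* **Counts** (`simulate_bisoxbis_counts()`): coverage is Poisson per
  treatment (defaults 18x Bis / 16x OxBis, typical whole-genome means),
  drawn independently because the two treatments are separate libraries;
  retained counts are binomial at the chemistry-implied retention rate.
* **Chemistry** (`chemistry_model()`): non-conversion of unmodified C
  (default 0.42%), over-conversion of modified C (default 1.7%, the
  low end of the printed conversion range applied symmetrically), OxBis
  5hmC oxidation efficiency (99.33%), TAB TET efficiency (98.74%) and
  BGT protection (100%).
* **Array betas** (`simulate_array_betas()`): truth expectation plus
  clamped Gaussian noise (default sd 0.02, a realistic array technical
  noise), two replicates per treatment, detection p-values with a
  configurable failure fraction. Probe-design effects (type I/II
  chemistry) are deliberately not emulated.
* **hMeDIP tiles** (`simulate_hmedip()`): Poisson input around a flat
  background, negative-binomial IP counts (dispersion 0.01) with mean
  scaled by an enrichment function of the tile's average true 5hmC —
  the antibody's semi-quantitative behaviour reduced to a monotone
  mean-enrichment curve.
* **Spike-ins** (`simulate_spikein()`): controls with fixed truth
  (5mC-methylated lambda, fully hydroxymethylated pUC18/APC), plus an
  equal number of unmodified sites per control so conversion efficiency
  is estimable from the same molecule. Unprotected 5hmC in TAB is
  treated as oxidised and converted.
* **Amplicon reads** (`simulate_amplicon_reads()`): a comonotone-coupling
  construction — per read, one shared versus independent latent uniforms
  — interpolates between all-or-none and independent per-CpG sampling
  while keeping every CpG's marginal level fixed.

## Array differential calling

Betas passing the detection filter (p < 0.01 in all samples) are
transformed to M-values, $M = \log_2(\beta / (1-\beta))$ with betas
capped at 0.01/0.99. Base 2 is the standard M-value convention; the
underlying description writes an unbased log, so the base is an argument.
The Bis-vs-OxBis contrast uses an empirical-Bayes moderated t: per-probe
pooled variances are shrunk toward a prior fitted by moment matching on
the log variances (mean and variance of $\log s^2$ against log-F
moments, with a Newton trigamma inversion), and the moderated statistic
is referred to $d_0 + d$ degrees of freedom. This is the standard
moderated-t construction, implemented here directly so the prior can be
forced (e.g. $d_0 = \infty$) in closed-form checks; the test suite
verifies agreement with limma's `eBayes` to 1e-10. Significance defaults
to BH-adjusted p < 0.05 with $\Delta\beta > 0$ (raw-p optional — reports
in this family are ambiguous about which was used, and the BH default is
the stricter reading).

## hMeDIP enrichment and specificity audit

Fragments are extended to 300 bp from their 5' end and counted on a
300-bp tiling; tiles with fewer than 20 reads summed across samples are
removed. IP is contrasted with input by a conditional exact
negative-binomial test at fixed dispersion 0.01: library sizes are plain
column sums (no normalisation factors), counts are mean-scaled to a
common library size and rounded, the test conditions on the adjusted
tile total, and the two-sided p doubles the smaller tail (capped at 1).
IP replicates are summed before the contrast. `logFC` uses CPM with a
prior count of 0.5 to avoid log of zero. Tiles with BH FDR < 0.1 and
logFC > 0 are called enriched; logFC bins at 1.8/2.4 (boundaries to the
lower bin) split calls into low/medium/high enrichment. In the
dispersion-to-zero limit the test reduces to the conditional binomial
exact test, which the suite verifies to 1e-6 on all totals up to 50.

The specificity audit compares single-base 5hmC inside summit windows
(summit ±150 bp, clipped at chromosome ends, merged when touching)
against the gaps between them. The permutation null shuffles the order
of the alternating window/gap segments along the chromosome — lengths
and labels preserved, positions reassigned — so segment-length
confounding is controlled; the description of the original scheme says
only "random permutation", and this length-preserving construction is
our interpretation. The statistic is the mean of per-window region
averages minus the mean of per-gap region averages (regions without
contributing CpGs are excluded from their class mean), and the empirical
p-value is $(1 + \#\{null \ge obs\}) / (n_{perm} + 1)$. Peak-level
specificity restricts to peaks whose every CpG has at least 10x coverage
in both treatments, classifies peaks by region-average 5hmC > 0, and
compares the observed positive fraction with length-preserving random
placements.

## Feature enrichment

Enrichment of CpG sets in genomic features is computed at CpG level (not
base-pair level): observed versus expected under uniform sampling from
the tested universe, with upper-tail hypergeometric p for enrichment and
lower-tail for depletion. Level bins are left-closed right-open with an
unbounded last bin (printed bin labels overlap, so a boundary rule had to
be chosen). CpG-island shores are the ±2-kb flanks, clipped at
coordinate 0 and chromosome ends, with bases inside any island
subtracted — shores are by definition non-island sequence. Region
classification uses "at least one significant CpG" by default with a
`min_sig` knob (descriptions alternate between "at least one" and
"more than one").

## Spike-in estimators

All efficiencies pool counts across sites before forming ratios
(per-site values are recoverable from the count tables). The OxBis
oxidation and TAB estimators normalise by the retained fraction in Bis,
which cancels incomplete modification of the control but assumes
negligible over-conversion of modified cytosines in Bis; recovery
simulations therefore set over-conversion to zero, since with a nonzero
value the normalised estimator is biased upward by construction, not by
defect. Single-molecule patterns are classified by per-read modified
fraction into five classes — exactly 0, then right-closed bins to 10, 50,
80 and 100% (fully unmodified reads are their own class because "no
5hmC" and "little 5hmC" are biologically distinct; the remaining
boundaries follow the printed bin labels with right-closure).

## Numerical choices and degenerate inputs

* Coordinates are 0-based half-open everywhere internally; 1-based
  formats are converted at the I/O boundary only.
* Proportion tests on tables whose pooled proportion is 0 or 1 return
  p = 1 (the reference implementation yields NaN there).
* Zero residual variance in the array fit is absorbed by the prior;
  all-identical probes give t = 0, p = 1.
* The trigamma inversion runs Newton from $0.5 + 1/y$ to relative
  tolerance 1e-8, with asymptotic shortcuts for extreme arguments.
* Empirical permutation p-values use the add-one rule and so are never
  exactly zero.

## Problem sizes

The test and reproduction workloads use $10^4$ CpG methylomes at 10-60x
coverage, $10^4$ null tiles, 999 permutations for planted-signal audits
(99 for the 50-seed calibration check), spike-in depth $10^5$ per site,
and exhaustive small-table enumerations (all 2x2 tables with group sizes
up to 10-15; all tile totals up to 50). These sizes give Monte-Carlo
standard errors well inside the asserted tolerances while keeping the
whole suite in the seconds-to-minutes range.

## Known limitations

* No beta-binomial overdispersion in the count model and no smoothing
  across CpGs — the caller is exactly the per-CpG subtraction test.
* The generator's 5hmC landscape is a labelled beta mixture, not a
  chromatin-state model; enrichment results on synthetic data validate
  bookkeeping and calibration, not biology.
* Array preprocessing/normalisation is consumed, not implemented; probe
  design effects and batch structure are out of scope.
* hMeDIP is modelled at tile-count level; fragment-level biases (CpG
  density dependence, GC bias) are not emulated.
* Peak calling itself is out of scope — summits are inputs.
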