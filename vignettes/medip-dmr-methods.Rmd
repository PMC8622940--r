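---
title: "Methods: region-level differential methylation for meDIP-seq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: region-level differential methylation for meDIP-seq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(medipdmr)
```

# The analysis problem

meDIP-seq measures enrichment of methylated DNA: sequenced fragments pile up
over methylated regions, so the data are region-level counts rather than
per-CpG methylation fractions. `medipdmr` implements a complete region-level
differential-methylation pipeline for a three-group developmental-exposure
design — an exposed group (PAE), a handling/feeding control (PF) and an
untreated control (CON) — crossed with sex, with a few animals per cell.
The scientific questions it answers are:

1. which genomic regions differ in methylation enrichment because of the
   exposure itself, because of the control treatment, or in both exposed
   groups relative to control;
2. which of those differences are common to both sexes and which are
   sex-specific;
3. whether the differential regions concentrate in particular genomic
   features (promoters, exons, introns, CpG islands, ...), and which
   biological gene sets they implicate.

# Pipeline model, stage by stage

## Consensus regions and counting

Each sample contributes a peakset (e.g. MACS2 peaks from its own library).
Peaks from all samples are pooled and merged by single-linkage union: any
two peaks sharing at least one base are combined. Coordinates are 0-based
half-open (BED) throughout, so intervals that merely touch share no base and
are not merged. A merged region's *support* is the number of distinct
samples contributing at least one overlapping peak; regions supported by
fewer than `min_samples = 3` samples are discarded. Sex chromosomes are
removed before testing, since X/Y copy-number differences between the sexes
produce large methylation-enrichment artifacts that are not treatment
effects.

Fragment counting assigns each sequenced fragment to the region containing
its **start base**. Because consensus regions are non-overlapping, this only
matters for fragments spanning a region boundary, and it guarantees that
each fragment is counted at most once, keeping library-size accounting
exact. The library size of a sample is its total fragment count.

## Normalization and batch adjustment

Counts are converted to RPKM (`count / (length/10^3) / (lib_size/10^6)`) and
log2-transformed with a pseudocount (default 0.5, configurable) so that zero
counts stay finite; any positive constant leaves contrasts asymptotically
unchanged. Batch variation is then removed with a parametric empirical-Bayes
location/scale adjustment: per-region linear models with batch indicators
plus the *protected* biological design (treatment group with CON reference,
plus sex), standardization of residual batch deviations, method-of-moments
priors (normal for location, inverse-gamma for scale), iterated posterior
updates for the per-batch location `gamma*` and scale `delta*` (relative
tolerance `1e-4`, capped at 100 iterations, both configurable), and finally
back-transformation that restores the protected fit. With a single batch the
adjustment is the identity. The implementation is validated against
`sva::ComBat` (agreement to ~1e-5) in the test suite; `sva` is used only as
an oracle, never as the implementation, because the pipeline exposes the
fitted `batch_model` (shrunken location/scale estimates, prior
hyperparameters, iteration counts) for inspection.

## Differential testing

Three analysis tiers mirror the study design:

* **sex-concordant**: `~ group + sex` on all samples;
* **female-specific**: `~ group` on females only;
* **male-specific**: `~ group` on males only.

Ordinary least squares is fit per region with treatment coding (CON
reference), so the coefficients are directly `PAE − CON` and `PF − CON` in
log2 units, and the three contrasts of interest are `PAEvCON = b_PAE`,
`PFvCON = b_PF` and `PAEvPF = b_PAE − b_PF`. Residual variances are
moderated with an empirical-Bayes scaled-F prior estimated by the
trigamma-inverse moment method; the moderated t statistic uses the posterior
variance `(d0*s0^2 + d*s^2)/(d0 + d)` on `d0 + d` degrees of freedom.
Setting `d0 = 0` recovers the classical per-region t-test exactly, and the
whole procedure matches `limma::lmFit`/`eBayes` (used as a cross-check in
the tests) to numerical precision. A deliberate modeling choice: the
upstream normalization produces continuous log2 values, so a Gaussian
moderated linear model is used rather than a count GLM; moderation provides
the same small-sample variance stabilization that count-model
empirical-Bayes machinery would.

Benjamini–Hochberg correction is applied within each contrast × tier
(`stats::p.adjust`), and significance means `q < alpha` with `alpha = 0.05`.

## DMR classification and the sex-tier reassignment

Per tier, the three significance flags classify each region:

| PAEvCON | PAEvPF | PFvCON | category |
|---|---|---|---|
| yes | yes | no | `PAE_specific` |
| no | yes | yes | `PF_specific` |
| yes | any | yes | `shared` |

The rules are mutually exclusive. A region called with the same category in
the concordant tier *and* in a sex tier is considered driven primarily by
that sex and is removed from the concordant tier (sex tiers are never
changed); "overlap" means identical region id, since all tiers are fit on
one consensus set. A region appearing in both sex tiers is kept in both
with a warning.

Direction is defined by the category's two defining contrasts (PAE:
PAEvCON and PAEvPF; PF: PFvCON and the sign-flipped PAEvPF, so "down" reads
as lower methylation in PF than in both other groups; shared: PAEvCON and
PFvCON): `up`/`down` when both agree in sign, `inconsistent` otherwise. A
DMR is flagged robust when `|logFC| >= log2(1.5)` in both defining
contrasts.

Direction bias is tested against the expected 50/50 split with a
Monte-Carlo chi-squared test: `B = 2000` binomial(n, 1/2) replicates and the
add-one estimator `p = (1 + #{chi2_rep >= chi2_obs})/(B + 1)`, whose floor
is `1/(B+1)` (≈ 0.0005 at the default `B`). Two exact consequences are worth
noting: an odd total forces `p = 1` (the most balanced achievable replicate
already ties the observed statistic), and very lopsided splits sit exactly
on the floor.

## Feature annotation and permutation enrichment

Regions receive every feature class they overlap by at least one base
(CpG island, exon, intron, the promoter windows `[TSS−200, TSS)` and
`[TSS−1500, TSS)` on the coding strand, 5′/3′ UTR). Regions overlapping an
exon and an intron of the same gene are additionally labeled
intron/exon-boundary regions; regions with no gene-derived overlap are
intergenic. Enrichment of a DMR set is measured against 10,000 size-matched
random subsets of the tested region universe (sampling without replacement),
with a one-sided add-one empirical p in the direction of the observed
deviation. The null preserves subset size only — not DMR lengths or
chromosome composition — which is the plainest reading of a size-matched
subset null.

## Gene-score resampling

Gene scores are `-log10` of the best region p-value among a gene's regions
for the chosen contrast. A gene set's observed statistic is the mean member
score; the null resamples the same number of scores from the scored-gene
universe without replacement (10,000 iterations; set sizes restricted to
[2, 2000]). Multifunctionality — genes that belong to many sets inflating
set-level significance — is handled by a leave-out robustness re-run: the
top `k_top` most multifunctional genes (default 1% of scored genes) are
removed and the test repeated with the same seed; sets that lose
significance are flagged (reported, not dropped). Final category-specific
pathway lists apply the same contrast-intersection logic as the DMR
classification to set-level significance.

# The synthetic study generator

`sim_config()` encodes the study conditions: 3 groups × 2 sexes × 5 animals
(30 samples), two near-balanced batches orthogonal to the biology, litters
contributing at most one animal per sex, 5,000 consensus-sized regions with
log-normal lengths (median ≈ 465 bp, matching observed DMR sizes),
negative-binomial counts with a common dispersion of 0.1, per-region
log-normal baseline rates giving a median-length region a mean count near
60 (typical meDIP peak depth), log-normal library-size factors (sd 0.2), a
0.5 log2 multiplicative batch shift, and planted DMRs — 10% of regions,
assigned round-robin across every tier × category × direction cell at
±1 log2 unit. Regions on the sex chromosome carry a +1 log2 female baseline
(two X copies), an intentional tripwire: skipping sex-chromosome removal
produces conspicuous artifacts. Peaksets are the true regions with ≤30 bp
boundary jitter and per-sample dropout; fragments are placed with start
bases uniform within their region, so start-base counting reproduces the
count matrix exactly. One master seed derives independent per-stage seeds
via a counter scheme, so skipping a stage never shifts another stage's
randomness.

What the generator does *not* emulate: spatially correlated methylation
along chromosomes, immunoprecipitation efficiency and CpG-density bias,
GC effects, litter random effects, and peak-calling noise beyond boundary
jitter and dropout. Passing recovery tests therefore demonstrates the
statistical machinery under the design's sampling structure, not robustness
to those real-data complications.

# Numerical and design choices

* **Strict overlap.** Merging and intersection require a shared base;
  touching half-open intervals never merge. Chromosome names are matched
  exactly (an explicit flag strips a `chr` prefix at the read boundary).
* **EB iteration.** Batch-adjustment posterior updates iterate to relative
  tolerance `1e-4` (cap 100); single-batch input short-circuits to the
  identity.
* **Degenerate inputs.** Zero library sizes, confounded batch designs,
  rank-deficient models, all-zero residual variances and out-of-range
  p-values are refused with named diagnostics rather than propagated.
* **Significance threshold** is strictly `q < alpha`, matching "FDR < 0.05".
* **Problem sizes in the checks.** The recovery analysis uses the full
  5,000-region, 30-sample design; calibration replicates use 400 regions
  with 500–1,000 resampling iterations, sizes chosen to exercise every stage
  while keeping the whole suite fast enough to run routinely.

# Known limitations

* The empirical-Bayes batch rescaling slightly perturbs null p-values (its
  per-region scale estimates are noisy at 15 samples per batch); at 5,000
  regions a KS test can detect this, which is a property of the adjustment
  method itself — the implementation agrees with the reference `sva::ComBat`
  to ~1e-5. Calibration of the testing step is therefore assessed on a
  batch-free null, and the batch adjustment is validated by its own
  contract (shift removal + protected-effect preservation).
* With 5 animals per group × sex cell, the sex-stratified tiers have
  limited power: at a planted effect of 1 log2 unit and dispersion 0.1, the
  5-vs-5 moderated z statistic is bounded near 3.5, so joint significance in
  two contrasts at BH-corrected thresholds recovers only a minority of
  sex-tier planted regions, while the concordant tier (10 vs 10) recovers
  ~85–90%. This is the expected behavior of sex-stratified analyses at this
  sample size: far fewer sex-specific than sex-concordant calls.
* Gene scores use the best region p-value per gene; genes hosting many
  regions get more chances at a small p. The resampling null inherits this
  only partially; the multifunctionality re-run is the corresponding
  robustness guard.
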