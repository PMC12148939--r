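---
title: "Methods: repeatability of thermal adaptation from pool-seq time series"
author: "evoreseq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: repeatability of thermal adaptation from pool-seq time series}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(evoreseq)
```

## The analysis in one paragraph

`evoreseq` analyses evolve-and-resequence (E&R) experiments in which
replicate lines from several differentiated genetic backgrounds adapt to a
cold and a hot thermal regime, and both allele frequencies (pool-seq) and a
multi-trait phenotype panel are measured before and after adaptation.  The
pipeline asks four questions.  (1) Which SNPs changed more than genetic
drift can explain?  (2) Are the changes pleiotropically shared between
regimes (synergistic/antagonistic) or private to one regime, and how
repeatable are they across backgrounds, at SNP and gene level?  (3) How
parallel are the multivariate *directions* of change — angles, rates and
convergence/divergence of change vectors — in trait space and in
allele-frequency space?  (4) Do genomic offsets (weighted allele-frequency
distances to the best-adapted reference line) predict phenotypic and fitness
maladaptation, within and between backgrounds?

## The drift null

### The classical beta approximation

Under pure Wright-Fisher drift, the frequency `p_t` after `t` generations at
variance effective size `Ne` has mean `p_0` and variance `p_0 (1 - p_0) F`
with

```
F = 1 - (1 - 1 / (2 Ne))^t.
```

The classical approximation models `p_t | p_0` as `beta(alpha + 0.001,
beta + 0.001)` with `alpha = p_0 (1 - F) / F`, `beta = (1 - p_0)(1 - F) /
F`; the 0.001 offsets keep the density integrable at the boundaries, a crude
stand-in for the fixation atoms of the discrete process.  This is exposed as
`drift_null_pvalue()`.  It is accurate in the bulk of the distribution but
not in the far tails: against an exact Wright-Fisher simulation its tail
probabilities deviate by up to roughly 30% in relative terms (and much more
at loci observed at the 0/1 boundary), so it cannot by itself deliver
calibrated outlier detection at per-tail probabilities of `1e-4`.

### The exact observation-process null

Candidate detection must separate selection from *everything* the null
process produces: drift, the binomial sampling of a finite pool of diploids,
and the binomial sampling of a finite number of reads — with read counts so
discrete (depth ~50) that continuous approximations are meaningless in the
far tail.  `wf_exact_null()` therefore computes the conditional distribution
of the evolved read count given the ancestor read count exactly:

1. **Ancestral frequency prior.** The distribution of true ancestral
   frequencies is estimated once per sample from all loci's ancestor read
   counts by nonparametric maximum likelihood (EM over a frequency grid) —
   a genome-wide empirical-Bayes prior.  A uniform prior is available.
2. **Posterior per locus** over the true ancestral frequency, from the
   two-stage pool+read likelihood.
3. **Drift**, exactly: one binomial generation onto the `2 Ne`-chromosome
   grid, then the Wright-Fisher transition matrix raised to the power
   `t - 1` (binary powering; `2 Ne` of a few hundred keeps this in
   milliseconds).
4. **Sampling**, exactly: binomial pool (2 x pool size chromosomes) and
   binomial reads.
5. **Randomized tail probabilities.** The point mass of the observed count
   enters the tail with a uniform weight.  This classical construction
   makes null p-values *exactly* Uniform(0,1) despite the discreteness;
   with `randomize = FALSE` deterministic mid-p values are returned
   instead.  The uniform draws come from a seeded substream, so scans are
   reproducible.

The computation collapses to unique (reads, depth) tuples, so a million
loci cost little more than fifty.  A moment-matched beta-binomial
approximation of the same chain (`poolseq_null_pvalue()`) is kept as a fast
alternative; it is accurate to a few percent down to `1e-3` but sits ~20%
low at the `1e-4` tail.

Calibration was verified by simulation: under a neutral synthetic
experiment (Ne = 200, 60 generations, pool 60, depth 50, 1e6 loci) the
per-line, per-tail flag rate matches nominal q within three binomial
standard errors at q = 1e-2 and q = 1e-4 (the acceptance suite re-runs
this).

### Divergence times and Ne

The sequenced "ancestors" are generation-3 samples of the hot lines, so
divergence spans the sampling generation plus 3 for cold lines and minus 3
for hot lines (`adjust_generations()`); with the default design (cold
sampled at generation 57-59, hot at 67-69) that gives 60-62 and 64-66
generations.

`estimate_ne()` estimates the variance effective size per line from the
same data: per locus, the squared frequency change is corrected by unbiased
estimates of both samples' two-stage sampling variance (`Var(p_obs) =
p(1-p) [1/(2 pool) + (1 - 1/(2 pool))/depth]`); corrected numerators and
`p0(1-p0)` denominators are summed separately (a ratio-of-sums temporal F)
and `F = 1 - (1 - 1/(2Ne))^t` is inverted exactly.  The construction is
conditionally unbiased with no small-F approximation; parameter recovery on
simulated data at Ne 50-500 is within a few percent at 1e4 loci.  When the
corrected F is non-positive the estimate is flagged as "no detectable
drift" (`ne = Inf`).

Selection coefficients are logit slopes, `s = (logit(p_t) - logit(p_0)) /
t`, with boundary frequencies clamped to `1/(20 pool)` (pooled data hit 0/1
routinely); they are used as relative weights `|s|` in the offsets, for
which this simple, fully specified estimator suffices.

## SNP classes and gene-level repeatability

A regime "hit" at a locus requires *both* replicate lines of a background
beyond the per-tail threshold (default `q = 1e-2` for classification,
`1e-4` for the strict candidate set) *with the same direction* of change.
Hits in both regimes in the same direction are synergistically pleiotropic
(SP), in opposite directions antagonistically pleiotropic (AP); hits in
exactly one regime are private-cold or private-hot.  Classes are mutually
exclusive per locus and background.  Genes inherit SNP classes when the SNP
lies inside the protein-coding gene span (1-based inclusive; exon-resolved
CDS intervals are available via `read_gene_annotation(feature = "cds")`).
Cross-background repeatability is summarised by upset-style exclusive
intersection counts and pairwise Jaccard indices (`overlap_counts()`), and
tested against forward drift simulations that re-run the entire
classification pipeline on neutrally evolved, pool-seq-sampled replicates
of the design (`expected_overlap_by_drift()`, add-one permutation p).

**Detectability of antagonism.** At Ne = 200 and ~60 generations, drift has
standard deviation ~0.22 on an intermediate-frequency allele, so even a
*complete* antagonistic wipe (dp = -0.4 from p0 = 0.4) is ~2 s.d. of the
null — no calibrated test can flag it, in either direction, reliably.  This
is the detection bias against pleiotropic SNPs inherent to the design.
`classification_recovery()` therefore scores recovery among planted loci
whose true responses exceed 3 s.d. of the drift-plus-sampling null in every
relevant replicate; under the planted scenario (s = 0.1, Ne = 200) SP and
private classes are recovered at 92-100% with zero SP/AP confusion, while
AP yields no detectable loci at all — the package reproduces the
*asymmetry* of detectability rather than hiding it.

## Change-vector geometry

Traits are mean-scaled by the ancestral grand mean per trait and assay
temperature (means and standard errors alike), making changes proportional
and comparable across traits.  Change vectors run from a background's
pooled ancestor to each evolved line, at the line's local assay
temperature; genomic change vectors are `p_t - p_0` over the union
candidate set.  Rates are `||change|| / t`, scaled by the dataset maximum
when reported.

The angle between two change vectors is the arccosine of the normalised dot
product (vector correlation through the origin; centred Pearson available
via `centered = TRUE`).  When two lines share a measured ancestor, the
ancestor's measurement error inflates the expected dot product by the sum
of its squared standard errors; `pairwise_angle()` subtracts this error
component from the numerator.  The denominator is left at the observed
norms by default — correcting it as well is available behind
`denominator_correction = TRUE` but can render the angle undefined when the
error exceeds the signal, which is then reported as such rather than
clamped.  Genomic angles use no correction: each line has its own sequenced
ancestor proxy, so the errors are independent.  Cosines are clamped to
[-1, 1] at tolerance 1e-12 before the arccosine; a corrected cosine beyond
that tolerance returns "error exceeds signal".

Divergence compares the distance between two evolved lines (`E_d`) with the
distance between their ancestors (`S_d`); within-background `E_d` subtracts
the evolved lines' squared standard errors under the root and floors the
result at zero (flagged) when the error dominates.  `div = E_d - S_d` is
positive when lineages diverge; values are scaled by the distance between
the two most differentiated ancestors.

Two nulls accompany the geometry.  `random_angle_null()` draws isotropic
random vectors (standard-normal components, normalised) and records mean
pairwise angles — in 7 dimensions the null mean is 90 degrees with s.d.
~22, so observed means of 40-70 degrees are extremely non-random.
`permutation_regime_test()` permutes regime labels across lines *within
each genetic background* (the exchangeability the design actually
supports), recomputing the hot-minus-cold difference in mean angle,
divergence or rate; p-values use the add-one correction `(k+1)/(n+1)`.
With three backgrounds of four lines there are only `6^3 = 216` distinct
stratified label assignments, so the smallest attainable two-sided p is
about `2/216` — worth keeping in mind when reading very small permutation
p-values from designs of this size.

## Offsets: predicting maladaptation from genomic distance

For each background, the reference is the evolved line of the focal regime
with the highest laboratory fitness (lifetime offspring per couple divided
by egg-to-adult development time) at its own temperature; ties resolve
lexicographically and are flagged.  The reference's candidate set is the
smallest fraction (default 0.001) of its empirical p-values, ties included;
each SNP carries the reference's `|s|` as weight.  Then, for every other
line:

* genomic offset = sum over candidate SNPs of `|p_ref - p_test| * |s_ref|`
  (a weighted L1 distance; unit weights for random-SNP controls, whose
  loci have no estimated `s`),
* phenotypic offset = Euclidean distance in mean-scaled trait space at the
  assay temperature (hot, 35 C, being the primary surface),
* fitness offset = test fitness / reference fitness.

Correlations of the genomic offset with the other two are reported pooled
and per reference, separately for within- and between-background pairs, and
the group difference is tested by ANCOVA (linear model with a
genomic-offset x group interaction).  `random_snp_offsets()` repeats the
genomic offsets on uniformly drawn SNP sets of the same size as the
candidate set.

## The synthetic-data generator

The generator is the package's test bed and defines the study conditions:

* **Design** (`experiment_design()`): 3 backgrounds x 2 regimes x 2
  replicate lines, pools of 60 diploids, mean read depth 50 (Poisson per
  locus and sample), cold lines sampled at generation 57, hot at 67,
  ancestor proxies at generation 3 of the hot lines.  True effective sizes
  default to 240 (cold) and 190 (hot) — hot lines experience stronger drift,
  bracketing a study-wide mean of ~215.
* **Ancestral variation** (`draw_ancestral_frequencies()`): a common
  ancestral frequency per locus (uniform on [0.05, 0.95]), a
  Balding-Nichols beta kernel with F_ST-like `differentiation` (default
  0.15; the study populations' actual differentiation is not published, so
  scenarios expose it as a free parameter), and binomial sampling of a
  finite founder pool (default 350 diploids, matching laboratory census
  sizes of a few hundred) which generates differential fixation between
  backgrounds.
* **Architecture** (`assign_architecture()`): SP/AP/private classes with a
  common `|s|`; signs are random per locus.  Trait effects are
  linear-additive: the proportional change of trait j at assay temperature
  T is `effect_size * loading_j * sign(s_T) * dp` summed over loci, so an
  allele favoured in a regime improves regime-appropriate trait values
  (offspring production and early fecundity up, development time down) and
  an antagonistic allele helps at one temperature and harms at the other.
  Default `effect_size` 0.004 per locus gives tens-of-percent fitness gains
  for a few hundred selected loci swept halfway — strong but plausible local
  adaptation over ~60 generations at `s = 0.1`.
* **Traits**: seven traits at two assay temperatures with illustrative
  ancestral baselines; reported standard errors are `trait_noise` (default
  2%) of the ancestral mean, and realised means add Gaussian error of that
  magnitude.  Laboratory fitness derives from the lrs and dev_time traits,
  so fitness offsets need no separate generator.
* **Determinism**: one master seed; per-line and per-stage substreams are
  derived by hashing stage names, so any line can be regenerated alone.

Scenario presets: `scenario_neutral()` (calibration),
`scenario_planted_classes()` (classification recovery),
`scenario_background_private()` (offset prediction: each background adapts
through loci polymorphic only in itself and fixed elsewhere, drawn under
strong differentiation with 100 founders).

What the generator deliberately omits: linkage and draft (the drift null is
single-locus, free recombination), epistasis, sex chromosomes and
males-only pooling, and block effects in phenotyping.  Passing tests
therefore demonstrate the statistical machinery under the stated
single-locus model, not robustness to LD or genotype-by-environment
structure in real data.

## Problem sizes and numerical choices

The bundled checks run at desk scale, chosen to keep Monte-Carlo error
well below the assertion tolerances: calibration at 1e6 loci (binomial
3-s.e. bands at per-tail 1e-4 and 1e-2), Ne recovery at 1e4 loci over 60
generations (tolerance 15%), angle-correction bias at 1000 replicates
(tolerance 2 degrees), classification recovery at 1e4 loci with 2% planted
per class, and offset scenarios at 2e4 loci with ~250 private loci per
background and a 0.01 candidate fraction — the fraction is raised from the
0.001 used on ~10-million-SNP genomes so the candidate set keeps a
comparable absolute size (~200 SNPs) on the small panel.

Other numerics: frequency grid of 1024 midpoints and 300 EM iterations for
the empirical prior; `2 Ne` capped at 4000 chromosomes for the transition
matrix (beyond that the moment-chain null takes over); cosines clamped at
1e-12; permutation and simulation p-values use `(k+1)/(n+1)`; Jaccard of
two empty sets is 0, flagged.

## Limitations

The exact null conditions on the ancestor-proxy read count and treats cold
lines' proxy-to-line divergence (3 + 57 generations on two branches) as a
single 60-generation chain; the neglected term is `F_3 * F_57`, under 1% of
the drift variance.  Randomized p-values make marginal candidates
seed-dependent by construction (strong candidates are unaffected); use
`randomize = FALSE` for deterministic mid-p at the cost of conservative
extreme tails.  The selection-coefficient estimator ignores drift between
the two time points and is a relative weight, not an efficient estimator.
Gene assignment uses whole protein-coding gene spans by default, not
exon-resolved CDS.  All repeatability statistics inherit the assumption of
independent loci.
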