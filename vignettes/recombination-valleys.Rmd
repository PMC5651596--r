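---
title: "Detecting recombination rate valleys in regulatory domains"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting recombination rate valleys in regulatory domains}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The question

Regulatory elements and the genes they control can be seen as functional
units that are most useful when inherited together. If selection favours
co-inheritance, the genomic span between a regulatory element and its
target — an eQTL SNP and its gene's TSS, a meQTL and its CpG, the two
anchors of a Hi-C contact, a DNase peak and a correlated promoter — should
show a *depressed* meiotic recombination rate relative to comparable random
stretches of the genome: a **recombination rate valley**.

`recvalley` implements the inference machinery for this question: a rate
oracle built on genetic maps, link-set hygiene, three matched-control
generators, two significance procedures stratified by anchor distance, DNA
methylation correlation analyses, a random-forest rate predictor, and a
synthetic-genome generator used to validate the whole pipeline on planted
effects.

## Rate model

A genetic map is a monotone mapping from physical position (bp) to
cumulative genetic distance (cM). The mean recombination rate of an
interval $[s, e)$ is

$$ r = \frac{\mathrm{cM}(e) - \mathrm{cM}(s)}{(e - s)/10^6} \quad
   \text{(cM/Mb),} $$

with $\mathrm{cM}(\cdot)$ linearly interpolated between flanking markers
and clamped to the terminal values outside the mapped range (no genetic
distance accrues where there are no markers; such intervals are reported
as rate 0 with a `no_coverage` flag rather than silently). A masked
variant (`interval_rate_masked()`) restricts the average to unmasked
bases — e.g. gene bodies padded by 2 kb, to show an effect is not merely
proximity to coding sequence.

Links carry two anchors on one chromosome. Distance is measured between
anchor midpoints (the symmetric choice); the analysed span is the closed
hull of both anchors. Spans are stratified into three distance classes —
short (1–10 kb), medium (10–100 kb), long (100 kb–1 Mb), half-open on the
left boundaries — and everything outside is excluded. Short-range rates
are dominated by local marker density, so the substantive claims live in
the medium and long classes.

All internal coordinates are 0-based half-open; 1-based file conventions
(genetic map text) are converted at the I/O boundary, behind a `coords`
flag because map files in the wild are inconsistent.

## Matched controls

Three control generators, in increasing stringency:

1. **Length-matched** (`sample_length_matched()`): one random interval per
   link with exactly the span's length, uniform on the same chromosome.
2. **Feature-matched rejection sampling**
   (`sample_feature_matched_rejection()`): repeats length-matched draws
   until the Euclidean distance between the candidate's and the link's
   feature vectors falls below a tolerance of 0.01, or 10,000 draws are
   exhausted. Features are interval means of supplied tracks — GC
   fraction, CpG density, SNP density, PRDM9 motif density — each min–max
   normalized to $[0,1]$ *before* the distance is taken: a raw-unit
   tolerance would be dimensionally meaningless across percentages and
   densities, so the tolerance is defined in normalized space. On
   exhaustion the best candidate seen is returned flagged `matched =
   FALSE`; flagged controls are excluded from downstream tests by default
   (the alternative — keeping poorly matched controls — quietly weakens
   the matching claim).
3. **k-d tree matching** (`build_candidate_index()` +
   `sample_kdtree_matched()`): enumerates candidate intervals on a start
   grid with a ladder of lengths (classically 1-kb grid, lengths 1 kb to
   1 Mb in 1-kb steps), indexes their normalized feature vectors (tracks
   plus interval length) in a per-chromosome k-d tree, queries the 1000
   nearest candidates per link, drops candidates that are essentially the
   link itself — non-overlapping candidates less than 1 kb away, or
   overlap exceeding 50% of the shorter interval — optionally drops
   candidates overlapping a CTCF motif, and samples one survivor
   uniformly. Building per-chromosome trees makes chromosome an exact
   matching feature. Genome-scale enumeration is supported only behind a
   `subsample` factor and an explicit candidate cap; exhaustive
   enumeration is for desk-scale genomes.

A fourth, domain-constrained generator (`sample_within_domain()`) draws
the control inside the chromatin domain containing the link, for analyses
that must control for domain-level rate differences.

The k-d tree itself is compiled code (`src/kdtree.cpp`); its results are
checked against a brute-force scan in the test suite, never trusted on
faith.

## Significance

**Paired test.** Each link is paired with its matched control and the
two-sided Wilcoxon signed-rank test is applied to the paired rate
differences. (A Mann–Whitney U test has no standard paired form; the
signed-rank test is its paired analogue, and this choice is recorded in
the result metadata.) Zero differences are dropped — the classical
convention, matching the common exact implementations — with
`n_effective` reported. For `n_effective <= 25` the null is computed
*exactly* by convolution over the (possibly tied, doubled-to-integer)
ranks, which equals enumerating all $2^n$ sign assignments; above 25 a
normal approximation with tie correction and continuity correction is
used. The exact branch is verified against full enumeration in the tests.

**Permutation test.** The null universe is every same-chromosome pair
(SNP, TSS) whose distance falls in the class under test. Each of 10,000
rounds samples as many random pairs as there are links and records the
median span rate; the observed median is ranked in this null. The
depletion p value is one-sided with the add-one correction,

$$ p = \frac{1 + \#\{\text{null} \le \text{observed}\}}{1 + n_\text{perm}}, $$

so the smallest attainable value at 10,000 rounds is $1/10001 \approx
9.999\times10^{-5}$ — just under the $10^{-4}$ significance threshold used
throughout, which is therefore reachable only by an observed median more
extreme than every permutation. Pairs are sampled *without*
materializing the cross product: per-SNP feasible-window counts over the
sorted TSS vector weight the SNP choice, then index arithmetic picks the
TSS; uniformity over the implied universe is tested against full
enumeration on a small instance.

**The valley test** (`valley_test()`) runs both procedures per distance
class and flags classes where every available p value is below the
threshold (default $10^{-4}$). The figure-style summary
(`mean_rate_by_distance()`) reports per-distance-bin means with a band of
half-width $\mathrm{sd} \times 1.96/10$ — the convention implemented
verbatim, with the sample standard deviation ($n-1$ denominator, 0 for a
singleton) and the fixed divisor 10 regardless of bin occupancy.

**Group contrasts** (`group_compare()`, e.g. housekeeping- versus
non-housekeeping-associated links, or constitutive versus tissue-specific
links from `classify_constitutive()`): the groupwise valley depth is
`mean(control) - mean(observed)` and the difference between groups is
tested by permuting group labels over the per-link depletion values,
two-sided, again with the add-one correction. The between-group test is
this package's contract; it is the natural exchangeable-label null for
the quantity reported.

## Methylation and prediction

`window_correlation()` scans the genome in non-overlapping windows
(default 500 kb), averages each signal per window, and correlates across
windows; it accepts any two of feature track, CpG methylation track, and
genetic map (as a rate signal). `quantile_rate_profile()` assigns each
link the unweighted mean CpG level over its span (links spanning no CpG
are dropped), bins links into methylation quantiles — ties collapse into
the lowest applicable quantile — and reports per-quantile mean and sd of
the rate.

`train_rate_predictor()` fits a random forest (500 trees) of interval
rate on the feature table from `interval_feature_table()`: chromosome (a
categorical adjustment, entered as a factor), interval length, the
fraction of the interval covered by each link type's merged spans, mean
methylation, and optionally hotspot density (hotspots are consumed as
published interval calls and counted by midpoint containment, never
detected). Skill is evaluated by chromosome-stratified cross-validation —
folds are whole chromosomes assigned round-robin, so prediction is always
on unseen chromosomes; plain row folds when chromosomes are fewer than
folds — and reported as Pearson r and MSE of pooled out-of-fold
predictions. Whether to evaluate in-sample or by cross-validation was an
open choice; cross-validation is the defensible one and is the package's
default. Forest hyperparameters beyond the tree count pass through to
`randomForest` (`nodesize`, `mtry`, ...).

`depletion_recapitulation()` asks how much of the observed link-versus-
control rate difference a predictor reproduces:
`(mean pred control - mean pred link) / (mean obs control - mean obs link)`,
reported raw plus clipped to $[0,1]$, and flagged undefined when the
observed difference is zero.

## The synthetic generator

`make_scenario()` builds every input the pipeline consumes, with known
ground truth. The landscape is piecewise constant: baseline 1 cM/Mb,
multiplied by 0.5 inside planted "valley" domains and by 10 inside 2-kb
hotspots (5 per Mb); effects multiply where they overlap. The reference
`planted_valley` conditions are 2 chromosomes of 20 Mb, markers every
500 bp, 40 non-overlapping domains of 100–400 kb, and 400 1-bp-anchor
links at 10–600 kb distances, 90% of which lie fully inside a domain.
CTCF motifs are planted outside domains, mirroring the analysis of
CTCF-uninterrupted link sets (a flag plants interrupting motifs for
filter tests).

Matching tracks are moving-average-smoothed Gaussian fields scaled into
realistic ranges (GC 0.45 ± 0.06, CpG density 0.02 ± 0.008, ...). The
smoothing window is 300 kb: GC and CpG landscapes are autocorrelated at
the isochore scale of hundreds of kb, and this is what makes
feature-matching at tolerance 0.01 a meaningful exercise rather than a
lottery.

Methylation is coupled to the *locally smoothed* rate: the level at each
CpG is an affine map of the standardized rate smoothed over the
methylation-domain scale (100 kb by default), mixed with an independent
random field of the same correlation length carrying the residual
variance, plus iid noise, clipped to $[0,1]$. Matching the correlation
lengths of signal and noise is deliberate: window averaging then shrinks
both components equally, so the correlation measured on 500-kb windows
stays near the configured coupling. Coupling to the raw per-CpG rate
would instead let the hotspot spikes average away while the noise field
does not, and the window-level correlation would be badly attenuated —
a scale mismatch, not a property of the biology being emulated.

The `null` preset sets the valley multiplier to 1 *and* places links
uniformly. With no rate effect, forcing 90% of links into 40 shared
domains would leave the marginal rates untouched but make ~9 links share
each domain's local landscape; the paired differences would then be
strongly clustered, and the paired test — whose null assumes independent
pairs — would reject far too often. That is a dependence artefact of
co-location, not a recombination effect, so the rate-null condition is
uniform placement. (The `planted_valley` preset keeps the clustering,
which is the mechanism under study; its significance is assessed against
that same clustered placement, where the planted effect is overwhelming.)

What the generator does **not** emulate: linkage disequilibrium and
coalescent noise in map estimation, variable marker density (the real
reason short-range estimates are unstable), sequence composition (no
FASTA), chromosome-scale rate gradients, or bimodal CpG methylation.
Passing tests on synthetic data therefore demonstrate the correctness and
calibration of the *machinery*, not the robustness of the biological
conclusion to map-estimation artefacts.

## Numerical choices and degenerate inputs

* Uncovered bedGraph bases count as 0 in bin averages (densities are zero
  where absent), with `uncovered = "missing"` to treat them as NA instead.
* Deterministic tie-breaks everywhere a choice is arbitrary:
  best-per-target ties resolve to the shorter link then the leftmost
  anchor; top-fraction thresholding orders by score, then distance, then
  position.
* Pruning (`prune_overlapping()`) is greedy by ascending p with a 1-kb
  anchor-exclusion radius; the output is stable under re-application.
* Random shifts (`shift_links()`, defaults 1–5 kb, signed-uniform) move
  both anchors by the same offset, preserving span length and distance
  class; offsets are clipped at chromosome ends.
* Degenerate inputs are flagged, not guessed at: empty distance classes
  are skipped; a constant prediction target yields an undefined-flag
  correlation with MSE still reported; fully masked intervals yield NA
  with a flag; a zero observed difference makes recapitulation undefined.
* Every stochastic stage of the pipeline driver derives its own seed
  deterministically from the single global seed.

## Problem sizes

The test suite exercises the reference 2 × 20 Mb conditions for the
planted-effect and matching checks, scaled-down 2 × 5 Mb scenarios for
unit tests, 200 replicates for null calibration, 10,000 permutations for
the headline significance run, and 2,000 training intervals for predictor
checks. These sizes were chosen so the full validation runs comfortably
on a laptop while keeping every Monte-Carlo margin wide relative to its
acceptance band.

## Limitations

The paired signed-rank test assumes independent pairs; when links cluster
heavily in shared domains its p values overstate significance (see the
null-preset discussion above) — the permutation-median test is the more
robust of the two procedures in that regime, and both are reported.
Feature matching is only as good as the supplied tracks; the rejection
sampler degrades to length matching (with a warning) when none are given.
The k-d tree index is rebuilt per session (external pointers are not
serializable). Genome-scale candidate enumeration requires subsampling.
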