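---
title: "Radiation hybrid mapping with rhmapper: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Radiation hybrid mapping with rhmapper: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`rhmapper` implements the full analysis chain for radiation hybrid (RH)
mapping with high-density SNP arrays: genotype calling from raw
intensities, two-point linkage and group construction, multipoint
ordering against an assembly prior, robust-map extraction from an MCMC
posterior over orders, genetic validation of marker orders in half-sib
families, placement of unmapped SNPs and scaffolds, and an analytic
model of panel resolution. This vignette explains the models behind
each stage, the assumptions of the synthetic-data generator that stands
in for real genotyping data, and the numerical and design choices a
maintainer should know about.

## The breakage–retention model

An RH panel is a set of hybrid clones, each retaining a random
collection of donor-chromosome fragments produced by irradiation. The
working model throughout the package is the standard haploid
equal-retention model:

* breaks occur along a chromosome as a Poisson process with rate one
  break per 100 centiRays (cR), so the probability of at least one
  break between two points `d` cR apart is `theta = 1 - exp(-d/100)`;
* each resulting fragment is retained independently with a single
  panel-wide probability `r`;
* a marker is observed "present" in a clone exactly when its fragment
  was retained (a genotyping-error emission probability `eps` exists in
  the model but defaults to 0, since the calling stage is designed to
  emit unknowns rather than wrong calls).

Physical distance enters through the panel's resolution parameter in
Kb/cR. The defaults used across the package are the two pig panels as
re-estimated at high marker density — 90 clones each at 8.6 Kb/cR
(IMpRH, the lower-resolution panel) and 5.3 Kb/cR (IMNpRH2) — with
retention defaulting to 0.30; published per-chromosome retention
fractions for these panels live in supplementary material we do not
reproduce, so `retention` is an explicit, configurable parameter in the
range 0.2–0.35 rather than an asserted constant.

Two markers separated by breakage probability `theta` then have
clone-wise joint probabilities

```
P(1,1) = r(1-theta) + r^2 theta
P(1,0) = P(0,1) = r theta (1-r)
P(0,0) = (1-r)(1-theta) + (1-r)^2 theta
```

`two_point()` maximises this likelihood numerically over the unit
square and reports `LOD = log10 L(theta_hat, r_hat) - log10 L(1, r_1)`,
where `r_1` is the retention MLE under independence. Linkage groups
(`build_linkage_groups()`) join pairs reaching LOD 6 in every panel on
which both markers are typed and keep connected components of size
greater than 10; smaller components and singletons are reported as
unlinked rather than silently dropped.

## Multipoint likelihood and comparative ordering

For an ordered set of markers, each clone follows a two-state hidden
Markov chain over fragment retention with initial distribution
`(1-r, r)` and transitions

```
P(0->0) = (1-theta_k) + theta_k (1-r)     P(0->1) = theta_k r
P(1->0) = theta_k (1-r)                   P(1->1) = (1-theta_k) + theta_k r
```

for interval `k`. Missing calls are marginalised by the forward
algorithm. `multipoint_loglik()` fits the per-interval `theta_k` and
the panel-wide `r` by EM (forward–backward expected break counts and
expected retained new-fragment draws), declaring convergence when the
log-likelihood gain drops below `1e-6`; `theta` is kept inside
`[1e-6, 1 - 1e-6]` to avoid log singularities. The chain is an
independence-jump process with stationary distribution `(1-r, r)` and
is therefore reversible: an order and its reversal have identical
likelihood, so orders are treated as equivalence classes under
reversal, and emitted maps are oriented so the first marker has the
smaller reference position. Interval lengths accumulate as
`d_cR = -100 log(1 - theta_hat)`. The EM and forward pass are compiled
(Rcpp): ordering searches and MCMC evaluate the profile likelihood tens
of thousands of times, and the package's test oracles re-derive the
same quantities independently in R by brute-force enumeration of all
`2^m` hidden paths on small instances.

Because a draft assembly already proposes an order, ordering is scored
by a comparative criterion:

```
score(order) = sum_panels loglik(order) - lambda * breakpoints(order, reference)
```

where `breakpoints` counts adjacent pairs of the candidate order that
are not adjacent (in either orientation) in the reference. Where the RH
data are informative they can pay for deviations from the prior; where
they are not, the assembly order is kept. The penalty weight defaults
to `lambda = 3 log(10)` — a LOD-3-equivalent cost per breakpoint,
i.e. a deviation must improve the data likelihood 1000-fold per broken
adjacency — because the original analysis delegated this weighting to
an external mapping engine without stating a value; `lambda` is an
explicit argument everywhere, `lambda = 0` recovers the pure RH
criterion, and large `lambda` provably freezes the prior order.
`order_search()` improves the initial (reference) order with segment
reversals (2-opt) and relocations of segments of length 1–3 (Or-opt)
until no move improves the score; on instances small enough to
enumerate (six markers and fewer) the search attains the exhaustive
optimum, which is how it is tested.

## Robust maps from an order posterior

`mcmc_orders()` samples orders from the target density proportional to
`exp(score)` by Metropolis–Hastings with a symmetric proposal mixture:
adjacent transposition (probability 0.4), random segment reversal
(0.3), and relocation of a random segment of length at most 3 (0.3,
with the identity insertion allowed so the move is exactly symmetric).
The default budget is 5000 iterations with 1000 discarded as burn-in,
and every post-burn-in state is recorded without thinning. Since whole-
order reversal is itself a proposal and leaves the target invariant,
each recorded sample is canonicalised to the orientation aligned with
the reference before storage; pairwise precedence frequencies
`q_ij` (`pair_agreement()`) are computed on these canonical samples and
satisfy `q_ij + q_ji = 1` exactly.

`extract_robust()` mirrors framework-map construction: while any
retained pair has `max(q_ij, q_ji)` below the support threshold `eta`
(default 0.95, exposed as an argument), the marker involved in the most
weakly-supported pairs is removed; ties are broken by the lower summed
two-point LOD to the marker's current consensus neighbours, then by
name for determinism. The consensus order of the survivors is their
Copeland ranking (number of pairs won at `q >= 0.5`), and the output
carries a re-checked certificate that every retained pair meets `eta`.
The exact elimination rule and threshold are this package's own
concrete realisation of the published robust-map idea, whose reference
implementation's defaults are not documented; on synthetic data it
removes precisely the markers that are genuinely unorderable (e.g.
co-located duplicates) and retains well-spaced markers in the true
order.

## Genetic validation in half-sib families

The genetic data consist of many small half-sib families — one
genotyped sire, two or more offspring, each from a different,
ungenotyped dam — so only paternal meioses are informative. At a
sire-heterozygous marker an offspring homozygote fixes the paternal
allele; an offspring heterozygote is ambiguous (the dam allele is
unknown) and treated as missing rather than imputed from population
frequencies, a conservative choice that avoids modelling dam allele
frequencies. With biallelic SNPs at allele frequency 0.5 this makes
roughly a quarter of sites informative per meiosis.

Crossovers are counted by minimum-recombinant phasing. We solve the
phasing exactly rather than by alternating heuristics: the sire phase
over the family's informative sites is chosen to minimise the total
number of grandparental-origin switches summed over offspring, via a
dynamic program whose state is the vector of current offspring origins
(`2^n_offspring` states — trivial for half-sib families). An earlier
iterative implementation (per-offspring path updates alternating with
per-site majority votes) could lock into inconsistent frames and
produce spurious crossovers; the exact DP cannot, and it guarantees the
parsimony bound that the true phase is always a feasible solution, so a
family's detected total never exceeds its true crossover count. Two
consequences are worth knowing. First, within a family the attribution
of a switch to a particular offspring can be genuinely ambiguous (with
two offspring, a relative switch could belong to either); totals and
interval profiles are well defined, per-meiosis attributions are not
always. Second, parsimony undercounts: crossovers outside a meiosis's
informative span are censored, and two crossovers in different
offspring within a sparsely informative stretch can cancel. At 500
markers on a 1-Morgan chromosome the detected length is ~95 cM from 728
meioses; at 100 markers it is substantially lower. Comparisons between
two orders on the same data (`compare_orders()`) are paired and
unaffected by this shared bias — the order needing fewer recombination
events is the more parsimonious, which is the validation logic used
against corrupted assemblies.

Each detected crossover's probability mass is spread uniformly over the
map intervals between its two flanking informative sites, giving
per-interval recombination rates; genetic length is
`100 * total mass / n_meioses` cM. Mendelian inconsistencies
(offspring allele absent from a homozygous sire) are logged and
excluded site-wise.

## Placement of unmapped SNPs and scaffolds

The similarity score between an unmapped SNP (uSNP) and a mapped SNP
counts clones retaining both, forms the 1-df chi-square of the 2x2
presence/absence table over jointly observed clones (no continuity
correction), and reports `S = -log10(p)`. Scoring is one-sided: only
co-retention above expectation is evidence of proximity, so negative
associations and degenerate margins score 0 (an alternative
single-cell test of the (present, present) count is available behind
`method = "match"`; the full-table statistic is the default). An
empirical null (`empirical_null()`, 1000 resamples by default) takes a
mapped SNP and its maximum score against a wrong chromosome;
assignment uses the lower-resolution panel and requires exactly one
chromosome at or above the threshold — 5 is supported by the null but
admits multiple assignments, 7 yields unique ones, and both are
ordinary arguments. The RH position on the assigned chromosome is the
score-weighted barycenter of the two best-scoring mapped neighbours on
the higher-resolution panel, and the assembly position comes from a
monotone piecewise-cubic (Hyman) spline of bp on cR fitted through the
mapped SNPs after reduction to a longest increasing subsequence —
a non-monotone fit would locally invert coordinates. Predictions are
clamped to `[1, chromosome length]`; queries outside the fitted range
use the terminal slope and are flagged as extrapolated.

Scaffolds inherit the placements of their SNPs: minority chromosomes
are dropped when a strict majority exists (otherwise the scaffold is
unresolved), the scaffold interval spans the surviving predictions, and
cross-validation against a comparative-homology table yields the 5-way
classification — `discordant`, `noinfo` (not alignable to the
reference organism), `nosynt` (no homologous region on this genome),
`valid` (same chromosome within 1 Mb) and `sscvalid` (same chromosome,
further). Coordinates are 1-based inclusive in TSV outputs and 0-based
half-open in BED exports.

## Panel resolution

Under three idealisations — true order, even spacing, error-free
vectors — two markers `d` Kb apart on a panel with resolution `c`
Kb/cR and retention `r` are separated in one clone when a break falls
between them and exactly one fragment is retained, so across panels

```
P(separated) = 1 - prod_panels (1 - 2 r (1-r) (1 - exp(-(d/c)/100)))^N
```

This reconstruction (the original supplementary derivation is not in
the main text we implement from) is validated in the test suite against
Monte-Carlo simulation from the package's own generative process over a
grid of `(d, r, c)`, and at survey scale — 41,729 markers over 2.45 Gb
of autosomes, two 90-clone panels — it gives an expected
distinct-position fraction of 99.8–99.9% across `r` in 0.2–0.35,
consistent with the published theoretical value of 99.7%.
`design_tradeoff()` evaluates `n * P(G/n)` over a grid of array sizes:
with the default panels about 246K of 1M genotyped markers are
expected mappable, against 94K of 100K — the strong diminishing return
that argues against very large arrays for RH mapping.
`count_distinct_positions()` and `observed_distinct_fraction()` apply
the corresponding empirical counters to fitted maps; positions within
`1e-3` cR are treated as equal because the EM bounds `theta` away from
zero, so truly unseparated markers sit a vanishing but nonzero distance
apart.

## What the synthetic data do and do not emulate

The generator reproduces the statistical structure the analysis
assumes: an exact Poisson fragment process (exponential inter-break
distances in cR) with independent per-fragment retention — so the
multipoint model is correctly specified and parameter recovery is a
fair test — marker-level two-cluster log-normal intensities with
SNP-specific multiplicative shifts, a configurable intermediate-zone
overlap fraction, designed hamster cross-hybridizers and genomic
control failures, Poisson crossovers in sire meioses with unphased
diploid offspring genotypes and never-emitted dams, and assembly orders
corrupted by the three observed error classes (single-marker
misplacement, segment relocation, default end-placement), every edit
logged. Intensity clusters are truncated to their calling regions, so
with zero overlap the fixed thresholds recover the truth exactly — that
property anchors the end-to-end calling tests.

Deliberately not emulated: the X chromosome (single-copy in male-DNA
panels, plus the selection-locus retention peak near HPRT), per-clone
or per-region retention heterogeneity, array batch effects, linked
dams, and genotyping error in family data. Passing tests therefore
demonstrate correctness of the algorithms under the stated model, not
robustness to these real-data effects; the calling thresholds in
particular are fixed constants tuned to the original experiment's
intensity scale, not adaptive estimates.

## Numerical choices and problem sizes

* All intensity-threshold comparisons are strict (`<`, `>`); values at
  a cutoff fall into the missing zone. The missing-call filter is
  "more than 10 of 180", scaled as `ceiling(10/180 * n)` for other
  panel sizes and recorded in the report.
* `theta` and `r` are optimised within `[1e-6, 1 - 1e-6]`; two-point
  fits use alternating golden-section search, the multipoint EM stops
  at a `1e-6` log-likelihood gain.
* MCMC records every post-burn-in iteration; scores are cached per
  order equivalence class, so revisited orders cost nothing.
* Elimination and DP ties are broken deterministically (lower
  neighbour LOD, then lexicographic; first-found optimum in the
  phasing DP), making every pipeline stage reproducible from a single
  master seed (`derive_seed()` keeps derived seeds under 2^31).
* Test and acceptance problem sizes are chosen to make Monte-Carlo
  bands meaningful on one CPU: 90-clone panels throughout; 10,000-clone
  pairs (5 replicates) for two-point recovery; 30 markers x 12–16
  replicates for map-length calibration; 50 replicates of the
  100-marker / 728-meiosis order comparison; a 3 x 360-marker panel at
  ~50 Kb spacing for hold-out placement; 250–300 Monte-Carlo draws per
  point for the resolution oracle. Where a single stochastic draw would
  make a calibration check a coin flip (map length at 90 clones has a
  ~5% relative SD), the check averages independent replicates instead
  of widening the band.

## Known limitations

Genotype calling is fixed-threshold by design and does not separate
clone, SNP and array effects; the robust-map elimination is greedy, not
globally optimal; minimum-recombinant counting undercounts crossovers
at realistic marker informativeness (quantified above); placement
assumes the mapped SNPs' own positions are correct and its error rates
on synthetic data (wrong chromosome and >1 Mb errors both well under
10%) should be read as a lower bound on real-data error; and the
resolution formula inherits its three idealisations, which is why the
observed distinct fraction on real maps is expected to fall below the
theoretical one.
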