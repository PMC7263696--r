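---
title: "Models and methods behind RecScreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind RecScreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(RecScreen)
```

This vignette is the package's own account of the statistics it
implements: the growth model behind the fluctuation analysis, the
scoring rules of the replica-pinning track, what the simulator does and
does not emulate, and the numerical and design choices that were
genuinely open.

## The Luria–Delbrück model

A culture (or pinned colony) grows clonally from `n0` to `nf` cells.
Recombination events occur at a constant per-cell rate `mu` during
growth, so the expected number of *events* per clone is
`m = mu * (nf - n0)`. Each event happens while the population is still
expanding; under deterministic exponential growth with events uniform
over the population increase, the clone founded by one event reaches a
final size with the classical law P(size ≥ k) = 1/k, implemented as
`min(nf, floor(1/u))` with `u ~ Uniform(0,1]`. The resulting count of
recombinant *cells* at sampling time is heavy-tailed: most clones carry
few recombinants, occasional early events produce "jackpots" that
dominate the mean. Assumptions, deliberately classical: no phenotypic
lag, no fitness difference between recombinants and parents, no
reversion, no cell death. Nothing in the plate data constrains these,
and the median-based estimator below is the standard partner of exactly
this model.

The probability mass function is computed with the Ma–Sandri–Sarkar
recursion,

$$p_0 = e^{-m}, \qquad
  p_r = \frac{m}{r}\sum_{i=0}^{r-1}\frac{p_i}{r-i+1},$$

which is numerically stable (all terms positive) and costs
O(r_max²); evaluating it to r_max = 500 takes milliseconds.

```{r pmf}
round(ldPmf(2, 8), 4)
```

## Rate estimation by the method of the median

Plate counts are first normalised to recombinants per `norm_cells`
(default 10⁷) viable cells using the plating design — culture volume,
per-plate fold-dilutions and plated volumes. With the default design (a
4 ml culture; 200 µl of a 10²-fold dilution on selective medium; 100 µl
of a 10⁵-fold dilution on permissive medium) the normalisation reduces
to `5000 * sel / perm`.

The per-10⁷ convention matters: the sample median of the normalised
counts is treated as the median count of a pseudo-culture of 10⁷ cells,
the Lea–Coulson median equation

$$\frac{r_{med}}{m} - \ln m = 1.24$$

is solved for `m`, and the rate is `m / 1e7`. The left-hand side is
strictly decreasing in `m`, so the root is unique; `leaCoulsonM()`
brackets it on [10⁻⁹, 10⁶] with bisection (`uniroot`, tolerance 10⁻¹²)
and polishes with a few guarded Newton steps. Tie-breaks and degenerate
inputs: the even-sample median is the mean of the central pair
(conventional sample median); a zero or negative median returns `NA`
rather than throwing, so one dead strain cannot abort a batch; cultures
with zero permissive-plate colonies are dropped with a warning (no
viable-count estimate exists for them), and a test in which every
culture is dropped is an error.

Jackpot handling. A culture is operationally a jackpot when its
normalised count exceeds half of `norm_cells` — i.e. when a majority of
plated cells are recombinant, which is what "all colonies had a
recombination event" looks like in count space. When more than half the
cultures of a test are jackpots the estimate is flagged
`indeterminate`; this is a parameter (`jackpot_ceiling`), not a claim
about the underlying biology.

Hit triage is two-stage, mirroring screen practice: a first-pass rate
cutoff (default 2×10⁻⁵, about twice the wild-type rate) discards weak
candidates cheaply, then repeated fluctuation tests are compared to the
wild-type replicate rates with a one-sided *pooled-variance* Student's
t-test at P < 0.05 — pooled rather than Welch because the procedure
being reproduced is the plain Student's test.

## Scoring the replica-pinning screen

Colony measurements arrive as a plain table: plate, grid position,
strain, medium, area (pixels), circularity (the 4π·area/perimeter²
convention, consumed as given — the package never touches images).
Scoring applies, in order:

1. **Artifact filter**: keep circularity strictly greater than 0.8.
2. **Permissive ("total") scoring**: a colony counts when its area
   strictly exceeds 50% of the mean area of circularity-passing
   permissive colonies *on the same plate*. The plate-level mean is a
   design decision: the published wording does not fix the scope of
   "the mean pixel area", and plate-wise normalisation is how
   colony-array pipelines absorb plate-to-plate growth effects.
3. **Selective ("recombinant") scoring**: a selective colony counts
   when its *position-paired* permissive colony was scored and its area
   strictly exceeds 10% of its strain's mean scored permissive area.
   Pairing is the second open choice made here: without it the
   recombinant/total ratio has no ceiling, whereas paired scoring
   guarantees frequencies in [0, 1], matching hit tables that top out
   at 100%.
4. **Exclusions**: strains with fewer than 10 scored permissive
   colonies are excluded (too little data), as are strains on a
   configurable exclusion list (the deletion-collection strains
   carrying a secondary *msh3* mutation); list-excluded strains keep
   their frequency for distribution analysis but never enter hit
   calling.
5. **Classification**: frequency ≥ 0.87 is hyper-recombinant, ≤ 0.33
   recombination-deficient. The cutoffs are configuration — they come
   from an external cutoff-selection analysis of the ranked screen, not
   from this package.

All area and circularity thresholds are strict inequalities, following
the "greater than" wording they implement. The two serial selective
pinnings of the wet protocol are modelled as producing the single final
selective scan.

## The simulator

`simulateScreen()` is the package's synthetic-data generator and the
test bed for everything downstream. Per colony:

1. recombinants accumulate during colony growth under the LD model with
   `m = rate * cells_per_colony`;
2. pinning moves `round(transfer_fraction * cells_per_colony)` cells,
   drawn without replacement, so transferred recombinants are exactly
   hypergeometric (binomial is indistinguishable at the default
   transfer fraction but fails the sanity identity that moving *all*
   cells moves all recombinants);
3. a colony is positive if at least one recombinant transfers, and
   otherwise with `background_positive_prob`;
4. areas and circularities are drawn from truncated-normal measurement
   models, with configurable pinning-failure (2%) and low-circularity
   artifact (3%) channels.

Strains are laid out as 2×2 quadruplicate blocks in a 32×48 (1536
position) array replicated across `replicates/4` plates, and the output
is byte-identical given the seed.

Calibration, stated as the package's own choice: `cells_per_colony`
defaults to 10⁷ (a grown colony) and `transfer_fraction` to 5×10⁻⁴
(≈5000 cells per pin). With the background channel at 0.21 — the
frequency a recombination-dead strain actually scores, which only a
background channel can produce — a wild-type rate of 1.14×10⁻⁵ then
yields a simulated recombinant frequency near 0.49, inside the
0.46–0.56 band observed for wild type at pilot and screen scale. A
nominal transfer fraction of order 10⁻² cannot be reconciled with that
band: at m ≈ 114 events per colony the median recombinant load is
several hundred cells, and transferring 2% of the colony would make
virtually every pin positive. These constants parameterise plausibility,
not robot physics.

What the generator emulates: the rate → frequency link and its
saturation, jackpot dispersion, pin-transfer subsampling, background
positives, quadruplicate layout, measurement noise, pinning failures,
and fluctuation-test plating (binomial subsampling of culture and
recombinant populations per the design's dilutions). What it does not:
spatial plate effects (edge growth, neighbour competition), correlated
failures, plate-scan segmentation artifacts beyond a circularity score,
and any strain-to-strain variation not encoded in `strain_rates`.
Passing tests therefore validate the *arithmetic and the estimators*
under the assumed statistical structure, not the behaviour of a
physical screen.

## Problem sizes and numerical checks

The test suite exercises, among others: 10⁵-draw Monte-Carlo agreement
of simulated clones with the recursion (p₀ within 3 standard errors of
e⁻ᵐ for m ∈ {0.1, 1, 4, 10}); recovery of a wild-type-scale rate
(1.14×10⁻⁵) by the median method from 1000 simulated 5-culture tests
(within 2-fold) and from 100-culture tests (within 25%) — cultures of
10⁷ cells with a plating design scaled so both plates give countable
colonies; agreement of the median method with a censored
maximum-likelihood grid oracle built on the same recursion (within 30%
for m ∈ [2, 15]); calibration of the simulator's background (±0.02 of
0.21 over 3000 colonies) and wild-type band (0.40–0.60); exact
hand-computed scoring on toy plates; and exact agreement of the
hypergeometric overlap with exhaustive enumeration for universes of up
to 12 genes. These sizes were chosen so the full suite runs in about
two minutes on a laptop core while keeping Monte-Carlo error well below
each tolerance.

## Known limitations

* Absolute rates depend on the per-10⁷ normalisation convention; when
  cultures are much larger than 10⁷ cells the median-method estimate
  carries a modest upward bias relative to the per-cell truth (the
  pseudo-culture convention), which is why recovery experiments
  simulate cultures at the normalisation scale.
* The estimator offers no confidence intervals and no corrections for
  plating efficiency, phenotypic lag, or recombinant fitness; the
  maximum-likelihood machinery appears only as a test oracle.
* The exclusion list for *msh3*-carrying strains and the per-strain
  screen frequency tables are supplementary data distributed
  externally; the package ships the main hit tables only, and the
  distribution-level checks that need the supplementary tables run
  only when the user supplies them.
* Cutoff discovery, GO/network enrichment and ortholog lookup are
  consumed as inputs (configuration and fixture tables), never
  recomputed.
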