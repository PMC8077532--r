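---
title: "Scoring fish chronotypes and comparing them across a phylogeny"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring fish chronotypes and comparing them across a phylogeny}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`chronofish` implements a complete path from raw per-frame tracking tables
to species-level rest–activity chronotypes and phylogenetically corrected
comparisons. This vignette explains the models and procedures, the
parameters that matter, the numerical choices, and what the synthetic-data
tests do and do not establish about real recordings.

## The behavioral model

A recording is a sequence of 2-D centroid positions at a fixed frame rate
(default 15 frames s⁻¹), calibrated to arena centimetres. The scoring model
has three layers:

1. **Speed.** Each inter-frame interval gets a speed: Euclidean
   displacement divided by the frame interval. Centroid jitter from the
   tracker inflates speeds slightly; an optional centred moving-median
   smoother (`compute_speed(smooth_width = )`) is provided but **off by
   default**, because commercial-tracker smoothing settings vary between
   laboratories and an unsmoothed series is the most reproducible baseline.
2. **Activity classification.** An interval is active swimming iff its
   speed **strictly exceeds** the threshold (default 4 cm s⁻¹, chosen to
   cancel passive drift). The boundary case — exactly 4 cm s⁻¹ — is
   inactive. The threshold is configurable; raising it can only move time
   from "active" to "inactive", so total activity is non-increasing and
   total rest non-decreasing in the threshold (a property the test suite
   checks).
3. **Rest bouts.** A rest bout is a maximal run of inactive intervals whose
   summed duration is **strictly greater than** 60 s; a run of exactly
   60.000 s is not a bout. At 15 frames s⁻¹ that means 900 consecutive
   inactive intervals are not a bout and 901 are. Durations are computed as
   counts divided by the frame rate rather than accumulated floating-point
   sums, so the boundary is exact.

**Tracking gaps.** Fish are lost by trackers, and fabricated stillness is
the main hazard for rest scoring. Dropouts of at most `max_gap = 2` s are
filled by linear interpolation of position; anything longer yields
intervals that are *undefined* — neither active nor inactive — and
undefined intervals break rest runs. A long dropout therefore can never
masquerade as a rest bout, at the cost of slightly undercounting rest when
a fish genuinely rested through a dropout.

**Units of "total activity".** Hourly profile figures in the chronobiology
literature often leave activity units unstated. We interpret total
locomotor activity as *distance travelled during active intervals* (cm per
24 h): it is the integral of the measured velocity over active time, uses
no additional free parameter, and makes waking velocity (mean active-interval
speed) and total activity jointly interpretable. Callers preferring
active-time can integrate `active * dt` from the returned speed series; the
per-interval series is always exposed.

## Circadian metrics

Hourly profiles accumulate per-interval amounts into zeitgeber-aligned 1 h
bins, wrapping modulo 24 (ZT0 = lights-on; the laboratory convention of a
14 h:10 h cycle with recordings beginning at ZT3 is the default). A
recording that starts mid-hour covers its first and last ZT bins partially;
bins are therefore normalised by the recording time they actually contain,
reporting per-hour *rates*. Dropping partial bins instead would discard up
to two hours of a 24 h record; normalisation keeps them comparable.

Day and night summaries are **means, not sums**, over phase bins — with a
14 h day and a 10 h night, sums would bias any day/night comparison by the
phase-length ratio. The activity change ratio

$$A_R = \frac{D - N}{D + N}$$

is dimensionless, scale-invariant (the same animal measured in different
units has the same ratio), antisymmetric under phase exchange, and bounded
in [−1, 1]; it is undefined (reported `NA`, never 0) when an animal showed
no activity at all. Per-species one-sample t-tests of per-animal ratios
against 0 flag significant rhythmicity.

Rest bouts are apportioned to phases *proportionally to overlap*, not
assigned to their start phase: long bouts straddling lights-off would
otherwise systematically credit the phase in which sleep began. Phase rest
rates (min h⁻¹) re-multiplied by phase coverage recover total rest exactly
(a conservation property in the tests).

For constant-darkness recordings the same machinery runs against
*subjective* phase labels inherited from the prior entrained cycle;
`subjective_day_night()` labels its output accordingly, and
`day_night_means()` refuses a constant-dark photoperiod so the two analyses
cannot be conflated silently.

Shelter occupancy is the fraction of non-missing frames whose centroid
lies in the zone, overall and per phase. No dwell-time hysteresis is
applied: occupancy estimates time-in-shelter, not visit counts, and
centroid-in-zone is the assumption-free estimator of that quantity.

## The statistical battery

One-way ANOVAs compare species; Levene's median (Brown–Forsythe) test
checks variance homogeneity; two-way layouts (e.g. species × phase) use
Type II sums of squares — the paperless choice for mildly unbalanced animal
cohorts — with planned cell contrasts adjusted by the Šidák formula
$p_{adj} = 1-(1-p)^m$ over the $m$ comparisons actually requested.

The **nested ANOVA** deserves a note. To test a two-level lineage contrast
(e.g. rock-dwelling *mbuna* vs non-*mbuna*) the correct error stratum is
among-species-within-lineage, not the residual: species, not individual
fish, are the units of replication for a lineage-level claim. With $s$
species the test has $(1, s-2)$ degrees of freedom — 11 species give
$F_{1,9}$ — however many fish were measured. Both a species-means variant
(default) and an individual-level variant forming the same mean-square
ratio are provided; they agree on the F statistic construction and differ
only in how species means are weighted when cohort sizes differ.

Degenerate inputs are handled explicitly: identical values in every group
report $F = 0$, $p = 1$ (no variation to attribute) rather than a 0/0.

## Phylogenetic comparative methods

Species values (per-species means of per-animal metrics) are not
independent: closely related species share history. The package implements
the standard Gaussian machinery directly on the phylogenetic covariance
matrix **V**, whose (i, j) entry is the root-to-MRCA path length and whose
diagonal holds root-to-tip depths. `phylo_vcv()` accumulates each edge's
length over its descendant-tip block in one postorder sweep; the test suite
verifies it against an independent implementation on random trees,
including polytomies.

**Pagel's λ** scales the off-diagonal (shared-history) entries, leaving tip
variances unchanged — for ultrametric trees this is exactly equivalent to
multiplying internal branches by λ. λ = 1 keeps the Brownian structure;
λ = 0 is a star phylogeny, under which every method here collapses to its
non-phylogenetic counterpart (PGLS = OLS exactly; the simulation ANOVA's p
converges to the classical p — both tested).

**PGLS.** For fixed λ, coefficients come from generalized least squares
under λ-transformed **V** via a Cholesky whitening; the profile
log-likelihood is the exact multivariate-normal ML (σ² profiled out as
RSS/n). λ̂ maximises the profile likelihood over [0, 1] by bounded 1-D
optimisation (`optimize`, tolerance 1e-8), with both endpoints evaluated
explicitly so boundary maxima (common at λ = 0 or 1 with few taxa) are
never missed by the interior search. Coefficient standard errors use the
unbiased scale RSS/(n − p). R² is 1 − RSS/RSS₀ against the intercept-only
GLS fit at the same λ. Singular (PSD but rank-deficient) covariances from
zero-length branches fall back to an eigendecomposition square root with a
1e-12 ridge on the log-determinant.

**Size correction.** Eye area scales allometrically with body size; raw
area is square-root transformed to linearise it against standard length,
and the PGLS residuals of √area on length are the "residual eye areas"
carried into downstream regressions (against total rest and against the
activity change ratio). Measurements must be positive; violations are
reported by taxon.

**Simulation ANOVA (pANOVA).** Group effects on a trait are tested by
comparing the observed one-way F with F statistics computed on traits
simulated under Brownian motion on the tree. The simulation rate and root
are the ML estimates under BM from the observed trait (GLS mean as root,
mean squared whitened deviation as rate) — the convention of the
simulation-ANOVA literature, adopted because the procedure is then fully
determined by the data and tree. The p-value uses the add-one correction
$p = (1 + \#\{F^{null} \ge F^{obs}\})/(1 + n_{sims})$, so it is never
exactly zero at finite simulation counts; with $n_{sims} = 199$ the test
has exact 5% size under the null, which the acceptance suite confirms
empirically (500 experiments). A constant trait short-circuits to
$F = 0, p = 1$.

**Taxon substitution.** Data taxa absent from the tree can be attached at
the tips of close relatives (`substitute_taxa`), renaming the tips and
inheriting their branch lengths unchanged. This is appropriate when the
containing clade is well supported with short internal branches — the
substituted tip's covariance with every other taxon is then nearly
identical to the true position's — and is the user's scientific judgement
to make; the function only guarantees the bookkeeping (injective mapping,
exactly the mapped labels changed).

## The synthetic-data generator

The generator exists so that every stage is testable against known ground
truth without video. It emulates the study design it targets: 24 h
recordings at 15 frames s⁻¹ beginning at ZT3 under a 14 h:10 h cycle, in a
30 × 20 cm arena (the scale of a partitioned 10 l tank).

Behaviour is a two-state alternating-renewal process. Rest bouts are
exponential above a 20 s minimum (mean 120 s by default) — so plenty of
sub-61 s inactivity exists to exercise the strict bout threshold — and swim
bouts are exponential with phase-specific means chosen so the per-phase
swim fractions $a_{day} = c(1 + A)$, $a_{night} = c(1 - A)$ hit a target
activity change ratio $A$ at a target overall rest fraction (the constant
$c$ solves the coverage-weighted mean). Infeasible combinations (a required
swim fraction above 1 — e.g. strong nocturnality with almost no rest, since
the night is only 10 h long) raise an error rather than silently clipping.

Swimming is a correlated random walk: lognormal per-frame speeds
(mean 8 cm s⁻¹, sd 3 — positive and right-skewed, as fish burst-and-glide
locomotion is; the mean must exceed the activity threshold or the spec is
rejected), headings evolving by Gaussian increments, and **reflective
arena boundaries implemented by triangle-wave folding** of the unbounded
cumulated path, which is exact for elastic reflection and fully
vectorisable. Ground truth (true bouts, active distance, waking velocity,
phase-wise activity, shelter occupancy) is recorded from the latent
noise-free path; Gaussian position noise and frame dropout are applied
afterwards, so scorer-vs-truth comparisons isolate the observation model.

Trees are unit-depth Yule trees; regression traits put Brownian structure
in the predictor and λ-transformed Brownian noise of known rate in the
response, so PGLS recovery tests have exactly known targets.

**What passing tests show — and don't.** Closed-loop tests (noise-free
generation scored within 1% of ground truth) validate the scoring
*definitions* and their implementation, and noise/dropout tests validate
the gap policy. They do not validate behaviour the generator does not
emulate: real centroid jitter is autocorrelated rather than white, fish
interact with walls and shelters rather than reflecting elastically, real
rest is consolidated non-exponentially, and lighting transitions produce
startle artefacts. Conclusions about real recordings still require the
usual per-laboratory checks (threshold sensitivity, tracker QC).

## Problem sizes and reproducibility

Every stochastic component takes an explicit seed, and the pipeline is a
pure function of (inputs, config, seed); fixture files are byte-stable
across runs. The shipped test and acceptance settings use the sizes at
which the checks are statistically meaningful yet quick: 1000 random flag
sequences against the exhaustive bout oracle, 200 PGLS replicates on a
30-tip tree, 500 pANOVA experiments at 199 simulations each, 10 000
Brownian replicates for moment matching. The full suite runs in about a
minute on one CPU.

## Known limitations

- Periodogram/free-running-period estimation is out of scope; the
  constant-dark analysis uses subjective phase labels only.
- The nested ANOVA supports exactly two lineage levels (the design it
  serves); deeper nesting is not implemented.
- PGLS assumes a complete trait table over the matched taxa; no missing
  data imputation.
- λ is searched on [0, 1] only; values above 1 (over-dispersed phylogenetic
  signal) are not considered, matching standard practice.
- The pANOVA estimates its simulation rate under λ = 1 Brownian motion; a
  strongly non-Brownian trait makes the null conservative or liberal in the
  usual ways.
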