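---
title: "Models and methods behind perisim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind perisim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(perisim)
```

This vignette is the package's own account of its models, defaults and the
design decisions taken where the field leaves choices open. Everything
quantitative stated here is computed by the test suite or by
`scripts/acceptance.R`; nothing is quoted from elsewhere.

## Coordinates, grids and the blind spot

All coordinates are degrees of visual angle in right-eye (OD) format:
positive x temporal, positive y superior. Left-eye (OS) data are mirrored
(x ↦ −x) at import so that a single normative model serves both eyes; the
mirror is an involution and preserves blind-spot flags. For field tables on
mirror-symmetric grids the sensitivity columns are re-matched to the
mirrored location order; asymmetric grids (such as the 24-2 with its nasal
extension) must record OS data anatomically, i.e. column *k* is the mirror
image of the OD grid's *k*-th location, and the mirror is then a pure
relabeling.

The built-in 24-2 grid has 54 locations on a 6°-spaced lattice offset by
3°, rows of 4/6/8/9 points mirrored about the horizontal meridian, with the
nasal rows at y = ±3 extending to −27°. The two locations at (15, ±3) fall
on the temporal blind spot; they are flagged, never tested, and excluded
from every statistic, which leaves the 52 analyzed locations that all
deviation and progression analyses operate on.

## The Voronoi layer

Irregular grids are first-class citizens: tile geometry and the neighbor
graph never assume a lattice. Each location's tile is obtained by clipping
a convex boundary polygon against the perpendicular-bisector half-plane of
every other location (Sutherland–Hodgman clipping, O(n²)); cells are convex
and satisfy the defining property that every interior point is nearer its
generator than any other (verified by random probing — 1000 probes, zero
tolerated violations). The default clip boundary is the convex hull of the
locations dilated outward by half the median nearest-neighbor distance, so
edge locations get finite tiles; degenerate (collinear) grids fall back to
a dilated bounding box. Two locations are adjacent when their tiles share
an edge of positive length (detected as polygon edges lying on the pair's
bisector, tolerance 10⁻⁷ on coordinates of order 10, minimum shared length
10⁻⁹). This adjacency drives both the growth pattern and normative
smoothing.

## The simulated observer

The frequency-of-seeing (FoS) model is a cumulative Gaussian in dB:

P(seen | level *l*, threshold *t*) = fp + (1 − fp − fn) Φ((t − l)/σ).

A Gaussian FoS in dB is the standard simulation choice in perimetry; the
spread σ is constant by default (1 dB in the study conditions used by the
tests) — real observers show σ growing in damaged regions, which can be
emulated by building observers with larger `fos_sd`. Response times are
Gaussian (mean 400 ms, sd 60 ms) truncated to the response window; they
are reported but not analyzed. Out-of-range stimulus levels are clamped to
the machine's dynamic range (staircases legitimately ride the bounds) and
the response carries a `clamped` flag rather than an error.

The machine owns a single RNG stream seeded at `open_machine()`, isolated
from the global RNG and from the scheduler, so a full session is
bit-reproducible regardless of what the procedure layer does.

## Threshold procedures

**ZEST.** The state is a discrete probability mass function over the dB
domain (default 0–40 dB in 1-dB steps). The next stimulus is the posterior
mean rounded to the domain grid (QUEST's posterior mode is available via
`rule = "mode"`); each response multiplies the pmf by the likelihood
`prob_seen(level, t, likelihood_sd, fp_l, fn_l)` (or its complement) and
renormalizes. Defaults: likelihood spread 1.5 dB with 3% guess and lapse
rates baked into the likelihood asymptotes; stopping when the pmf standard
deviation falls below 1.5 dB, bounded to 4–25 presentations (a fixed-count
rule is available by setting `stop_sd = 0`). The prior is the bimodal
mixture 0.3·G(0, 5) + 0.7·G(peak, 5): the 0-dB component models damaged
locations, the other sits at the expected normal sensitivity. None of
these constants is forced by theory; they follow common perimetric ZEST
practice and are all configurable. The sequential posterior is identical
(to 10⁻¹²) to the brute-force normalized product of prior and per-trial
likelihoods, checked exhaustively for all 64 response sequences of length
6 on a 9-level domain.

**4-2 staircase.** Seen moves dimmer, not-seen brighter; the step is 4 dB
up to and including the move made at the first response reversal and 2 dB
afterwards; the second reversal terminates with the midpoint of the
last-seen / last-not-seen pair (the terminal estimate is not standardized
anywhere; the midpoint is symmetric and exactly testable). A level pinned
at a range bound on two consecutive presentations terminates with the
bound and a `pinned` flag. The implementation is verified against an
independently coded tracer on all 2⁶ response prefixes.

**Full Threshold.** One 4-2 staircase; if the estimate lands 4 dB or more
from the start, a second staircase starts at the first estimate and its
result is returned.

**MOCS.** Levels × repetitions in a seeded shuffled order; the FoS curve is
fit by maximizing the Bernoulli likelihood over (t, σ) with σ bounded to
[0.1, 20] dB (L-BFGS-B, initialized at the interpolated 50% crossing).
Non-convergence falls back to the interpolated crossing with
`converged = FALSE`; records that are all-seen or all-missed are rejected
with advice to widen the level range.

## Whole-field orchestration

Growth waves are breadth-first distances from the seed locations over the
Voronoi adjacency (24-2 default seeds: the four primary points (±9, ±9)).
A location opens once **at least one** adjacent lower-wave location has
finished (configurable to "all"; "any" keeps tests short), and its prior's
normal peak is the inverse-distance-weighted mean of finished neighbors'
estimates — with no finished neighbor it falls back to a supplied normal
guess or the domain midpoint. Blind-spot locations are treated as finished
from the start: they are never presented, contribute no estimates, and do
not block their neighbors. Each presentation picks uniformly at random
among open unfinished locations from a scheduler stream seeded separately
from the machine stream, so presentation order and responses are
independently reproducible. Catch trials are not inserted; in simulation
the record's fpr/fnr fields carry the observer's configured rates.

## Normative models and deviation maps

Per location, ordinary least squares of sensitivity on age gives the
age-expected normal value; total deviation is the departure from it. TD
cutoffs at the 0.5/1/2/5% levels are empirical quantiles (R's
linear-interpolation convention) of the cohort's TD residuals —
distribution-free by design. Pattern deviation subtracts the general
height, defined as the 85th percentile of TD over non-blind-spot
locations; PD cutoffs are quantiles of the general-height-corrected cohort
residuals. A value is flagged when it falls **strictly below** a cutoff;
ties go to the less pathological category. Mean deviation weights default
to inverse residual variance (uniform when any location's variance
degenerates to zero, and available by flag). The `"smooth"` fitting method
shrinks each location's residual sd and cutoffs toward its Voronoi
neighbors (self weight 0.5, neighbors sharing 0.5 equally) — a
re-specification of classical normative-value smoothing that extends
naturally to irregular grids; it is exactly the identity when dispersion
is spatially homogeneous.

The probability levels {0.5, 1, 2, 5}% and the report palette (red,
orange, green, blue borders from most to least significant) are package
conventions, stable across releases.

## Progression: PLR and PoPLR

Per location, OLS of TD (default; raw sensitivity behind `use =
"sensitivity"`) on years since the first visit; the p-value is the lower
tail of t with m − 2 degrees of freedom (alternative: negative slope).
Series with raw residual MAD (no consistency constant) above 2 dB are
flagged as highly variable. Degenerate zero-residual series get p = 0.5
when the slope is 0 and p underflowed to 10⁻³⁰⁰ (kept positive) for an
exact decline.

PoPLR combines the p-values as S = Σ −ln max(p, 10⁻⁶) and recomputes S
under random permutations of the visit order — one shared permutation per
draw across locations, preserving each field's spatial structure; dates
stay fixed. The combined p-value is (1 + #{S_perm ≥ S_obs})/(N + 1), which
is super-uniform under the null by construction; N defaults to 5000,
sampled with replacement from the permutation group and capped with a
warning at m! for short series. The permutation loop uses a hand-vectorized
matrix OLS (the design depends only on the fixed dates, so its
pseudo-inverse is computed once); tests pin this path to `lm()` at 10⁻¹⁰.

## Synthetic data: what it does and does not emulate

Healthy cohorts follow sensitivity = H0 − k·ecc − γ·(age − 45) + subject
offset + noise, clamped to the dB range after noise (mimicking a device's
reporting floor). Defaults H0 = 33 dB, k = 0.25 dB/degree, γ = 0.06
dB/year, between-subject sd τ = 1 dB, test-retest sd σ_w = 1.5 dB are
realistic orders of magnitude for white-on-white perimetry in healthy
adults and were fixed once as the package's study conditions. Series add
per-location linear slopes, a shared per-visit fluctuation, and
measurement noise. The generators deliberately satisfy the assumptions of
the analysis modules (linear age effect, independent residuals), which is
what makes exact-level calibration checks meaningful — and equally means
that passing them does **not** demonstrate robustness to real-data
features they omit: learning and fatigue effects, floor-induced
non-Gaussian variability in damaged fields, spatially correlated defects,
eccentricity-dependent variability (available but off by default), or
media opacities.

## Problem sizes and numerical choices

The verification suite uses sizes chosen to make Monte-Carlo bands tight
enough to be meaningful while keeping a full run in minutes on one core:
1000 ZEST runs for accuracy (mean |error| ≤ 2 dB), 200 stable + 100
progressing series at 500 permutations each for PoPLR calibration
(rejection at α = 0.05 within [2%, 9%], power strictly higher), cohorts of
n = 200 for slope recovery (≥ 90% CI coverage) with 500 held-out fields
for flag-rate calibration ([2.5%, 8%] at the 5% level), 100 replicate
full-field examinations for the end-to-end loop (mean |error| ≤ 2.5 dB),
and 1000 Voronoi probes. Tolerances elsewhere: pmf normalization 10⁻¹²,
tile disjointness/area closure 10⁻⁹/10⁻⁶, bisector detection 10⁻⁷.

## Known limitations

Planar degrees are assumed throughout — no map projection for very
peripheral angles, where a tile's Euclidean geometry distorts. Temporal
(flicker) and kinetic stimuli exist as types but have no simulation
backend. There is no catch-trial logic, fixation monitoring, or binocular
scheduling. The growth pattern conditions each prior on the weighted mean
of finished neighbors; conditioning on full neighbor posteriors would
propagate uncertainty but is not implemented. CSV serialization quantizes
dB values to two decimals by design (bit-exact round trips of
human-readable files).
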