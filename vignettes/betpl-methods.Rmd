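---
title: "Methods: step-length inference for olfactory-cued navigation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: step-length inference for olfactory-cued navigation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(betpl)
```

## The model

Pelagic seabirds that navigate by wind-borne odors are predicted to fly in
near-unidirectional segments whose lengths $l$ follow a bi-exponentially
truncated power law (BETPL):

$$p(l) = N\, l^{-\mu}\, e^{-\lambda_1 l}\, e^{-\lambda_2 / l},
\qquad \mathrm{lim}_a \le l \le l_{\max},$$

with a universal exponent $\mu = 3/2$ and truncation parameters tied to the
turbulent odor environment: $\lambda_1 \propto 1/T$ (where $T$ is the odor
autocorrelation timescale) and $\lambda_2 \propto T\, c_\tau^2 / C^2$ (where
$c_\tau$ is the detection threshold and $C$ the mean odor concentration).
Because $T$ and $C$ depend on wind speed, the two truncation parameters are
wind-dependent while $\mu$ is not. This package implements the full chain
needed to confront that prediction with GPS tracking data, and a synthetic
cohort generator so every stage can be exercised without external data.

## Step extraction

Trajectories (10-minute GPS fixes) are projected to a local plane with an
azimuthal-equidistant projection about the trajectory centroid — distances
from the center are preserved exactly on the sphere, and pairwise distances
within the ≲1000 km span of a foraging trip are preserved to well under 1%.
Steps are extracted by the axis-projection method: the track (optionally
rotated by $\theta \in \{0, 15, 30, 45\}^\circ$ to break any alignment with
a preferred travel direction) is projected on the x and y axes, direction
reversals of each 1-D series mark turning points, and the 1-D distances
between consecutive turning points from both axes are pooled. Zero
displacements never count as reversals — direction is carried across
stationary runs so that GPS jitter at rest does not fragment steps. Gaps
longer than 60 minutes split a trip into separately processed pieces, and a
configurable 1-km radius filter removes nest-attendance fixes.

Two properties of this estimator matter for interpretation:

* it preserves the tail exponent of power-law walks (the test suite refits
  $\mu = 2$ within $\pm 0.1$ on a $10^4$-step walk), **but**
* it distorts the distribution near the generative small-scale cutoff
  (same-sign 1-D displacements merge), so the goodness-of-fit scan tends to
  place $\mathrm{lim}_a$ *above* the generative cutoff rather than at it.
  The robustly recovered quantity is $\lambda_1$; exponent estimates from
  single short trips are biased low, and converge to $3/2$ only as samples
  grow — mirroring the convergence-with-displacement behaviour the method
  is designed to exhibit.

## Grid likelihood, mean-likelihood estimates, intervals

The BETPL likelihood factorizes through three sufficient statistics
($\sum \log l_i$, $\sum l_i$, $\sum 1/l_i$), so the whole cost of a grid
evaluation is the normalization integral at each node. That integral is
computed with a Gauss–Legendre rule in $\log l$ (200 nodes; machine
precision against adaptive quadrature across the grid corners), evaluated
for all $(\lambda_1, \lambda_2)$ at once as one matrix product per $\mu$
slab. Slab-wise evaluation bounds memory and is numerically identical to a
monolithic evaluation. The reference grids are $\mu \in [1,3]$ step 0.01,
$\lambda_1 \in (0, 0.2]$ step 0.002, $\lambda_2 \in (0,3]$ step 0.005, and
a fixed-$\mu$ mode pinning $\mu = 3/2$ with both lambda steps refined to
0.0005; grids are open at zero (first node one step above), and fits whose
argmax touches the upper bounds are flagged boundary-limited.

Because the likelihood surface is strongly skewed, the estimator of record
is the *mean likelihood*: the likelihood-weighted mean of each parameter
under a flat prior over the grid, with 95% bounds from the 2.5/97.5
percentiles of each parameter's marginal normalized likelihood. The grid
argmax is reported alongside. A `coarsen` factor multiplies all grid steps
for large-cohort runs; the refinement test checks that halving steps moves
estimates by less than one original step.

## Goodness of fit and parametrization selection

Candidate parametrizations (18 $\mathrm{lim}_a$ values × 4 rotations) are
ranked by a uniform-sensitivity Kolmogorov–Smirnov statistic,
$\max |S(l)-P(l)| / \sqrt{P(1-P)}$, which equalizes sensitivity between the
bulk and the tails. The selected candidate minimizes the statistic among
sufficient samples (≥ 30 steps by default), with a deterministic tie-break:
larger sample, then smaller $\mathrm{lim}_a$, then smaller $\theta$.
Scanning fits run in the same mode (free or fixed $\mu$) as the downstream
analysis. A parametric-bootstrap p-value for the statistic is available but
off by default — selection, not significance, is its role here.

## Alternative families and model comparison

Five alternatives are fitted by maximum likelihood on the truncated
support: single exponential, bi-exponential mixture, pure power law, power
law with upper truncation only, and a BETPL+exponential mixture.
Multi-parameter families use bounded quasi-Newton optimization with
jittered restarts and nested warm starts, so the likelihood ordering
powerlaw ≤ upper-truncated ≤ BETPL ≤ BETPL+exponential holds on any common
sample. The mixture weight is constrained to $[0.05, 1]$: the upper end is
the meaningful pure-BETPL limit (only a vanishing BETPL component is a
degeneracy), and fits at any bound are flagged.

Each family gets its own GoF scan over $(\mathrm{lim}_a, \theta)$ and those
rows are reported for audit. The family *verdict*, however, is computed on
a common sample (the BETPL-selected candidate): log-likelihoods of samples
with different sizes are not comparable — a difference of five steps moves
AIC by an order of magnitude more than any real between-family difference
does, and in null experiments that artifact mis-assigned a fifth to a third
of exponential walks. On the common sample, the BETPL enters the AIC
comparison with its continuous maximum likelihood (the grid remains the
estimator of record for parameters; a coarse grid must not handicap the
family against continuously optimized alternatives). Measured on
step-resolved synthetic walks this assigns ≥ 95% of exponential-null
trajectories to the exponential family and BETPL walks to the BETPL.
At a 10-minute cadence and a few hundred steps, BETPL and bi-exponential
walks become hard to separate — a resolution limitation to bear in mind
with real short trips.

## Wind

Wind grids (0.5°, 6-hourly, 10 m) are stored as u/v component arrays;
components — not speeds — are interpolated trilinearly (speed interpolation
is biased low near direction shear), and speed is taken as the magnitude of
the interpolated vector. Per-trip summaries report the arithmetic mean,
root-mean-square and cubic-mean speeds (gust-weighted alternatives; the
power-mean ordering is asserted in tests). Head/cross-wind components are
resolved against the bearing to the next fix, with head² + cross² equal to
speed² by construction. Supported dialects are a long-format CSV and the
in-memory array constructor; both yield identical summaries. No NetCDF
reader ships because no NetCDF interface package is available in the
package's dependency set; the CSV dialect carries the same content.

## Hypothesis tests

Trips surviving the scan (and, when model comparison is run, supported for
the BETPL) enter ordinary least-squares regressions of $\log \lambda$ on
$\log \bar v$, with slope CI, per-point 95% confidence and prediction
bands, and outlier flags; trip-duration subsetting (> 4 days by default,
{2..6} available) mirrors the headline analysis. $\lambda_2$ regressions
default to fixed-$\mu$ estimates, which are markedly more precise; free-$\mu$
results are reported alongside. Exponent universality is probed two ways:
a Pearson correlation of $\hat\mu$ with mean wind, and the mean squared
error of $\hat\mu$ about $3/2$ in cumulative displacement subsets with a
Kendall trend statistic. Covariates (sex, period; region only when not
confounded with wind by a two-sample t-test) are screened as
interaction-only and interaction+main-effect extensions of the reference
model, reported when ΔAIC ≤ 4.

## The synthetic cohort generator

Two trajectory generators exist. `gen_betpl_walk()` draws BETPL step
lengths directly (headings uniform or von Mises about a target bearing) —
useful for validating estimators against known truth. The mechanistic
generator `gen_odor_walk()` contains no step-length distribution at all: it
simulates the odor-contact process. On acquiring the olfactory map (signal
at the detection threshold $c_\tau$), the signal decays at the mean
dilution rate $C/T$ while fluctuating with turbulent diffusivity $C^2/T$;
the map is lost when the signal is exhausted. Contact durations are then
first-passage times of a drift-diffusion process, and the three BETPL
features *emerge*: $\tau^{-3/2}$ in the intermediate range, an exponential
long-duration cutoff $1/(4T)$ from the drift, and a short-duration
suppression $e^{-\tau_2/\tau}$ with $\tau_2 = T c_\tau^2 / (4 C^2)$ from
the diffusive barrier. A mean-reverting concentration process crossed at a
symmetric threshold was evaluated first and rejected: its excursion
statistics do not produce the short-scale suppression (the fitted
$\lambda_2$ scaled the wrong way with $c_\tau/C$), whereas the
acquisition-at-threshold / loss-at-exhaustion structure reproduces all
three scalings — the acceptance script measures the log-log slopes within
a few hundredths of the predicted $-1$, $+1$, $+1$. The simulation step is
$dt = \min(T/100,\; T (c_\tau/C)^2/32)$ — the short-passage scale must be
resolved, and a Brownian-bridge correction catches within-step boundary
crossings. Lost phases last $T/20$ on average (re-acquisition is fast
relative to decorrelation), flown at the same speed with a fresh uniform
heading, so they contribute small-scale steps that the $\mathrm{lim}_a$
scan discards. Segments shorter than $2\,dt$ are discretization artefacts
and are dropped from fitted samples.

Cohorts couple the signal parameters to a per-trip wind speed
$U \sim \mathrm{Uniform}(2, 12)$ m/s. The correlation time follows
$T(U) = T_{\mathrm{ref}} (U/U_{\mathrm{ref}})^{3/2}$ with
$T_{\mathrm{ref}} = 1125$ s at $U_{\mathrm{ref}} = 6$ m/s, so
$\lambda_1 \propto U^{-3/2}$ — the sign and size of the empirically
observed wind dependence (the theory fixes only $\lambda_1 \propto 1/T$,
not the direction of $T(U)$; a naive $T \propto 1/U$ would give a positive
wind slope, contradicting the observed negative one, so the generator
encodes the observed dependence). Mean concentration follows the
wind-driven flux heuristic $C \propto U^{\gamma-1}$ with $\gamma = 2.1$
(inside the reported 2–3 range), giving
$\lambda_2 \propto U^{3/2 - 2(\gamma-1)} = U^{-0.7}$. Trip durations draw
from 2–8 days, flight speed is 40 km/h, fixes every 10 minutes. Wind grids
give each trip its own time window at its own mean speed, modulated by a
smooth ±3% spatial pattern with a slowly wandering direction, so that the
along-track mean closes on the generative $U$ within 5%. All randomness
descends from one master seed through named substreams; regeneration is
bitwise reproducible.

What the generator does *not* emulate: behavioural modes unrelated to
navigation (rest on water, area-restricted search), position error,
heterogeneous per-bird flight speeds, and spatially structured wind within
a trip. Passing pipeline tests on these cohorts therefore demonstrates
estimator correctness and statistical power under the model's own
assumptions, not robustness to every feature of real tracking data.

## Numerical choices and problem sizes

Normalizations are memoized through shared quadrature nodes per sample
support; CDFs use dense log-spaced tabulation (8192 points, ~1e-7
accuracy); sampling inverts the tabulated CDF. Tests and the acceptance
script scale the study down to run on one CPU in minutes: coarsened grids
(steps × 2–8) for multi-fit loops, 3–6 candidate parametrizations in
cohort scans, cohorts of 60 trips for the regression power checks, 100
replicates at n = 5000 for interval coverage, 16–20 trajectories for
model-discrimination rates, and pooled samples of ~20,000 segments for the
emergent-exponent check. The full reference grids stay the defaults for
single-trajectory analysis.

## Known limitations

* $\lambda_2$ sits below the 10-minute GPS resolution for realistic flight
  speeds; its recovery through the full pipeline is noisy (the raw-segment
  scaling suite is where the $\lambda_2$ predictions are sharply testable).
* Marginal-percentile intervals undercover modestly when samples come from
  the axis projection of a single walk (pooled 1-D steps are not
  independent draws); coverage is nominal on i.i.d. samples.
* The scan's selected $\mathrm{lim}_a$ is an analysis choice, not an
  estimate of a physical cutoff.
* Model discrimination at a 10-minute cadence needs several hundred steps
  per trip; below that, BETPL vs bi-exponential verdicts are unstable.
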