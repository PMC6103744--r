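---
title: "Models and methods behind flynav"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind flynav}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flynav)
```

# The scientific problem

Walking fruit flies locate attractive odor sources with two distinct,
separable behavioral programs. While odor is present they run upwind,
faster and straighter (the **ON response**); when odor is lost they slow
down and turn sharply, producing a local search (the **OFF response**).
Upwind orientation needs wind direction information from the antennae;
the gait changes are driven by odor alone. `flynav` implements
phenomenological models of these two responses, a stochastic navigation
agent built on them, the trajectory-analysis conventions of the walking
assay, and the synthetic stimuli and plume environments needed to exercise
everything without recorded data.

# The ON and OFF response functions

Both channels start from **adaptive compression**. Odor concentration
(normalized so 1.0 is the strongest delivered stimulus, a 10% apple cider
vinegar dilution) passes through a Hill nonlinearity with exponent 1 whose
half-maximum point is pushed rightward by a slowly integrated odor
history \(A\):

\[
\tau_A \frac{dA}{dt} = \mathrm{odor}(t) - A(t), \qquad
C(t) = \frac{\mathrm{odor}(t)}{\mathrm{odor}(t) + \kappa_d + A(t)} .
\]

The baseline \(\kappa_d = 0.01\) (normalized units) comes from Hill fits to
dose-response data and is held fixed during all response-model fits. The
ON drive is a first-order low-pass of \(C\)
(\(\tau_{ON} \frac{d\,ON}{dt} = C - ON\)); the OFF drive is the rectified
difference of a slow and a fast low-pass of \(C\)
(\(OFF = \max(0, R_2 - R_1)\)), which responds only to decreases from a
previously higher level. Four variants are provided — ACF, FAC, CF, FC —
crossing stage order (compression first or filtering first) with the
presence or absence of adaptation. The reference fitted parameters are in
`response_param_table()`; the ACF rows
(\(\tau_{ON} = 0.72\) s, \(\tau_A = 9.8\) s for ON;
\(\tau_{fast} = 0.62\) s, \(\tau_{slow} = 4.84\) s, \(\tau_A = 10.08\) s for
OFF) are the ones the navigation model uses.

**Stage order in the filter-first variants.** The equations for FAC are
not uniquely determined by its name; here the filter is applied to the raw
odor and the adaptation state is likewise driven by the raw odor, so that
adaptation tracks the stimulus identically in both stage orders. This is a
documented modelling choice, kept deliberately simple.

**Integration.** All state equations advance by forward Euler at
\(\Delta t = 20\) ms, matching the behavioral sampling rate; the recursion
is \(y_i = y_{i-1} + (\Delta t/\tau)(x_{i-1} - y_{i-1})\) from zero initial
state (trials begin after a long odor-free period, so 0 is the resting
state). Halving the step changes reference-model outputs by well under 1%.
One sharp corner is worth stating: at the fastest fitted constant of any
variant combined with the top of the deliverable stimulus band
(\(\tau = 0.3\) s, 1 Hz), the Euler gain deviates from the analog
first-order response by about 2.6%, slightly more than at the reference
constants (where agreement is within 2%). The tests therefore check the
simulation against the exact discrete-time gain at that corner and against
the analog formula elsewhere.

# Fitting

`fit_response_model()` minimizes the pooled sum of squared residuals
across all stimulus/target pairs jointly, using bounded
Levenberg-Marquardt least squares (`minpack.lm::nls.lm`, tolerances
1e-12, up to 400 iterations) with multi-start: additional starts perturb
the initial guess by log-uniform multiplicative factors (default within
4-fold). The OFF filter's fast < slow ordering is enforced structurally by
fitting \(\tau_{fast}\) and the positive increment
\(\tau_{slow} - \tau_{fast}\). The additive baseline of a behavioral trace
defaults to the pre-stimulus mean of that target (upwind velocity and turn
probability both have nonzero resting values) and can instead be co-fitted.
`fit_hill()` fits \(R(c) = b + R_{max} c^n / (c^n + \kappa_d^n)\) the same
way and refuses flat or under-determined inputs.

For the per-cycle modulation analysis of frequency-sweep responses,
cycle boundaries are local minima (ascending sweeps) or maxima
(descending) of the stimulus after smoothing with a 0.5-s moving average —
the extremum type is prescribed by the analysis convention, the detector
is ours. The jackknife standard error over leave-one-group-out estimates
\(\bar x_i\) uses the standard form
\(SE = \sqrt{\tfrac{n-1}{n}\sum_i (\bar x_i - m)^2}\) with \(m\) the mean
of the estimates, which reduces exactly to \(|\bar x_1 - \bar x_2|/2\) for
two estimates.

# The navigation agent

Ground speed and turn probability are modulated by the ON and OFF
functions:

\[
v = \max(0,\; v_0 + \kappa_1 ON - \kappa_2 OFF), \qquad
P = \big[P_0 - \kappa_3 ON + \kappa_4 OFF\big]_0^1 ,
\]

with \(v_0 = 6\) mm/s and \(P_0 = 0.12\) per 20-ms sample. Heading changes
per sample sum four terms: a stochastic turn
\(\rho\,\mathrm{sign}(g)\,g^2/\sigma\,\Delta t\) with
\(g \sim N(0, \sigma)\), \(\sigma = 20\) deg/s and
\(\rho \sim \mathrm{Bernoulli}(P)\); an odor-gated upwind drive
\(\kappa_5\, ON \sin\psi\) (deg/sample); a constant weak downwind drive
\(-\kappa_6 \sin\psi\); and optionally a bilateral term
\(\kappa_7 (C_L - C_R)\,\Delta t\). Here \(\psi\) is the wind angle in the
fly's frame, zero when heading upwind.

Three points deserve explanation:

* **Signed squaring.** Squaring a Gaussian draw produces the heavy-tailed
  angular-velocity distribution seen in flies but destroys the turn
  direction; we use \(\mathrm{sign}(g)\,g^2/\sigma\), which preserves
  sign, keeps units of deg/s, and has the intended kurtosis.
* **Units and the time step.** \(\kappa_5\) and \(\kappa_6\) are expressed
  per sample and the turn probability is a per-sample rate, both calibrated
  at 50 Hz; the random and bilateral terms are rates (deg/s) multiplied by
  \(\Delta t\). When stepping a 15-Hz plume movie, all per-sample
  quantities are rescaled by \(\Delta t / 0.02\) so rates per unit time are
  preserved — the baseline stochastic turn rate is 6 turns/s at either
  step size.
* **Sign convention for \(\psi\).** Verbal statements of the sign
  conventions for wind angle, turn direction and the upwind drive are easy
  to render mutually inconsistent; what is unambiguous is the *function*
  of each term. We define \(\psi = \mathrm{wrap}(\text{upwind} - H)\), under which
  \(+\kappa_5 ON \sin\psi\) makes \(\psi = 0\) (upwind) the stable fixed
  point of the deterministic dynamics and \(-\kappa_6\sin\psi\) stabilizes
  downwind, which is the behavior both terms must produce.

Bilateral sensing compresses the concentrations at the fly position (left)
and 0.74 mm perpendicular-right of the heading through the same adaptation
state, driven by the position odor. The offset is interpreted fly-centric.
Gains of 40 and 300 deg/s bracket the literature-derived and
high-performance regimes; a swap mode exchanges the antennae.

Positions integrate \(x \mathrel{+}= \Delta t\, v \cos H\),
\(y \mathrel{+}= \Delta t\, v \sin H\) (heading frame: 90 deg is upwind)
and are clamped to the domain edge with heading unchanged — the physical
arenas had walls and moats, and clamping is the simplest wall model.
Turn probability is clipped to \([0,1]\), since the linear rate equation
can transiently leave that range. `on_scale` and `off_scale` multiply the
two functions everywhere they appear (speed, turn probability, upwind
gating); applying them uniformly is a choice — applying them only in some
equations is equally consistent with the verbal model description. For
ensemble summaries the model's turn probability is reported as the rate
driving \(\rho\) (stored per sample in `turn_prob`), not re-extracted from
simulated trajectories; curvature-based extraction is reserved for data,
where the rate is unobservable.

# Trajectory pipeline

Raw 50-Hz tracking tables pass through: rejection of trials with gaps or
under 25 mm of total movement; resolution of head/tail ambiguity (tracker
orientation is only defined up to 180 deg) by segmenting the orientation
series at sudden ~180-degree jumps and giving each segment the branch that
best aligns with the direction of movement, stationary segments inheriting
the previous decision; zero-phase two-pole Butterworth filtering at 2.5 Hz
of coordinates and unwrapped orientation (zero-phase because the analysis
is offline and group delay would corrupt odor alignment; the filter is
applied with odd-reflection edge padding to suppress startup transients).
Gait parameters use central differences; curvature (angular velocity over
ground speed) and the 20 deg/mm turn indicator are defined only where
ground speed is at least 1 mm/s.

**Warping.** The odor front advects down the arena at 119 mm/s, so each
fly encounters it late by \((y_{inlet} - y)/119\) s. Samples during the
stimulus are shifted earlier by the delay at the fly's current position;
pre- and post-odor segments shift by the delay at the position held at
onset and offset. Re-gridding may skip or repeat single samples; the tail
of the record that receives no data is marked invalid.

**Exclusions.** Samples within 3 mm of the side walls and all samples
after the fly first reaches the upwind end are maskable; "reached the end"
is implemented as coming within 5 mm of the upwind wall (the exact
distance is not prescribed; 5 mm is about two body lengths).

**Statistics.** Period comparisons (before/during/after odor) use
two-sided paired Wilcoxon signed-rank tests via `stats::wilcox.test`:
exact for up to 25 nonzero paired differences, otherwise the
continuity-corrected normal approximation, with Bonferroni correction
(\(\alpha/3\)). Under the normal approximation, 500 uniformly positive
differences give \(p = 1.3\times10^{-83}\), the floor seen in large
simulated ensembles. Proportion comparisons use the pooled two-proportion
\(z\) test with two-sided normal p-values.

**Empirical D-functions** bin the signed per-sample heading change by
\(\psi\) (default 18 circular bins). The heading increment is the forward
difference: a centered difference mixes in the turn that *brought* the fly
to its current \(\psi\), which for stationary heading dynamics exactly
cancels the commanded drive and biases the curve toward zero.

# Synthetic data

**Arena environments** place the commanded stimulus waveform at the inlet
(upwind end) and advect it downwind as a pure delay, uniform across the
arena width; optional Gaussian widening of peaks with distance emulates
diffusion. **Plume-walk stimuli** sample a movie along a straight upwind
transect at 6 mm/s (the average walking pace), one sample per frame,
starting 8.9 cm lateral and 30 cm downwind. Note the default start sits
just outside the default 16-cm imaged width, as in the original recording
geometry; positions laterally outside the grid simply read zero
concentration, and only the downwind coordinate is bounds-checked.

**The synthetic plume** is a kinematic puff model, not a flow simulation:
Gaussian puffs released at a fixed rate advect downwind at 100 mm/s, widen
linearly with travel, dilute as the square of their width (2-d mass
conservation) with an additional e-folding amplitude decay, and ride a
slowly meandering centerline (an Ornstein-Uhlenbeck offset sampled at
release, growing from zero at the source). The movie is normalized so the
time-mean at the source pixel is exactly 1. This reproduces the structure
that matters to the navigation model — a centerline concentration maximum
decaying monotonically downwind, Gaussian time-averaged cross-sections
whose width grows linearly with distance, and intermittent exposure at the
edges — and is fully determined by its seed. What it does *not* reproduce:
realistic spectral content, filament fine structure, spatially correlated
velocity fluctuations, or any calibrated intermittency statistics; tests
passing on this plume show the navigation machinery responds correctly to
plume-like spatial statistics, not that performance numbers would transfer
to a measured plume. Geometry defaults (0.74 mm/pixel, 15 Hz, 240 s,
300 x 160 mm) mirror the imaging configuration; the test-suite and
examples rasterize coarser (~3 mm/pixel) and shorter (40-60 s) movies,
which leaves the generator's statistics unchanged.

**Synthetic behavior** simulates model flies in arena environments with
per-fly log-normal ON/OFF scale factors and writes raw tracking tables,
optionally corrupted with the tracker's characteristic artifacts: Gaussian
position jitter, spurious 180-degree orientation flips (overlapping flips
cancel, as a double tracker error would), and frozen-position bouts. The
tests use around 10 odor trials per fly, the order contributed by real
flies in a two-hour session; with fewer trials, per-fly means are too
noisy for the per-fly scale to be recovered cleanly.

# Evaluation

Success means entering a 2-cm radius of the source at any time (boundary
inclusive). Scale sweeps run a seeded ensemble per grid cell (cell \(i\)
uses seed + \(i\), so any cell is individually reproducible), over
`on_scale`, `off_scale`, the bilateral gain, or a common multiplier on the
wind-drive gains. Occupancy maps are proportions of total time per spatial
bin, log10-scaled with empty bins floored at one sample. Spatial ON/OFF
maps average the instantaneous function values per bin, which localizes
the ON response inside the plume and the OFF response at its edges.

On the bundled synthetic plume the qualitative orderings of the full model
hold robustly (roughly 150 trials per condition, 90-s trials at 15 Hz):
success is non-decreasing in the ON scale; a correct bilateral comparison
at gain 300 beats swapped antennae decisively; and zeroing the wind-drive
terms collapses success even with bilateral sensing intact. Absolute
success percentages measured with a recorded plume movie and real flies
depend on data that is not distributed; this package reproduces the
pipeline and its orderings, not those numbers.

# Problem sizes and determinism

Everything in the test-suite and acceptance script is desk-scale by
design: response-model fits run on six 70-s stimuli at 50 Hz (about 21,000
fitted points) in roughly a second; baseline-contract checks use 300
trials x 3,500 samples (about a million agent steps); plume ensembles use
150 trials of 90 s at 15 Hz per condition. Every stochastic component —
generators, ensembles, optimizer multi-starts — is seeded, and a fixed
seed reproduces results bit for bit.

# Known limitations

* The agent has no stop/start (moving-probability) dynamics, no turn-
  duration structure, and independent per-sample angular velocities; the
  matched quantity is the turn *rate*, not the angular-velocity
  distribution itself.
* Wind in every environment is spatially uniform and steady; local flow
  fluctuations that a turbulent plume would impose are absent, which tends
  to make wind a more reliable cue for the model than it would be in
  reality.
* Walls are modelled by position clamping; flies interacting with real
  walls and moats behave more richly, and wall-pinned stretches of
  simulated trajectories are effectively stationary to the gait analysis.
* The head/tail correction is a heuristic; orientation errors during
  purely stationary episodes are unrecoverable from movement information.
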