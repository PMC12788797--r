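---
title: "Methods: diffusion spectra, PAPA ratios and FRAP recovery from single-molecule tracking"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: diffusion spectra, PAPA ratios and FRAP recovery from single-molecule tracking}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(smtkit)
library(dplyr)
```

smtkit analyzes fast live-cell single-molecule tracking (SMT) of nuclear
proteins. Its central statistic is the **chromatin-bound fraction**: the
probability mass of the inferred diffusion-coefficient distribution below
0.1 µm²/s, interpreted as molecules tethered (directly or indirectly) to
chromatin. Around that core it implements the trajectory quality-control
filters used for fast SMT movies, cell-wise bootstrap errors, a three-scheme
variance decomposition, proximity-assisted photoactivation (PAPA) ratio
statistics, and a seven-step FRAP recovery analysis. Every stage is paired
with a synthetic-data generator with known ground truth, so the whole
pipeline is testable end to end without any external data.

## The observation model

A molecule in diffusive state with coefficient $D$ imaged at frame interval
$\Delta t$ (default 7.48 ms) and localized with Gaussian error
$\sigma_{loc}$ per coordinate produces 2-D frame-to-frame displacements
whose length $r$ follows a Rayleigh density

$$f(r) = \frac{r}{s^2} e^{-r^2 / 2 s^2}, \qquad
  s^2 = 2\,(D\,\Delta t + \sigma_{loc}^2),$$

so that $\mathbb{E}[r^2] = 4 (D \Delta t + \sigma_{loc}^2)$. Detection is
restricted to a finite axial slab (full depth 0.7 µm for HILO illumination):
molecules are observed only while $|z|$ is inside the slab, which censors
fast molecules and is the source of the defocalization bias discussed below.

The paper-grade acquisition parameters are the defaults throughout:
$\Delta t = 7.48$ ms, focal depth 0.7 µm, pixel size 0.16 µm,
tracking search radius 1.0 µm with no blinking tolerance
(`max_blinks = 0`). The localization precision of such setups is not a
published number here; we default $\sigma_{loc} = 0.03$ µm, a conventional
value for bright rhodamine dyes at these frame rates, and expose it as a
parameter everywhere.

## Trajectory quality control

Three filters are applied, in this order, by `filter_trajectories()`:

1. **Mask assignment** — only trajectories whose every localization falls
   inside one, and only one, nuclear mask are kept (`assign_to_masks()`).
2. **Dense-frame truncation** — if any frame of a cell's movie holds more
   than 6 localizations, frames are removed from the start of the movie up
   to the last offending frame (`truncate_dense_frames()`). Truncation is a
   strict prefix by design: tracking errors caused by a dense early burst
   contaminate linking, so everything before the burst ends is discarded.
3. **Minimum displacements** — cells with fewer than 100 frame-to-frame
   displacements after the first two filters are excluded
   (`filter_min_displacements()`).

The displacement count is taken after truncation because truncation changes
it; the chain is idempotent.

## Diffusion-spectrum inference

`infer_spectrum()` estimates occupations on a fixed log-spaced grid of
diffusion coefficients (default 100 points over $[0.01, 100]$ µm²/s, the
convention of published state-array tools). Trajectories are first split
into segments of at most `splitsize` jumps (default 3); each segment is
treated as drawn from a single grid state, with log-likelihood the sum of
its jump Rayleigh log-likelihoods. Occupations are then estimated by
expectation-maximization from a uniform start, making the procedure fully
deterministic. The published state-array method marginalizes over a grid of
localization errors with a full trajectory likelihood; we deliberately fix
$\sigma_{loc}$ and use per-jump Rayleigh likelihoods — simpler, much
cheaper, and adequate for the bound-fraction statistic, which integrates
over a broad region of the grid.

Two further choices deserve explanation.

**Segment-length stratification.** Under defocalization the state
composition of the data varies with segment length: fast molecules exit the
slab after a frame or two and leave mostly 1-jump segments, while bound
molecules produce full-length segments. A single occupation vector shared
across lengths is therefore misspecified, and its maximum-likelihood
compromise is dominated by the more informative long segments — on two-state
simulations this inflates the bound fraction by several percentage points.
We instead run the EM separately within each segment-length stratum (each
stratum's mixture is then correctly specified) and combine the stratum
spectra weighted by segment counts. On simulations this removes nearly all
of the length-compromise bias at no accuracy cost when defocalization is
absent (without it, length is independent of state and all strata estimate
the same mixture).

**Defocalization correction.** Fast molecules yield fewer observation units,
so raw occupations under-represent them. The correction divides occupations
by the probability that a 1-D Brownian particle, started uniformly in the
slab, survives absorbing boundaries for a residence time `dt_total`
(`defocalization_retention()`, an odd-term Fourier series truncated at
1e-10, clipped to $[10^{-6}, 1]$), then renormalizes. We set
`dt_total` to **one frame interval** by default: an observed jump requires
residence across one interval, and on simulations the measured segment
yields per molecule track the one-interval retention curve closely over the
data-supported range of $D$ — slab re-entry (which starts new trajectories)
and sub-`splitsize` segments almost exactly cancel the longer residence a
full segment would naively require. Correcting with the full segment
duration (`splitsize` intervals) over-corrects severely on the same
simulations, recovering ~0.20 for a true bound fraction of 0.30. The
correction remains an approximation: at very high $D$ (tens of µm²/s) the
continuous-time series underestimates discrete-frame retention, and the
yield curve depends mildly on the photobleaching rate. Both regimes are far
from where the bound-fraction mass sits.

The EM itself uses safeguarded SQUAREM acceleration: plain EM on fine grids
has an extremely long flat convergence tail; squared extrapolation along the
EM path cuts the sweep count by roughly an order of magnitude, and each
accelerated step is accepted only if it does not decrease the
log-likelihood, so the log-likelihood trace is non-decreasing and the fixed
point is unchanged. Convergence is declared at a relative log-likelihood
change below $10^{-8}$, with a cap of 1000 sweeps.

The **bound fraction** is the occupation mass strictly below 0.1 µm²/s
(`bound_fraction()`). The threshold is deliberately strict ("below"), and
the statistic is insensitive to its exact placement because the inferred
spectra are strongly bimodal around it.

As an independent cross-check, `two_state_jumplength_fit()` fits the
empirical jump-length CDF to a two-component Rayleigh mixture (the classic
kinetic-model analysis), with the bound component constrained to
$D \le 0.1$ µm²/s and the free component to $D \ge 0.15$ µm²/s for
identifiability, multi-started on a coarse lattice. Its
defocalization-corrected bound fraction agrees with the spectrum-based
estimate within 0.05 on two-state simulations.

## Resampling

`cellwise_bootstrap()` treats the cell as the unit of independence: each of
96 trials resamples n cells with replacement from the n-cell dataset, pools
their trajectories and re-evaluates the statistic; the 95% CI is the 2.5/97.5
percentile interval of the trials. `bootstrap_bound_fraction()` is a fast
path for the bound-fraction statistic: the per-segment likelihood matrix is
built once and each trial only reweights segments by cell multiplicities.
Trials warm-start from the full-data occupations and use a relative
log-likelihood tolerance of $10^{-6}$ — trial values feed a percentile CI
read at ~0.005 resolution, and on simulations the looser tolerance moves
trial values by far less than that. The point estimate is computed with the
same settings as `infer_spectrum()` and is identical to it.

`variance_decomposition()` quantifies variance sources without any model:
n jumps are drawn 1000 times (1) from the entire pool, (2) from one
uniformly chosen cell, or (3) from one uniformly chosen imaging day, and the
s.d. of the trial statistic is recorded per scheme and n. The pool curve
falls as $n^{-1/2}$; the cell and day curves plateau at the between-cell and
between-day spread. The trial statistic is injectable and defaults to the
mean jump length — the natural model-free summary of a jump pool.

## PAPA ratio statistics

In a PAPA acquisition only stroboscopic readout frames are saved; the saved
stream cycles through four 30-frame blocks — spontaneous readout, violet
(direct-reactivation) readout, a second spontaneous readout, and green
(proximity-reactivation) readout — repeated 5 times (600 saved frames).
`count_reactivations()` tallies each new trajectory to the phase of its
first localization. The per-cell **corrected G/V ratio** is
$(n_{green} - n_{spont2}) / (n_{violet} - n_{spont1})$ with negative
excesses floored at zero; a cell with zero violet excess has no
direct-reactivation signal to normalize against and is flagged missing.
Each cell is then normalized by the **aggregate** corrected ratio of the
same-day control cells (computed on pooled counts, not a mean of per-cell
ratios — robust to low-count cells). For example a cell with corrected G/V
0.36 on a day whose control aggregate is 0.26 has normalized ratio 1.4.

`papa_bootstrap()` resamples condition cells with replacement (control
aggregates stay fixed, matching the day-matched normalization), pools counts
within each day, normalizes day-wise, and combines days weighted by the
pooled violet excess. Because the control aggregate is held fixed, its own
sampling noise is not propagated into the CI; control pools should therefore
be comfortably larger than the condition CI width requires.

The PAPA count simulator draws Poisson tallies with rates
spont, spont + violet, and spont + control_ratio·violet + interaction·green,
scaled by a per-cell log-normal brightness factor. The `control_ratio` term
models the residual proximity-independent PAPA background of the dye pair
(so a non-interacting control sits at a non-zero corrected ratio, as real
SNAP-tag controls do), and the interaction-driven excess is exactly linear
in the `interaction` multiplier.

## FRAP analysis

`analyze_frap_movie()` runs the seven steps in order:

1. **Nuclear mask** — per-frame z-normalization, sum projection, Gaussian
   blur (σ = 2 px), isodata (intermeans) threshold, hole filling, largest
   connected component.
2. **Background subtraction** — each frame's median non-nuclear pixel value
   is subtracted from that frame.
3. **Photobleach correction** — pre-bleach frames are scaled so their
   in-mask sums equal the last pre-bleach frame's; post-bleach frames so
   theirs equal the first post-bleach frame's ("nuclear intensity" is the
   in-mask sum; with a fixed mask this is equivalent to the mean).
4. **FRAP(t)** — mean intensity in the bleach-spot disk, divided by its
   pre-bleach mean. Times are referenced to the bleach event, taken to occur
   one frame interval before the first post-bleach frame.
5. **Log-binned resampling** — 100 log-spaced bins from 0.01 s to the last
   time point; each non-empty bin contributes the arithmetic mean of its
   timestamps and values. This stops the long tail from dominating the fit.
6. **Gradient-smoothing test** — radial profiles (1 px annuli) of the first
   post-bleach frames, each min-max normalized; a maximum absolute change
   between successive normalized profiles above 0.1 flags diffusion-coupled
   recovery. The threshold is a package choice (no published quantitative
   criterion exists); it cleanly separates the simulator's reaction-dominant
   regime (uniform refill, change ≈ 0) from its diffusion regime (a
   relaxing Gaussian profile, change ≫ 0.1). `diffusion_timescale()`
   supports the same judgement analytically: molecules at D = 2 µm²/s cross
   a 0.75 µm spot in r²/4D ≈ 70 ms, far below typical first-frame delays,
   so diffusive recovery would be invisible anyway.
7. **Constrained fits** — `fit_single_exp()` fits
   $A(1 - e^{-\Delta t/\tau})$ with $A \in [0,1]$;
   `fit_double_exp()` fits
   $A_1 (1 - e^{-\Delta t/\tau_1}) + A_2 (1 - e^{-\Delta t/\tau_2})$ with
   $A_i \ge 0$, $A_1 + A_2 \le 1$ via the reparameterization
   $A_1 = Sp$, $A_2 = S(1-p)$, $S, p \in [0,1]$, reported with
   $\tau_1 \le \tau_2$. The amplitude-sum bound realizes the implicit
   constant term: recovery cannot exceed the pre-bleach plateau, and no
   additive offset is fitted. Both fits are multi-started from a fixed
   lattice (τ ∈ {0.1, 1, 10, 100} s crossed with amplitude splits), so they
   are deterministic; fits on unbinned curves are rejected by default.

## The synthetic-data generators

`simulate_smt_dataset()` emulates the acquisition: each molecule draws a
state once (no switching, matching the inference assumption), performs 3-D
Brownian steps of per-axis variance $2 D \Delta t$, is localized with
Gaussian error only while inside the axial slab, photobleaches with a
geometric lifetime (default mean 8 frames — typical of observed track
lengths in fast SMT), and photoactivates at a uniformly random frame.
Uniform activation mirrors the continuous 405 nm reactivation used in real
acquisitions and keeps per-frame localization counts in the realistic 0–6
range; were all molecules present from frame zero, the dense-frame
truncation filter would discard essentially the whole movie. Re-entry into
the slab starts a new trajectory id (there is no gap tolerance downstream).
Between-cell and between-day heterogeneity act on the bound-state weight
(defaults: cell s.d. 0.05, day s.d. 0.005 — cell-to-cell variability in
such data is roughly two orders of magnitude larger in variance than
day-to-day variability). Lateral positions reflect at the field-of-view
boundary and observed coordinates are clamped to it.

What the generator does **not** emulate: within-trajectory state switching,
camera noise statistics (EMCCD gain, read noise), detection/localization
from pixel data, anisotropic or anomalous diffusion, and chromatin-context
structure. Passing parameter-recovery tests on this generator therefore
demonstrates correctness of the estimators under the stated model, not
robustness to every artifact of real movies.

`simulate_frap_movie()` builds a disk nucleus at unit plateau intensity with
a circular bleach spot (default radius 0.75 µm) whose intensity drops by the
bleach depth (default 1: the intentional bleach pulse is saturating) and
recovers double-exponentially; total nuclear intensity is conserved by
debiting the refill uniformly from the rest of the nucleus, so the
photobleach-correction anchors see a constant nuclear sum as they would in
reality. Observational photobleaching is multiplicative per frame, the
background is a constant offset, and Gaussian pixel noise is added last.
The default frame interval of 0.25 s places the first post-bleach frame
250 ms after the bleach event. A `"diffusion"` mode replaces uniform refill
with a relaxing Gaussian profile for exercising the gradient-smoothing test.

## Numerical choices and degenerate inputs

- EM: uniform initialization, no prior, relative log-likelihood tolerance
  $10^{-8}$, 1000-sweep cap, SQUAREM acceleration with monotonicity
  safeguard. Identical inputs give identical spectra.
- Retention series: truncated when terms fall below $10^{-10}$; clipped to
  $[10^{-6}, 1]$ so the correction can never divide by zero.
- Greedy linking resolves equidistant candidates by lowest localization
  index; linking is only exercised on synthetic data here (real inputs come
  with trajectory ids from the upstream tracker).
- Empty jump tables, all-constant FRAP images, masks covering the whole
  frame, zero-intensity anchor frames, and days without control cells are
  rejected with informative errors; cells whose corrected PAPA denominator
  floors at zero become missing values excluded from aggregation.
- Bootstrap trials that error are recorded missing; at least ~94% of trials
  must succeed (90 of 96) or the bootstrap aborts.

## Problem sizes used in the test and acceptance runs

Parameter-recovery checks run at: 200 cells / ≥ 5×10⁴ jumps for the
two-state bound-fraction recovery (exact 30/70 mixture, i.e. no
between-cell spread, matching the stated mixture); 10⁶ walkers for the
Monte-Carlo retention oracle; 100 simulated FRAP movies (noise s.d. 0.02)
for τ recovery plus 10 noiseless movies for model selection; 100 replicate
16-cell experiments for bootstrap coverage; and 24-cell datasets with
dominant between-cell spread for the variance decomposition. These sizes
were chosen to keep Monte-Carlo error comfortably below the tolerances being
tested.

## Known limitations

- The defocalization correction is calibrated to the jump/segment yield
  geometry and is approximate at very high D and for extreme photobleaching
  rates; it assumes the assumed $\sigma_{loc}$ is correct.
- The fixed-$\sigma_{loc}$ Rayleigh likelihood cannot separate states whose
  $D\,\Delta t$ is far below $\sigma_{loc}^2$ (~0.12 µm²/s here): all such
  states collapse into the immobile region. That is immaterial for the
  bound fraction but means spectra should not be over-read below the
  resolution floor.
- PAPA bootstrap CIs do not propagate control-aggregate uncertainty (the
  control is held fixed by construction).
- The FRAP fits assume reaction-dominant recovery; the gradient-smoothing
  test must be consulted before interpreting τ values as exchange rates.

## A compact example

```{r example, eval = FALSE}
sim <- simulate_smt_dataset(smt_sim_config(seed = 1))
jumps <- sim$trajectories |>
  filter_trajectories() |>
  compute_jumps()
spec <- infer_spectrum(jumps)
bound_fraction(spec)
glance(spec)
bootstrap_bound_fraction(jumps, n_trials = 96, seed = 1) |> glance()
autoplot(spec)
```
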