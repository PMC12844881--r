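---
title: "Methods: thermal-fate analysis of cortical activity at fever temperatures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: thermal-fate analysis of cortical activity at fever temperatures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thermofate)
```

## The scientific problem

When body temperature rises from ~36 °C into the fever range (above ~38 °C),
cortical pyramidal neurons face two opposing pressures: their spike threshold
depolarises (more depolarization is needed to fire) and their input
resistance falls (a given synaptic current depolarises them less). Despite
this, population firing in somatosensory cortex can remain remarkably
stable. The stabilising population is the subset of neurons that keep firing
at every temperature — *STAY* neurons — which appear to scale their
excitatory drive to track the rising threshold, helped by warmth-activated
cation channels (TRPV3, active between roughly 31 and 39 °C). Blocking or
knocking out TRPV3 flattens that compensation, hyperpolarises the resting
potential by about 3 mV, and thins out the STAY population.

`thermofate` implements the complete analysis chain for this kind of
experiment:

1. **Trace features** from current-clamp sweeps recorded at 30, 36 and
   39 °C: resting membrane potential (RMP), spike threshold (ST) by a
   second-derivative criterion, depolarization-to-threshold, evoked PSP peak
   and late (net-inhibitory) component, input resistance, rheobase, F–I
   curves, spike height and afterhyperpolarization.
2. **Thermal-fate classification** of each cell as NEVER / STOP / STAY /
   START, with exact two-tailed binomial comparisons of fate proportions
   between conditions.
3. **Extracellular unit classification** into narrow-spiking (putative
   interneuron) and wide-spiking (putative principal) classes from
   trough-to-peak waveform durations, with a Hartigan dip test of
   bimodality, exact one-dimensional 2-means, and period-restricted
   normalized firing rates across baseline / fever / recovery.
4. **Body-temperature telemetry**: summary statistics, fever-episode
   detection, heating rates, and latency metrics around loss of postural
   control (LPC) and seizure onset.
5. A **synthetic-data generator** that reproduces the statistical structure
   of all three data streams with known ground truth, so every estimator in
   the chain is testable without recorded data.

## The spike-threshold estimator

The threshold convention is: *the membrane potential at which the second
derivative of V~m~ exceeds 5 SDs of its pre-stimulus distribution*.
Numerically this needs care, because a raw double difference amplifies
recording noise by fs².  `estimate_spike_threshold()` therefore:

- smooths V~m~ with a zero-phase (forward–backward) 2 kHz Butterworth
  low-pass before double differencing (scaled by fs²);
- computes the criterion `mean + 5 * SD` over the 100 ms immediately before
  the stimulus;
- searches backward from the detected spike peak, at most 10 ms, for the
  exceedance run containing the upstroke, and reports the raw V~m~ at that
  run's earliest sample.

The 10 ms backstop matters: in long noisy sweeps the pre-stimulus
second-derivative distribution is exceeded by chance every ~10⁵ samples, and
without a locality constraint such excursions far from the spike would
masquerade as take-offs. When no exceedance occurs within the span (e.g. a
linear ramp with no inflection), the estimate is flagged failed rather than
fabricated. On noiseless synthetic spikes the estimator lands within
~0.3 mV of the generative take-off; the zero-phase smoothing smears the
upstroke slightly backward, which reads the PSP a fraction of a millisecond
early and accounts for the small negative bias measured in the tests.

Spike *detection* (as opposed to threshold measurement) uses the
conventional derivative criterion: dV/dt > 20 mV/ms sustained for 0.1 ms,
or V~m~ above −20 mV, with a 2 ms refractory window. Candidate runs are
located on the whole trace and then filtered by onset time, so an analysis
window that opens mid-spike cannot fabricate an event at its first sample.
Evoked spikes are counted in a 150 ms window opening 2.5 ms
post-stimulus; the per-cell threshold is read from the first spike of the
first spiking sweep, whose take-off may legitimately precede the counting
window.

## The synthetic intracellular generator

Each simulated sweep is a pre-stimulus baseline of −50 mV (the evoked
protocol's holding level, just below threshold), plus

- an excitatory PSP: difference-of-exponentials kernel (rise 2 ms, decay
  20 ms) starting 3 ms after the stimulus — the monosynaptic latency; the
  delay also guarantees that threshold crossings of strongly driven cells
  fall inside the 2.5 ms-onset counting window;
- a delayed inhibitory component (onset 15 ms, decay 50 ms) whose amplitude
  shrinks with temperature in the unblocked condition;
- Gaussian noise low-pass filtered at 1 kHz and rescaled to an exact SD
  (default 0.3 mV): strong enough to stress every estimator, band-limited
  enough not to trip the derivative spike-detection criterion.

When the *deterministic* part of the trajectory crosses the
temperature-specific threshold from below, a stereotyped action potential
is pasted in: cosine rise to baseline + 60 mV, repolarization to threshold
− 10 mV (the AHP), then exponential relaxation back onto the subthreshold
trajectory. Driving spike initiation from the deterministic component is a
deliberate design choice: ground-truth fate labels are then exact by
construction, the noiseless-recovery contract is meaningful, and the noise
still perturbs every measured feature. The alternative — letting noise
trigger spikes — would make the intended fate of marginal cells a random
variable and the recovery tests statements about the generator rather than
the estimators.

Temperature structure is carried by per-temperature parameter maps
(defaults for the unblocked condition in parentheses): RMP depolarises with
warming (−75.1 / −73.5 / −71.3 mV at 30 / 36 / 39 °C),
depolarization-to-threshold grows (6.0 / 8.2 / 10.4 mV), input resistance
falls (150 / 120 / 100 MΩ), and the late inhibitory amplitude shrinks
(2.0 / 1.5 / 1.0 mV). The TRPV3-block / knockout maps hyperpolarise the RMP
by ~3 mV (−77.1 / −76.3 / −74.4 mV), use the blocker-condition threshold
map (7.15 / 8.39 / 10.0 mV) and hold both PSP gain and the late component
flat across temperature. Between-cell variability is drawn once per cell: a
threshold offset (SD 1.0 mV), an RMP offset (SD 1.5 mV) and a log-normal
input-resistance factor (SD 0.12).

Fates are realized through the PSP gain rule, which is where the biology of
the STAY mechanism lives:

- **STAY**: gain = 1.2 × the cell's own depolarization-to-threshold at each
  temperature — excitation tracks the threshold, producing the positive
  PSP–ST coupling the correlation analysis is designed to detect;
- **STOP**: flat gain just above the 30 °C requirement — sufficient when
  cool, overtaken as the threshold climbs;
- **START**: gain growing with temperature (0.7 / 0.9 / 1.2 × requirement);
- **NEVER**: 0.6 × requirement throughout;
- block/knockout conditions force flat gains for every fate (so START, which
  needs a rising gain, cannot be requested there — the configuration errors
  out instead of silently failing to realize it).

The step protocol (500 ms injections from −80 mV) is an exact
integrate-and-fire construction: the membrane relaxes exponentially toward
`holding + I·R_in` with τ = 20 ms, and crossing times are computed in closed
form, so the generative rheobase is exactly the smallest grid amplitude
whose steady state exceeds threshold — which is what the grid-scan oracle
in the tests asserts.

What the generator deliberately does **not** emulate: conductance-based
channel dynamics, stimulus artifacts, series-resistance errors,
temperature-dependent kinetics of the PSP kernels, and trial-to-trial
adaptation. Passing tests therefore demonstrate correctness of the
estimators against the stated trace model, not robustness to every
pathology of real recordings.

## The dip statistic

No dip-test implementation is available to this package, so the statistic
is implemented from its definition: the minimal sup-norm distance between
the empirical CDF and the closest *unimodal* CDF — a nondecreasing
distribution function convex up to its mode and concave beyond it (the
greatest-convex-minorant / least-concave-majorant geometry).

The computation exploits an equivalence: the sample admits a unimodal CDF
within half-width `d` exactly when a taut string threaded through the
vertical gates `[i/n − d, (i−1)/n + d]` at the order statistics (anchored
at 0 and 1 far outside the data) has a slope sequence that rises and then
falls. The taut string is the Euclidean shortest path through the gates,
computed with a funnel algorithm in C++; the dip is then found by bisection
on `d` to 10⁻¹¹. Tied values are merged into weighted knots and a single
atom (jump) of the fitted CDF is allowed at a tied knot, so degenerate
discrete samples (e.g. all values equal) behave sensibly; for tie-free data
the statistic satisfies `1/(2n) ≤ dip ≤ 1/4`, is invariant under increasing
affine transforms, and equals `1/(2n)` exactly for equally spaced values.

Correctness is guarded by an independent oracle in the test suite: a linear
program (via `boot::simplex`) that minimises the sup deviation over
unimodal piecewise-linear CDFs with an enumerated slope-peak position. The
two routes agree to 10⁻⁶ on every random instance tested (n = 4–14, five
distribution families).

The p-value is calibrated by bootstrap: the fraction of 10,000 uniform(0,1)
samples of the same size whose dip is at least the observed one. The
uniform is the standard least-favourable reference for the dip; the seeded
generator makes the p-value reproducible. On the study-scale duration
mixture (n = 633, modes 0.35 / 0.95 ms, SDs 0.05 / 0.15 ms, 22 % narrow)
the observed dip exceeds the null's 99.9th percentile several-fold, so the
bootstrap p is 0 at 10⁴ draws — reported as such, consistent with the
p < 0.001 bound the analysis requires.

## One-dimensional 2-means

The narrow/wide split minimises the 2-means objective on the duration
distribution. In one dimension the optimal two-class partition is always a
contiguous split of the sorted values, so `split_two_classes()` computes
the global optimum directly by scanning all n − 1 splits with prefix sums
(O(n log n) including the sort). We chose this over Lloyd iteration with
deterministic extreme-point starts after observing that Lloyd can stall in
local optima on exactly this kind of data, which would violate the
brute-force-equality property the tests enforce. The exact scan is
deterministic, needs no seed, and *is* the 2-means solution. Ties between
optimal splits send the boundary duration to the wide class, matching the
convention that published boundaries (e.g. "< 0.6 ms" vs "> 0.6 ms") leave
equality undefined.

## Firing-rate normalization

Rates are computed per period (baseline / fever / recovery, 45 min each)
using only the last 25 min of each period, which discounts transients such
as tissue recovery at the start of the baseline and the heating ramp at
the start of the fever period. Each unit is normalized to its own baseline
rate; units with a zero baseline rate are excluded from normalized
summaries and flagged, never divided through. Units enter the analysis only
with ≥ 900 spikes and with at least one spike in each tenth of the
recording span — a testable operationalization of "present throughout".

## Telemetry

Fever episodes are maximal runs of samples strictly above the threshold
(default 38.0 °C, configurable); a single hot sample counts as an episode
of one cadence duration, matching the convention of marking individual
fever entries. Event temperatures are read at the nearest sample rather
than interpolated — at a 5-minute cadence interpolation would pretend to
precision the data do not have. The synthetic telemetry generator plants
raised-cosine excursions, linear heating ramps (e.g. 36→39 °C at
0.01 °C/s) and bounded baseline noise around 36.5 °C so fluctuation
summaries recover their configured values exactly.

## Statistical primitives

Deming (errors-in-variables) regression uses the closed form with
error-variance ratio λ = 1 (orthogonal regression) by default; the ratio is
exposed because nothing in the data fixes it. Degenerate clouds (zero
covariance) are flagged, not silently fitted. Correlations are
pairwise-complete — features like spike threshold are undefined for
non-spiking cells *by construction*, so dropping incomplete pairs is the
only honest treatment and imputation is never performed. The two-tailed
binomial test enumerates the binomial mass exactly (all outcomes with point
probability ≤ that of the observed count); the reference proportion is
always an explicit argument, because the natural reference (the comparison
condition's observed STAY rate, or 50 %) depends on the contrast being
made. Repeated-measures ANOVA and post-hoc machinery are outside this
package's scope; standard R routines serve there.

## Problem sizes and numerical choices

The shipped tests and the acceptance script run everything at the sizes the
analysis itself uses where that is cheap (n = 633 units, 10,000 bootstrap
draws) and at reduced but statistically adequate sizes where the full
protocol would be wasteful: recovery cohorts use 15 cells × 10 seeds
(matching the blocker cohort's n = 15), the noiseless parameter-recovery
sweep uses 40 cells with a 3-step current grid, and pipeline smoke tests
use a handful of cells with shortened sweeps. Bisection tolerances (10⁻¹¹
for the dip), the 2 kHz smoothing cutoff, the 10 ms threshold search span,
and the 1 kHz noise band are all fixed defaults exposed as arguments.

## Known limitations

- The dip statistic's unimodal class is continuous except for one optional
  atom at a tied knot; heavily discretised data with several large ties are
  outside its intended domain.
- The generator's PSP-gain coupling coefficient for STAY cells (1.2) is a
  free parameter: the strength of the excitation–threshold coupling is
  qualitative in the source material, so only its sign and consequences
  (fate realization, positive PSP–ST correlation) are pinned down.
- `read_sweeps()` accepts the package's own long-format CSV container;
  laboratory formats (HDF5, ABF, NWB) must be exported to it upstream.
- Waveform durations inherit the waveform sampling grid (one-sample
  quantization at 30 kHz ≈ 0.033 ms).
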