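---
title: "Methods: kT-point pTx design and B1+ shimming for a liver-sized ROI at 7 T"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: kT-point pTx design and B1+ shimming}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(ktptx)
```

# The problem

At 7 T the RF wavelength in tissue is about 13 cm, smaller than the human
abdomen. The transmit field `B1+` of a fixed channel combination therefore
interferes destructively somewhere inside any liver-sized target, and the
resulting flip-angle (FA) dropouts cannot be removed by amplitude scaling.
With a many-element transmit array the per-channel complex weights become
degrees of freedom: a single static weight vector (B1+ shimming) or a short
sequence of weighted subpulses played at different excitation k-space
locations (kT-points) can homogenize the 3D flip angle. This package
implements that design chain on synthetic data with the interference
structure of a remote three-ring 32-element body array, together with the
analyses — L-curves, channel-count comparisons, relative local SAR — used
to quantify the trade-offs.

# Synthetic study conditions

The synthetic generator defines the study conditions; its defaults are
fixed and everything downstream is tested against them.

* **Grid**: 48 × 48 × 40 voxels at 4 mm isotropic — the resolution at which
  relative B1+ maps are acquired in practice; isocentre origin, metres
  internally, voxel centres, right-handed axes. 1-based channel numbering
  at all interfaces.
* **Body**: elliptic cylinder with 80 × 60 mm semiaxes (a torso-scale
  cross-section that fits the 192 mm field of view).
* **ROI**: right-offset ellipsoid (centre (26, 4, 0) mm, semiaxes
  (48, 40, 60) mm, ~7.5 × 10^3 voxels ≈ 0.48 L) standing in for a manually
  drawn whole-liver ROI.
* **Array**: three rings of 10/12/10 loop elements at z = −120/0/+120 mm on
  a 300 mm-radius cylinder behind the bore liner (remote array: radius well
  outside the body). Per element the field is
  `(d_ref/d)^gamma * exp(-d/L_att) * exp(-i 2 pi d / lambda + i phi_e)` with
  `lambda = 130 mm` (tissue at 297 MHz), `L_att = 150 mm`, `gamma = 1`, and
  a seeded random feed phase `phi_e` per element. This geometric-decay +
  propagation-phase model is **not** a full-wave EM simulation; it is a
  stand-in for measured maps that reproduces the one property the analysis
  depends on: RF-wavelength-scale relative phase variation across the ROI,
  hence zero-phase-shim dropouts and a benefit from more channels. A useful
  consequence: the random feed phases are a pure gauge — any shim can absorb
  them — so optimized CV values are essentially independent of the
  generator seed, while the zero-phase baseline varies with it.
* **Dead channels**: channels 11, 20, 24 and 32 can be zeroed to emulate
  transmit instabilities, leaving 28 usable channels; dead channels are
  dropped from all solves and re-inserted as zero weights on output.
* **Calibration scheme**: `n_channels + 2` small-flip GRE images — all
  channels on (equal magnitude, zero phase), all channels off, then one
  channel at a time — sharing a smooth positive receive profile and complex
  Gaussian noise; 34 measurements for 32 channels. The default flip scale
  puts the all-on peak at 5°, where `sin(alpha) ≈ alpha` within 1%.
* **VOPs**: synthetic virtual observation points — Hermitian PSD
  channel × channel matrices built from a few random rank-one terms and
  normalized so the median quadratic form over unit-norm weights is 1. They
  carry the *shape* of a local-SAR constraint in relative units; absolute
  W/kg would require EM body-model simulation, which is out of scope, and
  every VOP artifact is labelled synthetic.

What the phantom does **not** emulate: organ-specific tissue contrast,
respiratory motion, RPE image reconstruction, ΔB0 (deliberately neglected
for ~1 ms pulses), and realistic inter-subject variability. Passing tests
therefore demonstrate the correctness and the qualitative physics of the
pipeline, not in vivo performance figures.

# Relative B1+ mapping

The estimator forms, per channel,
`m_ch(r) = (I_ch(r) - bias) / sum_ch' (I_ch'(r) - bias)` where `bias` is
the spatial complex mean of the all-off image. Design choices:

* **Bias as a scalar complex mean.** Complex-valued Gaussian noise is
  zero-mean, so in the complex domain there is no Rician-style bias to
  remove; the scalar mean is a minimal DC-offset guard and is exactly zero
  on noiseless data, which keeps two invariants exact there: multiplication
  of every image by a common nonzero complex map (the receive profile)
  cancels identically, and the channel-sum of the estimates is exactly
  1 + 0i at every valid voxel. The remaining role of the all-off image is
  noise estimation: `sigma_hat` from its spread sets the validity mask
  (`|denominator| >= noise_floor_factor * sigma_hat`, default factor 3).
* **Channel-sum normalization** (rather than the all-on image) makes the
  sum-to-one identity a construction, testable to machine precision.
* **Noise-adaptive smoothing.** The transmit field varies smoothly on the
  few-centimetre scale — mapping resolutions above 10 mm are known to
  suffice for pulse design — so at finite SNR the estimator averages the
  *ratio* maps with a one-voxel-radius boxcar over valid voxels. Because
  smoothing acts on the already-cancelled ratio, receive independence and
  the sum-to-one identity survive exactly; because it is enabled only when
  the all-off image indicates noise, the noiseless estimator stays exact.
  At a per-image ROI SNR of 20 this reduces the median per-voxel complex
  error from ~8% to ~3% of the ROI median map magnitude. (A raw per-voxel
  ratio cannot beat the 1/SNR ≈ 5% noise floor at that SNR; exploiting
  smoothness is what buys the margin.)
* Voxels failing the noise floor are excluded from all downstream ROI
  statistics (validity ∧ ROI), and channels whose valid-ROI median
  magnitude collapses are flagged as dead.

# Static shimming

The shim cost is `CV - w * eta`: the coefficient of variation of the
superposed |B1+| over the ROI against the transmit efficiency (mean
constructive-interference fraction). Both terms are dimensionless and O(1),
and the default weight is `w = 1`. The weighting deserves a note: with
`w = 0` the minimizer of pure CV on this phantom is a *flat but
destructive* interference pattern (efficiency ≈ 0.13) — spatially uniform
yet uselessly weak, something no scanner protocol would run, and the CV/η
trade-off is precisely why the efficiency term belongs in the cost. `w = 0`
remains available and is used in the tests where pure-CV minimization is
itself the proposition (feasible-set nesting of magnitude+phase over
phase-only shims, and of 32 independent channels over grouped channels).

The optimizer is a quasi-Newton (BFGS) local search with analytic
gradients in an unconstrained parametrization — phases, plus
log-magnitudes in `mag_phase` mode — from 100 pseudo-random equal-amplitude
phase starts (the first start is the zero-phase shim; an optional
`init_weights` adds a warm start). Reported metrics are always recomputed
from the returned weights, never taken from optimizer internals, and
returned weights are rescaled to a requested total power `sum |b|^2` (CV
and η are invariant under that scaling and under a global phase).

# kT-point design

**Timing.** The total pulse is held at ~1 ms so that ΔB0 can be neglected:
a fixed 920 µs RF-on + blip budget with 80 µs blips gives subpulse
durations `round((920 - (n_kt - 1) * 80)/n_kt)` µs = 420/253/170/120/87 µs
for 2–6 kT-points (round-to-nearest reproduces the 87 µs entry), and the
single-subpulse static case uses 1000 µs.

**System matrix.** In the small-tip-angle approximation
`FA(r) = |sum_j (tau_j/1 ms) sum_ch B_ch(r) b_ch,j exp(i k_j r)|` in
degrees, with one unit-conversion scalar (`deg_scale`, degrees per unit
relative field per unit weight per ms; default 1) because the maps are
relative. Blips are ideal instantaneous k-space jumps that contribute time
but no RF. The final subpulse always sits at the k-space origin.

**Solve.** The magnitude-only target (uniform nominal 10°) is handled by
variable exchange: solve the Tikhonov system at fixed target phase, adopt
the phase of the achieved field, repeat. Each half-step minimizes the joint
objective, so the iteration is monotone (asserted in tests); the target
phase is initialized from the zero-phase-shim field, which makes the
`n_kt = 1` case reduce to a regularized static magnitude+phase shim.
Phase adoption converges slowly near its fixed point, so the final solve
runs up to 200 iterations with a `1e-9` relative-change tolerance; a
singular normal system at `beta = 0` falls back to a tiny ridge with a
warning.

**Trajectory.** Greedy placement starts from the origin and repeatedly adds
the candidate whose optimal weights (closed-form Tikhonov at the current
target phase) most reduce the objective, from a symmetric 7×7×7 Cartesian
grid spanning ±`pi / (2 * ROI extent)` per axis; candidates are scanned in
order of increasing ‖k‖ with strict improvement required, so ties resolve
toward low k. Local refinement is a coordinate search (half-grid-spacing
steps, halved per sweep) with a weight re-solve per trial; when a power
target is set, beta is re-adapted every 50 re-solves by
`beta <- beta * sqrt(P/P_target)`. The design subsamples the ROI to 2500
seeded voxels for the solves (the normal equations scale with the voxel
count) while all reported metrics use the full valid ROI; the best of
`n_starts` target-phase initializations is kept and everything is
deterministic per seed.

**L-curves.** Beta is swept over 27 log-spaced values in `[1e-10, 1e3]`,
descending. Each point is designed twice — warm-started from the previous
beta and from scratch — and the lower-objective solution is kept, so warm
starts accelerate but cannot corrupt the curve. Matched-power readings use
the budget convention: the lowest CV among swept solutions whose
integrated power `sum |b|^2 tau` does not exceed the budget; the reference
budget is the phase shim rescaled to the nominal 10° mean FA. Dense
sampling matters here — budget readings off a coarse grid alias the
comparison between neighbouring configurations.

# Evaluation

* **Bloch oracle**: per-voxel rigid-rotation integration of the
  piecewise-constant RF at a 1 µs raster with blips as instantaneous
  transverse-phase jumps `exp(i (k_j - k_{j+1}) r)`; the independent check
  for every small-tip prediction (≤ 1% ROI-median disagreement at 10°,
  ≤ 5% at 30°, and `|Mxy| = sin(FA)` for a hard pulse).
* **Power and SAR**: integrated RF power `sum_ch,j |b|^2 tau_j` (blips
  contribute nothing); relative peak local SAR as the max over VOPs of the
  duration-weighted time average of `b_j^H Q b_j`. A per-channel
  average-power compliance checker mirrors the shape of a power-controlled
  safety supervision (6.6 W / 3.3 W per-channel averages as configurable
  relative limits).
* **Channel grouping**: 8/16/20-channel configurations drive groups of
  elements with identical phase; the group map is the exact complex sum of
  its members. The shipped groupings are editable ring-adjacent defaults
  (pairs for 16; fives/threes for 8; 3/2-blocks on the outer rings with the
  inner ring individual for 20) since the exact hardware grouping pattern
  is a per-site choice. Total power is held constant across configurations
  by the comparison-time normalization.
* **SAR-regularized solve**: the power penalty can be replaced by a
  smoothed worst-case SAR penalty (log-sum-exp with a temperature of 20% of
  the current peak, softmax-weighted VOP combination, damped fixed point).

# Numerical choices and degenerate inputs

Population (not sample) standard deviation in CV; an all-destructive shim
(zero mean field) raises an error rather than returning NaN; efficiency
excludes zero-denominator voxels with a warning count; `raster_us` must
divide every subpulse duration; k locations beyond a configured `k_max`
error; empty ROIs, empty groups after dead-channel removal, missing
calibration measurements and missing sidecar volumes all error by name.
Every stochastic routine takes an explicit seed and is bit-reproducible;
the pipeline embeds a config hash and seed in every artifact.

# Problem sizes

The shipped defaults are desk-scale by design: the 48×48×40 grid with a
~7.5k-voxel ROI, 2500 design voxels, 27-point beta sweeps and 100-start
shims complete in minutes on one core; unit tests run on a 20×20×16
phantom with a 12-element array. These sizes are the package's chosen
study conditions, stated here so results are interpreted at the scale that
produced them.

# Known limitations

The field model omits electrodynamics (no E-fields, hence only *relative*
SAR); the estimator's smoothing trades a little spatial resolution for
noise robustness and assumes a smooth receive profile; grouping patterns
are plausible defaults, not a specific hardware's wiring; the greedy +
coordinate-search trajectory optimizer finds good local optima, not
certified global ones — the multi-start and warm-start machinery plus the
monotonicity guarantees are the mitigation, and every comparison the
package makes is recomputed from returned solutions rather than optimizer
state.
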