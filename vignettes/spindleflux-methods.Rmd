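---
title: "Models and methods behind spindleflux"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind spindleflux}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

spindleflux analyses the turnover and transport of fluorescent reporters
on the metaphase spindle from two-channel 2D time-lapse stacks, and ships
a stochastic simulator that generates such stacks with known kinetics.
This vignette is the package's own account of the models, the parameter
choices, and the numerical details; it states nothing that the test suite
and `scripts/acceptance.R` do not themselves compute.

## The transport model in the simulator

Each of `n_molecules` reporter molecules lives on a one-dimensional
spindle axis with origin at the spindle centre, poles at
±`spindle_length/2`, and a transverse coordinate used only for rendering
(the 2D image is the projection the analyses actually consume; all the
measurements are along the pole-to-pole axis, which is why transport is
modelled in 1D). Per sub-step `dt_sim`:

* **Unbound** molecules take Gaussian diffusion steps of sd
  `sqrt(2 D dt)` and reflect at the poles and at the spindle half-width;
  the modelled cytoplasm ends at the poles, so the binding lattice spans
  the entire unbound domain and the closed-form binding equilibrium
  `k_on / (k_on + k_off)` holds exactly in the transport-free limit
  (this is asserted as a property test against the binomial band).
* **Binding** occurs with probability `1 − exp(−k_on(x) dt)`, where
  `k_on(x)` is `k_on_base` boosted by `k_on_chrom_boost` inside the
  chromosome band (|x| < `chromosome_band_halfwidth`). The boost is the
  package's stand-in for the Ran-GTP gradient: chromatin-proximal release
  from importin inhibition is modelled as a purely chromosome-local
  increase in on-rate.
* Each binding event enters a **motor state** with probabilities
  `p_motor_poleward` / `p_motor_equatorward` (otherwise plain lattice
  binding). Bound non-motor molecules advect poleward — away from the
  centre, toward the nearer pole — at `flux_velocity`, the microtubule
  poleward flux. Motor molecules move at their own velocity; equatorward
  motors park at the chromosome band edge and revert to plain lattice
  binding there, and any bound molecule reaching a pole is clamped there
  and unbinds. These boundary rules are a design choice: they keep
  trajectories physical where no observational constraint exists.
* **Unbinding** occurs with probability `1 − exp(−k_off dt)`; `k_off`
  may be a scalar or a pole/intermediate/chromosome triple applied by
  axial thirds of each half-spindle, for emulating zone-resolved
  turnover directly.
* **Photo-events** fire at the start of the frame they name: a bleach
  turns fluorescent molecules inside the region dark with the stated
  efficiency, an activation does the reverse. FRAP-type reporters start
  bright, photoactivatable reporters start dark
  (`initially_fluorescent`).

The update is discrete-time with exponential-waiting-time probabilities
rather than an exact event-driven scheme; at the default
`dt_sim = 0.1 s` and rates at or below a few per second the
discretization error is far below the stochastic noise, and the scheme
vectorizes over tens of thousands of molecules. Molecule number is
conserved exactly, and a configuration plus seed reproduces stacks
bit-for-bit — both are asserted in the tests.

Rendering bins fluorescent molecules onto the pixel grid, convolves with
a Gaussian point-spread kernel (sd 1 px), scales by
`photons_per_molecule`, adds `background_level`, then applies Poisson
photon noise and additive Gaussian read noise. The reference channel is a
static tapered spindle envelope with a central intensity dip whose
half-depth points sit exactly at the chromosome band edges — the
simulated counterpart of the gap of microtubule staining from which the
chromosome edges are measured. It is static by design: the reference
channel serves purely as a registration/segmentation landmark.

## Default parameters and why

| parameter | default | rationale |
|---|---|---|
| `spindle_length` | 10 µm | metaphase spindle pole-to-pole scale in HeLa-type cells |
| `spindle_half_width` | 2.5 µm | equatorial half-width; envelope tapers to the poles |
| `chromosome_band_halfwidth` | 1 µm | metaphase plate thickness on the axis |
| `pixel_size` | 0.1 µm | 60–100× confocal sampling |
| `frame_interval`, `n_frames` | 5 s, 25 | 120 s of recovery at 5-s cadence, the FRAP acquisition design |
| `k_off` | 0.0277 /s | recovery half-life `ln 2 / k_off` = 25 s, the scale of measured spindle-protein turnover |
| `k_on_base` | 0.3 /s | bound fraction 0.92: a strongly spindle-enriched reporter |
| `diffusion_coeff_unbound` | 20 µm²/s | cytoplasmic diffusion of a GFP-sized fusion |
| `photons_per_molecule`, `background_level`, `read_noise_sd` | 50, 10, 2 | moderate-SNR EMCCD-like imaging |
| `burn_in_s` | 30 s | several binding relaxation times (`1/(k_on+k_off)` ≈ 3 s) before frame 1 |

The pair (`k_on_base`, `diffusion_coeff_unbound`) deserves emphasis: the
FRAP analysis interprets the bleached-half recovery rate as the off-rate,
which is only valid in the *reaction-dominant* regime where an unbound
molecule mixes across the spindle before rebinding. The defaults realize
that regime — the diffusion length per unbound excursion,
`sqrt(2 D / k_on)` ≈ 11 µm, exceeds the spindle length — while keeping
92% of molecules bound so the measured signal is dominated by the slow
exchanging pool. With slow diffusion or a large unbound fraction the
one-phase fit is transport-contaminated and the round-trip identity
`k_fit ≈ k_off` degrades; the simulator makes this regime dependence easy
to explore deliberately.

## What the simulator emulates — and what it does not

It emulates: half-spindle bleaching and stripe photoactivation, zone-wise
recovery gradients, poleward flux of the bound lattice state, mixed
motor-driven populations, acquisition fade-free imaging with shot and
read noise, and a reference channel suitable for masking and
registration. It does not emulate: 3D optics or z-stacks, photobleaching
during acquisition, chromosome motion, spindle elongation or rotation
beyond commanded rigid offsets, reporter maturation, or tubulin
turnover. Passing the round-trip tests therefore demonstrates that the
*analysis* is correct and unbiased under the stated model, not that real
spindles satisfy the model — in particular, real recovery curves can be
multi-exponential and real drift non-rigid.

## Image preparation

Registration is rigid (translation + rotation), matching the standard
StackReg RigidBody treatment of spindle movement: FFT cross-correlation
initializes the translation, a coarse rotation grid plus Nelder-Mead
refines all three parameters against the intensity correlation with
frame 1, and one transform is applied to both channels with bilinear
interpolation. Segmentation Gaussian-smooths the reference frame
(sd 2 px), applies an Otsu threshold, keeps the largest connected
component and fills holes; an inverted-contrast input fails loudly
rather than producing an inverted mask. The pole axis is the principal
axis of the mask (masks rounder than axis ratio 1.2 are rejected), poles
are the extremal mask pixels along it, and the chromosome edges are the
half-depth crossings of the central trough of the pole-to-pole reference
profile, or user-supplied values echoed unchanged.

Zone compartmentalization splits the mask at the axis midpoint and each
half into three equal-length axial bins (pole, intermediate, chromosome
from the pole inward). The equal-thirds rule is a parameter-free choice
made here; nothing in the data dictates where the zone boundaries lie,
and any monotone re-binning would preserve the qualitative axial
gradients. The bleached half is the side holding the majority of the
bleach geometry's axial extent; a geometry straddling the midpoint with
more than 40% of its span on each side is rejected as ambiguous. Line
profiles average across a band of fixed physical width (default 2 µm)
perpendicular to the axis at 1-px steps; bands leaving the image are
clipped with a warning flag. Background is a user rectangle outside the
cell or, as a fallback, the per-frame 1st-percentile pixel value.

## FRAP numerics

Double normalization uses the whole spindle as the reference ROI;
full-scale normalization is applied to bleached ROIs only, and decay
fits for unbleached ROIs run on the double-normalized trace — the
full-scale map is defined by the bleached compartment's depth and has no
analogue on the rising side. Both exponential fits anchor time at the
first post-bleach frame, run Levenberg-Marquardt (minpack.lm) with
`k ∈ [1e-5, 10] /s`, initialize the plateau from the mean of the last
three points and `k` from the half-change crossing time, and never
throw on optimizer failure: they return `converged = FALSE`. Fits with
`r_squared < 0.8` are flagged rather than silently excluded, and
`halflife * k = ln 2` holds exactly by construction. Degenerate inputs
(constant traces, zero amplitude, a rising trace fed to the decay model)
are reported as non-converged.

## Photoactivation numerics

Per-frame profiles are fitted with a Gaussian plus a constant offset;
the offset absorbs diffuse background and unconverted signal, and an
offset-free mode exists for strict single-Gaussian replication.
Non-converged frames are dropped (and counted) from the centre track.
The quadratic kinematics fit runs in seconds internally and reports
µm/min and µm/min²; duplicated time points are rejected as
rank-deficient.

The landmark extrapolation solves `x0 + u0 t + a t²/2 = 0` with the
signed axis pointing from the landmark toward the initial pulse
position, so `x0 ≥ 0` always. Two real roots generally exist; the root
of smallest magnitude — the nearest crossing, possibly backward in
time — is used, and both roots are retained for audit. Backward
extrapolation is deliberate: a pulse moving poleward never reaches the
chromosome edge forward in time, and the reference-point velocity is
the de-drifted quantity that makes cells with different activation
distances comparable. The headline velocity is reported poleward-signed
(+1 when motion away from the landmark is poleward, i.e. the
chromosome-edge case; −1 for the pole case). The raw correlation of
`u0` with `x0` across cells remains available as a Spearman diagnostic
rather than being corrected further.

## Statistics

Mann-Whitney U uses midranks; the two-tailed p-value is exact (the full
rank-sum null, via the standard Wilcoxon distribution) for combined
n ≤ 12 without ties and the tie-corrected normal approximation without
continuity correction otherwise — the switch point keeps the exact path
in exactly the small-cohort regime where it matters. Spearman's rho is
the Pearson correlation of midranks with the t approximation for the
p-value. Profile averaging rescales each cell to its own pole-to-pole
span, interpolates to a common 100-point grid, max-normalizes per cell,
and uses per-grid-point t-distribution 95% intervals. Star codes are
`*` ≤ 0.05, `**` ≤ 0.01, `***` ≤ 0.001, `****` ≤ 0.0001. No
multiple-testing correction is applied.

## Validation design and problem sizes

The test suite validates each operation against an independent oracle —
closed-form quadratic roots against a brute-force time scan, exponential
fits against a dense grid search, exact Mann-Whitney against full
enumeration of group assignments — and the pipeline end to end against
the simulator's ground truth. The round-trip experiments use 20,000
molecules for FRAP (with the chromosome-boost arm at
`k_on_chrom_boost = 8`, averaged over four simulated cells, mirroring
how cohort means are compared across real cells) and 10,000 molecules
over 46 frames at 2-s cadence for photoactivation, with stripe
activation 2 µm from the spindle centre; the motor arms use 10
simulated cells per condition. These sizes give stable
single-experiment estimates while keeping the whole validation suite
quick on a laptop. The on-rate boost produces the
chromosome-faster-than-pole recovery ordering through capture
competition — a bright unbound molecule crossing the 2-µm band is
captured there with appreciable probability only when the boosted
on-rate is high (at boost 8, `k_on` = 2.4 /s gives a per-crossing
capture probability near one half) — so weak boosts change zone
amplitudes but not their recovery order.

## Known limitations

* Single-exponential FRAP models only; no reaction-diffusion or
  double-exponential model selection.
* 2D + time only; inputs must already be projections.
* Rigid registration cannot absorb non-rigid deformation or spindle
  elongation.
* The simulator's motor states are memoryless per binding event; no
  processivity beyond the bound interval, no speckle-level detail.
* The chromosome-edge detector assumes a single central staining gap;
  prometaphase or disorganized plates need user-supplied edges.
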