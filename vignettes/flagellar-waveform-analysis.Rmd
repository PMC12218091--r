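---
title: "Flagellar waveform kinematics and energetics: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Flagellar waveform kinematics and energetics: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flagkin)
```

This vignette explains the models behind `flagkin`: what the synthetic
generator emulates, how the tracing and kinematic stages are defined, how the
energetics are computed, and which design choices were genuinely open and why
they were resolved the way they were.

## The tethered-sperm assay and the waveform representation

In a tethered assay the sperm head adheres to the slide and the flagellum
beats approximately in the focal plane; high-speed dark-field imaging
(250 frames/s, 1000 frames is typical for mouse cauda sperm) records the
beat. The natural planar representation is the tangent angle ψ(s, t): the
angle of the local tangent against a fixed axis as a function of arc length
s (s = 0 at the head–flagellum junction) and time. Curvature is
κ = ∂ψ/∂s; its kymograph shows propagating bends as diagonal bands. All
analysis stages of this package consume ψ(s, t) on a uniform
arc-length × time grid, so the generator and the tracer meet in the same
representation.

## The synthetic beat generator

`beat_params()`/`simulate_beat()` produce a tangent-angle traveling wave

$$\psi(s, t) = A(s)\,\sin\!\big(2\pi(ft - s/\lambda) + \phi_0\big),$$

integrated along arc length (midpoint rule on a 0.25 µm internal grid) so
every frame is inextensible by construction; arc length is conserved to
better than 0.1%. Defaults: total length 110 µm, f = 3–7 Hz,
λ = 110 µm, 250 frames/s.

Design choices that were open, and how they were resolved:

* **Wave family.** The wave is prescribed in ψ, not in transverse
  displacement, because ψ is the analysis representation — generator and
  analyzer then close exactly over the same object.
* **Tether model.** The head is clamped in position *and* orientation:
  every built-in envelope has A(0) = 0. With a prescribed (not dynamically
  consistent) wave, a free pivot would exchange boundary work
  M(0)·ψ̇(0) with the tether and the motor energy ledger (below) would not
  close; clamping the head angle removes that boundary flux, and is
  consistent with a head stuck to the slide. Custom envelopes with
  A(0) ≠ 0 are accepted, but the energy-balance property is then only
  approximate.
* **Wavelength.** λ defaults to 110 µm, comparable to the tail length, as
  in the single-wave shapes typical of wildtype mouse sperm. Much shorter
  wavelengths dephase the proximal tail so strongly that the largest
  printed midpiece amplitudes (up to 39 µm) cannot be reached by any
  envelope scale without self-crossing shapes.
* **Envelope families.** `"flexible"` ramps from the head over ~14 µm and
  tapers moderately beyond 70 µm (a calmer distal tip keeps extreme beats
  from self-crossing in projection). `"stiff-midpiece"` multiplies in a
  strong suppression proximal to the midpiece–principal junction
  (28.7 µm) with a small floor so that midpiece amplitude scales
  continuously through the stiff categories. These shapes are modelling
  choices — the rigid-midpiece phenotype is only described by its
  amplitude categories, not by a functional form.

`render_frames()` draws each frame as a constant-linear-density ridge,
convolves with a Gaussian PSF (default σ = 0.6 µm at 0.33 µm/px), adds a
uniform background, and applies Poisson shot noise plus Gaussian read
noise. SNR is defined as ridge peak over background noise sd
(`sqrt(background + read_noise^2)`). The renderer deliberately omits the
bright head blob, out-of-focus light, neighbouring cells and debris —
passing tests on these scenes therefore demonstrates correctness of the
chain, not robustness to every real-world artifact.

## Population sampling

`population_spec()`/`sample_population()` draw cells from mixture weights
over the four flexibility categories; per cell, a target midpiece
amplitude is drawn uniformly from the category's printed range (27–39,
16–27, 6–15, 0.6–6 µm) and the envelope scale is solved by bisection so
the ground-truth amplitude hits the target within 2%. Category allocation
is multinomial by default; `method = "stratified"` allocates
largest-remainder counts n·w. The stratified mode exists for validation:
when the question is whether the *chain* reproduces a known composition,
multinomial sampling noise (±3.5 percentage points at n = 1000 for a 17%
class) is irrelevant variance, and removing it isolates classification
error. Population runs use two beat cycles sampled at 12 frames per cycle
per cell; the solver measures the ground-truth amplitude with exactly the
same time sampling as the renderer, so the peak-to-peak metric is
consistent between the solve and the traced measurement.

## Centerline tracing

Per frame: Otsu threshold (integer-histogram implementation), removal of
components below `min_object_px`, a single-flagellum check, Zhang–Suen
thinning, then ordering by the shortest path (Dijkstra over the
8-connected skeleton, diagonal cost √2) from the skeleton endpoint
nearest the head anchor to the farthest pixel. That path bypasses short
side twigs without an explicit pruning pass; frames whose skeleton mass
lies substantially off the path (> 35% — self-touching or looped shapes)
or whose nearest endpoint is farther than 6.3 µm from the anchor are
dropped, as are frames tracing to an outlier-short length
(< 85% of the recording median). Dropped frames are filled by linear
interpolation between neighbours so the time grid stays uniform; a
recording with fewer than 80% of frames traced is rejected.

The ordered pixel chain is fitted with smoothing splines x(u), y(u)
against cumulative chord length (≈0.25 degrees of freedom per µm), and
the smoothed curve is resampled at 1 µm arc steps up to 100 µm. Because
the blurred ridge cap erodes the skeleton endpoint by about 1 µm, the arc
origin is re-anchored at the known tether point — without this, every
arc-length set point shifts distally and section amplitudes inherit a
systematic +0.5–1 µm bias on a growing envelope.

Round-trip accuracy at SNR 10 (verified in the tests): traced arc length
within 1%, tangent-angle RMSE < 0.05 rad, midpiece amplitude within 5%
(typically well under 1%).

## Kinematics

* **Curvature** by central differences (one-sided at the ends); optional
  Gaussian smoothing along s.
* **Beat frequency**: at stations 50% and 75% of the traced length, the
  κ(t) series is Savitzky–Golay smoothed (window spanning ~1/12 s, at
  least 5 frames — long against frame noise, short against a beat period
  of a few Hz) and significant alternating extrema are kept by
  persistence pruning at 10% of the series range. The per-station
  frequency is (n_turning − 1) / (2·span): n − 1 half-periods elapse
  between the first and last turning point, so this estimator is exact
  for a pure tone, while counting n itself would bias a 4 s record of a
  5 Hz tone by 0.13 Hz.
* **Section amplitudes.** The cell axis is the time-averaged tangent over
  the head-adjacent 6.3 µm. For each arc station the transverse excursion
  of that material point is tracked over time (Savitzky–Golay window 5)
  and its amplitude is the *full* peak-to-peak excursion; the section
  value is read at the section's distal set point (midpiece 28.7 µm,
  principal min(108.7, L) µm). Peak-to-peak at the set point is the only
  reading consistent with the printed category ranges: a material point
  at arc length s can never move farther than s from the tethered head,
  so a *half* peak-to-peak midpiece amplitude is bounded by 28.7 µm and a
  section-mean by ~17.5 µm, while the highly-flexible category extends to
  39 µm. Full peak-to-peak at 28.7 µm is bounded by 57.4 µm and reaches
  every printed bin.
* **Classification.** The printed category ranges leave small gaps
  (15→16 µm) and an open bottom (< 0.6 µm); they are implemented as
  contiguous half-open bins [0, 6), [6, 16), [16, 27), [27, ∞) so every
  amplitude is classified, treating the gaps as rounding.

## Shape modes

The time-mean profile ψ̄(s) is subtracted and the centered (time ×
arclength) matrix decomposed by SVD. Modes are orthonormal under the
ds-weighted inner product; B_k(t) are the projections. A planar traveling
wave needs exactly two modes in quadrature, and its B₁–B₂ trajectory is a
circle; beat-to-beat variability distorts it. The circularity score
whitens (B₁, B₂) to unit covariance and reports
1 − sd(r)/mean(r), clipped to [0, 1] — the circle/irregular-circle
contrast is qualitative in the literature, so this quantitative score is
a package definition. Collinear coefficients (zero minor axis after
whitening) are reported as a degenerate cycle rather than a score.

## Energetics

All computations are quasi-static (sperm Reynolds numbers are ≪ 1) and
use resistive-force theory — local anisotropic drag
f_h = −(ξ_t v_t t̂ + ξ_n v_n n̂) — rather than slender-body theory;
the drag anisotropy ratio defaults to 2. Velocities and rates are central
time differences.

* **Hydrodynamic dissipation** D_h(t) = ∫(ξ_t v_t² + ξ_n v_n²) ds, with
  regional integrals over the head, midpiece and principal windows (the
  three sum to the total exactly).
* **Internal dissipation** D_i(t) = ∫ η_i κ̇² ds — friction between
  flagellar cross-sectional planes as viscous resistance to curvature
  rate.
* **Active moment.** With a free distal end, force balance gives
  F(s) = −∫ₛᴸ f_h ds′ and the internal moment
  M(s) = −∫ₛᴸ (r(s′) − r(s)) × f_h ds′ (planar z-component), so
  M(L) = F(L) = 0 by construction. The motor (dynein) moment is
  m_a = M − EIκ + η_i κ̇: the elastic response is removed, and the
  interfilament friction term enters with a positive sign because the
  friction acts at the sliding interface in series with the motors — the
  motors must overcome it in addition to transmitting the bending moment.
  This sign is what closes the energy ledger below; with the opposite
  sign the motor net power would equal D_h − D_i, which no energy
  bookkeeping supports.
* **Motor powers.** The local motor power density is
  π(s,t) = m_a·∂ψ̇/∂s; motor input P_in(t) integrates its positive part,
  motor dissipation D_m(t) its negative part.
* **Cycle averages** are taken over the integer number of beat periods
  nearest the record length (never beyond it) and reported in fW.

The testable contract of the whole module is the cycle-averaged ledger
⟨P_in⟩ − ⟨D_m⟩ = ⟨D_i⟩ + ⟨D_h⟩ (elastic storage averages to zero over
integer cycles); on generator beats it closes to well under 1%, and the
test suite enforces 5%.

Material parameters (EI = 2×10⁻²¹ N m², η_i = 10⁻²² N m² s,
ξ_t = 0.7×10⁻³ N s/m², ξ_n = 2ξ_t, interfilament spacing 1.85×10⁻⁷ m)
are literature-scale placeholders exposed in `material_params()`:
absolute fW outputs scale with them, so only contrasts between conditions
and orders of magnitude are meaningful. Vigorous wildtype-like beats land
at hundreds of fW of motor input under these defaults.

## Group statistics

`compare_groups()` averages each quantity within animal first and runs an
unpaired equal-variance Student t-test across the animal means (Welch
behind a flag); pooling cells across animals would treat technical
replicates as biological ones. Percentages from `population_breakdown()`
are computed over all classified records; when a recording fails QC it
contributes no class, which matters if failures correlate with phenotype.

## Problem sizes and determinism

Unit tests run beats of 2 cycles at 12–60 frames/cycle and short rods;
the population gates run 1000 cells per mixture at SNR 10 (roughly 7–8
minutes per mixture on one CPU). All randomness flows through explicit
seeds: a `population_spec` seed fixes the sampled beats, a separate seed
fixes the imaging noise, and identical seeds give bit-identical outputs.

## Known limitations

* Planar analysis only; 3-D torsion and out-of-plane beating are out of
  scope, as are free-swimming trajectories and CASA-style track metrics.
* The renderer's optics are a stand-in (no head blob, uniform focus); the
  tracer's robustness is demonstrated against this model, not against
  crowded fields or debris.
* Self-crossing projections are dropped rather than resolved; recordings
  of extremely curled cells lose a few frames per cycle (interpolated,
  and bounded by the 80% QC rule).
* Absolute energetic outputs are parameter-conditional; fitting material
  parameters to real recordings is out of scope.
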