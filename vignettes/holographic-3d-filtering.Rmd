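---
title: "Volumetric pattern recognition in holographic microscope fields"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Volumetric pattern recognition in holographic microscope fields}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(holofilter)
```

## The model

A digital holographic microscope records, in a single shot, the complex
amplitude $u_0(x, y)$ of a monochromatic field in one plane.  Because a
monochromatic field in a uniform medium obeys the Helmholtz equation, its
3D spectrum is confined to a spherical shell of radius $n/\lambda$ (the
Ewald sphere), and one recorded plane determines the field everywhere:
each plane-wave component $(k_x, k_y)$ propagates with the pure phase
$\exp(+j 2\pi z k_z)$, where

$$k_z = \sqrt{(n/\lambda)^2 - k_x^2 - k_y^2},$$

taking the positive root (forward flux only) and discarding evanescent
components (negative radicand) and components outside the objective
aperture ($k_x^2 + k_y^2 > (\mathrm{NA}/\lambda)^2$).  `kz_grid()`,
`field_to_spectrum()`, `spectrum_to_field()` and `reconstruct_volume()`
implement this angular-spectrum machinery.  Propagation is a spectral
phase, so in-band energy is conserved exactly; the package's forward
transform uses the $\exp(-j2\pi \mathbf{k}\cdot\mathbf{r})$ kernel with
unitary $1/\sqrt{N}$ normalisation, so Parseval holds to machine
precision.  Spectra are stored in FFT-native order (DC at `[1, 1]`);
`fftshift2()` recenters for display.

### One plane of a 3D correlation is a 2D correlation

The shell constraint is what makes volumetric template matching cheap.
For the 3D cross-correlation $R(\mathbf{r}) = \int u(\mathbf{x})
h^*(\mathbf{x}-\mathbf{r})\,d\mathbf{x}$ of a propagating field with an
arbitrary 3D kernel, the spectral product $U(\mathbf{k}) H^*(\mathbf{k})$
exists only on the shell, so only the kernel's restriction to the shell —
a 2D function $H(k_x, k_y)$ — matters.  One output plane is

$$R_Z(r_x, r_y) = \mathcal{F}^{-1}\!\left[\,U(k_x,k_y)\,
  H^*(k_x,k_y)\, e^{+j2\pi Z k_z}\right],$$

a 2D circular correlation of the reconstructed plane $u_Z$ with one fixed,
$Z$-independent 2D kernel.  `correlate_plane()` / `correlate_volume()`
implement this; `brute_force_correlate3d()` evaluates the literal
triple-sum correlation (lateral shifts as explicit circular sums, the
axial sum over the kernel's impulse responses at the true axial lags,
normalised by $1/n_z$ as the discrete surrogate of the shell-delta
integration) and agrees with the fast path to machine precision.  The
axial sum must follow the kernel's native propagation continuation rather
than a periodic wrap: the propagation phases are not $z$-periodic on any
finite grid, so a fully circular axial correlation would disagree at the
percent level — the identity, like the underlying integral, runs over the
whole axis.

Two conventions are worth stating because every numeric in the package
depends on them.  Field spectra are unitary, so energy bookkeeping is
exact.  Kernels use the integral convention — the space-domain kernel is
$h = (1/N)\sum_k H e^{+j2\pi \mathbf{k}\cdot\mathbf{r}}$ — so an all-pass
kernel ($H \equiv 1$ over the band) is exactly the band-limited identity
and a kernel whose impulse response equals a template is that template's
matched filter, with correlation peak equal to the template energy.

### The nonlinear filter cascade

A linear kernel designed for the focal plane does not discriminate well
across defocus, which motivates a cascade: correlation layers interleaved
with pointwise cubic thresholds $T(x) = a x^3 + b x^2 + c x + d$ and read
out by the squared modulus $|\cdot|^2$.  `filter_model()` holds the
layers; `apply_filter()` runs them.  The thresholds act on complex values
with (possibly) complex coefficients: the cascade carries phase until the
final modulus, which is what lets later correlation layers reuse the
propagation structure of the field.  Layer one consumes the reconstructed
(propagating) volume plane-wise per the shell identity.  After a
threshold the volume is no longer a propagating field and the shell
identity no longer applies; subsequent layers correlate every plane with
the same fixed 2D kernel — the discrete form of the identity above, which
coincides exactly with the layer-one path on propagating volumes, keeps a
delta kernel the exact identity, and preserves circular shift invariance.
The trainable degrees of freedom remain 2D throughout: a compact
`kernel_extent` block of spectral samples per layer (default 16×16),
zero-padded into the full grid (`pad_kernel()`), which keeps the
effective kernel small relative to the image and controls wrap-around.

## Training

References are labelled reconstructions; the desired output of an
in-class reference is a delta of unit magnitude at the first
lexicographic voxel, of an out-of-class reference identically zero
(`desired_output_for()`).  The objective is the peak-weighted squared
error

$$E = \sum_{i,j} (R_{ij} - O_{ij})^2 + n \sum_j (R_{1j} - O_{1j})^2,$$

with $n$ the voxels per volume, so the designated peaks carry weight $n$
(`objective()`).  Because $E$ is a non-convex function of hundreds of
complex parameters, optimisation uses simulated annealing (`anneal()`):
Metropolis acceptance under geometric cooling, one Gaussian-perturbed
complex parameter per move.

Annealing parameters (all in `anneal_schedule()`, defaults chosen once
for convergence of the scaled protocol):

* `t_initial` — by default set from probe moves so a median uphill move is
  accepted with probability 1/2 (acceptance-ratio rule).  A temperature
  tied to the objective's absolute size instead would be orders of
  magnitude too hot and destroy the warm start.
* `t_final` — four decades below `t_initial`.
* `cooling_factor` 0.95, `steps_per_temperature` 200 — roughly 36 000
  moves for the scaled problem, a few minutes on one core.
* `step_scale` 0.1 — proposal s.d. relative to the parameter-group RMS,
  shrinking with temperature.  Order-of-RMS moves are useful for global
  exploration but throw the state far from the matched-filter start
  before cooling; a tenth of the RMS refines it instead.

The kernel is warm-started at the analytic matched filter — the average
in-class spectrum restricted to the trainable support, scaled to unit
mean peak (`matched_filter_kernel()`) — since the linear-correlation
limit of the cascade is the natural starting point and annealing from it
converges far faster than from noise.

Two properties of this objective are worth knowing before interpreting
trained filters.  First, for noise-free references the minimiser of $E$
is an output-flattening (inverse-type) filter, not the matched filter:
the matched filter maximises peak SNR under white noise, and $E$ contains
no noise term.  A well-converged anneal therefore *moves away* from its
warm start; that is the optimiser working, not failing.  Second, $E$
penalises every voxel equally, so it constrains the out-of-class
*designated* outputs much more strongly (weight $n$) than the single
largest out-of-class sidelobe (weight 1).  The discrimination ratio
reported by `evaluate_filter()` — minimum in-class designated peak over
maximum out-of-class output anywhere in the volume — consequently
improves only moderately under $E$-minimisation (from about 1.3 to about
1.5 on the scaled two-class problem); a direct margin objective would be
needed to push it further, at the cost of leaving the formulation.  The
cascade's answer is the decision layer instead: `add_sharpening_layer()`
appends an all-pass second layer with the pure cubic $T(x) = x^3$, which
cubes every output intensity and therefore cubes the ratio (about 1.5³ ≈
3.2 on the scaled problem) at no cost to shift invariance.  Annealing the
second layer's coefficients under $E$ was tried and *reduced* the ratio —
$E$ rewards rescaling, not margins — so the fixed cubic is the default
and coefficient annealing an option.

## The synthetic scenario

No public dataset of holographic bacteria fields exists, so
`synthetic scenes` are generated: rod-shaped scatterers of two size
classes (capsule geometry, anti-aliased over one pixel) at random 3D
positions and in-plane orientations in the field.  Defaults, chosen once:

* Optics: He-Ne illumination (0.633 µm), NA 1.25, water (n = 1.33),
  pixel pitch 0.25 µm — just inside the Nyquist pitch
  $\lambda/2\mathrm{NA} \approx 0.253$ µm, emulating a magnification
  matched to the camera.
* Geometry: in-class rods 2.0 × 0.8 µm, out-of-class 1.4 × 0.7 µm — the
  two species are similar rods of slightly different size; no published
  dimensions exist for the original experiment, so these are invented
  and stamped into generated files.
* Transmittance: amplitude 0.95, phase 0.5 rad — a weak phase object,
  the regime in which the first-Born composition used by
  `render_scene()` (scattered perturbations summed on the unit
  illumination wave, each propagated from its own plane) is accurate.
* Reference sets are built by rotation in 45° steps (`rotations` of
  them, cycling), with an optional seeded size jitter (s.d. 5%) standing
  in for natural cell-to-cell variation.  The training protocol used by
  the tests sets the jitter to zero: rotation-generated references only.

Off-axis recording is simulated as interference with a tilted reference
wave and inverted by Fourier side-band demodulation
(`simulate_hologram()` / `demodulate_hologram()`).  Recovery within the
NA band is exact when the carrier exceeds three band radii and lies on
the spectral grid (an integer number of fringes across the field);
off-grid carriers leak through the periodic window at the percent level.
What the generator does *not* model: refractive-index structure inside
the cells, out-of-plane pose, multiple scattering, partial coherence,
aberrations, and (by default) noise — so green tests here demonstrate
the correctness of the machinery and the qualitative detection
behaviour, not performance on real recordings.

## Detection

`run_pipeline()` chains render → (optional hologram round trip) →
background subtraction → volume reconstruction → filter → peak finding.
The undiffracted unit background is subtracted in the DC spectral bin
(`subtract_background()`), keeping the scattered field's own mean — which
carries each object's total scattering strength, the strongest size
discriminator — identically in training and deployment.  Kernels trained
on small volumes transplant to scene grids at the same pitch by moving
their (origin-anchored) impulse response (`resample_kernel()`), which
preserves correlation peak values.

`find_peaks()` reports local maxima above a threshold, greedily pruned
with an ellipsoidal exclusion zone (`min_separation = c(lateral, axial)`
voxels, default 6 and 24 in the pipeline): correlation responses are
axially elongated by the depth of field, and under multi-object
interference the defocus ridge of one rod breaks into several axial
local maxima; an isotropic radius either duplicates objects axially or
merges distinct ones laterally.  The price is that two objects stacked
at the same lateral position within the axial radius are reported once.
The detection threshold is calibrated from training statistics as the
geometric mean of the minimum in-class peak and the maximum out-of-class
output (`calibrate_threshold()`).  Axial localisation is coarse (the
ridge is flat over ±1–2 µm); lateral localisation is sub-pixel in the
scaled demonstration.  The reconstruction z-step matters at this NA: the
axial response decays within ~0.3 µm, so the pipeline default is
dz = 0.25 µm — a coarser grid misses focus and halves peak values.

## Problem sizes and numerical choices

The test-suite protocol is deliberately scaled: reference volumes
16×16×8 at 0.25 µm pitch (6 in-class + 6 out-of-class references, 4
orientations), full-grid 16×16 trainable support, ~36 000 anneal moves;
the end-to-end scene is 128×128 (32 × 32 µm) with 6 + 4 rods over ±3 µm
depth and 33 reconstruction planes.  The full-size protocol (32×32×16
volumes, 25 + 17 references, 8 orientations, 16×16 support padded into
32×32) is the package default in `build_training_set()`.  Degenerate
inputs are refused loudly (empty z grids, non-increasing z, overlapping
rods, carriers violating separability, oversize brute-force grids);
plateau ties in peak finding break by ascending lexicographic voxel
index, making reports fully deterministic; all randomness flows from
explicit integer seeds and callers' RNG state is restored on exit.

## Known limitations

* The discrimination ratio of a single linear layer saturates near 1.5
  under the peak-weighted objective (see *Training*); the cubic decision
  layer is required for comfortable threshold separation.
* Kernel transplantation truncates the impulse-response energy outside
  the training grid (small for compact templates) and assumes equal
  pixel pitch.
* The axial coordinate of a detection is the peak plane of a flat ridge:
  expect ±1–2 µm of axial uncertainty at these settings.
* Circular boundary conditions throughout; callers needing linear
  behaviour must pad (the trainer's zero-padding of kernel supports is
  the built-in instance of this).
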