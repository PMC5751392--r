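---
title: "Methods: 2D multiresolution hybrid strain estimation and the phantom simulator"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: 2D multiresolution hybrid strain estimation and the phantom simulator}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its science: the estimation
model and its assumptions, the tunable parameters and why their defaults
are what they are, what the phantom simulator does and does not emulate,
and the numerical choices made where the design was genuinely open.

## 1. Problem and signal model

Quasi-static elastography estimates the axial displacement field between
two RF frames acquired before and after a small uniaxial compression, then
differentiates it into strain.  The package's sign conventions are fixed
once: the axial axis is the first matrix axis with depth increasing along
it, positive axial displacement is motion toward greater depth, and
compression is reported as *positive* strain (the displacement gradient is
negated exactly once, inside `strain_map()`).

The probe is assumed to ride the compressed surface, as in freehand
scanning.  A material point at depth $z$ therefore appears displaced by
$u_z(z) - \delta$, where $u_z$ is the lab-frame displacement and $\delta$
the applied compression: displacement is zero at the transducer face and
grows in magnitude with depth.  Two consequences follow.  First, the
coarse search ranges must widen with depth, which is why the level-1
search half-range grows row by row.  Second, the chained 1D estimator's
$\tau_{0,0}=0$ initialization of the shallowest window is consistent, so
the baseline is implemented on its own best terms.

## 2. Preprocessing

`analytic_signal()` forms the complex signal per scan line with the FFT
half-spectrum construction (no installed package provides a Hilbert
transform; the construction is standard and testable against a tone).
`demodulate()` multiplies by $e^{-i w_0 t}$ with $w_0 = 2\pi f_0$ by
default — the carrier is the natural demodulation frequency, and a warning
fires if a caller strays more than 25% from it.  Envelope and phase are
taken as modulus and argument of the baseband, which is mathematically
what the downstream stages consume.

`build_pyramid()` decimates axially by the configured rates (default
8, 4, 2, with the undecimated baseband reserved for the fine stage).
Anti-aliasing uses a 64-tap linear-phase FIR at cutoff $0.8 (f_s/r)/2$,
applied symmetrically so no group delay biases displacement.  Each rate
must satisfy $f_s/r > 2B$, where $B$ is the frequency at which the average
line power spectrum falls 20 dB below its peak — a cheap, conservative
bandwidth estimate.  With the default 60%-bandwidth pulse at 7.5 MHz the
baseband's $B$ is about 4 MHz, so rate 8 ($f_s/8 = 15$ MHz) passes with
margin.

## 3. Coarse estimation

* **Level 1** — nine windows on a 3×3 grid at axial/lateral fractions
  1/6, 1/2, 5/6 (the symmetric reading of "evenly distributed").  Each is
  an exhaustive ZNCC search.  Window: 10 carrier wavelengths axially × 10
  lines; search half-range $1.5\times$ the displacement expected from
  `expected_max_strain` (default 5%, covering the 4% study ceiling), grown
  50% per row.
* **Level 2** — 7×11 windows, calculation window 1/3 the level-1 size;
  **level 3** — windows half the level-2 size tiling the frame at 50%
  overlap (a standard density that keeps the grid fine enough for the
  fine-stage interpolation).
* **Tracking** — greedy hill-climbing over the correlation surface with a
  full 5×5 stencil (the minimal strict enlargement of 8-connectivity).
  Ties break deterministically: smallest offset magnitude, then axial,
  then lateral offset.  Each window is tracked from *two* seeds — the
  delivering seed (the result of the window above in the same column) and
  the initialization bilinearly interpolated from the coarser level — and
  the branch ending on the higher correlation wins.  The second branch is
  the error-correction mechanism: with only the delivering seed, greedy
  search stalls on speckle-noise local maxima whenever the per-row
  displacement increment exceeds the correlation peak width (which happens
  at the study's higher strain levels), and the error then propagates down
  the whole column.
* **Validity** — windows whose peak correlation falls below 0.3 are marked
  invalid and replaced by the median of valid neighbours before
  interpolation; 0.3 is low enough never to reject plausible speckle
  matches, high enough to catch decorrelated windows.
* **Lateral finalization** — the level-3 lateral field is smoothed along
  each row by a Savitzky–Golay filter (window 9, order 2: preserves smooth
  lateral trends, suppresses line-to-line jitter) and entries below 0.25
  lines are zeroed — sub-quarter-line shifts are below lateral resolution
  and shifting for them would only add interpolation noise.

## 4. Fine estimation

The per-window Newton iteration on the baseband is

$$\tau \leftarrow \tau - \frac{1}{w_0}\,
  \arg\!\Big[e^{i w_0 \tau} \sum_t \overline{x_1(t)}\, x_2(t+\tau)\Big],$$

with $x_2$ evaluated at fractional lags by complex linear interpolation —
equivalent to correlating against an oversampled signal without
materializing one.  The phase of the correlation is near-linear with slope
$w_0$, so convergence takes a handful of iterations; the defaults
(tolerance $10^{-3}$ samples, cap 20) are generous.  Convergence to the
*true* lag is only guaranteed when the initialization error is below half
a carrier period ($\pi/w_0$, 8 samples at 120 MHz/7.5 MHz); beyond that
the iteration lands on a phase-wrapped alias one period away.  This
capture range is tested explicitly.

The modified (2D hybrid) form runs every window independently: the
initialization is the coarse axial field interpolated to the window
center, and the post-frame line is first replaced by the line at
`line + round(lateral)` — whole-line quantization, because the lateral
pitch is two orders of magnitude coarser than the axial sampling and
sub-line interpolation would buy little.  Two safeguards feed the strain
stage: windows flagged unconverged, and windows whose result lies more
than half a carrier period from their coarse initialization (a
capture-range violation, hence an alias by the method's own theory), are
replaced by the 3×3 median of converged neighbours, so isolated spikes
cannot dominate the least-squares strain fit.

Fine windows default to 1.5 wavelengths (25 samples) at 75% overlap —
standard phase-based elastography sizing, trading axial resolution against
phase-estimate variance.  The downsampled-1D baseline applies the
configured window length on the decimated axis, so decimation by $r$ runs
$1/r$ as many windows: the computational saving that motivates that
baseline.

## 5. Strain and metrics

LSQSE computes, at each interior grid point, the slope of the
least-squares line fit of displacement against depth over a centered
kernel (default 41 fine-grid points ≈ 1.5 mm at the default overlap — a
conventional resolution/variance trade-off).  The slope weights are the
closed-form normal-equation weights, applied by convolution; tests verify
exactness on linear fields and agreement with per-window normal equations
to $10^{-10}$.

CNRe is $2(\bar s_1-\bar s_2)^2/(\sigma_1^2+\sigma_2^2)$ over the
inclusion and background ROIs — invariant under affine rescaling of the
map, nonnegative, infinite only for noiseless maps.  The strain ratio is
reported background/inclusion so the configured contrast of 5 reads as 5.
Default ROIs are 1.5 mm-radius circles at the inclusion center and at the
same depth 6.5 mm laterally — safely inside and outside the 3 mm
inclusion; exact ROI geometry is config-exposed because no authoritative
coordinates exist.

Binary images threshold at the whole-map mean (the low-strain inclusion is
black).  A caveat found with the FEM truth itself: under
displacement-controlled compression the columns above and below a stiff
inclusion strain *harder* than the far field, and the far-field background
straddles the whole-map mean, so mean-thresholding marks far more than the
geometric inclusion fraction $\pi r^2/(wh)$ black — on estimated maps,
edge-column noise adds further.  The area ratio is therefore reported as
computed and compared against the geometric reference line without any
correction.

## 6. The phantom simulator

`solve_fem()` solves 2D plane-strain linear elasticity on a regular
bilinear-quadrilateral mesh.  Near-incompressibility (ν = 0.495) locks
fully integrated bilinear elements, so the volumetric (λ) term is
integrated with a single central point and the deviatoric (μ) term with
2×2 Gauss — selective reduced integration.  Boundary conditions: the top
edge moves down by the applied compression with lateral slip free; the
sides are traction-free; the bottom is axially fixed.  The default bottom
condition leaves lateral slip free (one node pinned to remove rigid
motion): it admits the exact closed-form uniform-strain solution for a
homogeneous block, which the patch test verifies to well under 1%, and it
is the cleaner reading of "the bottom is fixed" for a phantom resting on a
plate; `bottom_bc = "clamped"` is available.  The element-centroid axial
strain field and nodal displacements are exposed through bilinear
evaluators.  At the default 80×80 mesh the inclusion/background strain
ratio changes by under 2% when the mesh is halved (tested at 40 vs 80).

The background modulus is never stated in the study conditions — only the
inclusion's 100 kPa and the strain contrast of 5 — so
`calibrate_contrast()` root-finds $E_{bg}$ until the FEM
background/inclusion strain ratio, measured on the same ROIs the imaging
metrics use, hits the target within 2%.  Linearity makes the result
independent of the compression level.  The calibrated default is 12.93 kPa.

RF synthesis replaces a full acoustic simulation with a separable
convolution point-spread function: each scatterer contributes its
amplitude × a Gaussian lateral beam weight (σ = 0.4 mm) × a
Gaussian-enveloped pulse at its two-way travel time, with a 60% −6 dB
fractional bandwidth; white noise is added at 30 dB SNR.  Scatterers are
Poisson-many (20/mm², several per resolution cell, fully developed
speckle) with standard-normal amplitudes, displaced by the interpolated
FEM field between frames.  The stated pitch (0.255 mm × 128 lines) and
the stated 20 mm image zone are mutually inconsistent; the package honors
the image zone, defaulting to `width / n_lines` ≈ 0.156 mm, with the pitch
config-exposed.

What the simulator does **not** emulate: diffraction and depth-dependent
focusing (the beam is depth-invariant, so lateral resolution is
optimistic, uniformly), element-level delay-and-sum, frequency-dependent
attenuation, and any nonlinear or viscous tissue behaviour.  Passing tests
therefore demonstrate correctness of the estimators on shift-and-deform
speckle with realistic bandwidth and noise — not performance on real
tissue, where decorrelation is harsher and the advantage of lateral
compensation is, if anything, larger.

## 7. Problem sizes and determinism

Unit tests run on reduced geometries (10 mm phantoms, 64 lines, 32-element
meshes) chosen to exercise every code path in seconds; the headline
acceptance tests and `scripts/acceptance.R` use the full study conditions
(20 mm, 128 lines, 80-element mesh, five speckle realizations per strain
level, medians reported — single realizations of CNRe ratios are heavy-
tailed, medians are not).  Every random draw (scatterers, both frames'
noise) derives deterministically from one integer seed; identical seeds
reproduce frames, fields, maps and CSVs bit for bit, which is itself under
test.

## 8. Known limitations

* The lateral field is estimated only at coarse resolution and applied as
  whole-line shifts; no lateral strain is computed (axial strain only).
* The final accuracy is bounded by the coarse stage: where block matching
  fails at scale (severe decorrelation), the fine stage cannot recover
  beyond its half-period capture range.
* Mean-threshold binary images over-segment under displacement-controlled
  loading (see §5); area ratios should be read against the geometric
  reference as a trend, not an absolute.
* The estimated strain map's deepest rows sit where the post-compression
  frame images material from beyond the phantom; their windows are flagged
  and median-filled but remain the noisiest region.
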