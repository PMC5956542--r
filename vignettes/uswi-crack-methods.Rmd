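---
title: "Shear-wave imaging of soft-tissue cracks: model, algorithms and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Shear-wave imaging of soft-tissue cracks: model, algorithms and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

A liver laceration (crack) is a thin, blood-filled tear in otherwise
homogeneous parenchyma. On B-mode ultrasound it is nearly invisible: the
blood-filled gap is hypoechoic and provides almost no speckle contrast.
Mechanically, however, the contrast is enormous — blood supports essentially
no shear stress, so a crack is a near-perfect reflector for shear waves even
when it is a small fraction of a wavelength thick. `USWIcrack` simulates an
ultrasonic shear-wave imaging (USWI) experiment end to end and localizes the
crack from the *reflected* shear wave, without ever reconstructing an
elasticity map:

1. **Phantom** — a 5.0 x 5.0 cm liver-mimicking solid
   (rho = 1200 kg/m^3, nu = 0.499, E = 6 kPa, shear speed
   c = sqrt(E/(3 rho)) ~ 1.29 m/s) containing one of three analytic crack
   geometries filled with a blood-mimicking material
   (rho = 1060 kg/m^3, E = 0.005 Pa).
2. **Wave simulation** — a thin rod on the centre plane pushes vertically
   for one cycle at 100 Hz; the axial displacement movie is exported on a
   200 x 400 x 106 grid (0.0125 cm spacing, 5000 frames/s).
3. **RF synthesis** — a 5 MHz linear-probe point spread function is
   convolved with a random scatterer field that deforms with the wave;
   each frame is a 2596-sample x 256-beam RF image sampled at 40 MHz.
4. **Speckle tracking** — phase-sensitive 2-D correlation of the complex
   baseband recovers frame-to-frame axial displacement, which is
   accumulated over the 105 frame pairs.
5. **Directional filtering** — a quadrant mask in the [k, omega] plane
   splits each depth row's x-t slab into incident and reflected waves; the
   absolute reflected displacement is summed over frames.
6. **Detection** — Sobel edge detection on the accumulated reflected-wave
   image, connected-component selection, and a per-depth comparison with
   the analytic edge (the "given" positions).

The geometry puts the push rod at x = 2.5 cm and the imaging region to its
left (x in [0, 2.5] cm): inside the ROI the incident wave travels toward
smaller x, and the *right* edge of the crack is the near end facing the
source. Only that edge reflects detectably for a 1.6 mm crack — the
transmission tests assert that the wave beyond the crack is attenuated by
more than a factor of five — so only the right edge enters the report,
exactly as a sonographer scanning from one side would see it.

## The wave model and its assumptions

The full problem is near-incompressible 2-D elasticity. The package solves
the heterogeneous scalar shear-wave equation instead,

$$ \rho\, \partial_t^2 u = \nabla \cdot (\mu \nabla u), \qquad
   \mu = \frac{E}{2(1+\nu)}, $$

for the axial displacement u — the only field component the imaging chain
uses. A vertically oscillating plane source generates pure shear motion
governed by mu and rho, and the scalar form avoids the volumetric locking
that plagues displacement-based discretizations at nu = 0.499. The crack is
a *soft inclusion*: its cells carry the blood-mimicking mu, and the
harmonic edge-averaging of the stiffness means a liver/blood cell interface
transmits essentially no shear traction. No internal boundary condition is
imposed on the crack surface (the alternative "roller on the crack
boundary" reading would additionally constrain the crack walls; the soft
inclusion alone already reproduces the near-total reflection the method
relies on).

Discretization: cell-centred second-order finite differences, leapfrog in
time, internal step 0.5 x the CFL bound subdividing the 0.2 ms frame
interval exactly. Boundary conditions are traction-free at the top surface
(zero normal flux), fixed at the bottom row, and zero normal derivative at
the sides (a roller surrogate). The push prescribes
u = A sin(2 pi f t) on the rod cells for one period (10 ms), after which
the rod cells revert to ordinary elastic cells. The push amplitude A is
not stated in the reference conditions; the default of 100 um keeps the
largest frame-to-frame motion (~13 um) well under a quarter ultrasound
wavelength (77 um), so phase-based tracking is unambiguous, while staying
in the linear regime of the model. A grid-refinement test asserts the
mid-depth trace changes by less than 5% RMS when the spacing is halved.

## Imaging chain parameters

| parameter | default | why |
|---|---|---|
| centre frequency f0 | 5 MHz | typical linear abdominal probe |
| sampling frequency fs | 40 MHz | 8 samples/carrier period; axial pitch c/(2 fs) = 19.25 um |
| axial bandwidth | half-power width 0.5 f0 | makes the correlation-lattice axial speckle size 14 samples = 0.270 mm |
| lateral PSF | Gaussian, FWHM 0.5 mm | one-way beam profile of the probe |
| scatterer density | 6 per wavelength (per axis) | ~36 scatterers per resolution cell: fully developed speckle (the 6-per-lambda^2 reading leaves ~6 per cell, which measurably fails a Rayleigh KS test) |
| tracking kernel | 0.270 mm ax x 0.586 mm lat | about one speckle cell: minimum-variance kernel |
| search region | 0.781 mm (full width) | generous bound on inter-frame motion |
| correlation filter | Hanning 0.308 mm ax x 0.781 mm lat | variance reduction across estimation points at modest resolution cost |
| phase-to-distance factor | c/(4 pi f0) | pulse-echo round trip |

"Half-power relative bandwidth of 50%" is implemented as the Gaussian
*power* spectrum having half-power full width 2.5 MHz; together with the
lattice definition of speckle size below, this reproduces both printed
speckle dimensions, which is the strongest available constraint on the
intended convention.

**Speckle size** is measured on the correlation lattice: the distance
between the outermost contiguous lags of the 2-D baseband autocorrelation
whose magnitude stays above half the zero-lag value. On the default
lattice this gives 14 axial samples (0.270 mm) and 6 beams (0.586 mm). A
continuum (interpolated) FWHM would give sqrt(2) x the PSF widths instead
(0.71 mm laterally) — the lattice measurement is the only definition
consistent with both printed values simultaneously.

**Envelope statistics.** At the default density the envelope of a
synthesized frame passes a Kolmogorov-Smirnov test against a Rayleigh
distribution at alpha = 0.01 and its mean/standard-deviation ratio sits
near the Rayleigh value sqrt(pi/(4 - pi)) ~ 1.91. The reference
implementation reported 2.3 for this ratio, *above* the fully-developed
limit; that value depends on unstated windowing and is logged for
comparison, not enforced.

## Speckle tracking

Tracking is phase-sensitive: frames are demodulated at f0 (zero-phase
brick-wall low-pass at f0), windows about one speckle cell in size are
correlated over the search region, the correlation fields are smoothed
across estimation points by the separable Hanning filter (per lag — the
alternative, filtering across lags per point, would blur the very peak
the estimator needs), and the axial estimate is refined from the phase of
the complex correlation at the peak lag after removing the carrier phase
of the integer lag. Estimates accumulate at fixed grid points (Eulerian):
per-frame motions are at most ~13 um against a 0.125 mm grid, so
material-point advection would change estimates by well under a percent of
the accumulated displacement. Accumulation also cancels noise shared by
consecutive frame pairs — the error variance after k pairs grows
sub-linearly in k, which a dedicated test asserts.

The synthetic-shift oracle (same scatterer realization, exactly displaced)
shows mean absolute errors well under lambda/20 for shifts up to a quarter
wavelength. Tracked displacement is biased slightly *low* relative to the
true field — shearing under the PSF decorrelates the speckle — which
propagates into detected crack depths a few percent short of truth, and
into detected edges slightly left of the given edge (the reflected-wave
amplitude also decays into the last fraction of a wavelength before the
edge because the interface is not perfectly rigid).

## Directional filtering

Per depth row, the x-t slab is Fourier transformed; quadrants with
sign(kx * omega) fixed correspond to the two travel directions, and the
DC/Nyquist lines are split equally so the two masks sum to one. This makes
the decomposition *exactly* complementary (incident + reflected = input to
round-off) and exactly energy-preserving. No taper is applied: a window
that must be divided out after inversion amplifies its own edge leakage by
the inverse taper — measured at two orders of magnitude at the outermost
samples — which destroys both the purity of a plane-wave decomposition and
the energy bookkeeping. The cost of going windowless is wrap-around
leakage on transient movies, which is concentrated in the outermost rows
and columns; detection therefore trims a margin (1 mm lateral, 0.25 mm
axial by default) before thresholding, and clears a further three-pixel
border of the edge mask. The quadrant-to-direction
assignment is not hard-coded: it is calibrated once per session on a
synthetic rightward wave, and the caller states which direction is
incident (toward smaller x in the default geometry).

## Detection rules

The reflected-amplitude image is edge-detected with the 3x3 Sobel stencils
and thresholded by Otsu's method on the gradient-magnitude histogram (a
quantile override is available). Connected components shorter than 3 mm
vertically are discarded as speckle artefacts; among the survivors the
*leftmost* (smallest mean x) is the crack boundary — the reflection
builds a standing-amplitude artefact line *between* the edge and the
source, i.e. to the right of the true edge, so the leftmost long component
encodes the manual disambiguation a reader would apply. Each depth row
contributes the sub-pixel position of its strongest gradient — the
steepest flank is the physical amplitude step at the crack wall, and
unlike a centroid it is unaffected when the boundary and artefact
responses blur into one component on a coarse estimation grid. The
contour's vertical extent is the detected depth.

A detectability gate precedes extraction: a genuine crack reflects
near-totally, so the peak accumulated reflected amplitude is comparable to
the peak accumulated incident amplitude (ratios approaching 1), while the
leakage floor of a homogeneous movie stays well below half. Detection
requires the ratio to exceed 0.5, the midpoint of that gap; the
homogeneous control exits here with "no crack detected".

## What the synthetic data does and does not emulate

The generator reproduces the study conditions: geometry, materials, push,
frame timing, probe PSF, scatterer statistics and tracking windows. It
does not model fluid-solid interface (Scholte) waves at the top surface,
acoustic attenuation or electronic noise, beamforming artefacts,
hematoma, liver capsule or vessels, or a Mach-cone radiation-force push —
all outside the plane-wave, pure-elastic scope. Passing tests therefore
demonstrate the *method chain* (tracking, directional filtering, edge
detection) under ideal plane-wave insonation of an idealized elastic
medium, not clinical performance.

Because the solver is a scalar surrogate rather than the original
finite-element solution, detected positions are not expected to reproduce
reference values digit-for-digit; the quantitative claims carried by the
tests are the bound-type and sign-bias ones: right-edge errors within a
few percent (well inside the 5% bound), detected depths slightly short of
truth, left-of-given bias at mid depths, direct-path accuracy at least as
good as the speckle path, and a silent homogeneous control.

## Problem sizes

Tests and the acceptance script run the full-fidelity physics and imaging
(0.0125 cm wave grid, 106 frames, 2596 x 256 RF frames, full scatterer
density) with the tracking stage on its `"reduced"` preset: a 0.25 mm
axial by 0.195 mm lateral estimation grid and a lag search trimmed to
+/-3 axial samples and +/-1 beam, which covers the at-most-13 um
inter-frame motion of the default push with a four-fold margin. The `"full"` preset (0.125 mm grid,
0.781 mm search) is the printed configuration; it changes the tracking
cost by roughly two orders of magnitude but not the method. The
grid-refinement, shift-oracle and module-level tests run on smaller
lattices built by `makeFixture()`.

## Known limitations

- The scalar solver omits mode conversion and the Scholte wave, so
  near-surface rows (the first ~2 mm) are less faithful; the slim crack,
  which lives near the surface, shows the largest depth underestimate.
- Lateral displacement is estimated only at integer beam resolution and is
  not used downstream (the directional filter consumes axial motion only).
- The detected contour is a single leftmost component; branching or
  multiple cracks would need a multi-component extension.
- Reports are persisted as CSV/YAML; large arrays stay in memory as S4
  objects (`saveRDS()` if persistence is needed).
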