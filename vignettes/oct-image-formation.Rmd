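---
title: "Image formation in two-dimensional spectral-domain OCT: model and numerics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Image formation in two-dimensional spectral-domain OCT: model and numerics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`octsim2d` simulates spectral-domain OCT image formation in a two-dimensional
geometry: infinite cylinders and extruded profiles, illuminated and collected
through cylindrical lenses. This vignette is the package's account of the
model, its numerical machinery, and the design decisions a user should know
about before trusting a simulated tomogram.

## The physical model

### Source and lens train

The source is a weakly guiding single-mode fiber whose end-face field is a
Gaussian, `E(y) = E0 exp(-y^2/w0^2)` with `w0 = 4.6 µm` (half the mode-field
diameter). Propagation to the collimating lens (focal length `f1 = 25 mm`)
and through it to the midplane is paraxial; both steps have closed forms
(`field_on_first_lens()`, `midplane_field()`), and the package verifies them
against direct quadrature of the angular-spectrum and Fresnel integrals to
better than 0.1 %. The midplane field is a Gaussian of 1/e half-width
`2 f1/(k w0)` (about 2.25 mm at 1300 nm) clipped by the aperture stop of
radius `h = 3.5 mm`; the clip occurs at about 9 % of the peak amplitude and
is part of the model — it produces weak side lobes of the focal spot that are
visible in the deep, low-intensity parts of tomograms.

The focusing lens (`f2 = 36 mm`) is treated as aplanatic. Under the sine
condition a ray at aperture height `y` focuses at angle `theta` with
`y = f2 sin(theta)`, so the aperture maps to the angular half-width
`alpha_max = asin(h/f2) = 0.0974 rad`. (The tangent convention would differ
by under 0.5 %; it is not used.) The focused field is the one-dimensional
Debye–Wolf integral over `theta in [-alpha_max, alpha_max]` with
`sqrt(cos theta)` apodization and prefactor
`sqrt(f2/lambda) exp(-i pi/4 + i k f2)`; all global `exp(ikf)` phases are kept
so that arm lengths stay explicit. For perpendicular polarisation the
integrand carries only `Ez`; for parallel polarisation the lens rotation
produces `(Ex, Ey) = (-sin theta, cos theta) E`. The two channels never mix
in 2D; they are simulated independently.

One convention deserves emphasis: the refractive index used in the plane-wave
phases of the Debye–Wolf integral, `n_debye`, defaults to 1 when *rendering*
the beam (this keeps the displayed focal spot free of strong side lobes that
the angular clipping would otherwise emphasize), but the solver-facing beam
synthesis (`beam_on_grid()`) always uses the physically consistent in-medium
wavenumber `k n_med`, because the scattered-field formulation requires the
incident field to satisfy the background Helmholtz equation exactly.

### Sample scattering

Two interchangeable scattering backends deliver complex far-field amplitudes
on the collection circle, normalized so the physical field at large `k l` is
`amplitude * sqrt(2/(pi k l)) * exp(i k l)`:

* **Analytic series** (`cylinder_far_field()`): every plane-wave component of
  the focused beam scatters off an infinite circular cylinder with the exact
  normal-incidence series solution; center offsets enter as phase factors on
  the incident and scattered legs at the in-medium wavenumber. Perpendicular
  polarisation is the transverse-magnetic case; parallel is the
  transverse-electric case solved through the axial magnetic field. The
  coefficients are validated against an independent SciPy implementation and
  against the optical theorem (`C_ext = C_sca` for lossless cylinders, exact
  to 1e-10). For scenes with several cylinders the analytic path superposes
  the exact single-cylinder responses; it therefore neglects inter-cylinder
  multiple scattering. Use the grid path when that matters.

* **Grid solver** (`helmholtz_solve()`): the scalar Helmholtz problem
  `lap E + k0^2 n^2 E = 0` for the out-of-plane field, in scattered-field
  form with source `k0^2 (n^2 - n_med^2) E_inc`. The default scheme is the
  convergent Born series: a preconditioned fixed-point iteration whose
  Green's operator is diagonal in Fourier space,
  `G = (p^2 - kb^2 - i*eps)^(-1)` with `kb = k0 n_med` and
  `eps = 1.05 max|k^2(r) - kb^2|`, applied by FFT. The iteration converges
  for arbitrary contrast as long as `eps` bounds the potential; `eps` here is
  set by the absorbing layers rather than the (weak) sample contrast.
  `scheme = "gmres_fdfd"` runs restarted GMRES on the same preconditioned
  frequency-domain operator instead; it is also the automatic fallback if the
  Born iteration stalls. Returned solutions always satisfy the stated
  relative residual (default 1e-5) of the discretized operator, or the solver
  raises with the achieved residual.

  Absorbing boundaries are a cubic ramp of the imaginary part of `n^2`
  (peak 1.4) over `boundary_width` (default 10 µm) on every side, giving
  below 1e-4 amplitude reflection at normal incidence for the default layer.
  Grids are padded to 5-smooth sizes for the FFTs.

  Scenes are rasterized by permittivity averaging: each cell's `n^2` is the
  mean over `subsampling^2` sub-cells (default 10x10), which suppresses
  staircase artifacts on curved boundaries; only boundary cells are
  subsampled. A disc's rasterized area converges to `pi a^2` as
  `subsampling^-2`.

  The far field is extracted by the 2D Green's-function contour integral with
  the large-argument Hankel asymptotic. The contour is a grid-aligned
  rectangle just inside the non-absorbing region: field values are exact grid
  values (no interpolation) and normal derivatives are fourth-order central
  differences. A circle with analytic field values reproduces the series far
  field to machine precision, and the result is independent of the contour
  (tested at two radii to 1e-6). With this machinery the grid far field of a
  1 µm cylinder matches the analytic series to 0.6 % at 13 cells per vacuum
  wavelength and 0.15 % at 24, shrinking with refinement as dx^2.

  The parallel (in-plane) channel is not offered on arbitrary grids: in 2D it
  obeys a divergence-form equation for the axial magnetic field that the
  Born-series Green's operator does not precondition, and every parallel
  quantity the package needs is available exactly on the cylinder-scene path.
  This narrowing is deliberate; arbitrary-map parallel solves would need a
  trustworthy independent oracle that the cylinder series already provides.

### Reference arm and detection

The reference mirror sits at the focus of the reference telescope, making the
arm lengths matched there. Its far field has a closed form: expanding the
Debye–Wolf plane waves in Bessel functions (Jacobi–Anger) and keeping
outgoing waves, each observation angle receives exactly one cylindrical wave
whose amplitude is `pi * exp(-i pi/4)` times the converging angular density
at the same angle, times the mirror reflection coefficient. The default is an
ideal mirror, `mirror_r = 1`: the tomogram is normalized by the reference
intensity, so a constant reflectivity cancels; an angle-dependent Fresnel
coefficient can be passed when the reference mirror is a dielectric
interface. The closed form is verified against brute-force propagation of
the Debye–Wolf integral: the amplitude error falls below 1 % by `k l ~ 2e5`
and keeps decreasing.

Detection reverses the illumination: the outgoing far field is sampled on the
collecting lens, propagated to the midplane by the Fresnel integral with the
paraxial lens transmission, focused on the fiber end face by the Debye–Wolf
integral of the collimating lens (`alpha1 = asin(h/f1)`), and overlapped with
the fiber mode, `alpha(k) = integral E(y,k) exp(-y^2/w0^2) dy`. The axial
field component is neglected in the overlap (its contribution is of order
`sin^2(alpha_max) ~ 1e-2` in amplitude on a component that is itself small).
Crucially, *both arms pass through the identical numerical operator*, so its
common phases and any common quadrature bias cancel in the cross-correlation;
depth calibration then rests only on the in-medium scattering phases. A
sample arm identical to the reference arm reconstructs to a peak at depth 0
with normalized intensity exactly 1 — this identity anchors the depth origin
and the intensity scale.

### Reconstruction and the depth-aliasing law

The interferogram is processed as the cross-correlation
`z(omega) = W(omega) alpha_sca alpha_ref*`, which removes the DC and
autocorrelation terms. The spectral weight `W` is the source power `S^2` by
default (`weighting = "amplitude"` is available): the product of the two arms
already carries one field factor per arm, so the power weight corresponds to
a source spectrum applied once per arm. The inverse DFT uses indices
`-N/2 .. N/2-1` (an even `N` is required and enforced), scaled by
`1/sqrt(N)` so that spectral and A-scan energies match (Parseval); times map
to depth via `x = tc/(2 n_med)`. The depth axis has length `N`, is two-sided,
and its maximum equals

`c t_max = c/(2 n_med) (N/2 + 1/N - 3/2) pi b / (2 sqrt(ln(1/epsilon)))`

for the Gaussian spectrum `S = b/sqrt(2) exp(-(b/2 (omega-omega0))^2)`
sampled between the points where it has fallen to `epsilon max(S)`
(`b = 2 sqrt(ln 2) lambda0^2/(pi c delta_lambda)`, 1.76e-14 s for the default
source). Signals delayed beyond `t_max` alias back with the exact DFT period;
`depth_period()` exposes the period, and the property tests exercise the
wrap-around arithmetic. Magnitudes are reconstructed (consistent with
log-scale display); whether a plot uses a linear or decadic-log scale is a
display option, not baked into the data.

## Numerical parameters and their defaults

| parameter | default | role |
|---|---|---|
| `n_theta` | 201 | Gauss–Legendre nodes of the illumination angular spectrum; the integrand has at most a few tens of oscillations across the aperture, and doubling changes nothing at 1e-7 |
| `n_collect` | 257 | collection angles at which far fields are evaluated, then spline-interpolated onto the lens-plane nodes; far fields are smooth on this scale (interpolation error under 1e-4 even for 80 µm lateral offsets) |
| `n_xi` | 2048 | lens-plane nodes of the backward Fresnel (chirp) integral; the phase sweeps ~260 cycles across the aperture at the band edge. 1024 leaves a ~2e-5 artifact floor in deep tomogram regions; 2048 is converged (identical to 8192 to 7 digits) |
| `n_theta1`, `n_yf` | 201, 161 | collimating-lens angles and fiber-plane overlap nodes; both integrands are mildly oscillatory Gaussians |
| `dx` | `lambda_min/13` | grid-solver spacing; 13 cells per vacuum wavelength is the coarsest acceptable sampling, 24 is used where backscatter accuracy matters (the coupling integral sees only the weak backscatter lobe) |
| `subsampling` | 10 | sub-cells per axis in permittivity averaging |
| `boundary_width` | 10 µm | absorbing layer; 40 µm available for runs that need very low boundary reflections |
| `tolerance` | 1e-5 | relative Helmholtz residual; the contract is enforced, not advisory |

## The synthetic phantoms

`make_single_cylinder()` records the predicted front–back optical separation
`d = 2 a n_cyl/n_med` as an attribute. `make_cylinder_cluster()` fills a disc
region with a mirror-symmetric hexagonal lattice of identical cylinders — a
stand-in for the reference symmetric arrangement, whose coordinates are not
published — optionally jittered by independent per-axis uniform displacements
with stated bounds (the generating distribution of the reference phantom is
likewise unpublished; only achieved min/max displacements are known, which
the generator reports for comparison). The default region (radius 5.5 µm,
pitch 2.2 radii) holds 83 cylinders of 0.5 µm radius without overlap.
`make_dentin_slab()` places water-filled tubules (`n = 1.33`, radius 1 µm)
uniformly at random in a dentin slab (`n = 1.52`); the background index
equals dentin everywhere so that the air–dentin surface reflection is
suppressed and only tubules scatter. All randomness flows through the
spec's seed; identical spec and seed give bit-identical scenes.

`mean_free_path()` converts a slab's tubule concentration into the scattering
mean free path `L = pi a^2/(C_sca f)`, `f = N pi a^2/(Lx Ly)`, with `C_sca`
from the exact series at the in-medium wavelength. For the dense reference
slab (122 tubules in 40.4 × 69.3 µm²) this gives 7.0 µm — multiple scattering
dominates — and 24.8 µm for the diluted slab.

What the generator does *not* emulate: real dentin microstructure (tubule
size dispersion, peritubular cuffs, gradual index variations), absorption and
dispersion (all indices are real and constant across the band), shot noise
and detector roll-off, and 3D geometry (everything is extruded along the
cylinder axis). Passing tests therefore demonstrate the fidelity of the
*image-formation chain* on controlled scenes, not quantitative agreement
with measured dentin tomograms.

## Measuring echoes, and what sits deep in a cylinder tomogram

The front- and back-surface echoes of a single cylinder are the two dominant
peaks of the axial A-scan; their separation reproduces `2 a n_cyl/n_med`
within one depth bin for radii from 2 to 20 µm. Behind the back surface the
tomogram is not empty: apart from the specular multiple-reflection echo
(transmission, three internal reflections, transmission — expected one echo
spacing behind the back surface), the converged model shows weaker,
laterally broad features a few bins away from the specular positions
(glory-type off-axis internal paths and beam-side-lobe interactions). These
features are physical within this model: they are independent of all
quadrature refinements and are reproduced identically by an independent
re-implementation of the chain. `axial_echo_train()` therefore locates the
multiple-reflection echo by its mechanism rather than by raw strength: it
extrapolates the *measured* front/back spacing arithmetically (each
additional pair of internal traversals adds the same optical distance) and
takes the local maximum nearest the extrapolated position, within an
eighth-spacing window. The measurement uses only the A-scan itself; for the
default 20 µm cylinder it lands on the depth bin at 63.75 µm with the
expected `r^2`-suppressed amplitude.

## Problem sizes used by the shipped tests

The test suite runs the full-resolution A-scans (160 wavenumbers) for the
5 µm and 20 µm cylinders, single-wavenumber grid-solver validations at 13 and
24 cells per wavelength on ~300–540² grids, and a scaled-down cluster B-scan
(32 wavenumbers, 9 scan positions, spectral cut-off 1e-8) for the
polarisation-contrast, symmetry, determinism and normalization properties;
these sizes keep the whole suite around three minutes on one CPU while
exercising every operator at the accuracy the acceptance checks need.
Full-scale B-scans (83 positions) run in tens of minutes per polarisation
with the analytic path; grid-path B-scans cost one Helmholtz solve per
wavenumber and position and are meant for batch use via `run_from_config()`.

## Known limitations

* Strictly 2D: cylindrical lenses, slit aperture, extruded scatterers.
  Axial and lateral point-spread functions differ from the 3D instrument's.
* The analytic multi-cylinder path is single-scattering; dense clusters need
  the grid path (perpendicular polarisation) for inter-scatterer coupling.
* Real refractive indices only; no dispersion, absorption, or noise model.
* The grid solver covers the perpendicular channel; parallel polarisation is
  exact on cylinder scenes only.
* Aberrations are not modeled (the Debye–Wolf integrand accepts an arbitrary
  midplane field, so a phase screen can be injected by power users, but no
  tested interface is provided).
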