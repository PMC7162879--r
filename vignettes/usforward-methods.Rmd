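---
title: "Methods: the usforward ultrasound forward-problem framework"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the usforward ultrasound forward-problem framework}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(usforward)
```

## The problem

An implanted device built from two stacked piezoelectric layers can be
powered and interrogated by an external ultrasound transducer in the
1-10 MHz band. Designing such a device requires predicting (i) the
steady spatial distribution of acoustic pressure around the implant in
inhomogeneous soft tissue, and (ii) the time-resolved echoes that travel
back to the external transducer. `usforward` solves both forward
problems on the same scene description with two deliberately different
operators:

* a **full-domain scattering operator**: the volume integral equation for
  the total pressure in a lossy background, solved iteratively — a
  near-field, time-invariant picture;
* a **ray-tracing operator**: straight acoustic rays refracted and split
  at interfaces, carrying amplitude, attenuation and phase delay — a
  far-field, time-of-flight picture.

## Acoustic model

### Power-law attenuation and the complex propagation coefficient

Each material is described by longitudinal velocity $v$ (m/s), density
$\rho$ (kg/m³) and a power-law attenuation pair $(a, y)$ with $a$ in
dB MHz$^{-y}$ cm$^{-1}$. At frequency $f$ the per-cell complex
propagation coefficient is $\gamma = \alpha + i\beta$ with

$$\alpha = a f_{\mathrm{MHz}}^{\,y} \cdot \frac{100}{8.6859}\ \text{Np/m},
\qquad
\beta = \frac{\omega}{v} + a\,\tan\!\Big(\frac{\pi y}{2}\Big)
  f_{\mathrm{MHz}}^{\,y}\cdot\frac{100}{8.6859}.$$

Unit conventions worth making explicit:

* everything internal is SI (m, s, kg, Np); the table constant is read
  as dB MHz$^{-y}$ cm$^{-1}$, the only reading consistent with its
  published units, so the $(2\pi)^{-y}|\omega|^y$ form collapses to
  $a f_{\mathrm{MHz}}^y$;
* the dispersion factor $\tan(\pi y/2)$ diverges at $y = 1$ (fat,
  muscle). The power-law dispersion relation has no finite tangent form
  there, so for $|y-1| < 10^{-9}$ the correction term is set to zero.
  This only affects $\beta$'s small correction term, never $\alpha$;
* the published water density ("1") is taken as the standard
  1000 kg/m³; the shipped table row can be overridden;
* the piezoelectric rows carry no attenuation pair; scene assembly
  treats them as lossless ($a=0$, $y=1$), while asking for their
  propagation coefficient directly is an error so that silent zero-loss
  assumptions cannot leak into user code;
* PDMS is shipped as a synthetic row with fat-like acoustic properties
  (its impedance is close to fat); it is a modelling stand-in, not a
  measured characterisation.

### Contrast functions

Scenes deviate from a homogeneous background $(\rho_0, \gamma_0)$
(water by default) through two per-cell contrast maps,
$\Delta\rho = (\rho_0-\rho)/\rho$ and
$\Delta\gamma = \gamma_0^2 - (\rho_0/\rho)\,\gamma^2$, both identically
zero wherever the medium equals the background.

## Computational mesh

The domain is an axis-aligned box tiled by cubic cells at three
resolution levels ($h$, $h/2$, $h/4$); cell data live at barycenters,
cells are half-open, and all cell bounds are held as integers in units
of $h/4$, which makes face adjacency exact. Refinement proceeds by
octant splits and propagates across shared faces (not edges or corners)
so that face-adjacent cells never differ by more than one level.

Adjacency is encoded in six sparse matrices (one per face direction): a
same-level or coarser neighbour contributes a single unit entry; a
coarse cell facing $k \le 4$ finer cells carries equal weights $1/k$
(the simplest scheme whose rows sum to one); boundary rows are zero.
The unscaled operators
$\mathrm{div} = 3D - N_{xx+} - N_{yy+} - N_{zz+}$ and
$\mathrm{grad}_c = D - N_{cc-}$ are kept verbatim for testability. For
the physics a scaled variant divides each row by the barycenter
distance to the neighbour and orients the divergence as a forward
difference, $(N_{cc+} - D)/h$; composed with the backward-difference
gradient this reproduces the standard 7-point Laplacian on uniform
interiors. (As printed, the unscaled divergence is the *negated*
forward difference — composing it verbatim with the gradient gives the
Laplacian with the wrong sign, so the scaled physical variant flips
it.)

## The scattering operator

### Kernel quadrature

The integral-equation kernel is the lossy free-space Green function
$G(\mathbf r) = e^{-\gamma_0 |\mathbf r|}/(4\pi|\mathbf r|)$. At the
study's mesh resolutions the cells are many wavelengths across
($h = 2.5$ mm $\approx 8\lambda$ at 5 MHz in water), and a naive
point-kernel-times-volume quadrature produces inter-cell couplings of
order $10^2$: the discrete system then has nothing to do with the
weakly-scattering physics it discretises. `usforward` therefore uses
the *weak form* of the kernel: every entry is the exact analytic mean
of the point kernel over the source cell's equivalent-volume sphere
(radius $r_{eq} = h(3/4\pi)^{1/3}$),

$$\bar G = G(\mathbf r)\cdot
\frac{3\,(x\cosh x - \sinh x)}{x^3},\quad x = \gamma_0 r_{eq},$$

with the exact sphere mean on the diagonal (the same regularisation,
evaluated at zero distance). The averaging carries the intra-cell phase
cancellation that the point kernel ignores, keeps the operator a small
perturbation of the identity in the Born regime, and reduces to the
classical $3/(8\pi r_{eq})$ self-term in the lossless limit. This is
the package's own quadrature choice; the operator interface and all
contracts are unchanged by it.

### Incident field and solver

The source is a circular piston (default radius 5 mm) discretised on a
regular raster; the incident field
$p^{inc}(\mathbf r) = i\omega\rho_0\sum_k G(\mathbf r - \mathbf r_k)
s_k\,\Delta S$ is computed once per scenario and never updated during
iteration.

The linear system $O[p^{tot}] = p^{inc}$, with
$O[p] = p - \bar G[\Delta\gamma\, p\,V]
- \bar G[\nabla\!\cdot(\Delta\rho \nabla p)\,V]$, is solved by
conjugate gradients on the normal equations: directions are built from
the Hermitian adjoint $O^H$, with direction weight
$\|O^H r_n\|^2/\|O^H r_{n-1}\|^2$ and step
$\|O^H r_n\|^2/\|O \xi_n\|^2$. A variant using *plain* (unsquared) norm
ratios is retained behind `variant = "norm"`: its step size has the
wrong scale and it diverges or stagnates on all but trivial scenes,
which is why the squared form is the default. The stopping rule is the
study's: at most 100 iterations, relative residual
$\|r\|_2/\|p^{inc}\|_2 \le 10\%$, with the full error/step history
returned for convergence plots.

The dense kernel matrix is held explicitly up to a few thousand cells
(the desk-scale regime all shipped scenes use); the solver only touches
it through matrix-vector products, so a matrix-free path can be swapped
in for larger domains.

## Phantom stage

Grey-level slice stacks are smoothed per-slice with a 5×5 Gaussian mask
($\sigma = 1$ px, reflection padding), clustered by k-means on
intensity (centres initialised at evenly spaced quantiles of the unique
values, so the result is deterministic; clusters are relabelled in
increasing mean intensity), and despeckled: any voxel none of whose six
face neighbours shares its label takes the majority neighbour label,
ties to the smaller label.

Tissue boundaries are found by radial marching: from the tissue
centroid, 2048 near-uniform directions (Fibonacci sphere) are marched
in half-voxel steps until the label changes; the transition midpoint is
a boundary sample and the radial direction is its outward normal. The
procedure assumes star-convex tissues; when the centroid falls outside
the tissue the march starts from the nearest tissue voxel and a warning
is logged. A single-voxel tissue degenerates to its six face centres
with axis normals.

Grid cells take the majority label among the voxel centres they cover
(ties to the smaller label); cells finer than the voxel raster sample
the voxel containing their barycenter.

### Synthetic scenes

Because the original anatomical imagery is not redistributable, the
package generates its study scenes:

* `water_tank` — a homogeneous water box, 30 cm × 25 cm × 25 cm by
  default, matching the bench-validation tank geometry, with the source
  plane on one wall;
* `layered_breast` — a hemispherical breast analog: 2 mm skin shell
  (mapped to the fat-like PDMS row, as in the physical phantom's
  construction), 10 mm subcutaneous fat shell, breast core of 25 mm
  outer radius, mounted on a 10 mm muscle "chest wall" slab in a water
  bath; 6 cm cube domain, 2 mm voxels, 10 mm base mesh;
* `homogeneous` — a single-material box for operator tests.

These emulate the *geometry and material layering* of the study
scenes, not real tissue: there is no intra-tissue heterogeneity, no
speckle-generating microstructure, and the interfaces are smooth
analytic surfaces. Passing tests therefore demonstrate the correctness
of the operators and bookkeeping on faithful geometry, not predictive
accuracy on clinical anatomy.

## Implant models

An implant is a nominal bounding solid (default 1 cm × 1 cm × 0.5 cm)
in one of three shapes — plano-convex **lens** (cylindrical lower half
plus a paraboloid cap of height equal to half the bounding thickness),
**disk** (right cylinder), **cone** (apex along the orientation axis) —
containing a PDMS shell (default 0.5 mm), an outer and an inner
piezoelectric layer. The six allowed inner/outer material pairs combine
PZN-PT or PZT-5A with LiNbO₃, BaTiO₃ or PVDF; layer thickness pairs are
0.5/1 … 2.5/5 mm.

Nesting is realised by an anisotropic parametric shrink: each inner
surface is the nominal shape with radius reduced by the cumulative
offset $\delta$ and height reduced by $\delta$ (base raised
$\delta/2$). A fully isotropic inward offset would collapse the inner
core for most allowed thickness pairs inside the default 5 mm-tall
envelope, so the shrink is the geometry that keeps every pair up to
2/4 mm realisable while preserving strict nesting; 2.5/5 mm needs a
taller bounding box and is rejected by validation. Exact lens curvature
and cone apex angle are not prescribed anywhere; both derive from the
bounding dimensions and are documented assumptions.

Every layer surface is sampled with spacing below a quarter wavelength
at 10 MHz in soft tissue (≈ 38 µm), with analytic outward normals and
their exact negatives as inward normals. Embedding assigns layer
materials to cells innermost-wins, appends the layer surfaces to the
scene, optionally refines the mesh to the finest level over the implant
box plus the source–implant corridor, and keeps the pre-override maps
so the operation is reversible.

## Ray tracing

* **Refraction index.** The study's $n_j$ is taken as
  $n = v_{\mathrm{background}}/v_{\mathrm{medium}}$, which reduces the
  vector Snell update to the standard $\sin\theta_1/v_1 =
  \sin\theta_2/v_2$.
* **Amplitude split.** The framework's conservation rule
  $\Upsilon = \Upsilon^T + \Upsilon^R$ is enforced exactly:
  $\Upsilon^R = R\,\Upsilon$, $\Upsilon^T = \Upsilon - \Upsilon^R$ with
  $R = (Z_2-Z_1)/(Z_2+Z_1)$. The physically standard pressure
  transmission $T = 1 + R$ violates that conservation and is available
  via `split_mode = "pressure"`. $R$ is the normal-incidence
  coefficient regardless of the actual angle (the 1-D interface model;
  no oblique formula is prescribed).
* **Normals.** Interface hits are detected as label changes of the
  per-cell material map (bisected to sub-step precision); the normal is
  the nearest sampled surface normal within the intersection tolerance
  sphere of radius $0.5 \times 4500/f$ (4500 m/s is the stated average
  velocity of the media involved), flipped when needed so it opposes
  the incident direction. With no surface sample in range the ray
  continues straight into the new medium (logged by its segment
  record).
* **Emission.** Rays start at uniform random points of the source disk
  with directions drawn in a forward cone (default half-angle 30°,
  seeded); per-ray amplitude is the source amplitude over the ray
  count. The angular density is a configuration choice, as no emission
  formula is prescribed.
* **Termination.** Domain exit, 1000 accumulated wavelengths, carried
  amplitude below the 10 µV equivalent ($10^{-5}$), or a generation cap
  (default 6 interface events) that bounds the branching tree.
* **Detection.** A ray is recorded when its terminal segment crosses
  the detector disk; amplitude is attenuated to the crossing point and
  the arrival time is the accumulated $\sum \Delta\ell_i/v_i$. Records
  below threshold are dropped and at most 1200 are kept (largest
  amplitudes first) — both rules applied bit-exactly by
  `filter_echo_records()`.

## Signals

The impulsive excitation is
$v(t) = 10\sin(\omega t)\,
\exp\{-[0.2\,\omega(t - 8\pi^2/\omega)]^2/20\}$ (the $\Pi$ in the
printed envelope is read as $\pi$, the only dimensionally sensible
reading), sampled at 20 MS/s over 100 µs, matching the acquisition
chain. Echo synthesis superposes the excitation template at each
arrival time scaled by its amplitude, under the stated perfect
electromechanical coupling (pressure-to-voltage factor 1). Echo energy
is $\sum_t |x(t)|^2$; the spectrum is the one-sided DFT magnitude
without further normalisation, so time-domain energy equals
$\sum_k |X_k|^2 / N$ over the full transform (Parseval, verified in the
tests).

## Problem sizes and tolerances

The shipped study scene (layered breast, lens implant PZT-5A/LiNbO₃
1 mm/2 mm, 5 MHz) uses the 6 cm domain with base $h = 10$ mm refined to
2.5 mm over the source–implant corridor, giving ≈ 1800 cells — the same
resolution ladder as the full-size phantoms at a desk-scale cell count
chosen so the dense kernel and 100-iteration budget run in seconds.
Solver-oracle comparisons use ≤ 500-cell random-contrast boxes with
property perturbations of a few percent (Born regime), where the
iterative solution is required to match a dense direct solve to
$10^{-6}$ relative and the adjoint to pass the inner-product identity
to $10^{-10}$. Geometry identities (refraction at matched indices, unit
norms) are asserted to $10^{-12}$ away from grazing incidence, where
the vector update is ill-conditioned.

## Known limitations

* Longitudinal waves only: no shear-wave conversion, elasticity or
  anisotropy; no diffraction in the ray picture.
* The Born-regime assumption is structural: strongly resonant
  configurations would need finer meshes and a different kernel
  treatment.
* Angle-independent interface coefficients and the amplitude
  conservation split are the framework's stated simplifications, not
  oblique-incidence physics.
* The synthetic scenes are geometric analogs; no claim is made about
  predictive accuracy on clinical imagery.
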