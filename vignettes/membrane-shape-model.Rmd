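---
title: "The isolation-membrane shape model: methods and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The isolation-membrane shape model: methods and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the science and the
numerics: the physical model and its assumptions, the parameters that
matter, how the minimiser works and where it can fail, what the
synthetic-image generator does and does not emulate, and the design
choices made where the problem left the design open.

## The physical model

The expanding isolation membrane (IM) is modelled as one axisymmetric
surface standing for two closely juxtaposed membranes with the same
curvature and area — the lumen between them is thin, so they stay nearly
parallel.  The surface runs from a smoothly closed pole to an open
circular rim, parametrised by arc length $s \in [0, s_1]$ and tilt angle
$\theta(s)$, with $\dot x = \cos\theta$, $\dot z = \sin\theta$, and
total curvature $J = \dot\theta + \sin\theta / x$.

Its free energy is elastic bending plus osmotic work:

$$F = 2\pi \int_0^{s_1} \kappa_b\, x \Big(\dot\theta +
\frac{\sin\theta}{x}\Big)^{2}\, ds \;-\; P V,$$

where the prefactor — twice the per-membrane Helfrich coefficient
$\kappa_b/2$ — counts both membranes, so a closed double-membrane sphere
costs $16\pi\kappa_b$ regardless of radius.  Spontaneous curvature is
zero (the membranes carry few proteins).  The rim's own energy is
excluded: in vivo a curvature-stabilising protein complex sits on the
rim, so the rim is treated as energetically stable and only its radius
enters, as a constraint.  Morphological change is slow (minutes)
compared to mechanical relaxation (milliseconds), so each state is a
constrained equilibrium — the shape minimises $F$ at fixed total area
$A = 4\pi\int x\,ds$ and fixed rim radius $x(s_1) = x_r$.

**The sign of the osmotic term.**  The biological scenario is particle
*exclusion*: complexes larger than the opening cannot enter the covered
volume $V$, so the interior is depleted of them and the osmotic pressure
difference draws water out of $V$.  With $P$ the interior-minus-exterior
pressure difference, $P = -\,\Pi$ where $\Pi = c N_A k_B T \geq 0$ is
the van't Hoff pressure of the excess concentration $c$ of excluded
particles outside.  The reported `pressure_work` is the signed $P V$
(negative here), `total_free_energy = bending - pressure_work`
$= E_{bend} + \Pi V$, and minimisation therefore trades bending energy
against covered volume.  `model_params()` stores the magnitude $\Pi$ and
the non-negative $c$; the sign is applied inside the energy.

## Parameters

| parameter | default | units | origin |
|---|---|---|---|
| $\kappa_b$ | 20 | $k_BT$ per membrane | standard lipid-bilayer stiffness |
| $x_r$ | 12.5 | nm | half the ~25-nm exclusion cut-off measured for sorting-nexin-deficient cells |
| $A$ | $\pi$ | µm² | area of a 0.7-µm autophagosome, both membranes |
| $T$ | 303.15 | K | 30 °C culture temperature; not stated with the model, fixed here and recorded in every output |
| $c$ | 0 | µM | swept 0–15 (or 0–20) in 0.5-µM steps |
| `n_nodes` | 200 | — | meridian discretisation |

The temperature choice matters only through $k_BT$ and the van't Hoff
factor and shifts nothing qualitatively (±2% over 293–310 K).

## Discretisation and minimisation

The shape is the vector $(\theta_2,\dots,\theta_n, s_1)$ on a uniform
grid ($\theta_1 = 0$ pins smooth pole closure); $x$ and $z$ are midpoint
integrals of $\cos\theta$, $\sin\theta$.  This parametrisation makes the
geometric-constraint multiplier of the continuum functional identically
zero, leaving two scalar constraints (area, rim radius).

Numerical choices, each adopted for a concrete failure it prevents:

* **Staggered quadrature.**  Curvature and the bending/pressure
  integrands are evaluated at interval midpoints with forward
  differences of $\theta$.  Node-centred differences are blind to
  grid-scale sawtooth modes, which an optimiser will exploit to fake
  sub-resolution crumpling at zero apparent cost; the staggered form
  penalises them.  It also removes the pole singularity automatically:
  $\sin\theta_m / x_m \to \dot\theta$ at the pole without special cases.
  The area and rim constraints instead use the node-based trapezoidal
  rule, the same quadrature as `membrane_area()`, so converged profiles
  satisfy the package-level area check to the constraint tolerance
  (default $10^{-6}$ relative).
* **Augmented Lagrangian.**  Constraints enter as
  $\lambda r + \mu r^2$ with multiplier updates and penalty escalation
  until both residuals pass tolerance; the inner solver is L-BFGS-B with
  box constraints $\theta \in [-\pi/2, 3\pi/2]$ (excluding
  self-intersecting wrap-around) and an analytic gradient (reverse
  accumulation through the cumulative $x$ integral; validated against
  finite differences in the test suite).
* **Solver memory.**  The bending functional is ill-conditioned — the
  landscape around the spheroidal branch is flat to $\sim10^{-4}\,k_BT$
  along shape modes that move the aspect ratio by $10^{-3}$.  With the
  default 5 limited-memory vectors L-BFGS-B stalls in this basin and
  successive sweep points jitter; with 25 vectors (`lbfgs_memory`) and a
  tight stopping criterion (`lbfgs_factr = 1`) the aspect-ratio curve
  along a sweep is smooth and monotone.
* **Resolution guard.**  A tilt step per interval above
  $\min(0.7,\; 0.25 + x_m/4h)$ radians means the feature bends at a
  radius the grid cannot represent; there the staggered and node-based
  quadratures disagree and the optimiser can park spurious kinks in the
  gap.  Such steps are penalised out of the search space.  Because the
  guard still cannot make nanometre-scale rim flares representable, the
  equilibrium energy report uses the minimiser's own staggered
  quadrature; for resolved shapes it agrees with
  `free_energy(profile, params)` to $O(h^2)$ (0.03% at the defaults).
* **Starts and branch selection.**  Deterministic candidates — the
  analytic rim-matched spherical cap (closed form:
  $1-\cos\psi_1 = 2 - 4\pi x_r^2/A$), capsules of 150- and 250-nm tube
  radius, the warm start — plus seeded random perturbations are first
  minimised at a loose tolerance (branch comparison needs only
  $\sim10^{-5}\,k_BT$ discrimination), then the winner is polished
  tightly.  Ties within `tolerance_energy` resolve in favour of the
  warm start, keeping continuation smooth where the landscape is flat.
* **Continuation and hysteresis.**  Sweeps warm-start each point from
  the previous one, then run a reverse pass (high → low $c$); the
  lower-energy branch wins at each point.  The spheroid-to-tubule
  transition is first-order (the energy branches cross), so one-sided
  continuation alone would overshoot it.
* **Tubular classification.**  Aspect ratio $L/W \ge 1.5$ with $L$ the
  axial extent and $W = 2\max x$.  "Tubular" has no quantitative
  definition in the imaging literature this model connects to; the
  threshold is a package choice, always reported with the raw ratio.

Problem sizes used by the tests and the acceptance script — 200 nodes,
0.5-µM steps over 0–15 µM (tests) or 0–20 µM (acceptance script), four
starts per sweep point — were chosen so a full sweep resolves the
transition cleanly; refinement to 400 nodes moves minimised energies by
well under 0.5%.

## What the model sweep shows

With the functional and parameters above, the equilibrium shape
elongates monotonically but gently over 0–15 µM (aspect ratio 1.07 →
1.19) and jumps onto the tubular branch between 16 and 17 µM
(`scripts/acceptance.R` reports the measured onset; 16.5 µM at the
default grid).  Two cross-checks agree with this placement: a
restricted analytic family of prolate spheroids at fixed area puts the
sphere/tubule energy crossover near 19–20 µM, an upper bound the full
minimiser improves on; and the linear-response estimate of the osmotic
gain, $\Pi \Delta V \approx 111\,c\,k_BT$ per unit reduced volume,
matches the computed pressure-work column.

The onset scales directly with the bending-energy normalisation: halving
the bending prefactor (a single-membrane reading of the same shape)
halves it to ~10 µM, and a mean-curvature convention
($J/2$ in place of $J$) quarters it to ~4 µM.  Under the
double-membrane total-curvature normalisation implemented here — the
one consistent with the $16\pi\kappa_b$ closed-sphere energy — the
onset sits above, not below, the ~10 µM cytoplasmic ribosome
concentration.  The qualitative conclusion (osmotic exclusion of large
particles is sufficient to tubulate the cisterna at micromolar
concentration differences) survives in all conventions; the placement
of the threshold relative to the ribosome concentration does not, and
this package reports the number its stated functional actually
produces.

## The synthetic-image generator

`render_stack()` emulates the acquisition the morphometry rules were
written for: z-stacks at 0.2-µm intervals, lateral sampling 65 nm per
pixel (an assumption — the real camera's pixel pitch is not public — and
a parameter, not a constant), an anisotropic Gaussian point-spread
stand-in ($\sigma_{xy} = 100$ nm, $\sigma_z = 300$ nm), Poisson photon
statistics, Gaussian read noise, and a uniform background.  Structures
(rings, sub-resolution puncta, cup shells, capsule-shaped tubules, or
revolved model profiles) are sampled as deterministic point clouds
weighted by surface area, so noiseless renders are exactly reproducible
and photon mass is conserved to blur truncation.  Default photon budget
(40 000 per structure over background 10) puts structure peaks roughly
an order of magnitude above background, matching the look of
well-exposed yeast fluorescence data.

Deliberately **not** modelled: the true (Airy/Gibson–Lanni) PSF and the
deconvolution step applied to the real microscope's stacks, EM-gain
statistics, two-channel chromatic registration, bleaching and focal
drift.  Ground-truth-recovery tests on these images therefore validate
the measurement code, not the microscope: passing them says the pipeline
measures what is in the image, not that a particular real instrument
would produce that image.

## Morphometry rules and their numerics

Measurements run on the maximum-intensity projection, with 0-based pixel
indices and intensities at pixel centres:

* **Segmentation** — Gaussian smoothing (σ 0.5 px, border-renormalised),
  Otsu threshold (256-bin between-class variance), 8-connected
  labelling, minimum area 9 px.  Components whose peak does not exceed
  the expected maximum of background noise
  (median + MAD·($\sqrt{2\ln N}$ + 2), an extreme-value bound) are
  discarded, so noise-only images segment empty.  The area/circularity
  filter with recorded settings replaces the manual exclusion of
  non-IM signals that the original imaging protocol required.
* **Outlines** — sub-pixel iso-contours of the smoothed image at the
  threshold level; a 5-vertex circular moving average removes pixel
  staircase wiggle (which otherwise inflates perimeters by ~5%).
  All outline geometry (area, perimeter, centroid, second moments)
  comes from exact Green's-theorem polygon formulas.
* **IM size** — half the outline perimeter.  For hollow (ring-topology)
  components the mean of the outer and hole outlines is used: the
  bright band straddles the true outline symmetrically under blur, so
  averaging cancels the widening to first order.
* **Opening size** — the ellipse major axis, from filled-polygon second
  moments (axis length $4\sqrt{\lambda}$).  Rings again average outer
  and hole ellipses, then undo the known first-order ridge shift of a
  blurred thin ring (the band peaks inward of the true radius by
  $\sigma^2/2\rho$).  Sub-resolution filled blobs are modelled as what
  they are in this imaging context — unresolved small rings — and sized
  from blur-corrected intensity moments,
  $d = 2\sqrt{2(\lambda - \sigma^2)}$; this uses the configured
  `psf_sigma`, the one place the pipeline assumes knowledge of the
  instrument.  If a sub-resolution blob were instead a filled disc this
  estimator would undersize it by $\sqrt2$.
* **Classification** — elongation ≥ 2 → tubule; hole → ring; small →
  punctum; otherwise other.
* **Summaries** — quartiles by linear interpolation (type 7; the
  convention is recorded because no standard was stated), whiskers at
  the most extreme observations within 1.5 IQR of the quartiles.  The
  implementation is checked against an independent brute-force
  implementation of the same definition on 1000 random multisets.

Recovery performance at the defaults (100 seeded rings, 200–800 nm,
full noise): median absolute major-axis error ≈ 0.5 px, dominated by
sub-resolution puncta; resolved rings measure to ≤ 0.3 px.

## Known limitations

* Axisymmetric shapes only: pearling with broken symmetry, bent tubes
  and the "waving" of real mutant cisternae are outside the search
  space, so the computed onset is an upper bound on the true
  symmetry-unrestricted one (the soft mode at the transition is itself
  axisymmetric, so the bound should be tight).
* No dynamics: the model cannot address how tubules later collapse into
  spheres, only which static shape wins at each pressure.
* The rim is a hard constraint; partial rim stabilisation (intermediate
  protein levels) would need a rim energy term.
* The generator's Gaussian PSF and the pipeline's psf-aware corrections
  are mutually consistent by construction; on deconvolved real data the
  effective σ would have to be re-estimated.
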