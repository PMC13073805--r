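---
title: "Mapping the long-range electrostatic field of a chaperonin cavity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping the long-range electrostatic field of a chaperonin cavity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cavityfield)
```

## The problem

Chaperonins of the HSP60/HSP10 (GroEL/GroES) family are barrel-shaped
double-ring complexes whose enclosed chambers assist the folding of client
proteins. Their cavity walls are negatively charged, and a long-standing
question is what physical environment a substrate experiences inside the
chamber. One measurable component of that environment is the *long-range*
electrostatic potential — the smooth, reciprocal-space term of the Ewald
(particle-mesh Ewald, PME) decomposition of periodic electrostatics, i.e.
the potential of Gaussian-smeared charges, without the short-range
point-charge correction. Averaged over an equilibrated molecular-dynamics
trajectory, this potential turns out to be highly structured and nearly
time-invariant within the cavity, and its gradient is, to first order, a
constant electric field aligned with the barrel axis.

`cavityfield` implements the full analysis chain that extracts this field
from a trajectory of charge-annotated structures:

1. **Potential mapping** — the reciprocal-space Ewald potential of each
   frame on a periodic grid, frames rigidly superposed to a reference;
2. **Time statistics** — per-grid-point mean $\langle\phi_{lr}(r_i)\rangle$
   and population standard deviation
   $\sigma(r_i) = \sqrt{\langle\phi_{lr}^2\rangle - \langle\phi_{lr}\rangle^2}$,
   rescaled from kT/e at 300 K to volts;
3. **Cavity isolation** — the largest axis-aligned ellipsoid inscribed in
   the chosen cavity, found by a geometric inside-out inversion;
4. **Control-point selection** — in-ellipsoid grid points with
   $\sigma < 0.5$ V;
5. **Field fitting** — linear and quadratic polynomial models of
   $\langle\phi_{lr}(r)\rangle$ by least squares, the electric field as the
   negative analytic gradient, and export of the constant field in the
   4-field MD-engine keyword convention.

A synthetic-data module generates charged-barrel trajectories with planted
axial fields and noisy polynomial grids, so that each stage — and the chain
end to end — is testable against known ground truth without any external
trajectory.

## The potential model

For a frame with charges $q_j$ at positions $r_j$ in an orthorhombic cell of
volume $V$, the reciprocal-space potential is

$$\phi_{lr}(r) = \frac{4\pi C}{V} \sum_{k \neq 0}
  \frac{e^{-k^2/4\beta^2}}{k^2} \sum_j q_j \cos(k\cdot(r - r_j)),$$

with $k = 2\pi(m_x/L_x, m_y/L_y, m_z/L_z)$ and $C$ the Coulomb constant
expressed in (kT at 300 K)/e per e/Å. The splitting parameter $\beta$
(default 0.25 Å⁻¹, the documented default of the standard PME potential
mapping plugin; the source study does not state its value) sets the Gaussian
smearing width: the map is the potential of smoothed charges, meaningful
*away* from atoms. The $k=0$ term is dropped (tinfoil boundary), so
potentials are defined up to an additive constant; every downstream result
(gradients, fields, all non-intercept coefficients) is invariant to that
constant, which the test suite asserts explicitly.

`pme_reciprocal_grid()` evaluates this sum by smooth PME: cardinal B-spline
charge spreading (order 4 by default), 3D FFT, multiplication by the
influence function, per-axis deconvolution of the spline transfer function,
inverse FFT. `ewald_reciprocal_direct()` evaluates the same sum literally,
k-vector by k-vector, and serves as the independent oracle: on a 32³ grid
with 8 charges the two routes agree to better than $10^{-3}$ relative
(measured ~$10^{-4}$) at grid points more than 4 Å from any charge — near
charge sites the B-spline interpolation error concentrates, and the map is
not meant to be read there anyway.

Unit conventions: mesh potentials come out in kT/e at 300 K;
`rescale_to_volts()` multiplies by 0.0258 V, the conventional factor for
this map type (the exact CODATA value $k_B\,300\,\mathrm{K}/e = 0.025852$ V
differs by 0.2% and is available in `unit_constants()`; re-rescaling an
already-volt grid is an error by design).

### Frame alignment and grid placement

Frames are superposed onto the first frame by unweighted least-squares rigid
superposition (Kabsch, proper rotations only); the per-frame, post-fit
all-atom RMSD is returned. PQR-style inputs carry no masses, so the
unweighted centroid stands in for the center of mass everywhere, matching
the unit-weight superposition. After alignment, the mapping grid box is
re-centered at each frame's centroid (the residual drift is well below a
grid spacing); `accumulate_stats()` therefore accepts grids whose specs
differ only in center when `allow_center_drift = TRUE`, and records the
drift. Per-point statistics use the population (divide-by-N) variance —
the $\langle\phi^2\rangle - \langle\phi\rangle^2$ definition — evaluated in
its numerically stable two-pass form, so that identical frames give exactly
zero sigma.

## Cavity isolation by geometric inversion

`inscribe_ellipsoid()` finds the largest axis-aligned ellipsoid inside the
upper (or lower) cavity: center the assembly at its centroid, keep the
half above the xy plane, re-center the half and scan a small axial offset
$\Delta z \in [-6, 6]$ Å in 1 Å steps, rescale by the half's bounding-box
dimensions $(A, B, C)$, invert the scaled cloud inside out through a large
sphere, and read the inscribed radius $\rho$ off the enclosing radius of the
inverted cloud. Candidate semi-axes are $(A\rho, B\rho, C\rho)$; the scan
offset maximizing the volume wins; 1 Å is then subtracted from each
semi-axis as a safety margin.

Numerically, the inversion maps the atom nearest the scaled center to the
outermost inverted point, so $\rho$ equals the minimum scaled distance —
which is exactly what the cross-check `brute_force_inscribed()` computes by
direct minimization over atoms. The two routes agree to $10^{-13}$ Å on
random shells; the pre-shrink ellipsoid provably touches no atom center
(quadratic form $\ge 1$ for every atom of the scanned half) and growing any
semi-axis by 1% admits one.

Design decisions, where the procedure was genuinely open:

* the $\Delta z$ step is 1 Å (only the range is prescribed by the
  procedure's provenance; the known winning offset is an integer);
* "largest" means maximal volume across the scan;
* the shrink margin is applied in original (unscaled) Å after mapping back
  — the alternative ordering (shrink in scaled space) is not equivalent,
  and the unscaled reading makes "1 Å" a physical clearance;
* contact is tested against atom *centers*, not atom surfaces; membership
  itself is strict (`quad form < 1`), so a surface point is outside.

## Control points and the sigma filter

`select_control_points()` keeps grid points strictly inside the ellipsoid
with $\sigma < \sigma_{max}$ (default 0.5 V, applied after volt rescaling).
Both inequalities are strict, and the "keep low sigma" direction is the one
consistent with removing the high-fluctuation points near mobile atoms.
The selection records provenance (ellipsoid, threshold, `n_inside`,
`n_kept`) that survives the CSV round trip, and the removal percentage
$100(n_{inside} - n_{kept})/n_{inside}$ is an invariant of every run
report. `sigma_distribution()` summarizes the sigma field inside the
ellipsoid (density histogram, empirical CDF, fitted normal CDF,
tail-exceedance fractions); `autoplot()` draws it.

## Least-squares field models

With control points $\{r_i\}$ and observed potentials $F_i$, the design
matrix $M$ holds the monomials $x^{a_\alpha} y^{b_\alpha} z^{c_\alpha}$ —
4 terms for the linear model, 10 for the quadratic, first column all ones,
coordinates raw in global Å. The coefficient vector solves $A = M^+ F$ via
QR; rank decisions use the singular spectrum with a $10^{-10}$ relative
cutoff, and a deficient design (e.g. coplanar points) errors naming the
unresolvable term. $R^2 = 1 - S_{res}/S_{tot}$, unadjusted. Raw coordinates
near 200 Å make the quadratic normal equations ill-conditioned
(condition number $\sim 10^{14}$); the orthogonal decomposition sidesteps
this, an optional centered mode (`center = TRUE`) improves conditioning
further and reproduces identical predictions, and exact trailing-digit
agreement with coefficient tables produced by other solvers is therefore
not guaranteed. Standard errors come from the usual
$\hat\sigma^2 (M^TM)^{-1}$ covariance; `tidy()`/`glance()`/`augment()`
expose everything in broom shape.

The field is the negative analytic gradient: constant for order 1
(`export_field_keyword()` emits it as
`electric-field-z = <10 * Ez_V_per_Å> 0 0 0`, 4 significant figures, the
4-field engine convention), position-dependent for order 2 (validated
against central differences). `relative_components()` evaluates
$|E_x|/|E|$, $|E_y|/|E|$ and $-E_z/|E|$ at every control point to make
axial dominance checkable as a boolean.

## What the synthetic generators emulate — and what they do not

`make_barrel_trajectory()` produces the geometry the analysis assumes: a
negatively charged cylindrical wall (4000 atoms, 30 Å radius, 60 Å height
by default), cap disks carrying ±2.4 e that plant a known axial field
across the empty cavity, isotropic per-frame Gaussian jitter (0.3 Å), and a
10% subset of extra-mobile atoms (5× jitter) near the cavity floor that
reproduces the high-fluctuation zone the sigma filter exists for. The cell
is charge-neutral; the declared cavity ellipsoid is verified empty in every
frame; everything is a pure function of the spec and its seed. What it does
*not* emulate: protein geometry, solvent, short-range electrostatics, or
correlated (collective) motions — jitter is uncorrelated across atoms and
frames. Passing the end-to-end test therefore shows the pipeline recovers a
planted field's sign and axial dominance under idealized noise, not that
any particular biological system has such a field.

`make_planted_gridstats()` skips the trajectory entirely and plants a
polynomial mean field plus heteroscedastic noise on a grid — the fastest
way to test selection and fitting against exact ground truth, including
exact ($10^{-10}$) recovery in the noiseless limit and recovery within
three analytic standard errors under noise.

### The reconstructed reference set

The reference study's control-point file is available only on request, so
`make_reference_control_points()` builds a synthetic surrogate from
published quantities alone: the 120³ mapping grid geometry
(171.36 × 171.26 × 263.09 Å box; the absolute grid origin is not published,
so the box is centered on the published ellipsoid center), the published
ellipsoid, the published ten quadratic coefficients as truth, iid Gaussian
misfit calibrated to the published order-2 $R^2$ (0.9892), and a Gaussian
sigma field calibrated so the published fraction (8.4%) exceeds the 0.5 V
threshold (center 0.3 V chosen as a plausible mid-scale; only the tail
fraction is calibrated). Two things are *not* inputs and become genuine
consistency predictions: the order-1 refit and its $R^2$. On the surrogate
the linear fit lands at $A_z \approx 0.160$ V/Å and $R^2 \approx 0.975$
against published values 0.16188 and 0.9740 — a ~1% agreement that the
published tables did not have to exhibit, and the per-point axial-dominance
and sign-constancy properties of the quadratic field hold at every
surrogate point.

## Numerical choices and degenerate inputs

* FFT grids: counts must be ≥ 8 and ≥ the spline order per axis;
  orthorhombic cells only (a rhombic-dodecahedral production cell is out of
  scope — the analysis grid is orthorhombic anyway).
* Atoms are wrapped into the periodic cell before spreading; how the
  original study wrapped solvent-free frames is unstated, so wrapping is
  the documented convention here.
* Sigma is clamped at ≥ 0; identical frames give exactly 0 by the two-pass
  variance.
* All-equal observations make $R^2$ undefined — an error, not NaN.
* Fewer points than terms, empty halves, flat halves, atoms at the
  inversion center, ellipsoids containing no grid point: all explicit
  errors with actionable messages.
* Ties in the $\Delta z$ scan resolve to the first maximal offset in scan
  order.

## Problem sizes

The shipped tests and the acceptance script run at desk scale, chosen so
the full suite completes in well under a minute while every check retains
its resolving power: PME-vs-oracle on 32³ grids with 8 charges; shells of
~1000 atoms for the inscription oracle; $\ge 10^4$ control points for
noisy parameter recovery; the barrel end-to-end at 20 frames on a 48³ grid
(about 3 s). The reference surrogate uses the full published 120³ grid and
all ~15,000 surviving control points.

## Limitations

* Only the reciprocal-space term is computed — no short-range/real-space
  term, no self-energy correction; the map is meaningful away from atoms
  and up to an additive constant.
* The ellipsoid is a sampling region, not the cavity; fits are valid
  rigorously inside it.
* No sigma-weighted or regularized regression (a documented extension
  point); no binary trajectory formats (XTC/TRR) — the multi-model
  PDB/PQR carriers are the supported interchange.
* The surrogate reference set reproduces the published fits' statistical
  structure, not the underlying trajectory; conclusions about the real
  system rest on the published values it is built from.
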