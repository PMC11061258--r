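---
title: "Orientation, diffusion and free-energy analysis of helical peptides at lipid bilayers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Orientation, diffusion and free-energy analysis of helical peptides at lipid bilayers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(helimem)
```

## Scope and model

`helimem` analyses coarse-grained simulations of short cationic,
amphipathic helical peptides (antimicrobial peptides, AMPs) interacting
with planar lipid bilayers. The peptide is treated as a rigid helix — the
usual situation in coarse-grained force fields that restrain secondary
structure — represented by one backbone bead per residue. The bilayer is
planar and orthorhombic-periodic, with its normal along z. All internal
units are nm, ns, kJ/mol and Kelvin; angles are reported in degrees and
handled in radians internally.

Two workflows are covered:

1. **Descriptor analysis of unbiased trajectories**: helix orientation
   (tilt and spin angles, hydrophobic dipole moment), residue-class
   composition, distance-cutoff peptide–lipid contact fingerprints,
   z-density profiles, and lateral diffusion coefficients from Rayleigh
   fits of in-plane displacement distributions.
2. **Metadynamics thermodynamics**: reconstruction of well-tempered
   free-energy surfaces (FES) over the collective variables
   (z distance, cosine of the tilt) from Gaussian deposition records,
   Boltzmann projection to 1D potentials of mean force (PMF), partition
   coefficients, standard-state adsorption free energies
   $\Delta G^0$ and membrane-to-membrane transfer free energies
   $\Delta\Delta G^0$.

## Orientation conventions

The descriptors hinge on a handful of sign conventions which are pinned
once and asserted by the test suite:

* **Helix axis.** $\vec{NC} = \vec r_N - \vec r_C$ runs from the
  C-terminus to the N-terminus.
* **Tilt.** $\cos\varphi = NC_z / (|\vec{NC}|\,\alpha)$ with
  $\alpha = -1$ when the peptide sits above the bilayer centre (upper
  side) and $+1$ below. This makes $\varphi = 0^\circ$ mean "N-terminus
  approaching the membrane" and $\varphi = 180^\circ$ the C-terminus, on
  either leaflet.
* **Hydrophobic dipole moment.** $\vec\mu = \sum_i \mu_i \vec r_i$ over
  backbone beads, with $\vec r_i$ relative to the backbone centre of
  mass and $\mu_i$ the Fauchère–Pliska octanol/water hydrophobicity of
  residue $i$ (shipped as `fauchere_pliska`). The longitudinal part is
  the projection on $\widehat{NC}$; the transversal part
  $\vec\mu_\perp$ is the remainder.
* **Spin.** $\hat n$ is the unit z vector pointing from the peptide
  toward the nearer leaflet, i.e. $(0,0,\alpha)$; the tilt reference is
  $\hat t = \widehat{NC}\times(\widehat{NC}\times\hat n)$, normalised.
  The spin angle $\xi = \arccos(\hat t\cdot\hat\mu_\perp)$ is lifted to
  $[0^\circ, 360^\circ)$ by the sign of
  $\widehat{NC}\cdot(\hat t\times\hat\mu_\perp)$ (positive below
  $180^\circ$). With these choices $\xi = 180^\circ$ means the
  hydrophobic face points at the membrane — the physically favoured
  pose of an amphipathic helix lying on a bilayer.

Degenerate configurations — a vanishing transversal moment
($|\vec\mu_\perp| < 10^{-8}$) or a helix axis parallel to z
($|\sin\varphi| < 10^{-6}$, so $\hat t$ does not exist) — yield an
`NA` spin with an explanatory attribute rather than an arbitrary angle.

Two symmetry facts are worth spelling out because they are easy to get
wrong. Carrying the *same* rigid peptide to the other leaflet (a proper
$180^\circ$ rotation about an in-plane axis) leaves both tilt and spin
unchanged: the $\alpha$ and $\hat n$ conventions compensate. A plain
reflection $z\to-z$, by contrast, is improper — it builds the enantiomer
— and flips the spin quadrant, $\xi \to 360^\circ - \xi$, while leaving
$\cos\xi$ intact. Similarly, negating the transversal moment advances
the spin by exactly $180^\circ$ (mod $360^\circ$), consistent with the
$180^\circ/0^\circ$ anchor pair; the tests encode this identity.

Residue classes follow the standard coarse scheme: basic {K, R, H},
acidic {D, E}, polar {S, T, N, Q}, hydrophobic {G, A, V, L, I, P, F, M,
W, C, Y}. Under it the 37-residue LL37 helix is 43.2% hydrophobic and
CM15 contains no polar residue, which the tests pin as reference
fingerprints. Formal charges count +1 per K/R and −1 per D/E with
neutral histidine; zwitterionic termini cancel.

## Contacts and density profiles

A contact is a peptide-bead/lipid-bead pair within a minimum-image
distance of 0.6 nm (default). Counts are aggregated by residue class ×
lipid species and normalised — exactly once, tracked by an attribute —
by the total number of peptide beads of each class, so residues of
different size are comparable. Lipid head/tail roles are not
distinguished in the fingerprint matrix. Averages use a trailing time
window (default the last 1000 ns). The default cell-list counter is
asserted equal to an all-pairs scan on randomised systems. Density
profiles histogram wrapped z coordinates of headgroup beads, tail beads
and peptide beads, re-centred on the bilayer centre of mass, with a
0.1 nm default bin.

## Lateral diffusion

In-plane displacements of the peptide centre of mass over a window
$\Delta t$ follow, for a 2D Brownian walker, the Rayleigh law
$$P(r, \Delta t) = \frac{r}{2D\Delta t}
  \exp\!\left(-\frac{r^2}{4D\Delta t}\right),$$
whose maximum-likelihood estimate is the closed form
$\hat D = \langle r^2\rangle / (4\Delta t)$. The package uses the MLE
rather than histogram curve-fitting (no binning choices), with start
times on an overlapping one-frame stride and xy tracks unwrapped across
periodic boundaries before differencing (a per-frame jump above half a
box length is a wrap event). Confidence intervals come from a
moving-block bootstrap whose default block length is the window span in
samples, so the strong autocorrelation of overlapping windows is
respected. Default windows are 0.2, 2 and 100 ns; on confined
(tethered) walks the estimate decreases with the window — for an
Ornstein–Uhlenbeck walker the closed form is
$\hat D(\Delta t) = D\,(1 - e^{-\theta\Delta t})/(\theta\Delta t)$,
which the generator tests reproduce. No stationarity correction is
applied: the estimator is reported per window exactly as defined.
Units: $1\,\mathrm{nm^2/ns} = 10^{-5}\,\mathrm{cm^2/s}$ (the tests
encode the dimensional chain, not a remembered constant).

## FES reconstruction and thermodynamics

Deposition records store time-ordered Gaussians (centre, width
$\sigma$ per collective variable, height, bias factor $\gamma$),
possibly split across walkers; files are merged and sorted on read.
Heights are assumed to be stored *already tempered* (the common on-disk
convention of well-tempered runs), so the free-energy estimate is
$$F(s) = -\frac{\gamma}{\gamma-1}\sum_i h_i
  \prod_{cv}\exp\!\left(-\frac{(s-c_i)^2}{2\sigma_i^2}\right),$$
shifted to min 0; a flag supports the plain (untempered) convention.
Periodic axes (the spin angle, period $2\pi$) include their $\pm1$
period images; z and cos(tilt) are non-periodic. Gaussians whose
$\pm4\sigma$ support leaves the grid trigger a truncation warning.

The 2D $\to$ 1D projection integrates the Boltzmann probability over
the complementary variable and transforms back:
$W_1(s) = -\tfrac1\beta \ln \int e^{-\beta W(s,u)}\,du$, evaluated with
log-sum-exp stabilised trapezoid weights.

The partition coefficient between the membrane-bound region
($0 \le z \le \lambda$) and free solution is
$$\kappa = \frac{1}{2\lambda}\int_0^\lambda\!\!\int_{-1}^{1}
  e^{-\beta W(z,\cos\varphi)}\,d\cos\varphi\,dz
  \qquad\text{or}\qquad
  \kappa = \frac{1}{\lambda}\int_0^\lambda e^{-\beta W(z)}\,dz$$
for the 2D and 1D routes; the factor 2 is the width of the cosine
measure, and the two routes agree to $10^{-6}$ relative on smooth
surfaces by construction. The standard-state correction rescales to the
1 M reference (volume per molecule $V_0 = 1.660\,\mathrm{nm^3}$,
recomputed from Avogadro's number as a packaged self-check):
$\kappa^0 = \kappa\lambda/V_0^{1/3}$,
$\Delta G^0 = -k_BT\ln\kappa^0$ with
$k_B = 0.0083145$ kJ/(mol K) and $T = 300$ K by default. Transfer free
energies are differences,
$\Delta\Delta G^0 = \Delta G^0_C - \Delta G^0_M$; any common
water-phase offset cancels, so the result does not depend on the
(artificial) helical reference state of the peptide in water.

### Numerical choices

* **Energy origin.** Before integrating, the surface is anchored so the
  free region ($z > \lambda$) averages to zero — the only choice under
  which a non-interacting system gives $\kappa = 1$. A flatness check
  warns when that plateau deviates by more than 0.25 kT. With anchoring
  disabled, adding a constant $c$ multiplies $\kappa$ by
  $e^{-\beta c}$ exactly (asserted).
* **Quadrature.** The stored grid is treated as what it is — a
  piecewise-linear function of the collective variables. Boltzmann
  integrals along z therefore use the exact closed form of
  $\int e^{-\beta(\text{linear})}$ per grid cell (with a global
  exponent shift against overflow at deep minima); the bounded cosine
  axis uses the composite trapezoid. The cell-exact form integrates the
  grid representation to machine precision, which is what lets the
  square-well fixtures meet a $10^{-6}$ relative check against their
  closed forms.
* **$\lambda$ selection.** The paper-style "distance where the
  interaction becomes negligible" is operationalised as the smallest z
  beyond which $|W| < 0.5\,k_BT$ all the way to the far edge
  (`choose_lambda`), overridable by a fixed value in the
  configuration. Absence of a plateau is an error, not a guess.
* **Uncertainty.** Convergence is assessed from PMF snapshots: the
  trailing 30% of profiles are anchored on a common far-field window
  and their pointwise standard deviation is the PMF uncertainty;
  $\Delta G^0$ uncertainty recomputes $\kappa$ on each trailing profile
  and takes the standard deviation of the resulting $\Delta G^0$.
* **Sampling walls.** Half-harmonic walls
  ($\tfrac12\kappa_w(z-b)^2$ outside $[0, 8]$ nm,
  $\kappa_w = 5\times10^4$ kJ mol$^{-1}$ nm$^{-2}$ by default) are
  provided both for emulating restricted sampling in the generators and
  for masking wall-contaminated grid regions.

## Synthetic generators and what they do (not) show

Every pipeline input can be generated with known ground truth:

* `make_helix` — ideal helix, 0.15 nm rise, 0.23 nm radius, 100° per
  residue; optional radial side beads for contact fixtures.
* `make_bilayer` — the three packaged compositions (POPC 100%;
  POPE 10%/POPG 90%; CHOL 28.4%/DOPE 20%/DOPC 20%/DPSM 18.4%/
  DOPS 13.2%), 250 lipids per leaflet by default, largest-remainder
  apportionment (realised fractions within $100/(2n)$ percentage points
  of the request), jittered lattice, 4 nm head-plane separation,
  0.64 nm² per lipid.
* `make_trajectory` — rigid-body placement along interpolated
  z/tilt/spin waypoints plus optional Gaussian positional noise; the
  zero-noise round trip through `orientation_series` recovers the
  schedule to $10^{-6}$ degrees.
* `make_brownian_walk` — free or tethered (OU) 2D walks with exact
  increment statistics.
* `make_analytic_fes` — flat, square-well, harmonic-well, tilted-well
  and smooth Gaussian-well surfaces with analytically known $\kappa$. A
  discontinuous well cannot live on a finite grid, so square-well edges
  are snapped to nodes and ramp linearly over one cell; the reported
  `kappa_true` is the exact closed form of that ramped well (the
  idealised sharp-well value is attached separately as `kappa_sharp`).
* `make_hills` — greedy Gaussian deposition approximating a target
  surface so that reconstruction round-trips within
  $\approx\gamma/(\gamma-1)$ times the deposition tolerance
  (0.5 kJ/mol at the defaults).

All generators run on private seeded RNG streams: adding one generator
call never shifts another's output, and fixed seeds give bit-identical
results. The generators emulate *statistical structure only* — ideal
geometry, static bilayers, exact Rayleigh/OU statistics, noiseless or
Gaussian-noised kinematics. Passing tests therefore demonstrate the
correctness of the estimators and conventions, not force-field realism:
real trajectories add correlated lipid motion, membrane deformation,
helicity fluctuations and finite sampling, none of which the fixtures
model. Cluster-scale observables (multi-µs adsorption free energies of
real peptide/membrane systems) are out of scope by design.

## Problem sizes used in the packaged checks

The validation suite runs at desk scale, chosen for quadrature accuracy
rather than realism: analytic-surface grids of $10^3$–$1.6\times10^4$
z-nodes, $10^3$ hills × $10^4$ grid points for the reconstruction
oracle, $10^5$ ideal Rayleigh samples and 2–4 × 10⁴-step Brownian
walks, and bilayers of 16–250 lipids per leaflet. At these sizes the
whole suite completes in well under a minute on one core.

## Known limitations

* Orthorhombic boxes and a z-normal planar bilayer only; no curvature.
* Binary XTC trajectories are not read — no installed R-side reader
  covers the format; trajectories enter as in-memory objects or the
  columnar text dialect. GRO/PDB single-frame coordinates are
  supported.
* Electrostatic dipole moments (Debye) are out of scope: they need
  partial-charge assignment beyond the formal-charge bookkeeping here.
* The spin-angle CV route supports periodic reconstruction, but the
  packaged thermodynamic pipeline projects onto z from a
  (z, cos tilt) surface; spin-resolved thermodynamics can be assembled
  from the exported primitives.
* The hills dialect assumes tempered stored heights; records written
  with nominal heights need `heights_tempered = FALSE`.
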