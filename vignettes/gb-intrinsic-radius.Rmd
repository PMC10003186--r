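---
title: "Generalized Born electrostatics with adjustable intrinsic radii: model and methods"
author: "gbintrad"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Generalized Born electrostatics with adjustable intrinsic radii}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gbintrad)
```

## The model

The generalized Born (GB) model replaces explicit water with a continuum
dielectric.  For a solute of point charges $q_i$ (units of $e$) at mutual
distances $d_{ij}$ (Å), the GB solvation energy is the single double sum

$$G_{\mathrm{gb}} \;=\; \frac{1}{2}\Big(\frac{1}{\varepsilon_w}-1\Big)\,
k_e \sum_{i,j} \frac{q_i q_j}{f_{ij}}, \qquad
f_{ij} = \sqrt{\,d_{ij}^2 + R_i R_j\,
e^{-d_{ij}^2/(4R_iR_j)}\,},$$

with $\varepsilon_w$ the bulk water dielectric (78.5 throughout),
$k_e = 332.0636$ kcal·Å/(mol·e²) the electrostatic conversion constant, and
$R_i$ the *effective Born radius* of atom $i$.  The diagonal terms
($f_{ii}=R_i$) are the Born self energies
$G^{\mathrm{self}}_i = (\tfrac{1}{\varepsilon_w}-1)k_e q_i^2/(2R_i)$; the
off-diagonal terms screen the vacuum Coulomb interaction
$k_e q_iq_j/d_{ij}$.  `total_gb_energy()` evaluates the double sum;
`gb_self_energy()`, `interaction_energy()` and `desolvation_energies()`
evaluate the decomposition, and the two routes agree to $10^{-10}$
relative (this identity is tested, not assumed).

### The descreening integral and its two limits

Everything interesting happens inside $R_i$.  It is obtained from the
spatial integral of the electric-field energy density over the
water-excluded volume around atom $i$:

$$\frac{1}{R_i} = \frac{1}{\rho_i} - I_i, \qquad
I_i = \frac{1}{4\pi}\int_{\rho_i \le |r| \le r_{\max},\; r \in V_{\mathrm{excl}}}
\frac{1}{|r|^4}\, dr .$$

The two integration limits are the package's central objects:

* $\rho_i$, the **intrinsic radius** (lower limit), defines the dielectric
  boundary of the atom itself.  $I_i$ runs from 0 (fully solvated,
  $R_i=\rho_i$) to $1/\rho_i$ (fully desolvated, $R_i\to\infty$).
* $r_{\max}$ (upper limit) cuts the integral off at a finite distance;
  the default 999 Å is effectively no cutoff.

The integral over $V_{\mathrm{excl}}$ is evaluated as a pairwise sum over
the other atoms, each treated as a descreening sphere of radius
$s_j\rho_j$ ($s_j$ a per-class screening factor; see below), ignoring
sphere–sphere overlap.  For one sphere the angular part reduces by
azimuthal symmetry to a covered solid-angle fraction, and the radial
integral has the closed-form antiderivative
$F(r) = -\tfrac{1}{2r} - \tfrac{\ln r}{4d} + \tfrac{d^2-a^2}{8dr^2}$, so a
single interval-clipping expression covers every geometric case —
disjoint, sphere crossing the $\rho_i$ boundary, probe engulfed, and
sphere clipped at $r_{\max}$ (`sphere_descreen_integral()`).  An
independent adaptive-quadrature oracle (`descreen_integral_oracle()`,
accuracy target $10^{-6}$ relative) validates all branches; the suite
checks agreement to $10^{-4}$ relative on a stratified grid of more than
200 geometries.

Numerical edge cases: near-concentric geometries
($d < 10^{-9}\max(a,\rho)$) switch to the concentric closed form to avoid
cancellation in the $1/(4d)$ terms; a pairwise sum reaching $1/\rho_i$
(possible only in unphysical overlaps) is clamped just below the
complete-desolvation limit with a warning rather than producing a
negative radius silently.

### Born-radius modes and screening factors

Two modes are exposed via `gb_config(born_mode =)`:

* `"plain"` — direct inversion $1/R = 1/\rho - I$.  This is the
  Coulomb-field-approximation GB in its simplest form; it overestimates
  desolvation for large solutes, which is exactly the behaviour the
  $r_{\max}$ analysis studies.
* `"obc2"` — the OBC(II) tanh rescaling
  $1/R = 1/\tilde\rho - \tanh(\alpha\Psi - \beta\Psi^2 + \gamma\Psi^3)/\rho$
  with $\tilde\rho = \rho - 0.09$ Å, $\Psi = I\tilde\rho$, and
  $(\alpha,\beta,\gamma) = (1.0, 0.8, 4.85)$.  The coefficients are config
  fields, not constants.

`default_screen_table()` ships the standard HCT/OBC per-class screening
factors (H 0.85, C 0.72, N 0.79, O 0.85, S 0.96), which compensate the
neglected sphere–sphere overlap; `set = "unit"` gives the unscaled sum.
The study conditions used by the analyses are: the two-atom system in
plain mode with unit scales (the closed-form equations apply directly);
the amino-acid and protein-scale systems with HCT scales, the former in
OBC(II) mode (the parameterization used for amino-acid-scale GB MD) and
the latter in plain mode, where the desolvation-overestimation mechanism
being studied lives.  Both settings remain user-selectable everywhere.

`gb_config(rmax_mode =)` decides how the outer cutoff is applied:
`"clip"` (default) truncates each descreening sphere geometrically at
$|r| = r_{\max}$; `"drop"` discards whole descreening atoms beyond
$r_{\max}$.  The two agree without a cutoff and are compared in the tests.

### Desolvation reference state

The desolvation penalty is defined per atom relative to infinite
*molecular* separation in water:
$\Delta G^{\mathrm{self}}_i = G^{\mathrm{self}}_i(d) -
G^{\mathrm{self}}_i(\infty)$.  In the reference state each molecule is
solvated alone, so intramolecular descreening — which does not change as
the molecules separate — is retained, and only cross-molecule descreening
contributes to $\Delta G^{\mathrm{self}}$.  For single-atom molecules the
reference radius is exactly $\rho$.  This convention makes
$\Delta G^{\mathrm{self}} \to 0$ at large $d$ for molecules of any size;
with an atom-isolated ($R=\rho$) reference the multi-atom desolvation
would instead be dominated by a large constant intramolecular offset that
also depends on the scanned radii, obscuring the binding-induced penalty.

The interaction energy $G^{\mathrm{int}}$ sums the vacuum and screening
terms over *cross-molecule* pairs only (the `molecule_tag` field drives
the partition); all atoms of both molecules still descreen every Born
radius.

## Parameters that matter

| parameter | units | default | meaning |
|---|---|---|---|
| `epsilon_w` | — | 78.5 | bulk water dielectric |
| `rmax` | Å | 999 | outer integral cutoff (999 ≈ none) |
| `coulomb_constant` | kcal·Å/(mol·e²) | 332.0636 | unit conversion |
| intrinsic radii | Å | Bondi/mBondi2 tables | dielectric boundary per class |
| `radius_overrides` | Å | none | per-class ρ, the scanned quantity |
| screening factors | — | HCT values | pairwise-sum overlap compensation |
| `temperature` | K | 300 | PMF estimator scale |

Radius overrides name parameterization *classes* (free tokens such as
`"H-on-N"`, `"O-carboxyl"`), so a scan like "hydrogens bonded to nitrogen
from 1.1 to 1.5 Å" is a single override; reproducing the
guanidinium-hydrogen scans means overriding class `"H-on-N"`, which the
salt-bridge builder assigns to exactly those five hydrogens.

## Synthetic systems

No external data are needed; three builders regenerate the study systems
from a seed, and any `ensemble_spec()` with a fixed seed reproduces
bit-identical coordinates.

**H–O pair** (`build_ho_system()`): a carboxylate-type oxygen
($q=-0.82\,e$, $\rho=1.5$ Å) and an amine-type hydrogen ($q=+0.45\,e$,
$\rho=\rho_H$) at separation $d$ — the minimal Coulomb bond, where every
formula can be followed by hand.

**Arg–Glu salt bridge** (`build_salt_bridge_ensemble()`): a rigid planar
guanidinium fragment (C–N 1.33 Å, N–H 1.01 Å, sp² angles; charges +0.45
per H-on-N, −0.60 per N, +0.55 on C, summing to +1) facing a rigid
carboxylate (C–O 1.25 Å, O–C–O 126°; −0.82 per oxygen, +0.64 on C,
summing to −1) in the symmetric bidentate orientation, indexed by the
guanidyl-to-carboxyl carbon distance.  The fragment charges are an
idealized documented set, not a force-field transcription: the two
printed values (+0.45, −0.82) anchor the classes the scans act on, and
the remaining charges complete the ±1 totals symmetrically.  Snapshots
get Gaussian positional jitter (default σ = 0.1 Å, a thermal-scale spread
that blurs the reaction coordinate without changing bin assignment
qualitatively), the reaction coordinate is re-measured, and snapshots
with cross-fragment contacts closer than 0.8 Å are redrawn.

**Toy protein pair** (`toy_protein_builder()` /
`build_toy_protein_pair()`): two rigid 50-bead clusters.  Each cluster
has a 4-bead charged patch protruding on a spherical cap (radius 11.3 Å)
around the interface axis — net-positive `"H-on-N"` beads on one side,
net-negative `"O-carboxyl"` beads on the other — so the bound state near
$d = 23.7$ Å (center-of-mass distance) has a ~3 Å charge-complementary
contact.  Core beads (radius 2.0 Å) carry alternating ±1.0 e charges with
a small ±0.2 e net bias.  The alternating interior is deliberate: 50
beads stand in for a protein's thousands of partial charges, and the
desolvation penalty scales with the charge-squared density while the
interaction energy largely cancels between opposite signs.  With
genuinely weak interior charges at this bead count the cutoff-induced
association barrier would simply not exist; the chosen magnitudes put the
contact-window energetics on the tens-of-kcal/mol scale of a
charge-steered protein interface.  The clusters are a synthetic stand-in,
not a model of any particular complex.

## The analyses

1. **Distance profiles** (`distance_scan()`): every energy component on a
   grid of separations (default two-body grid step 0.01 Å).  Minima are
   located by grid argmin plus quadratic refinement through the
   bracketing triple (`locate_minimum()`), ties breaking toward smaller
   d, boundary minima flagged rather than refined.
2. **Parameter scans** (`parameter_scan()`): Cartesian product of
   per-class radius values and rmax values, one labeled profile per
   setting.
3. **Ensemble window averages** (`ensemble_binned_profile()`): unweighted
   snapshot means in half-open bins $[lo, hi)$; empty bins are kept and
   flagged, never silently dropped or zero-filled.
4. **PMF estimator** (`pmf_from_counts()`):
   $-RT\ln[n(d)/N_{\mathrm{ref}}]$ with $R$ the gas constant, counts taken
   in $d \pm w/2$ (default $w = 0.1$ Å, the ±0.05 Å counting convention),
   the bin grid laid so the reference separation (default 10 Å for
   amino-acid-scale systems) is exactly a bin center.  Empty bins are
   reported as undefined (NA), never as a substituted infinity; an empty
   reference bin is an error.  `sample_boltzmann_1d()` provides seeded
   inverse-CDF samples from a tabulated potential as the estimator's
   ground-truth generator.
5. **Barrier height** (`barrier_height()`): height of the highest point
   of a profile above its far-field plateau (the value at the largest
   scanned separation).

Problem sizes used by the shipped analyses and tests: 900-snapshot
salt-bridge ensembles (~240 in the 0.1 Å analysis window), 40-snapshot
toy-pair ensembles, toy-pair approach grids of ~47 points at 100 atoms,
and $10^5$-sample PMF validations — sizes at which every analysis runs in
seconds to a couple of minutes on a single core while leaving the window
statistics well resolved.

## What the synthetic ensembles do and do not show

The jittered rigid-fragment ensembles emulate the *geometry spread* of
thermal snapshots around idealized bound-state conformations.  They do
not sample a force field: there are no torsions, no exchange between
bound and unbound basins, no explicit-water PMFs.  Consequently the
package's ensemble results are trend-level statements about how the GB
energy components respond to the integration limits — the monotonic rise
of the desolvation penalty and the larger monotonic fall of the
interaction energy with growing intrinsic radii, and the growth of the
association barrier with rmax.  Quantities that depend on real
conformational statistics (absolute PMF depths, explicit-water minima
locations) are outside what these tests can certify.

## Known limitations

* Pairwise descreening ignores sphere–sphere overlap; the HCT screening
  factors compensate on average but are not exact.
* No ionic-strength term, no nonpolar (surface-area) solvation term, no
  periodic boundaries: all analyses are two-body in open boundary.
* The salt-bridge charge set is idealized; all claims built on it are
  trend-level by design.
* `read_pqr()` infers classes from atom/residue names by a documented
  rule table; exotic naming schemes may need explicit reassignment via
  `assign_radii()`.
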