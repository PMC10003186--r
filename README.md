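# gbintrad

Generalized Born (GB) continuum electrostatics with explicit control over
the two integration limits of the descreening integral: the per-atom
**intrinsic radius** ρ (the lower limit, defining the dielectric boundary)
and the outer cutoff **rmax**.  The package is for molecular modellers who
want to understand — not just apply — the common practice of retuning GB
atomic radii to fix Coulomb-bond (ionic / hydrogen bond) stability in
implicit solvent.

## The model

The effective Born radius of atom *i* comes from the spatial integral of
the electric-field energy density over the water-excluded volume around it:

    1/R_i = 1/rho_i - I_i,
    I_i   = (1/4pi) * Int_{rho_i <= |r| <= rmax, r in V_excl} dr / |r|^4

evaluated as a pairwise sum of closed-form per-sphere integrals (validated
against an adaptive-quadrature oracle).  With Born radii in hand, the GB
energy of charges q_i at distances d_ij is

    G_gb = (1/2) (1/eps_w - 1) k_e * sum_ij q_i q_j / f_gb(d_ij, R_i, R_j),
    f_gb = sqrt(d^2 + R_i R_j exp(-d^2 / (4 R_i R_j)))

which the package decomposes into per-atom **self (desolvation) energies**
ΔG_self (relative to infinite molecular separation in water) and the
cross-molecule **interaction energy** G_int (vacuum Coulomb plus GB
screening).  The total Coulomb energy of an approaching pair is
ΔG_self + G_int: an unfavorable desolvation penalty counterbalanced by a
favorable screened attraction.  Scanning ρ and rmax reveals which term
controls the stability of salt bridges and charge-complementary protein
interfaces, on three synthetic, seed-regenerable systems: a two-atom H–O
ion pair, an idealized Arg–Glu salt bridge, and a toy charge-complementary
protein pair.  PQR import/export connects the same machinery to real
structures.

## Worked example

How does the hydrogen intrinsic radius change the energetics of an ionic
H–O bond (q_O = −0.82 e, ρ_O = 1.5 Å; q_H = +0.45 e) at its equilibrium
separation d = 1.57 Å?

```r
library(gbintrad)
cfg <- gb_config(epsilon_w = 78.5, rmax = 999)
for (rho_H in c(1.1, 1.3, 1.5)) {
  bd <- energy_breakdown(build_ho_system(1.57, rho_H), cfg)
  cat(sprintf("rho_H=%.1f  dGself=%6.3f  Gint=%8.3f  total=%8.3f\n",
              rho_H, bd$dG_self_total, bd$G_int, bd$coulomb_total))
}
#> rho_H=1.1  dGself= 6.477  Gint= -16.769  total= -10.292
#> rho_H=1.3  dGself= 6.496  Gint= -19.112  total= -12.616
#> rho_H=1.5  dGself= 7.261  Gint= -21.337  total= -14.076
```

Growing ρ_H from 1.1 to 1.5 Å stabilizes the bond by 3.8 kcal/mol.  The
total desolvation penalty barely moves (+0.78 kcal/mol) because the
oxygen's penalty rises while the hydrogen's falls; the stabilization comes
almost entirely from the interaction term G_int (−4.57 kcal/mol).  The
same mechanism, with the same machinery, appears in the salt-bridge
ensemble and the toy protein pair — run the numbered scripts under
`analysis/` to reproduce the full set of scans (each prints its summary
and writes CSV tables under `results/`):

```sh
Rscript analysis/01_ho_two_atom.R        # rho_H distance scans + energy minima
Rscript analysis/02_arg_glu_saltbridge.R # bound-state window averages vs rho_H
Rscript analysis/03_toy_protein_pair.R   # rmax barrier + two-way adjustment
Rscript analysis/04_pmf_estimator.R      # count-based PMF validation
```

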