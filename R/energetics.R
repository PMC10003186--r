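#' Generalized Born pair function
#'
#' The effective interaction distance
#' `f_gb(d, R_i, R_j) = sqrt(d^2 + R_i R_j exp(-d^2 / (4 R_i R_j)))`
#' interpolating between `sqrt(R_i R_j)` at contact and `d` at large
#' separation.  Symmetric in i and j, always >= d and > 0.
#'
#' @param d Pair distance, Angstrom (>= 0).
#' @param R_i,R_j Effective Born radii, Angstrom (> 0).
#' @return Numeric vector, Angstrom.
#' @export
f_gb <- function(d, R_i, R_j) {
  if (any(R_i <= 0) || any(R_j <= 0)) stop("Born radii must be > 0")
  if (any(d < 0)) stop("distance must be >= 0")
  sqrt(d^2 + R_i * R_j * exp(-d^2 / (4 * R_i * R_j)))
}

#' Born self energy of a charge
#'
#' `G = (1/epsilon_w - 1) * ke * q^2 / (2 R)`: the solvation self energy of
#' a charge q with effective Born radius R.  Always <= 0 for epsilon_w > 1;
#' its magnitude decreases as R grows (desolvation), which is why the
#' difference relative to the fully solvated state (R = rho) is a positive
#' desolvation penalty.
#'
#' @param q Charge, e.
#' @param R Effective Born radius, Angstrom (> 0).
#' @param config A [gb_config()] supplying `epsilon_w` and the Coulomb
#'   constant.
#' @return Energy, kcal/mol (vectorized).
#' @export
gb_self_energy <- function(q, R, config = gb_config()) {
  if (any(R <= 0)) stop("Born radius must be > 0")
  (1 / config$epsilon_w - 1) * config$coulomb_constant * q^2 / (2 * R)
}

## Assert that a gb_born result was computed under `config`.
check_born_config <- function(born, config) {
  if (!inherits(born, "gb_born")) stop("born must be a gb_born result")
  if (!identical(attr(born, "config_key"), config_key(config))) {
    stop("Born radii were computed under a different gb_config; ",
         "recompute born_radii() with the requested configuration")
  }
  invisible(TRUE)
}

## Per-atom Born self energies in the infinite-separation reference state:
## each molecule solvated alone, so intramolecular descreening persists but
## all cross-molecule descreening vanishes.  For a single-atom molecule the
## reference radius is exactly rho (I = 0), recovering the analytic
## two-atom reference.
reference_self_energies <- function(sys_eff, config) {
  cfg0 <- config
  cfg0$radius_overrides <- NULL  # overrides already applied to sys_eff
  out <- numeric(nrow(sys_eff$atoms))
  for (tag in unique(sys_eff$atoms$molecule_tag)) {
    sel <- sys_eff$atoms$molecule_tag == tag
    sub <- mol_system(sys_eff$atoms[sel, , drop = FALSE])
    bref <- born_radii(sub, cfg0)
    out[sel] <- gb_self_energy(sub$atoms$charge, bref$R, config)
  }
  names(out) <- sys_eff$atoms$atom_id
  out
}

#' Per-atom desolvation energies
#'
#' The desolvation energy of atom i at the current geometry is its Born self
#' energy minus its value at infinite molecular separation in water,
#' `dG_self[i] = G_self(q_i, R_i(d)) - G_self(q_i, R_i(Inf))`.
#' In the reference state each molecule is solvated alone: the reference
#' radius keeps all intramolecular descreening (which does not change as
#' the molecules separate) and drops every cross-molecule contribution.
#' For single-atom molecules this reduces exactly to `R(Inf) = rho`, so an
#' isolated atom has zero desolvation energy.
#'
#' @param sys A `mol_system`.
#' @param born The [born_radii()] result for `sys` under `config`.
#' @param config The same [gb_config()] used for `born` (checked).
#' @return A list with `per_atom` (named numeric vector, kcal/mol) and
#'   `total` (their sum over all atoms of both molecules).
#' @export
desolvation_energies <- function(sys, born, config = gb_config()) {
  check_born_config(born, config)
  sys <- apply_radius_overrides(sys, config$radius_overrides)
  stopifnot(identical(sys$atoms$atom_id, born$atom_id))
  q <- sys$atoms$charge
  per_atom <- gb_self_energy(q, born$R, config) -
    reference_self_energies(sys, config)
  names(per_atom) <- born$atom_id
  list(per_atom = per_atom, total = sum(per_atom))
}

#' Intermolecular Coulomb interaction energy
#'
#' Sums, over every cross-molecule atom pair (k, l), the vacuum Coulomb term
#' `ke q_k q_l / d_kl` and the GB screening correction
#' `(1/epsilon_w - 1) ke q_k q_l / f_gb(d_kl, R_k, R_l)`.  Intramolecular
#' pairs are excluded; all atoms nevertheless contribute to each effective
#' Born radius through descreening.
#'
#' @inheritParams desolvation_energies
#' @return A list with `E_vac_int`, `G_gb_int` and their sum `G_int`
#'   (kcal/mol).
#' @export
interaction_energy <- function(sys, born, config = gb_config()) {
  check_born_config(born, config)
  sys <- apply_radius_overrides(sys, config$radius_overrides)
  stopifnot(identical(sys$atoms$atom_id, born$atom_id))
  pr <- interaction_pairs(sys)
  if (any(pr$d == 0)) {
    stop("coincident atoms across molecules (d = 0): vacuum term singular")
  }
  q <- sys$atoms$charge
  ke <- config$coulomb_constant
  qq <- q[pr$i] * q[pr$j]
  E_vac <- sum(ke * qq / pr$d)
  G_gb <- sum((1 / config$epsilon_w - 1) * ke * qq /
                f_gb(pr$d, born$R[pr$i], born$R[pr$j]))
  list(E_vac_int = E_vac, G_gb_int = G_gb, G_int = E_vac + G_gb)
}

#' Total GB solvation energy in unified form
#'
#' The single double sum
#' `(1/2)(1/epsilon_w - 1) ke sum_{i,j} q_i q_j / f_gb(d_ij, R_i, R_j)`
#' over all ordered pairs including i = j (for which `f_gb(0, R, R) = R`,
#' recovering the self terms).  Identical, as an algebraic identity, to the
#' sum of per-atom self energies plus the GB screening part of all pair
#' interactions.
#'
#' @inheritParams desolvation_energies
#' @return Energy, kcal/mol.
#' @export
total_gb_energy <- function(sys, born, config = gb_config()) {
  check_born_config(born, config)
  sys <- apply_radius_overrides(sys, config$radius_overrides)
  stopifnot(identical(sys$atoms$atom_id, born$atom_id))
  q <- sys$atoms$charge
  dm <- as.matrix(stats::dist(coords(sys)))
  fm <- f_gb(as.vector(dm), rep(born$R, times = length(q)),
             rep(born$R, each = length(q)))
  0.5 * (1 / config$epsilon_w - 1) * config$coulomb_constant *
    sum(outer(q, q) / matrix(fm, nrow = length(q)))
}

#' Intermolecular 12-6 Lennard-Jones energy
#'
#' `sum eps_kl [ (rmin_kl/d)^12 - 2 (rmin_kl/d)^6 ]` over cross-molecule
#' pairs with Lorentz-Berthelot combination (`rmin_kl = rmin_half_k +
#' rmin_half_l`, `eps_kl = sqrt(eps_k eps_l)`).  Used only to locate the
#' total-energy minimum of two-body profiles; the package ships no LJ
#' parameters of its own.
#'
#' @param sys A `mol_system` whose atoms carry `lj_rmin_half` (A) and
#'   `lj_epsilon` (kcal/mol) for every atom involved in a cross pair.
#' @return Energy, kcal/mol.
#' @export
lj_energy <- function(sys) {
  pr <- interaction_pairs(sys)
  a <- sys$atoms
  need <- unique(c(pr$i, pr$j))
  miss <- need[is.na(a$lj_rmin_half[need]) | is.na(a$lj_epsilon[need])]
  if (length(miss) > 0L) {
    stop("missing Lennard-Jones parameters for atom(s): ",
         paste(a$atom_id[miss], collapse = ", "))
  }
  rmin <- a$lj_rmin_half[pr$i] + a$lj_rmin_half[pr$j]
  eps <- sqrt(a$lj_epsilon[pr$i] * a$lj_epsilon[pr$j])
  sr6 <- (rmin / pr$d)^6
  sum(eps * (sr6^2 - 2 * sr6))
}

#' Full energy breakdown of a two-molecule system
#'
#' Convenience wrapper computing Born radii and every energy component at
#' once: per-atom self and desolvation energies, the total desolvation
#' penalty, the vacuum and GB-screening interaction terms, the total Coulomb
#' energy `dG_self + G_int`, and (optionally) the intermolecular
#' Lennard-Jones energy and grand total.
#'
#' @param sys A `mol_system` with >= 2 molecule tags.
#' @param config A [gb_config()].
#' @param born Optional precomputed [born_radii()] result (recomputed when
#'   NULL).
#' @param lj If TRUE, also evaluate [lj_energy()] (requires LJ parameters on
#'   the atoms).
#' @return An object of class `energy_breakdown`: a list with elements
#'   `self_per_atom` (G_self at d, kcal/mol), `dG_self_per_atom`,
#'   `dG_self_total`, `E_vac_int`, `G_gb_int`, `G_int`, `coulomb_total`,
#'   `E_lj` (NA unless `lj`), `E_total` (NA unless `lj`) and `born`.
#' @export
energy_breakdown <- function(sys, config = gb_config(), born = NULL,
                             lj = FALSE) {
  if (is.null(born)) born <- born_radii(sys, config)
  check_born_config(born, config)
  sys_eff <- apply_radius_overrides(sys, config$radius_overrides)
  q <- sys_eff$atoms$charge
  self_at_d <- gb_self_energy(q, born$R, config)
  names(self_at_d) <- born$atom_id
  des <- desolvation_energies(sys, born, config)
  inter <- interaction_energy(sys, born, config)
  E_lj <- if (lj) lj_energy(sys_eff) else NA_real_
  res <- list(self_per_atom = self_at_d,
              dG_self_per_atom = des$per_atom,
              dG_self_total = des$total,
              E_vac_int = inter$E_vac_int,
              G_gb_int = inter$G_gb_int,
              G_int = inter$G_int,
              coulomb_total = des$total + inter$G_int,
              E_lj = E_lj,
              E_total = if (lj) des$total + inter$G_int + E_lj else NA_real_,
              born = born)
  class(res) <- "energy_breakdown"
  res
}

#' @export
print.energy_breakdown <- function(x, ...) {
  cat("<energy_breakdown> (kcal/mol)\n")
  cat(sprintf("  dG_self  %10.4f\n", x$dG_self_total))
  cat(sprintf("  E_vac    %10.4f\n", x$E_vac_int))
  cat(sprintf("  G_gb_int %10.4f\n", x$G_gb_int))
  cat(sprintf("  G_int    %10.4f\n", x$G_int))
  cat(sprintf("  Coulomb  %10.4f\n", x$coulomb_total))
  if (!is.na(x$E_lj)) {
    cat(sprintf("  LJ       %10.4f\n  total    %10.4f\n", x$E_lj, x$E_total))
  }
  invisible(x)
}

#' Export an energy breakdown
#'
#' Writes a JSON summary and a flat CSV (one row per atom for the self
#' terms, one summary row for the totals).
#'
#' @param bd An `energy_breakdown`.
#' @param json_path,csv_path Output paths (either may be NULL to skip).
#' @return Invisibly, the paths written.
#' @export
write_energy_breakdown <- function(bd, json_path = NULL, csv_path = NULL) {
  stopifnot(inherits(bd, "energy_breakdown"))
  written <- character(0)
  if (!is.null(json_path)) {
    jsonlite::write_json(
      list(dG_self_total = bd$dG_self_total, E_vac_int = bd$E_vac_int,
           G_gb_int = bd$G_gb_int, G_int = bd$G_int,
           coulomb_total = bd$coulomb_total, E_lj = bd$E_lj,
           E_total = bd$E_total,
           dG_self_per_atom = as.list(bd$dG_self_per_atom)),
      json_path, auto_unbox = TRUE, digits = NA, na = "null")
    written <- c(written, json_path)
  }
  if (!is.null(csv_path)) {
    per <- data.frame(row_type = "atom",
                      atom_id = names(bd$dG_self_per_atom),
                      G_self = unname(bd$self_per_atom),
                      dG_self = unname(bd$dG_self_per_atom),
                      stringsAsFactors = FALSE)
    tot <- data.frame(row_type = "summary", atom_id = "(all)",
                      G_self = NA_real_, dG_self = bd$dG_self_total,
                      stringsAsFactors = FALSE)
    tot$E_vac_int <- bd$E_vac_int; per$E_vac_int <- NA_real_
    tot$G_gb_int <- bd$G_gb_int; per$G_gb_int <- NA_real_
    tot$G_int <- bd$G_int; per$G_int <- NA_real_
    tot$coulomb_total <- bd$coulomb_total; per$coulomb_total <- NA_real_
    utils::write.csv(rbind(per, tot), csv_path, row.names = FALSE,
                     quote = FALSE)
    written <- c(written, csv_path)
  }
  invisible(written)
}
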