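#' gbintrad: generalized Born electrostatics with adjustable intrinsic radii
#'
#' Tools to compute effective Born radii from the pairwise descreening
#' integral with adjustable lower (intrinsic radius, rho) and upper (rmax)
#' integration limits, decompose the Coulomb energy of a two-molecule system
#' into self (desolvation) and interaction terms, and run the distance /
#' rho / rmax scans that expose how the intrinsic radius controls
#' Coulomb-bond stability in implicit solvent.
#'
#' Units throughout: distances in Angstrom, charges in units of the
#' elementary charge e, energies in kcal/mol, temperatures in Kelvin.
#'
#' @keywords internal
"_PACKAGE"

## Electrostatic conversion constant: q1*q2/d with q in e and d in Angstrom
## times this constant gives kcal/mol.
.ke_default <- 332.0636

## Gas constant in kcal/(mol K).
.R_kcal <- 0.0019872

#' Gas constant in kcal/(mol K)
#' @return A length-one numeric.
#' @export
gas_constant_kcal <- function() .R_kcal

#' Construct a molecular system
#'
#' A molecular system is an ordered table of charged spheres ("atom sites"),
#' each carrying a position, a partial charge and an intrinsic radius, plus a
#' molecule tag that drives the inter/intra-molecular partition used by the
#' interaction-energy sums.  The intrinsic radius rho is the lower limit of
#' the descreening integral, i.e. the radius of the water-excluded sphere the
#' atom contributes to the dielectric boundary.
#'
#' @param atoms A data.frame with columns `atom_id` (unique identifiers),
#'   `class_label` (free-token parameterization class, e.g. `"H-on-N"`,
#'   `"O-carboxyl"`), `x`, `y`, `z` (Angstrom), `charge` (e),
#'   `intrinsic_radius` (Angstrom, > 0), `molecule_tag`.  Optional columns:
#'   `descreen_scale` (dimensionless factor applied to the atom's radius when
#'   it acts as a descreening sphere; default 1), `lj_rmin_half` (Angstrom)
#'   and `lj_epsilon` (kcal/mol) for the optional 12-6 Lennard-Jones term.
#' @param separation Optional scalar reaction-coordinate value d (Angstrom)
#'   with a declared definition.
#' @param separation_def Character description of how `separation` is
#'   measured (e.g. `"Czeta-Cdelta distance"`, `"center-of-mass distance"`).
#' @return An object of class `mol_system`.
#' @export
mol_system <- function(atoms, separation = NULL, separation_def = NULL) {
  stopifnot(is.data.frame(atoms))
  required <- c("atom_id", "class_label", "x", "y", "z", "charge",
                "intrinsic_radius", "molecule_tag")
  missing_cols <- setdiff(required, names(atoms))
  if (length(missing_cols) > 0L) {
    stop("atoms is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  if (!("descreen_scale" %in% names(atoms))) atoms$descreen_scale <- 1.0
  if (!("lj_rmin_half" %in% names(atoms))) atoms$lj_rmin_half <- NA_real_
  if (!("lj_epsilon" %in% names(atoms))) atoms$lj_epsilon <- NA_real_
  atoms$atom_id <- as.character(atoms$atom_id)
  atoms$class_label <- as.character(atoms$class_label)
  atoms$molecule_tag <- as.character(atoms$molecule_tag)
  rownames(atoms) <- NULL
  sys <- structure(
    list(atoms = atoms,
         separation = separation,
         separation_def = separation_def),
    class = "mol_system")
  validate_mol_system(sys)
  sys
}

#' Validate a molecular system
#'
#' Checks the structural invariants: unique atom ids, finite coordinates,
#' strictly positive finite intrinsic radii and descreening scale factors,
#' at least one molecule tag.
#'
#' @param sys A `mol_system`.
#' @return `sys`, invisibly, if valid; otherwise an error.
#' @export
validate_mol_system <- function(sys) {
  stopifnot(inherits(sys, "mol_system"))
  a <- sys$atoms
  if (anyDuplicated(a$atom_id)) stop("atom_ids must be unique")
  if (!all(is.finite(as.matrix(a[, c("x", "y", "z")])))) {
    stop("all position components must be finite")
  }
  if (!all(is.finite(a$intrinsic_radius)) || any(a$intrinsic_radius <= 0)) {
    stop("intrinsic_radius must be finite and > 0 for every atom")
  }
  if (any(!is.finite(a$descreen_scale)) || any(a$descreen_scale <= 0)) {
    stop("descreen_scale must be finite and > 0 for every atom")
  }
  if (length(unique(a$molecule_tag)) < 1L || any(!nzchar(a$molecule_tag))) {
    stop("every atom needs a non-empty molecule_tag")
  }
  if (!is.null(sys$separation) &&
      (!is.numeric(sys$separation) || length(sys$separation) != 1L)) {
    stop("separation must be a single numeric value or NULL")
  }
  invisible(sys)
}

#' @export
print.mol_system <- function(x, ...) {
  a <- x$atoms
  cat(sprintf("<mol_system> %d atoms, %d molecule(s) [%s]\n",
              nrow(a), length(unique(a$molecule_tag)),
              paste(unique(a$molecule_tag), collapse = ", ")))
  if (!is.null(x$separation)) {
    cat(sprintf("  separation d = %.4g A (%s)\n", x$separation,
                if (is.null(x$separation_def)) "unspecified" else
                  x$separation_def))
  }
  cat(sprintf("  net charge %+.3f e\n", sum(a$charge)))
  invisible(x)
}

#' Number of atoms in a system
#' @param sys A `mol_system`.
#' @return Integer count.
#' @export
n_atoms <- function(sys) nrow(sys$atoms)

#' Coordinates of a system as an N x 3 matrix
#' @param sys A `mol_system`.
#' @return Numeric matrix with columns x, y, z (Angstrom).
#' @export
coords <- function(sys) {
  as.matrix(sys$atoms[, c("x", "y", "z")])
}

#' Generalized Born configuration
#'
#' Collects the physical and numerical parameters of a GB calculation.
#'
#' @param epsilon_w Bulk water dielectric constant (dimensionless, > 1).
#'   Default 78.5.
#' @param rmax Outer cutoff of the descreening integral, Angstrom.  The
#'   default 999 is effectively no cutoff.
#' @param coulomb_constant Electrostatic conversion constant,
#'   kcal A / (mol e^2).  Default 332.0636.
#' @param born_mode `"plain"` (direct inversion of 1/rho - I) or `"obc2"`
#'   (tanh-rescaled effective radii with an offset lower integration limit).
#' @param obc_coefficients Named numeric vector `alpha`, `beta`, `gamma`,
#'   `offset` used only in `"obc2"` mode.  Defaults are the OBC(II) values
#'   (1.0, 0.8, 4.85, offset 0.09 A).
#' @param radius_overrides Named numeric vector or list mapping class labels
#'   to intrinsic radii (Angstrom); applied on top of whatever radii the
#'   system carries before any energy evaluation.
#' @param rmax_mode `"clip"` truncates each descreening sphere geometrically
#'   at the outer shell `|r| = rmax`; `"drop"` instead discards whole
#'   descreening atoms whose center lies beyond rmax and integrates the rest
#'   without an outer limit.
#' @param temperature Temperature in Kelvin (used by PMF utilities).
#' @return An object of class `gb_config`.
#' @export
gb_config <- function(epsilon_w = 78.5,
                      rmax = 999,
                      coulomb_constant = .ke_default,
                      born_mode = c("plain", "obc2"),
                      obc_coefficients = c(alpha = 1.0, beta = 0.8,
                                           gamma = 4.85, offset = 0.09),
                      radius_overrides = NULL,
                      rmax_mode = c("clip", "drop"),
                      temperature = 300) {
  born_mode <- match.arg(born_mode)
  rmax_mode <- match.arg(rmax_mode)
  stopifnot(epsilon_w > 1, rmax > 0, coulomb_constant > 0, temperature > 0)
  oc <- obc_coefficients
  stopifnot(all(c("alpha", "beta", "gamma", "offset") %in% names(oc)))
  if (!is.null(radius_overrides)) {
    radius_overrides <- unlist(radius_overrides)
    if (any(radius_overrides <= 0)) stop("override radii must be > 0")
    if (is.null(names(radius_overrides)) || any(!nzchar(names(radius_overrides)))) {
      stop("radius_overrides must be named by class label")
    }
  }
  structure(
    list(epsilon_w = epsilon_w, rmax = rmax,
         coulomb_constant = coulomb_constant,
         born_mode = born_mode,
         obc_coefficients = oc,
         radius_overrides = radius_overrides,
         rmax_mode = rmax_mode,
         temperature = temperature),
    class = "gb_config")
}

#' @export
print.gb_config <- function(x, ...) {
  cat(sprintf("<gb_config> epsw=%.4g rmax=%.4g ke=%.6g mode=%s (%s)\n",
              x$epsilon_w, x$rmax, x$coulomb_constant, x$born_mode,
              x$rmax_mode))
  if (!is.null(x$radius_overrides)) {
    cat("  overrides:",
        paste(sprintf("%s=%.3g", names(x$radius_overrides),
                      x$radius_overrides), collapse = " "), "\n")
  }
  invisible(x)
}

## Stable string key identifying the parts of a config that determine Born
## radii; used to detect config mismatch between a born_radii result and a
## later energy request.
config_key <- function(config) {
  ov <- config$radius_overrides
  ov <- if (is.null(ov)) "" else
    paste(sprintf("%s=%.10g", names(ov)[order(names(ov))],
                  ov[order(names(ov))]), collapse = ",")
  paste(sprintf("%.10g", config$epsilon_w), sprintf("%.10g", config$rmax),
        sprintf("%.10g", config$coulomb_constant), config$born_mode,
        config$rmax_mode,
        paste(sprintf("%.10g", config$obc_coefficients), collapse = ":"),
        ov, sep = "|")
}

#' Built-in intrinsic-radius tables
#'
#' Per-class intrinsic radii (Angstrom) for the free-token class labels used
#' by the synthetic builders and the PQR class-assignment rules.  The values
#' are the van der Waals (Bondi) radii and the mBondi2 variant commonly used
#' to seed GB dielectric boundaries: H 1.2 (mBondi2 raises H bonded to N to
#' 1.3), C 1.7, N 1.55, O 1.5, S 1.8.  These are transcription of standard
#' literature values, not a fitted parameter set.
#'
#' @param set `"mbondi2"` (default) or `"bondi"`.
#' @return Named numeric vector mapping class label to radius in Angstrom.
#' @export
default_radius_table <- function(set = c("mbondi2", "bondi")) {
  set <- match.arg(set)
  base <- c("H" = 1.2, "C" = 1.7, "N" = 1.55, "O" = 1.5, "S" = 1.8,
            "O-carboxyl" = 1.5, "bead" = 1.7)
  if (set == "mbondi2") {
    c(base, "H-on-N" = 1.3)
  } else {
    c(base, "H-on-N" = 1.2)
  }
}

#' Built-in descreening scale factors
#'
#' Per-class multiplicative factors applied to an atom's radius when it acts
#' as a descreening sphere, compensating the neglect of sphere-sphere
#' overlap in the pairwise descreening sum.  The values are the standard
#' HCT/OBC screening parameters (H 0.85, C 0.72, N 0.79, O 0.85, S 0.96);
#' beads use 0.8 as a generic heavy-group value.  An all-ones table (the
#' unscaled pairwise sum) is available via `set = "unit"`.
#'
#' @param set `"hct"` (default) or `"unit"`.
#' @return Named numeric vector mapping class label to scale factor.
#' @export
default_screen_table <- function(set = c("hct", "unit")) {
  set <- match.arg(set)
  classes <- c("H" = 0.85, "H-on-N" = 0.85, "C" = 0.72, "N" = 0.79,
               "O" = 0.85, "O-carboxyl" = 0.85, "S" = 0.96, "bead" = 0.8)
  if (set == "unit") classes[] <- 1.0
  classes
}

#' Assign per-class descreening scale factors
#'
#' Sets each atom's `descreen_scale` from a class table; classes missing
#' from the table keep their current factor.
#'
#' @param sys A `mol_system`.
#' @param table Named numeric vector class label -> scale factor.
#' @return A `mol_system` with updated `descreen_scale`.
#' @export
assign_screen_scales <- function(sys, table = default_screen_table()) {
  stopifnot(inherits(sys, "mol_system"))
  table <- unlist(table)
  hit <- sys$atoms$class_label %in% names(table)
  sys$atoms$descreen_scale[hit] <- unname(table[sys$atoms$class_label[hit]])
  validate_mol_system(sys)
  sys
}

#' Assign intrinsic radii from a class table plus overrides
#'
#' Every atom's intrinsic radius is replaced by `overrides[class]` when that
#' class is present in `overrides`, else by `table[class]`.  All other fields
#' are unchanged.  The operation is idempotent.
#'
#' @param sys A `mol_system`.
#' @param table Named numeric vector/list mapping class label to radius (A).
#' @param overrides Named numeric vector/list of per-class radius overrides
#'   (A); takes precedence over `table`.
#' @return A new `mol_system` with updated `intrinsic_radius`.
#' @export
assign_radii <- function(sys, table = default_radius_table(),
                         overrides = NULL) {
  stopifnot(inherits(sys, "mol_system"))
  table <- unlist(table)
  overrides <- if (is.null(overrides)) numeric(0) else unlist(overrides)
  lut <- c(overrides, table[setdiff(names(table), names(overrides))])
  labels <- sys$atoms$class_label
  unresolved <- setdiff(unique(labels), names(lut))
  if (length(unresolved) > 0L) {
    stop("no radius for class label(s): ", paste(unresolved, collapse = ", "))
  }
  radii <- unname(lut[labels])
  if (any(!is.finite(radii)) || any(radii <= 0)) {
    stop("assigned radii must be finite and > 0")
  }
  sys$atoms$intrinsic_radius <- radii
  sys
}

#' Apply per-class radius overrides to a system
#'
#' Unlike [assign_radii()], atoms whose class has no override keep their
#' current radius.  Errors if an override names a class absent from the
#' system, which catches typos in scan setups.
#'
#' @param sys A `mol_system`.
#' @param overrides Named numeric vector/list class label -> radius (A), or
#'   NULL for a no-op.
#' @return A `mol_system` with updated radii.
#' @export
apply_radius_overrides <- function(sys, overrides) {
  if (is.null(overrides) || length(overrides) == 0L) return(sys)
  overrides <- unlist(overrides)
  absent <- setdiff(names(overrides), unique(sys$atoms$class_label))
  if (length(absent) > 0L) {
    stop("radius override names class(es) absent from the system: ",
         paste(absent, collapse = ", "))
  }
  if (any(overrides <= 0)) stop("override radii must be > 0")
  for (cl in names(overrides)) {
    sys$atoms$intrinsic_radius[sys$atoms$class_label == cl] <- overrides[[cl]]
  }
  sys
}

#' Enumerate cross-molecule atom pairs
#'
#' Returns every unordered pair of atoms that belong to different molecules
#' (distinct `molecule_tag`), each pair exactly once.  These are the pairs
#' entering the intermolecular interaction-energy sums; intramolecular pairs
#' are excluded.
#'
#' @param sys A `mol_system` with at least two distinct molecule tags.
#' @return A data.frame with columns `i`, `j` (row indices into
#'   `sys$atoms`), `atom_i`, `atom_j` (atom ids) and `d` (pair distance, A).
#' @export
interaction_pairs <- function(sys) {
  stopifnot(inherits(sys, "mol_system"))
  tags <- sys$atoms$molecule_tag
  if (length(unique(tags)) < 2L) {
    stop("interaction undefined: system has a single molecule_tag")
  }
  n <- nrow(sys$atoms)
  idx <- which(outer(tags, tags, FUN = "!=") & upper.tri(matrix(TRUE, n, n)),
               arr.ind = TRUE)
  xyz <- coords(sys)
  d <- sqrt(rowSums((xyz[idx[, 1L], , drop = FALSE] -
                     xyz[idx[, 2L], , drop = FALSE])^2))
  data.frame(i = idx[, 1L], j = idx[, 2L],
             atom_i = sys$atoms$atom_id[idx[, 1L]],
             atom_j = sys$atoms$atom_id[idx[, 2L]],
             d = d,
             stringsAsFactors = FALSE)
}
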