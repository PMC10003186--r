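#' Ensemble specification
#'
#' Describes a reproducible synthetic conformer ensemble: which system
#' family to build, the target separations, how many snapshots per target,
#' the thermal positional jitter, and the seed.  A fixed seed regenerates a
#' bit-identical ensemble.
#'
#' @param family `"ho"`, `"saltbridge"` or `"toyprotein"`.
#' @param d_targets Numeric vector of target separations, Angstrom.
#' @param n_per Snapshots per target (>= 1).
#' @param sigma Gaussian positional jitter amplitude applied per coordinate,
#'   Angstrom (>= 0).  Default 0.1, a thermal-scale spread that blurs the
#'   reaction coordinate without changing bin assignment qualitatively.
#' @param seed Integer RNG seed.
#' @param params Named list of family-specific parameters (see the
#'   builders).
#' @return An object of class `ensemble_spec`.
#' @export
ensemble_spec <- function(family = c("ho", "saltbridge", "toyprotein"),
                          d_targets, n_per = 1L, sigma = 0.1, seed = 1L,
                          params = list()) {
  family <- match.arg(family)
  stopifnot(length(d_targets) >= 1L, all(d_targets > 0), n_per >= 1L,
            sigma >= 0, is.numeric(seed))
  structure(list(family = family, d_targets = as.numeric(d_targets),
                 n_per = as.integer(n_per), sigma = sigma,
                 seed = as.integer(seed), params = params),
            class = "ensemble_spec")
}

#' Two-atom hydrogen-oxygen ion pair
#'
#' The minimal Coulomb-bond system: a carboxylate-type oxygen (q = -0.82 e,
#' rho = 1.5 A) and an amine-type hydrogen (q = +0.45 e, rho = `rho_H`)
#' placed on the x axis at separation d, tagged as two molecules.  The
#' charges and radii are the standard force-field values for a glutamate
#' side-chain oxygen and an arginine guanidinium hydrogen.
#'
#' @param d Separation, Angstrom (> 0).
#' @param rho_H Hydrogen intrinsic radius, Angstrom (default 1.2).
#' @param lj Optional list `list(O = c(rmin_half, epsilon), H = c(rmin_half,
#'   epsilon))` of 12-6 Lennard-Jones parameters (A, kcal/mol) to attach.
#' @return A `mol_system` with two atoms and `separation = d`.
#' @export
build_ho_system <- function(d, rho_H = 1.2, lj = NULL) {
  stopifnot(d > 0, rho_H > 0)
  atoms <- data.frame(
    atom_id = c("O", "H"),
    class_label = c("O-carboxyl", "H-on-N"),
    x = c(0, d), y = 0, z = 0,
    charge = c(-0.82, 0.45),
    intrinsic_radius = c(1.5, rho_H),
    molecule_tag = c("glu", "arg"),
    stringsAsFactors = FALSE)
  if (!is.null(lj)) {
    atoms$lj_rmin_half <- c(lj$O[1], lj$H[1])
    atoms$lj_epsilon <- c(lj$O[2], lj$H[2])
  }
  mol_system(atoms, separation = d, separation_def = "O-H distance")
}

## Idealized planar guanidinium fragment (CZ + 3 N + 5 H-on-N) in the xy
## plane, CZ at the origin, eta nitrogens facing +x.  Bond lengths C-N
## 1.33 A, N-H 1.01 A, sp2 angles.  Charges: a simple symmetric set summing
## to +1 e with every H-on-N at the +0.45 e force-field value (N -0.60,
## CZ +0.55); an idealized stand-in, not a force-field transcription.
guanidinium_fragment <- function() {
  cn <- 1.33; nh <- 1.01
  deg <- pi / 180
  pos <- rbind(
    CZ   = c(0, 0),
    NE   = cn * c(cos(180 * deg), sin(180 * deg)),
    NH1  = cn * c(cos(60 * deg), sin(60 * deg)),
    NH2  = cn * c(cos(-60 * deg), sin(-60 * deg)),
    HE   = cn * c(-1, 0) + nh * c(cos(120 * deg), sin(120 * deg)),
    HH11 = cn * c(cos(60 * deg), sin(60 * deg)) + nh * c(1, 0),
    HH12 = cn * c(cos(60 * deg), sin(60 * deg)) +
      nh * c(cos(120 * deg), sin(120 * deg)),
    HH21 = cn * c(cos(-60 * deg), sin(-60 * deg)) + nh * c(1, 0),
    HH22 = cn * c(cos(-60 * deg), sin(-60 * deg)) +
      nh * c(cos(-120 * deg), sin(-120 * deg)))
  data.frame(
    atom_id = rownames(pos),
    class_label = c("C", "N", "N", "N", rep("H-on-N", 5)),
    x = pos[, 1], y = pos[, 2], z = 0,
    charge = c(0.55, -0.60, -0.60, -0.60, rep(0.45, 5)),
    molecule_tag = "arg",
    stringsAsFactors = FALSE)
}

## Idealized carboxylate fragment (CD + 2 O-carboxyl) in the xy plane, CD at
## the origin, oxygens facing -x (toward the guanidinium when CD sits at
## x = d > 0).  C-O 1.25 A, O-C-O angle 126 degrees.  Charges -0.82 e per
## oxygen (the force-field value) and +0.64 e on the carbon, summing to -1.
carboxylate_fragment <- function() {
  co <- 1.25
  deg <- pi / 180
  pos <- rbind(
    CD  = c(0, 0),
    OE1 = co * c(cos(117 * deg), sin(117 * deg)),
    OE2 = co * c(cos(-117 * deg), sin(-117 * deg)))
  data.frame(
    atom_id = rownames(pos),
    class_label = c("C", "O-carboxyl", "O-carboxyl"),
    x = pos[, 1], y = pos[, 2], z = 0,
    charge = c(0.64, -0.82, -0.82),
    molecule_tag = "glu",
    stringsAsFactors = FALSE)
}

## Rigid bidentate salt-bridge geometry at guanidyl-to-carboxyl carbon
## distance d: both fragments coplanar, the two inner guanidinium hydrogens
## (HH11/HH21) facing the two carboxylate oxygens symmetrically.
salt_bridge_geometry <- function(d, radius_table = default_radius_table(),
                                 screen_table = default_screen_table()) {
  g <- guanidinium_fragment()
  c_ <- carboxylate_fragment()
  c_$x <- c_$x + d
  atoms <- rbind(g, c_)
  atoms$intrinsic_radius <- 1  # placeholder, assigned from table below
  sys <- mol_system(atoms, separation = d,
                    separation_def = "CZ-CD distance")
  assign_screen_scales(assign_radii(sys, table = radius_table),
                       table = screen_table)
}

#' Deterministic salt-bridge builder
#'
#' Returns a function `d -> mol_system` producing the rigid idealized
#' guanidinium-carboxylate geometry (no jitter) for use with
#' [distance_scan()] / [parameter_scan()].
#'
#' @param radius_table Class-label radius table (default mBondi2 values).
#' @param screen_table Class-label descreening scale factors (default HCT
#'   values, matching the OBC-parameterized GB model used for the
#'   amino-acid-scale analyses).
#' @return A builder function of the separation d (CZ-CD distance, A).
#' @export
salt_bridge_builder <- function(radius_table = default_radius_table(),
                                screen_table = default_screen_table()) {
  function(d) salt_bridge_geometry(d, radius_table, screen_table)
}

## Apply Gaussian jitter to all coordinates; redraw on cross-molecule
## clashes (any cross-fragment atom-atom distance < 0.8 A), up to 100
## attempts.
jitter_system <- function(sys, sigma, measure_d) {
  if (sigma == 0) {
    sys$separation <- measure_d(sys)
    return(sys)
  }
  for (attempt in seq_len(100L)) {
    cand <- sys
    n <- n_atoms(sys)
    cand$atoms$x <- cand$atoms$x + stats::rnorm(n, 0, sigma)
    cand$atoms$y <- cand$atoms$y + stats::rnorm(n, 0, sigma)
    cand$atoms$z <- cand$atoms$z + stats::rnorm(n, 0, sigma)
    if (min(interaction_pairs(cand)$d) >= 0.8) {
      cand$separation <- measure_d(cand)
      return(cand)
    }
  }
  stop("fragment clash persisted for 100 jitter attempts")
}

#' Idealized Arg-Glu salt-bridge conformer ensemble
#'
#' Generates snapshots of the rigid bidentate guanidinium-carboxylate
#' geometry at each target CZ-CD distance, applies Gaussian positional
#' jitter of amplitude `sigma` to every atom, re-measures d, and rejects
#' (redraws) snapshots with any cross-fragment contact closer than 0.8 A.
#' Regeneration with the same spec is bit-identical.
#'
#' The fragment charge set is a documented idealized table: every H-on-N
#' carries +0.45 e and every carboxylate oxygen -0.82 e (the printed
#' force-field values for the guanidinium hydrogen and carboxylate oxygen);
#' nitrogen and carbon charges complete the +1/-1 fragment totals.
#'
#' @param spec An [ensemble_spec()] (family `"saltbridge"`); `params` may
#'   carry `radius_table`.
#' @return A list of snapshots `list(system = <mol_system>, d = <numeric>)`
#'   with d the re-measured CZ-CD distance.
#' @export
build_salt_bridge_ensemble <- function(spec) {
  stopifnot(inherits(spec, "ensemble_spec"), spec$family == "saltbridge")
  rt <- spec$params$radius_table
  if (is.null(rt)) rt <- default_radius_table()
  st <- spec$params$screen_table
  if (is.null(st)) st <- default_screen_table()
  measure <- function(s) {
    p <- coords(s)
    sqrt(sum((p[s$atoms$atom_id == "CZ", ] -
              p[s$atoms$atom_id == "CD", ])^2))
  }
  set.seed(spec$seed)
  out <- vector("list", length(spec$d_targets) * spec$n_per)
  k <- 0L
  for (d0 in spec$d_targets) {
    base <- salt_bridge_geometry(d0, rt, st)
    for (s in seq_len(spec$n_per)) {
      k <- k + 1L
      snap <- jitter_system(base, spec$sigma, measure)
      out[[k]] <- list(system = snap, d = snap$separation)
    }
  }
  out
}

## One rigid bead cluster.  `patch` beads sit on a spherical cap of radius
## `cap_radius` around the interface axis (one tip bead on the axis, the
## rest on a ring at 16 degrees polar angle) so the interface protrudes and
## makes close contact at the bound-state separation; the remaining beads
## are packed uniformly in a sphere of radius `cluster_radius` with minimum
## bead-bead separation `min_sep`.  Core beads carry alternating +/-
## charges of magnitude `core_charge` (near-zero net, high charge-squared
## density) plus a small net bias of sign `facing` on the first core bead.
make_bead_cluster <- function(n_beads, cluster_radius, cap_radius, min_sep,
                              patch, facing, tag, patch_class,
                              patch_charge, core_charge, patch_radius,
                              bead_radius) {
  pos <- matrix(NA_real_, nrow = n_beads, ncol = 3)
  ang <- seq(0, 2 * pi, length.out = patch)[-patch]
  for (k in seq_len(patch)) {
    v <- if (k == 1L) c(1, 0, 0) else {
      th <- 16 * pi / 180
      c(cos(th), sin(th) * cos(ang[k - 1L]), sin(th) * sin(ang[k - 1L]))
    }
    pos[k, ] <- cap_radius * c(facing * v[1L], v[2L], v[3L])
  }
  placed <- patch
  guard <- 0L
  while (placed < n_beads) {
    guard <- guard + 1L
    if (guard > 200000L) stop("could not place beads without overlap")
    p <- stats::runif(3, -cluster_radius, cluster_radius)
    if (sum(p^2) > cluster_radius^2) next
    dd <- sqrt(rowSums((pos[seq_len(placed), , drop = FALSE] -
                        matrix(p, placed, 3, byrow = TRUE))^2))
    if (min(dd) < min_sep) next
    placed <- placed + 1L
    pos[placed, ] <- p
  }
  pos <- sweep(pos, 2, colMeans(pos))  # d is the centroid (COM) distance
  n_core <- n_beads - patch
  q_core <- rep(c(core_charge, -core_charge), length.out = n_core)
  q_core[1L] <- q_core[1L] + facing * 0.2
  data.frame(
    atom_id = sprintf("%s%02d", tag, seq_len(n_beads)),
    class_label = c(rep(patch_class, patch), rep("bead", n_core)),
    x = pos[, 1], y = pos[, 2], z = pos[, 3],
    charge = c(rep(patch_charge, patch), q_core),
    intrinsic_radius = c(rep(patch_radius, patch),
                         rep(bead_radius, n_core)),
    molecule_tag = tag,
    stringsAsFactors = FALSE)
}

#' Deterministic toy protein-pair builder
#'
#' Builds the rigid two-cluster system once (from the seed) and returns a
#' function `d -> mol_system` that translates cluster B along x so that the
#' distance between the cluster centers equals d.  Cluster A carries a
#' net-positive interface patch of `"H-on-N"`-class beads protruding toward
#' +x; cluster B a net-negative `"O-carboxyl"`-class patch protruding
#' toward -x; at the bound-state separation near 23.7 A the opposing patch
#' tips make a close (~2.7 A) charge-complementary contact.  Core beads
#' carry alternating positive and negative charges with a small net bias of
#' opposite sign on the two clusters, giving the interior the high
#' charge-squared density that drives a realistic desolvation penalty while
#' contributing little net Coulomb attraction.  The charge magnitudes are
#' sized so the contact-window energies reach the tens-of-kcal/mol scale of
#' a charge-steered protein-protein interface; the clusters are a synthetic
#' stand-in, not a model of any real complex.
#'
#' @param seed Integer seed fixing the bead geometry.
#' @param n_beads Beads per cluster (default 50).
#' @param cluster_radius Radius of the core bead-center envelope, Angstrom
#'   (default 8).
#' @param cap_radius Radius at which patch beads protrude, Angstrom
#'   (default 11.3, making the overall cluster span roughly 10 A).
#' @param n_patch Patch beads per cluster (default 4).
#' @param patch_charge Magnitude of each patch bead charge, e (default
#'   0.5).
#' @param core_charge Magnitude of the alternating core bead charges, e
#'   (default 1.0).
#' @param bead_radius Intrinsic radius of core beads, Angstrom (default
#'   2.0; patch beads use their class radii, 1.3 and 1.5).
#' @return A builder function of the center-center distance d (A).
#' @export
toy_protein_builder <- function(seed = 1L, n_beads = 50L,
                                cluster_radius = 8, cap_radius = 11.3,
                                n_patch = 4L, patch_charge = 0.5,
                                core_charge = 1.0, bead_radius = 2.0) {
  set.seed(seed)
  a <- make_bead_cluster(n_beads, cluster_radius, cap_radius,
                         min_sep = 3.0, patch = n_patch, facing = +1,
                         tag = "A", patch_class = "H-on-N",
                         patch_charge = patch_charge,
                         core_charge = core_charge, patch_radius = 1.3,
                         bead_radius = bead_radius)
  b <- make_bead_cluster(n_beads, cluster_radius, cap_radius,
                         min_sep = 3.0, patch = n_patch, facing = -1,
                         tag = "B", patch_class = "O-carboxyl",
                         patch_charge = -patch_charge,
                         core_charge = core_charge, patch_radius = 1.5,
                         bead_radius = bead_radius)
  function(d) {
    stopifnot(d > 0)
    bb <- b
    bb$x <- bb$x + d
    assign_screen_scales(
      mol_system(rbind(a, bb), separation = d,
                 separation_def = "center-of-mass distance"))
  }
}

#' Toy charge-complementary protein-pair ensemble
#'
#' Snapshots of the rigid [toy_protein_builder()] system at each target
#' center-of-mass distance with optional Gaussian jitter (clash-rejected as
#' in the salt-bridge builder).  Same seed, same clusters, same ensemble.
#'
#' @param spec An [ensemble_spec()] (family `"toyprotein"`); `params` may
#'   carry `n_beads`, `cluster_radius`, `n_patch`, `patch_charge`,
#'   `bead_radius`.
#' @return A list of snapshots `list(system =, d =)` with d the re-measured
#'   center-of-mass distance.
#' @export
build_toy_protein_pair <- function(spec) {
  stopifnot(inherits(spec, "ensemble_spec"), spec$family == "toyprotein")
  p <- spec$params
  builder <- do.call(toy_protein_builder, c(list(seed = spec$seed),
    p[intersect(names(p), c("n_beads", "cluster_radius", "cap_radius",
                            "n_patch", "patch_charge", "core_charge",
                            "bead_radius"))]))
  measure <- function(s) {
    xyz <- coords(s)
    tags <- s$atoms$molecule_tag
    sqrt(sum((colMeans(xyz[tags == "A", , drop = FALSE]) -
              colMeans(xyz[tags == "B", , drop = FALSE]))^2))
  }
  set.seed(spec$seed + 1L)  # geometry seed consumed inside the builder
  out <- vector("list", length(spec$d_targets) * spec$n_per)
  k <- 0L
  for (d0 in spec$d_targets) {
    base <- builder(d0)
    for (s in seq_len(spec$n_per)) {
      k <- k + 1L
      snap <- jitter_system(base, spec$sigma, measure)
      out[[k]] <- list(system = snap, d = snap$separation)
    }
  }
  out
}

#' Seeded Boltzmann sampling from a tabulated 1-D potential
#'
#' Draws i.i.d. samples from the density proportional to
#' `exp(-U(d) / (R T))` by inverse-CDF sampling on a fine grid (the
#' tabulated potential is linearly interpolated; within-cell positions are
#' uniform).  Used as the ground-truth generator when validating the
#' count-based PMF estimator.
#'
#' @param potential A data.frame with columns `d` (strictly increasing, A)
#'   and `U` (kcal/mol, finite).
#' @param T Temperature, Kelvin.
#' @param n Number of samples (>= 1).
#' @param seed Integer seed.
#' @param grid_n Number of interpolation cells (default 4000).
#' @return Numeric vector of n separation samples, Angstrom.
#' @export
sample_boltzmann_1d <- function(potential, T = 300, n, seed = 1L,
                                grid_n = 4000L) {
  stopifnot(is.data.frame(potential),
            all(c("d", "U") %in% names(potential)), n >= 1L, T > 0)
  if (any(!is.finite(potential$U))) stop("U must be finite on its support")
  if (is.unsorted(potential$d, strictly = TRUE)) {
    stop("potential$d must be strictly increasing")
  }
  xs <- seq(min(potential$d), max(potential$d), length.out = grid_n + 1L)
  Us <- stats::approx(potential$d, potential$U, xout = xs)$y
  Umid <- (Us[-1L] + Us[-length(Us)]) / 2
  w <- exp(-(Umid - min(Umid)) / (.R_kcal * T))
  if (!all(is.finite(w)) || sum(w) <= 0) {
    stop("potential is unnormalizable at this temperature")
  }
  p <- w / sum(w)
  set.seed(seed)
  cell <- sample.int(length(p), n, replace = TRUE, prob = p)
  xs[cell] + stats::runif(n) * diff(xs)[cell]
}
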