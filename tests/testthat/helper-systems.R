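# Shared fixtures, all generated in code.

# 12-6 Lennard-Jones parameters (rmin/2 in A, epsilon in kcal/mol) for the
# amine hydrogen and carboxylate oxygen atom types of the ff99SB force
# field; caller-supplied to the builders, the package ships none.
ff99sb_lj <- list(O = c(1.6612, 0.2100), H = c(0.6000, 0.0157))

rho_h_grid <- c(1.1, 1.2, 1.3, 1.4, 1.5)

# Random many-atom system in which every atom is its own molecule, so every
# pair is a cross-molecule pair (the regime where the unified GB double sum
# decomposes exactly into self + screening interaction terms).
random_system <- function(n = NULL) {
  if (is.null(n)) n <- sample(2:8, 1)
  repeat {
    pos <- matrix(stats::runif(3 * n, 0, 8), ncol = 3)
    if (n == 1 || min(stats::dist(pos)) > 1.0) break
  }
  mol_system(data.frame(
    atom_id = paste0("a", seq_len(n)),
    class_label = "bead",
    x = pos[, 1], y = pos[, 2], z = pos[, 3],
    charge = stats::runif(n, -1, 1),
    intrinsic_radius = stats::runif(n, 0.8, 2.0),
    molecule_tag = paste0("m", seq_len(n)),
    stringsAsFactors = FALSE))
}

# Arbitrary two-molecule system with given per-molecule atom counts.
two_molecule_system <- function(n_a, n_b) {
  n <- n_a + n_b
  mol_system(data.frame(
    atom_id = paste0("x", seq_len(n)),
    class_label = "bead",
    x = c(seq_len(n_a), 20 + seq_len(n_b)), y = 0, z = 0,
    charge = 0.1,
    intrinsic_radius = 1.5,
    molecule_tag = rep(c("A", "B"), c(n_a, n_b)),
    stringsAsFactors = FALSE))
}
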