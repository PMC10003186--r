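test_that("H-O builder carries the printed charges and radii", {
  sys <- build_ho_system(1.57, 1.2)
  expect_equal(sys$atoms$charge, c(-0.82, 0.45))
  expect_equal(sys$atoms$intrinsic_radius, c(1.5, 1.2))
  expect_equal(build_ho_system(2, 1.5)$atoms$intrinsic_radius[2], 1.5)
  expect_equal(length(unique(sys$atoms$molecule_tag)), 2L)
  # far apart: reference state, everything ~ 0
  bd <- energy_breakdown(build_ho_system(999), gb_config(rmax = Inf))
  expect_lt(abs(bd$dG_self_total), 1e-6)
  expect_lt(abs(bd$coulomb_total), 0.15)
})

test_that("salt-bridge geometry is a rigid bidentate contact at the stated d", {
  ens <- build_salt_bridge_ensemble(
    ensemble_spec("saltbridge", d_targets = 4.0, n_per = 1, sigma = 0,
                  seed = 1))
  expect_length(ens, 1L)
  sys <- ens[[1]]$system
  expect_equal(ens[[1]]$d, 4.0, tolerance = 1e-12)
  expect_equal(n_atoms(sys), 12L)
  expect_equal(sum(sys$atoms$charge), 0, tolerance = 1e-12)
  expect_equal(sum(sys$atoms$class_label == "H-on-N"), 5L)
  expect_equal(sum(sys$atoms$class_label == "O-carboxyl"), 2L)
  # the two inner hydrogens make hydrogen-bond-range contacts to the oxygens
  pr <- interaction_pairs(sys)
  hb <- pr$d[pr$atom_i %in% c("HH11", "HH21") & pr$atom_j %in% c("OE1", "OE2")]
  expect_lt(min(hb), 2.1)
  validate_mol_system(sys)
})

test_that("ensembles regenerate bit-identically from the seed", {
  spec <- ensemble_spec("saltbridge", d_targets = c(3.5, 4.5), n_per = 5,
                        sigma = 0.1, seed = 33)
  e1 <- build_salt_bridge_ensemble(spec)
  e2 <- build_salt_bridge_ensemble(spec)
  expect_identical(lapply(e1, function(s) s$system$atoms),
                   lapply(e2, function(s) s$system$atoms))
  expect_identical(vapply(e1, `[[`, 1, "d"), vapply(e2, `[[`, 1, "d"))

  tspec <- ensemble_spec("toyprotein", d_targets = 30, n_per = 3,
                         sigma = 0.1, seed = 12)
  t1 <- build_toy_protein_pair(tspec)
  t2 <- build_toy_protein_pair(tspec)
  expect_identical(t1[[2]]$system$atoms, t2[[2]]$system$atoms)
})

test_that("jittered snapshots track the target separation window", {
  spec <- ensemble_spec("saltbridge", d_targets = 3.95, n_per = 60,
                        sigma = 0.1, seed = 7)
  dv <- vapply(build_salt_bridge_ensemble(spec), `[[`, 1, "d")
  expect_gt(sum(dv >= 3.9 & dv < 4.0), 10)
  expect_true(all(abs(dv - 3.95) < 1))
})

test_that("binned salt-bridge interaction energy relaxes toward zero with d", {
  spec <- ensemble_spec("saltbridge", d_targets = c(3.5, 5, 7, 9.5),
                        n_per = 4, sigma = 0.05, seed = 3)
  ens <- build_salt_bridge_ensemble(spec)
  cfg <- gb_config(born_mode = "obc2")
  pr <- ensemble_binned_profile(ens, bin_edges = c(3, 4, 6, 8, 10), cfg)
  g <- pr$G_int[pr$n > 0]
  expect_true(all(g < 0))
  expect_true(all(diff(g) > 0))
})

test_that("toy pair: complementary patches, neutral-ish cores, far-field decay", {
  b <- toy_protein_builder(seed = 5)
  sys <- b(60)
  a <- sys$atoms
  expect_equal(n_atoms(sys), 100L)
  patchA <- a$class_label == "H-on-N"
  patchB <- a$class_label == "O-carboxyl"
  expect_gt(sum(a$charge[patchA]), 0)
  expect_lt(sum(a$charge[patchB]), 0)
  expect_gt(sum(a$charge[a$molecule_tag == "A"]), 0)
  expect_lt(sum(a$charge[a$molecule_tag == "B"]), 0)
  expect_equal(sum(a$charge), 0, tolerance = 1e-9)
  bd <- energy_breakdown(sys, gb_config(rmax = 10))
  expect_lt(abs(bd$dG_self_total), 0.1)
  expect_lt(abs(bd$coulomb_total), 1.5)  # residual screened monopole
})

test_that("Boltzmann sampler matches closed-form statistics", {
  # flat potential: uniform distribution
  flat <- data.frame(d = c(2, 6), U = c(1, 1))
  s <- sample_boltzmann_1d(flat, T = 300, n = 10000, seed = 2)
  ks <- suppressWarnings(stats::ks.test(s, "punif", 2, 6))
  expect_gt(ks$p.value, 0.01)
  # harmonic potential: variance RT / k
  kspring <- 3
  dd <- seq(2, 8, by = 0.002)
  harm <- data.frame(d = dd, U = 0.5 * kspring * (dd - 5)^2)
  s2 <- sample_boltzmann_1d(harm, T = 300, n = 100000, seed = 4)
  expect_equal(stats::var(s2), 0.0019872 * 300 / kspring, tolerance = 0.05)
  # reproducibility
  expect_identical(sample_boltzmann_1d(harm, 300, 100, seed = 9),
                   sample_boltzmann_1d(harm, 300, 100, seed = 9))
  expect_error(sample_boltzmann_1d(data.frame(d = c(1, 2), U = c(NA, 1)),
                                   300, 10), "finite")
})
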