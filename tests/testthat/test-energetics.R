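test_that("f_gb interpolates between contact and large separation", {
  expect_equal(f_gb(0, 2, 3), sqrt(6))
  expect_equal(f_gb(2, 2, 2), sqrt(4 + 4 * exp(-0.25)))
  expect_equal(f_gb(2, 2, 2), 2.6674338, tolerance = 1e-6)
  expect_equal(f_gb(50, 1.5, 1.5), 50, tolerance = 1e-6)
  expect_identical(f_gb(1.3, 1.1, 2.2), f_gb(1.3, 2.2, 1.1))
  d <- runif(20, 0, 10)
  expect_true(all(f_gb(d, 1.4, 2.1) >= d))
  expect_error(f_gb(1, -1, 1), "> 0")
})

test_that("Born self energy has the right sign, scale and limits", {
  cfg <- gb_config()
  expect_equal(gb_self_energy(0, 1.5, cfg), 0)
  expect_equal(gb_self_energy(-0.82, 1.5, cfg), -73.4785, tolerance = 1e-4)
  expect_lt(gb_self_energy(-0.82, 1e9, cfg), 0)
  expect_gt(gb_self_energy(-0.82, 1e9, cfg), -1e-5)
  R <- seq(1, 10, by = 0.5)
  v <- gb_self_energy(0.5, R, cfg)
  expect_true(all(v <= 0) && all(diff(v) > 0))  # magnitude shrinks with R
})

test_that("desolvation energies vanish at separation and stay positive on approach", {
  cfg <- gb_config()
  sys <- build_ho_system(800)
  des <- desolvation_energies(sys, born_radii(sys, cfg), cfg)
  expect_equal(unname(des$per_atom), c(0, 0), tolerance = 1e-8)
  for (d in seq(1, 8, by = 0.5)) {
    sys <- build_ho_system(d, 1.2)
    des <- desolvation_energies(sys, born_radii(sys, cfg), cfg)
    expect_true(all(des$per_atom >= 0))
  }
})

test_that("desolvation reference is the isolated-molecule state", {
  # multi-atom molecules: at large separation dG_self -> 0 even though the
  # intramolecular descreening keeps every R above rho
  cfg <- gb_config()
  sys <- salt_bridge_builder()(60)
  born <- born_radii(sys, cfg)
  expect_true(all(born$R > born$rho))
  des <- desolvation_energies(sys, born, cfg)
  expect_lt(abs(des$total), 0.05)
  expect_error(desolvation_energies(sys, born, gb_config(rmax = 10)),
               "different gb_config")
})

test_that("opposite rho_H trends of the two desolvation penalties", {
  cfg <- gb_config()
  dg <- sapply(rho_h_grid, function(rh) {
    sys <- build_ho_system(1.57, rh)
    desolvation_energies(sys, born_radii(sys, cfg), cfg)$per_atom
  })
  expect_true(all(diff(dg["O", ]) > 0))
  expect_true(all(diff(dg["H", ]) < 0))
})

test_that("interaction energy: vacuum term, screening limit, rho_H trend", {
  cfg <- gb_config()
  sys <- build_ho_system(1.57, 1.2)
  ie <- interaction_energy(sys, born_radii(sys, cfg), cfg)
  expect_equal(ie$E_vac_int, -78.0455, tolerance = 1e-4)

  # fully screened far field: G_int -> ke q1 q2 / (eps_w d)
  far <- build_ho_system(50, 1.2)
  ief <- interaction_energy(far, born_radii(far, cfg), cfg)
  screened <- cfg$coulomb_constant * (-0.82 * 0.45) / (cfg$epsilon_w * 50)
  expect_equal(ief$G_int, screened, tolerance = 1e-4)

  g <- sapply(rho_h_grid, function(rh) {
    s <- build_ho_system(1.57, rh)
    interaction_energy(s, born_radii(s, cfg), cfg)$G_int
  })
  expect_true(all(diff(g) < 0))  # monotone stabilization with rho_H

  # coincident cross-molecule atoms are singular
  bad <- build_ho_system(3)
  bad$atoms$x[2] <- 0
  expect_error(interaction_energy(bad, born_radii(bad, cfg), cfg),
               "coincident")
})

test_that("unified GB double sum equals the self + screening decomposition", {
  cfg <- gb_config()
  # single atom: only the i = j term survives
  solo <- mol_system(build_ho_system(3)$atoms[1, , drop = FALSE])
  b <- born_radii(solo, cfg)
  expect_equal(total_gb_energy(solo, b, cfg),
               unname(gb_self_energy(-0.82, b$R, cfg)), tolerance = 1e-12)
  # zero charges
  z <- build_ho_system(3)
  z$atoms$charge <- 0
  expect_equal(total_gb_energy(z, born_radii(z, cfg), cfg), 0)
  # H-O at 3 A: identity to 1e-10 relative
  sys <- build_ho_system(3.0, 1.2)
  b <- born_radii(sys, cfg)
  uni <- total_gb_energy(sys, b, cfg)
  dec <- sum(gb_self_energy(sys$atoms$charge, b$R, cfg)) +
    interaction_energy(sys, b, cfg)$G_gb_int
  expect_lt(abs(uni - dec) / abs(uni), 1e-10)
})

test_that("decomposition identity holds across random all-cross systems", {
  set.seed(9)
  for (rep in 1:25) {
    sys <- random_system()
    cfg <- gb_config(rmax = sample(c(8, 999), 1))
    b <- suppressWarnings(born_radii(sys, cfg))
    uni <- total_gb_energy(sys, b, cfg)
    dec <- sum(gb_self_energy(sys$atoms$charge, b$R, cfg)) +
      interaction_energy(sys, b, cfg)$G_gb_int
    expect_lt(abs(uni - dec) / max(abs(uni), 1e-8), 1e-10)
  }
})

test_that("Lennard-Jones term has the textbook minimum and limits", {
  mk <- function(d) build_ho_system(d, lj = ff99sb_lj)
  rmin <- ff99sb_lj$O[1] + ff99sb_lj$H[1]
  eps <- sqrt(ff99sb_lj$O[2] * ff99sb_lj$H[2])
  expect_equal(lj_energy(mk(rmin)), -eps, tolerance = 1e-10)
  expect_equal(lj_energy(mk(500)), 0, tolerance = 1e-10)
  z <- mk(2.0)
  z$atoms$lj_epsilon[1] <- 0
  expect_equal(lj_energy(z), 0)
  miss <- build_ho_system(2.0)
  expect_error(lj_energy(miss), "H|O")
})

test_that("counterbalance: interaction outweighs total self across the rho_H range", {
  cfg <- gb_config()
  at <- function(rh) {
    bd <- energy_breakdown(build_ho_system(1.57, rh), cfg)
    c(self = bd$dG_self_total, gint = bd$G_int)
  }
  lo <- at(1.1); hi <- at(1.5)
  expect_lt(abs(hi["self"] - lo["self"]), abs(hi["gint"] - lo["gint"]))
})
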