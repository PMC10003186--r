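test_that("closed-form descreening integral matches known values", {
  # disjoint geometry, no cutoff: frozen from the quadrature oracle
  expect_equal(sphere_descreen_integral(1.5, 1.2, 3.0), 0.008756924,
               tolerance = 1e-6)
  # empty domains
  expect_equal(sphere_descreen_integral(1.5, 1.2, 10, rmax = 8), 0)
  expect_equal(sphere_descreen_integral(1.5, 0, 2.0), 0)
  # invalid input
  expect_error(sphere_descreen_integral(-1, 1, 2), "rho_i > 0")
  expect_error(sphere_descreen_integral(1.5, 1, 2, rmax = 1.0), "rmax")
})

test_that("closed form agrees with the quadrature oracle on all branches", {
  cases <- expand.grid(rho = c(1.0, 1.5),
                       a = c(0.5, 1.2, 2.0, 4.0),
                       d = c(0, 0.05, 0.3, 1.0, 2.0, 3.5, 8.0),
                       rmax = c(2.5, 5, Inf))
  for (k in seq_len(nrow(cases))) {
    cs <- cases[k, ]
    got <- sphere_descreen_integral(cs$rho, cs$a, cs$d, cs$rmax)
    ora <- descreen_integral_oracle(cs$rho, cs$a, cs$d, cs$rmax)
    if (ora > 1e-9) {
      expect_lt(abs(got - ora) / ora, 1e-4)
    } else {
      expect_lt(abs(got - ora), 1e-9)
    }
  }
})

test_that("oracle matches the analytic disjoint branch on random geometries", {
  set.seed(4)
  for (k in 1:50) {
    rho <- runif(1, 0.8, 2)
    a <- runif(1, 0.2, 2.5)
    d <- rho + a + runif(1, 0.05, 6)
    closed <- 0.5 * (a / (d^2 - a^2) + log((d - a) / (d + a)) / (2 * d))
    expect_equal(descreen_integral_oracle(rho, a, d), closed,
                 tolerance = 1e-5)
  }
})

test_that("integral is monotone in rmax and decreasing in d beyond contact", {
  base <- sphere_descreen_integral(1.5, 1.2, 3.0)
  expect_lt(sphere_descreen_integral(1.5, 1.2, 3.0, rmax = 3.5), base)
  rmaxes <- c(2, 3, 4, 6, 10, Inf)
  vals <- sphere_descreen_integral(rep(1.5, 6), 1.2, 3.0, rmaxes)
  expect_true(all(diff(vals) >= 0))
  dd <- seq(2.7, 12, by = 0.1)  # disjoint for rho 1.5, a 1.2
  expect_true(all(diff(sphere_descreen_integral(1.5, 1.2, dd)) < 0))
})

test_that("far field decays like the leading a^3/(3 d^4) term", {
  a <- 1.3
  got <- sphere_descreen_integral(1.5, a, 100)
  expect_equal(got, a^3 / (3 * 100^4), tolerance = 0.01)
})

test_that("born_radii recovers isolated and pairwise limits", {
  solo <- two_molecule_system(1, 1)
  solo$atoms <- solo$atoms[1, , drop = FALSE]
  solo <- mol_system(solo$atoms)
  b <- born_radii(solo, gb_config())
  expect_equal(b$I, 0)
  expect_equal(b$R, solo$atoms$intrinsic_radius)

  # H-O at d = 3: the oxygen radius grows by exactly the pair integral
  sys <- build_ho_system(3.0, rho_H = 1.2)
  b <- born_radii(sys, gb_config())
  expect_equal(b$R[b$atom_id == "O"], 1 / (1 / 1.5 - 0.008756924),
               tolerance = 1e-5)
  expect_true(all(b$R >= b$rho))
  expect_true(all(b$I >= 0 & b$I <= 1 / b$rho))

  # far separation: every I -> 0, R -> rho
  far <- born_radii(build_ho_system(500), gb_config(rmax = Inf))
  expect_equal(far$R, far$rho, tolerance = 1e-6)
})

test_that("growing a descreening sphere shifts I of both partners as expected", {
  cfg <- gb_config()
  b1 <- born_radii(build_ho_system(1.57, 1.1), cfg)
  b2 <- born_radii(build_ho_system(1.57, 1.5), cfg)
  # larger rho_H: more oxygen descreening, less hydrogen descreening
  expect_gt(b2$I[b2$atom_id == "O"], b1$I[b1$atom_id == "O"])
  expect_lt(b2$I[b2$atom_id == "H"], b1$I[b1$atom_id == "H"])
})

test_that("adding a descreening sphere never decreases I", {
  cfg <- gb_config()
  set.seed(21)
  for (rep in 1:10) {
    base <- random_system(n = 4)
    extra <- base$atoms[1, ]
    extra$atom_id <- "extra"
    extra$molecule_tag <- "extra"
    extra[, c("x", "y", "z")] <- runif(3, 0, 8)
    grown <- mol_system(rbind(base$atoms, extra))
    i0 <- born_radii(base, cfg)
    i1 <- born_radii(grown, cfg)
    expect_true(all(i1$I[seq_len(4)] >= i0$I - 1e-12))
  }
})

test_that("overdescreened geometries are clamped with a warning", {
  atoms <- data.frame(
    atom_id = c("p", paste0("s", 1:6)),
    class_label = "bead",
    x = c(0, 0.5, -0.5, 0, 0, 0, 0),
    y = c(0, 0, 0, 0.5, -0.5, 0, 0),
    z = c(0, 0, 0, 0, 0, 0.5, -0.5),
    charge = 0.1, intrinsic_radius = c(1.0, rep(4, 6)),
    molecule_tag = c("A", rep("B", 6)))
  sys <- mol_system(atoms)
  expect_warning(b <- born_radii(sys, gb_config()), "clamp")
  expect_true(all(is.finite(b$R)) && all(b$R > 0))
})

test_that("obc2 mode rescales radii through the tanh form", {
  sys <- build_ho_system(3.0, 1.2)
  plain <- born_radii(sys, gb_config())
  obc <- born_radii(sys, gb_config(born_mode = "obc2"))
  # isolated limit in obc2 is the offset-reduced radius
  solo <- mol_system(sys$atoms[1, , drop = FALSE])
  b <- born_radii(solo, gb_config(born_mode = "obc2"))
  expect_equal(b$R, sys$atoms$intrinsic_radius[1] - 0.09, tolerance = 1e-10)
  # both modes finite and positive, but not identical
  expect_false(isTRUE(all.equal(plain$R, obc$R)))
})

test_that("rmax clipping and whole-atom dropping agree without a cutoff", {
  sys <- build_ho_system(3.0, 1.2)
  clip <- born_radii(sys, gb_config(rmax = 999, rmax_mode = "clip"))
  drop <- born_radii(sys, gb_config(rmax = 999, rmax_mode = "drop"))
  expect_equal(clip$I, drop$I, tolerance = 1e-12)
  # with a cutoff between the atoms they differ: dropping removes the whole
  # sphere, clipping keeps the part inside rmax
  clip2 <- born_radii(sys, gb_config(rmax = 2.5, rmax_mode = "clip"))
  drop2 <- born_radii(sys, gb_config(rmax = 2.5, rmax_mode = "drop"))
  expect_true(all(drop2$I == 0))
  expect_true(all(clip2$I > 0))
  expect_true(all(clip2$I <= clip$I))
})
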