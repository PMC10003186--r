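test_that("distance_scan profiles decay to zero in the far field", {
  cfg <- gb_config()
  pr <- distance_scan(function(d) build_ho_system(d, 1.2),
                      seq(1.0, 8.0, by = 0.05), cfg)
  tail_row <- pr[nrow(pr), ]
  for (col in c("dGself_O", "dGself_H", "dGself_total", "G_int",
                "coulomb_total")) {
    expect_lt(abs(tail_row[[col]]), 0.2)
  }
  # the vacuum and screening components only cancel jointly (each decays
  # as 1/d); their sum is the physical interaction energy
  expect_lt(abs(tail_row$E_vac_int + tail_row$G_gb_int), 0.2)
  expect_gt(abs(tail_row$E_vac_int), 1)
  # single-point grid
  one <- distance_scan(function(d) build_ho_system(d), 2.5, cfg)
  expect_equal(nrow(one), 1L)
  # zero charges: all Coulomb columns identically zero
  zb <- function(d) { s <- build_ho_system(d); s$atoms$charge <- 0; s }
  zp <- distance_scan(zb, c(1.5, 2, 3), cfg)
  expect_true(all(abs(as.matrix(zp[, -1])) == 0))
  # builder failure is reported with the offending d
  expect_error(distance_scan(function(d) stop("boom"), c(1, 2), cfg),
               "d = 1")
})

test_that("parameter_scan produces one labeled profile per setting", {
  cfg <- gb_config()
  scans <- parameter_scan(function(d) build_ho_system(d),
                          rho_values = list("H-on-N" = rho_h_grid),
                          config = cfg, d_grid = c(1.57, 3))
  expect_length(scans, 5L)
  expect_true(all(grepl("rhoH-on-N=1\\.[1-5]_rmax=999", names(scans))))
  ov <- profile_meta(scans[[2]])$overrides
  expect_equal(unname(ov["H-on-N"]), 1.2)
  # singleton lists reduce to a plain distance scan
  single <- parameter_scan(function(d) build_ho_system(d),
                           rho_values = list("H-on-N" = 1.2),
                           config = cfg, d_grid = c(1.57, 3))
  direct <- distance_scan(function(d) build_ho_system(d),
                          c(1.57, 3),
                          gb_config(radius_overrides = c("H-on-N" = 1.2)))
  expect_equal(as.data.frame(single[[1]]), as.data.frame(direct))
  # absent class in an override errors
  expect_error(
    parameter_scan(function(d) build_ho_system(d),
                   rho_values = list(nope = 1.2), config = cfg,
                   d_grid = 2),
    "nope")
})

test_that("ensemble binning averages within half-open bins and flags empties", {
  cfg <- gb_config()
  snap <- list(system = build_ho_system(2.5), d = 2.5)
  ens <- list(snap, snap, snap)
  expect_warning(
    pr <- ensemble_binned_profile(ens, bin_edges = c(2, 2.4, 2.8, 3.2), cfg),
    "no snapshot")
  expect_equal(pr$n, c(0L, 3L, 0L))
  expect_true(all(pr$empty == c(TRUE, FALSE, TRUE)))
  bd <- energy_breakdown(snap$system, cfg)
  expect_equal(pr$coulomb_total[2], bd$coulomb_total)
  expect_true(is.na(pr$coulomb_total[1]))
})

test_that("PMF estimator reproduces exact count ratios", {
  # equal counts everywhere: flat PMF
  d <- rep(seq(1.05, 2.95, by = 0.1), each = 7)
  pr <- pmf_from_counts(d, bin_width = 0.1, d_ref = 2.05, T = 300)
  expect_true(all(abs(pr$pmf[pr$n > 0]) < 1e-12))
  # a doubled bin sits at exactly -RT log 2
  d2 <- c(rep(1.95, 100), rep(2.05, 200))
  pr2 <- pmf_from_counts(d2, bin_width = 0.1, d_ref = 1.95, T = 300)
  expect_equal(pr2$pmf[abs(pr2$d - 2.05) < 1e-9],
               -0.0019872 * 300 * log(2))
  expect_equal(pr2$pmf[abs(pr2$d - 2.05) < 1e-9], -0.4132,
               tolerance = 1e-3)
  # reference bin must be occupied
  expect_error(pmf_from_counts(d2, 0.1, d_ref = 9), "empty")
})

test_that("PMF estimator is invariant under sample duplication", {
  set.seed(5)
  d <- runif(500, 2, 6)
  a <- pmf_from_counts(d, 0.25, d_ref = 4.1)
  b <- pmf_from_counts(rep(d, 3), 0.25, d_ref = 4.1)
  expect_equal(a$pmf, b$pmf)
  expect_equal(b$n, 3L * a$n)
})

test_that("locate_minimum refines quadratically and flags boundaries", {
  d <- seq(1, 3, by = 0.1)
  par <- profile_table(data.frame(d = d, y = (d - 2)^2))
  m <- locate_minimum(par, "y")
  expect_equal(m$d_min, 2.0, tolerance = 1e-12)
  expect_false(m$boundary)
  mono <- profile_table(data.frame(d = d, y = d))
  expect_true(locate_minimum(mono, "y")$boundary)
  # off-grid parabola minimum is recovered exactly
  par2 <- profile_table(data.frame(d = d, y = 3 * (d - 2.0345)^2 - 1))
  expect_equal(locate_minimum(par2, "y")$d_min, 2.0345, tolerance = 1e-9)
})

test_that("total-energy minimum of the H-O system sits near the ionic-bond distance", {
  cfg <- gb_config()
  pr <- distance_scan(function(d) build_ho_system(d, 1.2, lj = ff99sb_lj),
                      seq(1.0, 3.0, by = 0.01), cfg, lj = TRUE)
  m <- locate_minimum(pr, "E_total")
  expect_false(m$boundary)
  expect_gt(m$d_min, 1.0)
  expect_lt(m$d_min, 3.0)
})

test_that("window_mean weights binned profiles by snapshot counts", {
  pr <- profile_table(data.frame(d = c(1, 2, 3), n = c(1L, 3L, 0L),
                                 y = c(4, 8, NA)))
  expect_equal(window_mean(pr, "y", 0.5, 3.5), (4 * 1 + 8 * 3) / 4)
  expect_warning(v <- window_mean(pr, "y", 5, 6), "no profile rows")
  expect_true(is.na(v))
})

test_that("barrier height measures the hump above the far-field plateau", {
  d <- seq(1, 10, by = 0.1)
  y <- -2 * exp(-(d - 1.5)^2) + 1.2 * exp(-(d - 3)^2 / 2)
  pr <- profile_table(data.frame(d = d, y = y))
  bh <- barrier_height(pr, "y")
  expect_gt(bh$height, 1.0)
  expect_equal(bh$d_peak, 3, tolerance = 0.2)
  flat <- profile_table(data.frame(d = d, y = -1 / d))
  expect_equal(barrier_height(flat, "y")$height, 0)
})
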