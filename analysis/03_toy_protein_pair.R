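#!/usr/bin/env Rscript

# Toy charge-complementary protein pair: the two-way rmax / intrinsic-radius
# adjustment.  A large integration cutoff rmax inflates the desolvation
# penalty and raises an association barrier in the total Coulomb energy;
# with rmax kept small (10 A), enlarging the interface radii (rho_H of the
# positive patch, rho_O of the negative patch) stabilizes the bound state
# through the interaction term.  Plain (Coulomb-field-approximation) GB
# with HCT screening factors.
#
# Outputs (results/toypair/):
#   approach_rmax*.csv   rigid approach profiles at rmax 10 / 15 / 25 A
#   barriers.csv         barrier heights vs rmax
#   window_vs_rho.csv    23.6-23.8 A window means at the two radius sets

suppressMessages(library(gbintrad))

out_dir <- "results/toypair"
builder <- toy_protein_builder(seed = 7)
d_grid <- seq(22, 45, by = 0.5)

scans <- parameter_scan(builder, rmax_values = c(10, 15, 25),
                        config = gb_config(), d_grid = d_grid)
write_results(scans, out_dir, config = gb_config())

barriers <- do.call(rbind, lapply(seq_along(scans), function(k) {
  bh <- barrier_height(scans[[k]], "coulomb_total")
  data.frame(setting = names(scans)[k], barrier = bh$height,
             d_peak = bh$d_peak)
}))
write.csv(barriers, file.path(out_dir, "barriers.csv"),
          row.names = FALSE, quote = FALSE)

spec <- ensemble_spec("toyprotein", d_targets = 23.7, n_per = 40,
                      sigma = 0.1, seed = 19)
ens <- build_toy_protein_pair(spec)
dv <- vapply(ens, `[[`, numeric(1), "d")
win <- ens[dv >= 23.6 & dv <= 23.8]
settings <- list(c("H-on-N" = 1.3, "O-carboxyl" = 1.5),
                 c("H-on-N" = 1.4, "O-carboxyl" = 1.6))
window_tab <- do.call(rbind, lapply(settings, function(ov) {
  cfg <- gb_config(rmax = 10, radius_overrides = ov)
  pr <- ensemble_binned_profile(win, bin_edges = c(23.6, 23.8), cfg)
  data.frame(rho_H = ov[["H-on-N"]], rho_O = ov[["O-carboxyl"]],
             n = pr$n[1], dGself = pr$dGself_total[1],
             G_int = pr$G_int[1], coulomb_total = pr$coulomb_total[1])
}))
write.csv(window_tab, file.path(out_dir, "window_vs_rho.csv"),
          row.names = FALSE, quote = FALSE)

cat("total-Coulomb association barrier vs rmax:\n")
print(barriers, row.names = FALSE, digits = 3)
cat("\nbound-state window (23.6-23.8 A) at rmax = 10 A:\n")
print(window_tab, row.names = FALSE, digits = 4)
cat("\nLarger rmax -> larger barrier (desolvation overestimation); larger\n")
cat("interface radii at small rmax -> extra stabilization via G_int.\n")
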