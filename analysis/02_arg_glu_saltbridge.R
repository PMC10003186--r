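#!/usr/bin/env Rscript

# Idealized Arg-Glu salt bridge: window-averaged ensemble energetics of the
# Coulomb-bond-formation state (Czeta-Cdelta distance 3.9-4.0 A) as a
# function of the guanidinium-hydrogen intrinsic radius, plus the distance
# profile of the rigid geometry.  GB configuration: OBC(II) radii with HCT
# screening factors, eps_w 78.5, rmax 999 A.
#
# Outputs (results/saltbridge/):
#   window_vs_rhoH.csv   window means of dGself, Gint, total vs rho_H
#   profile_rhoH*.csv    rigid-geometry distance profiles (3.2-10 A)

suppressMessages(library(gbintrad))

out_dir <- "results/saltbridge"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
rho_h <- c(1.1, 1.2, 1.3, 1.4, 1.5)

spec <- ensemble_spec("saltbridge", d_targets = 3.95, n_per = 900,
                      sigma = 0.1, seed = 42)
ens <- build_salt_bridge_ensemble(spec)
dv <- vapply(ens, `[[`, numeric(1), "d")
win <- ens[dv >= 3.9 & dv < 4.0]
cat(sprintf("ensemble: %d snapshots, %d in the 3.9-4.0 A window\n",
            length(ens), length(win)))

window_tab <- do.call(rbind, lapply(rho_h, function(rh) {
  cfg <- gb_config(born_mode = "obc2", radius_overrides = c("H-on-N" = rh))
  pr <- ensemble_binned_profile(win, bin_edges = c(3.9, 4.0), cfg)
  data.frame(rho_H = rh, n = pr$n[1], dGself = pr$dGself_total[1],
             G_int = pr$G_int[1], coulomb_total = pr$coulomb_total[1])
}))
write.csv(window_tab, file.path(out_dir, "window_vs_rhoH.csv"),
          row.names = FALSE, quote = FALSE)

scans <- parameter_scan(salt_bridge_builder(),
                        rho_values = list("H-on-N" = c(1.1, 1.3, 1.5)),
                        config = gb_config(born_mode = "obc2"),
                        d_grid = seq(3.2, 10, by = 0.1))
write_results(scans, out_dir, config = gb_config(born_mode = "obc2"))

cat("\nwindow averages (kcal/mol):\n")
print(window_tab, row.names = FALSE, digits = 4)
cat(sprintf(
  "\nrho_H 1.1 -> 1.5 A: desolvation penalty rises by %+.2f kcal/mol but the\n",
  window_tab$dGself[5] - window_tab$dGself[1]))
cat(sprintf(
  "interaction term falls by %+.2f; net Coulomb-bond stabilization %.2f kcal/mol.\n",
  window_tab$G_int[5] - window_tab$G_int[1],
  window_tab$coulomb_total[1] - window_tab$coulomb_total[5]))
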