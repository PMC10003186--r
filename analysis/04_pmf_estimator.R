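#!/usr/bin/env Rscript

# Validation of the count-based PMF estimator -RT ln[n(d)/Nref] on seeded
# Boltzmann samples from a known double-well potential (wells at 4 and 6 A,
# 1.5 kcal/mol barrier, T = 300 K), and a demonstration on the salt-bridge
# total-Coulomb profile used as a 1-D potential.
#
# Outputs (results/pmf/):
#   doublewell_pmf.csv    recovered vs true PMF per 0.1 A bin
#   saltbridge_pmf.csv    PMF sampled from the rigid-profile potential

suppressMessages(library(gbintrad))

out_dir <- "results/pmf"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

dd <- seq(3, 7, by = 0.002)
U <- 1.5 * ((dd - 5)^2 - 1)^2
samples <- sample_boltzmann_1d(data.frame(d = dd, U = U), T = 300,
                               n = 100000, seed = 13)
pr <- pmf_from_counts(samples, bin_width = 0.1, d_ref = 4.0, T = 300)
truth <- 1.5 * ((pr$d - 5)^2 - 1)^2 - 1.5 * ((4.0 - 5)^2 - 1)^2
tab <- data.frame(d = pr$d, n = pr$n, pmf = pr$pmf, true = truth,
                  error = pr$pmf - truth)
write.csv(tab, file.path(out_dir, "doublewell_pmf.csv"),
          row.names = FALSE, quote = FALSE)
ok <- !is.na(tab$error)
cat(sprintf("double well: %d occupied bins, max |error| %.3f kcal/mol (rms %.3f)\n",
            sum(ok), max(abs(tab$error[ok])),
            sqrt(mean(tab$error[ok]^2))))

# demonstration: the rigid salt-bridge total Coulomb profile as U(d),
# restricted to the Coulomb-bond region d >= 3.9 A.  Without a van der
# Waals wall the rigid profile deepens without bound at shorter d, which
# would soak up all Boltzmann weight; on the restricted range the bond well
# (~ -5 kcal/mol near 3.9 A) is marginal enough that the d = 10 A
# reference state is sampled, the situation the count-based estimator is
# designed for.
prof <- distance_scan(salt_bridge_builder(), seq(3.9, 10, by = 0.05),
                      gb_config(born_mode = "obc2"))
pot <- data.frame(d = prof$d, U = prof$coulomb_total)
s2 <- sample_boltzmann_1d(pot, T = 300, n = 200000, seed = 29)
pr2 <- pmf_from_counts(s2, bin_width = 0.1, d_ref = 10, T = 300)
write.csv(as.data.frame(pr2)[, c("d", "n", "pmf")],
          file.path(out_dir, "saltbridge_pmf.csv"),
          row.names = FALSE, quote = FALSE)
m <- locate_minimum(pr2, "pmf")
cat(sprintf("salt-bridge GB potential: PMF minimum at d = %.2f A, %.2f kcal/mol vs d_ref = 10 A\n",
            m$d_min, m$value))
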