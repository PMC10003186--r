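#' Construct a profile table
#'
#' A profile table holds energies (and, for histogram-derived profiles,
#' sample counts) along the separation coordinate d.  It is a plain
#' data.frame whose first column is `d` (strictly increasing), with scan
#' metadata (config, overrides, rmax, temperature, reference bin) attached
#' as attributes so CSV export can round-trip it.
#'
#' @param df A data.frame with a strictly increasing numeric `d` column.
#' @param meta Named list of metadata (e.g. `overrides`, `rmax`,
#'   `temperature`, `d_ref`, `N_ref`).
#' @return An object of class `profile_table`.
#' @export
profile_table <- function(df, meta = list()) {
  stopifnot(is.data.frame(df), "d" %in% names(df))
  if (is.unsorted(df$d, strictly = TRUE)) {
    stop("profile coordinate d must be strictly increasing")
  }
  if ("n" %in% names(df) && any(df$n < 0, na.rm = TRUE)) {
    stop("bin counts must be non-negative")
  }
  structure(df, class = c("profile_table", "data.frame"), meta = meta)
}

#' Metadata of a profile table
#' @param profile A `profile_table`.
#' @return Named list.
#' @export
profile_meta <- function(profile) attr(profile, "meta")

#' Distance scan of a two-molecule builder
#'
#' Evaluates the full energy breakdown on a grid of separation values.  The
#' builder is a function `d -> mol_system`; radius overrides in `config` are
#' applied to every built system, so the same builder serves every point of
#' a parameter scan.
#'
#' @param builder Function taking a separation d (Angstrom) and returning a
#'   `mol_system`.
#' @param d_grid Numeric vector of separations, Angstrom (strictly
#'   increasing).
#' @param config A [gb_config()].
#' @param lj If TRUE, include the Lennard-Jones and total-energy columns.
#' @return A `profile_table` with one row per d: per-atom desolvation
#'   columns `dGself_<atom_id>`, `dGself_total`, `E_vac_int`, `G_gb_int`,
#'   `G_int`, `coulomb_total`, and (when `lj`) `E_lj`, `E_total`.
#' @export
distance_scan <- function(builder, d_grid, config = gb_config(),
                          lj = FALSE) {
  stopifnot(is.function(builder), length(d_grid) >= 1L)
  rows <- vector("list", length(d_grid))
  for (k in seq_along(d_grid)) {
    d <- d_grid[k]
    sys <- tryCatch(builder(d), error = function(e) {
      stop(sprintf("builder failed at d = %g: %s", d, conditionMessage(e)))
    })
    bd <- energy_breakdown(sys, config, lj = lj)
    row <- c(d = d,
             stats::setNames(unname(bd$dG_self_per_atom),
                             paste0("dGself_", names(bd$dG_self_per_atom))),
             dGself_total = bd$dG_self_total,
             E_vac_int = bd$E_vac_int, G_gb_int = bd$G_gb_int,
             G_int = bd$G_int, coulomb_total = bd$coulomb_total)
    if (lj) row <- c(row, E_lj = bd$E_lj, E_total = bd$E_total)
    rows[[k]] <- row
  }
  df <- as.data.frame(do.call(rbind, rows))
  profile_table(df, meta = list(
    overrides = config$radius_overrides, rmax = config$rmax,
    epsilon_w = config$epsilon_w, born_mode = config$born_mode,
    temperature = config$temperature))
}

#' Cartesian parameter scan over intrinsic radii and rmax
#'
#' Runs [distance_scan()] (for a builder) or [ensemble_binned_profile()]
#' (for a snapshot ensemble) at every combination of the per-class radius
#' values and every rmax, returning one labeled profile per setting.
#'
#' @param x Either a builder function `d -> mol_system` or an ensemble (list
#'   of `list(system =, d =)` entries).
#' @param rho_values Named list mapping class label to a vector of intrinsic
#'   radii (Angstrom) to scan; NULL scans only rmax.
#' @param rmax_values Numeric vector of outer cutoffs (Angstrom).
#' @param config Base [gb_config()]; its overrides are extended by the scan
#'   settings.
#' @param d_grid Separation grid (builder case).
#' @param bin_edges Bin edges (ensemble case).
#' @param lj Passed to [distance_scan()].
#' @return A named list of `profile_table`s; each name encodes the setting
#'   (e.g. `"rhoH-on-N=1.2_rmax=999"`), and each profile's metadata carries
#'   the exact override mapping used.
#' @export
parameter_scan <- function(x, rho_values = NULL, rmax_values = NULL,
                           config = gb_config(), d_grid = NULL,
                           bin_edges = NULL, lj = FALSE) {
  if (is.null(rmax_values)) rmax_values <- config$rmax
  stopifnot(length(rmax_values) >= 1L)
  if (!is.null(rho_values)) {
    stopifnot(length(rho_values) >= 1L, !is.null(names(rho_values)),
              all(nzchar(names(rho_values))))
    grid <- expand.grid(rho_values, KEEP.OUT.ATTRS = FALSE)
  } else {
    grid <- data.frame(row.names = 1)  # single empty setting
  }
  out <- list()
  for (g in seq_len(nrow(grid))) {
    ov <- config$radius_overrides
    if (ncol(grid) > 0L) {
      setting <- stats::setNames(as.numeric(grid[g, ]), names(grid))
      ov <- c(setting, ov[setdiff(names(ov), names(setting))])
    }
    for (rmax in rmax_values) {
      cfg <- config
      cfg$rmax <- rmax
      cfg$radius_overrides <- ov
      label <- paste0(
        if (length(ov) > 0L)
          paste(sprintf("rho%s=%g", names(ov), ov), collapse = "_")
        else "base",
        "_rmax=", format(rmax))
      prof <- if (is.function(x)) {
        distance_scan(x, d_grid, cfg, lj = lj)
      } else {
        ensemble_binned_profile(x, bin_edges, cfg)
      }
      out[[label]] <- prof
    }
  }
  out
}

#' Bin-averaged energies of a conformer ensemble
#'
#' Averages each energy quantity over the snapshots whose reaction
#' coordinate d falls in each half-open bin `[lo, hi)`.  Empty bins are kept
#' and flagged (`n = 0`, energies NA) rather than silently dropped.
#'
#' @param ensemble List of snapshots, each `list(system = <mol_system>,
#'   d = <numeric>)`.
#' @param bin_edges Strictly increasing numeric vector of bin edges,
#'   Angstrom.
#' @param config A [gb_config()].
#' @return A `profile_table` with bin centers `d`, counts `n`, and mean
#'   `dGself_total`, `E_vac_int`, `G_gb_int`, `G_int`, `coulomb_total`
#'   columns, plus a logical `empty` flag.
#' @export
ensemble_binned_profile <- function(ensemble, bin_edges,
                                    config = gb_config()) {
  stopifnot(length(ensemble) >= 1L, length(bin_edges) >= 2L,
            !is.unsorted(bin_edges, strictly = TRUE))
  dvals <- vapply(ensemble, function(s) s$d, numeric(1))
  quantities <- c("dGself_total", "E_vac_int", "G_gb_int", "G_int",
                  "coulomb_total")
  vals <- matrix(NA_real_, nrow = length(ensemble),
                 ncol = length(quantities),
                 dimnames = list(NULL, quantities))
  for (k in seq_along(ensemble)) {
    bd <- energy_breakdown(ensemble[[k]]$system, config)
    vals[k, ] <- c(bd$dG_self_total, bd$E_vac_int, bd$G_gb_int, bd$G_int,
                   bd$coulomb_total)
  }
  bin <- findInterval(dvals, bin_edges, rightmost.closed = FALSE,
                      left.open = FALSE)
  nb <- length(bin_edges) - 1L
  centers <- (bin_edges[-1L] + bin_edges[-length(bin_edges)]) / 2
  df <- data.frame(d = centers, n = 0L)
  for (qn in quantities) df[[qn]] <- NA_real_
  for (b in seq_len(nb)) {
    sel <- bin == b
    df$n[b] <- sum(sel)
    if (any(sel)) {
      for (qn in quantities) df[[qn]][b] <- mean(vals[sel, qn])
    }
  }
  df$empty <- df$n == 0L
  if (any(df$empty)) {
    warning(sprintf("%d of %d bins contain no snapshot (flagged)",
                    sum(df$empty), nb))
  }
  profile_table(df, meta = list(
    overrides = config$radius_overrides, rmax = config$rmax,
    epsilon_w = config$epsilon_w, born_mode = config$born_mode,
    temperature = config$temperature, bin_edges = bin_edges))
}

#' Mean of a profile column over a d window
#'
#' Unweighted mean of an energy column over profile rows whose d lies in
#' `[lo, hi]`; for binned ensemble profiles the snapshot counts weight the
#' mean so the result equals the plain snapshot average over the window.
#'
#' @param profile A `profile_table`.
#' @param column Column name.
#' @param lo,hi Window limits, Angstrom (inclusive on bin centers).
#' @return Numeric scalar.
#' @export
window_mean <- function(profile, column, lo, hi) {
  stopifnot(column %in% names(profile))
  sel <- profile$d >= lo & profile$d <= hi & !is.na(profile[[column]])
  if (!any(sel)) {
    warning(sprintf("no profile rows in window [%g, %g]", lo, hi))
    return(NA_real_)
  }
  w <- if ("n" %in% names(profile)) profile$n[sel] else rep(1, sum(sel))
  sum(profile[[column]][sel] * w) / sum(w)
}

#' Potential of mean force from distance counts
#'
#' Histogram estimator `PMF(d) = -R T log(n(d) / N_ref)` with R the gas
#' constant, `n(d)` the number of samples falling within `d +/- bin_width/2`
#' and `N_ref` the count in the reference bin centered at `d_ref`.  Bins are
#' half-open `[lo, hi)` and laid out so that `d_ref` is exactly a bin
#' center; the PMF is zero there by construction.  Empty bins are reported
#' as NA (undefined), never as a substituted infinity.
#'
#' @param d_samples Numeric vector of separation samples, Angstrom.
#' @param bin_width Bin width, Angstrom (> 0); the conventional `+/- 0.05 A`
#'   counting window corresponds to the default 0.1.
#' @param d_ref Reference separation, Angstrom; its bin must be occupied.
#' @param T Temperature, Kelvin.
#' @return A `profile_table` with bin centers `d`, counts `n`, `pmf`
#'   (kcal/mol) and an `empty` flag; metadata records `d_ref`, `N_ref`, `T`.
#' @export
pmf_from_counts <- function(d_samples, bin_width = 0.1, d_ref = 10,
                            T = 300) {
  stopifnot(bin_width > 0, length(d_samples) >= 1L, T > 0)
  # lay the bin grid so that d_ref is exactly a bin center, even when it
  # falls outside the sampled range (the reference bin is then empty, which
  # is an error, not a silently relocated reference)
  k_lo <- min(floor((min(d_samples) - d_ref) / bin_width - 0.5), 0)
  k_hi <- max(ceiling((max(d_samples) - d_ref) / bin_width + 0.5), 0)
  centers <- d_ref + (k_lo:k_hi) * bin_width
  edges <- c(centers - bin_width / 2, centers[length(centers)] +
               bin_width / 2)
  counts <- tabulate(findInterval(d_samples, edges,
                                  rightmost.closed = FALSE,
                                  left.open = FALSE),
                     nbins = length(centers))
  iref <- which.min(abs(centers - d_ref))
  N_ref <- counts[iref]
  if (N_ref < 1L) stop(sprintf("reference bin at d_ref = %g is empty",
                               d_ref))
  keep <- seq(min(which(counts > 0)), max(which(counts > 0)))
  centers <- centers[keep]
  counts <- counts[keep]
  pmf <- ifelse(counts > 0, -.R_kcal * T * log(counts / N_ref), NA_real_)
  df <- data.frame(d = centers, n = counts, pmf = pmf,
                   empty = counts == 0L)
  profile_table(df, meta = list(d_ref = d_ref, N_ref = N_ref,
                                temperature = T, bin_width = bin_width))
}

#' Locate the minimum of a profile column
#'
#' Grid argmin refined by quadratic interpolation through the bracketing
#' triple of points (the refinement recovers sub-grid minima of smooth
#' curves exactly for a parabola).  Ties break toward smaller d.  A minimum
#' on the first or last grid point is returned unrefined with
#' `boundary = TRUE`.
#'
#' @param profile A `profile_table` with at least 3 rows.
#' @param column Column to minimize.
#' @return A list with `d_min` (Angstrom), `value` (column units) and
#'   `boundary` (logical flag).
#' @export
locate_minimum <- function(profile, column) {
  stopifnot(column %in% names(profile), nrow(profile) >= 3L)
  y <- profile[[column]]
  d <- profile$d
  ok <- !is.na(y)
  y <- y[ok]; d <- d[ok]
  if (length(y) < 3L) stop("need >= 3 non-missing values")
  k <- which.min(y)  # which.min takes the first (smallest-d) tie
  if (k == 1L || k == length(y)) {
    return(list(d_min = d[k], value = y[k], boundary = TRUE))
  }
  x0 <- d[k - 1L]; x1 <- d[k]; x2 <- d[k + 1L]
  y0 <- y[k - 1L]; y1 <- y[k]; y2 <- y[k + 1L]
  denom <- (x0 - x1) * (x0 - x2) * (x1 - x2)
  A <- (x2 * (y1 - y0) + x1 * (y0 - y2) + x0 * (y2 - y1)) / denom
  B <- (x2^2 * (y0 - y1) + x1^2 * (y2 - y0) + x0^2 * (y1 - y2)) / denom
  if (A <= 0) {  # degenerate (flat or concave) triple: keep the grid point
    return(list(d_min = x1, value = y1, boundary = FALSE))
  }
  dmin <- -B / (2 * A)
  C <- y1 - A * x1^2 - B * x1
  list(d_min = dmin, value = A * dmin^2 + B * dmin + C, boundary = FALSE)
}

#' Barrier height of a profile column
#'
#' Height of the highest point of the column above the far-field plateau,
#' taken as the value at the largest separation in the profile.  Zero when
#' the profile is monotone non-increasing toward contact from the plateau.
#'
#' @param profile A `profile_table`.
#' @param column Column name (default `"coulomb_total"`).
#' @return A list with `height` (column units, >= 0), `d_peak` (Angstrom)
#'   and `baseline`.
#' @export
barrier_height <- function(profile, column = "coulomb_total") {
  stopifnot(column %in% names(profile))
  y <- profile[[column]]
  ok <- !is.na(y)
  y <- y[ok]; d <- profile$d[ok]
  baseline <- y[length(y)]
  k <- which.max(y)
  list(height = max(0, y[k] - baseline), d_peak = d[k], baseline = baseline)
}
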