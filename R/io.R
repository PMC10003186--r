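## Rule table mapping (atom name, residue name) to a parameterization
## class.  Documented heuristics for the whitespace PQR dialect, which
## carries no bonding information:
##   - residue BEA            -> "bead" (toy cluster beads keep their class
##     via the patch atom names below)
##   - H names H, HN, HH*, HE*, HZ*, HD/HE on Arg/Lys/His side chains
##     -> "H-on-N" (hydrogens covalently bonded to nitrogen)
##   - other H*               -> "H"
##   - O names OE1/OE2/OD1/OD2/OXT -> "O-carboxyl"; other O* -> "O"
##   - N*/C*/S*               -> element classes
classify_atom <- function(elety, resid) {
  elety <- toupper(trimws(elety)); resid <- toupper(trimws(resid))
  if (resid == "BEA") {
    return(switch(substr(elety, 1L, 1L), P = "H-on-N", Q = "O-carboxyl",
                  "bead"))
  }
  first <- substr(elety, 1L, 1L)
  if (first == "H") {
    if (elety %in% c("H", "HN") ||
        substr(elety, 1L, 2L) %in% c("HH", "HE", "HZ")) return("H-on-N")
    return("H")
  }
  if (first == "O") {
    if (elety %in% c("OE1", "OE2", "OD1", "OD2", "OXT")) {
      return("O-carboxyl")
    }
    return("O")
  }
  if (first %in% c("N", "C", "S")) return(first)
  first
}

#' Read a PQR file
#'
#' Parses the whitespace-separated PQR dialect: `ATOM`/`HETATM` records
#' whose trailing fields are x, y, z (Angstrom), charge (e) and radius
#' (Angstrom), with an optional chain identifier.  Molecule tags come from
#' the chain field when at least two distinct chains are present, otherwise
#' from sequential `TER`-separated groups.  Class labels are assigned from
#' the atom and residue names by a documented rule table (guanidinium /
#' amine hydrogens to `"H-on-N"`, carboxylate oxygens to `"O-carboxyl"`,
#' elements otherwise).
#'
#' @param path Path to a PQR file.
#' @return A `mol_system`.
#' @examples
#' sys <- read_pqr(system.file("extdata", "ho_pair.pqr",
#'                             package = "gbintrad"))
#' born_radii(sys, gb_config())
#' @export
read_pqr <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  rec <- grepl("^(ATOM|HETATM)", lines)
  if (!any(rec)) stop("no ATOM/HETATM records in ", path)
  ter_group <- cumsum(grepl("^TER", lines)) + 1L

  ids <- character(0); elety <- character(0); resid <- character(0)
  chain <- character(0); grp <- integer(0)
  xyzqr <- matrix(NA_real_, nrow = sum(rec), ncol = 5)
  k <- 0L
  for (ln in which(rec)) {
    k <- k + 1L
    tok <- strsplit(trimws(lines[ln]), "\\s+")[[1L]]
    if (length(tok) < 10L) {
      stop(sprintf("line %d: expected >= 10 whitespace-separated fields %s",
                   ln, "(missing charge/radius columns?)"))
    }
    num <- suppressWarnings(as.numeric(tok[(length(tok) - 4L):length(tok)]))
    if (any(is.na(num))) {
      stop(sprintf("line %d: non-numeric coordinate/charge/radius field",
                   ln))
    }
    xyzqr[k, ] <- num
    elety <- c(elety, tok[3L])
    resid <- c(resid, tok[4L])
    chain <- c(chain, if (length(tok) >= 11L) tok[5L] else "")
    grp <- c(grp, ter_group[ln])
    ids <- c(ids, tok[3L])
  }
  if (any(xyzqr[, 5L] <= 0)) stop("non-positive radius in ", path)
  tags <- if (length(unique(chain[nzchar(chain)])) >= 2L) chain else
    paste0("m", grp)
  if (anyDuplicated(ids)) ids <- paste0(ids, ".", seq_along(ids))
  atoms <- data.frame(
    atom_id = ids,
    class_label = mapply(classify_atom, elety, resid, USE.NAMES = FALSE),
    x = xyzqr[, 1L], y = xyzqr[, 2L], z = xyzqr[, 3L],
    charge = xyzqr[, 4L], intrinsic_radius = xyzqr[, 5L],
    molecule_tag = tags,
    stringsAsFactors = FALSE)
  mol_system(atoms)
}

#' Write a system as PQR
#'
#' Whitespace-separated PQR with 4-decimal coordinates and charges, one
#' chain letter per molecule tag, and `TER` records between molecules (so
#' tag structure survives a round trip even without chain support in the
#' consumer).
#'
#' @param sys A `mol_system`.
#' @param path Output path.
#' @param resid Residue name to stamp on every record (default `"MOL"`;
#'   the synthetic builders use `ARG`/`GLU`/`BEA` so class labels survive
#'   re-import).
#' @return `path`, invisibly.
#' @export
write_pqr <- function(sys, path, resid = NULL) {
  stopifnot(inherits(sys, "mol_system"))
  a <- sys$atoms
  tags <- unique(a$molecule_tag)
  chain_of <- stats::setNames(LETTERS[seq_along(tags)], tags)
  if (is.null(resid)) {
    resid <- c(arg = "ARG", glu = "GLU", A = "BEA", B = "BEA")[a$molecule_tag]
    resid[is.na(resid)] <- "MOL"
  } else {
    resid <- rep_len(resid, nrow(a))
  }
  con <- file(path, "w")
  on.exit(close(con))
  for (t in tags) {
    sel <- which(a$molecule_tag == t)
    for (i in sel) {
      writeLines(sprintf(
        "ATOM %6d %-4s %-4s %s %4d %10.4f %10.4f %10.4f %8.4f %7.4f",
        i, substr(a$atom_id[i], 1L, 4L), resid[i], chain_of[t],
        match(t, tags), a$x[i], a$y[i], a$z[i], a$charge[i],
        a$intrinsic_radius[i]), con)
    }
    writeLines("TER", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Write a snapshot ensemble as PQR files plus a manifest
#'
#' One PQR per snapshot (`<prefix>_0001.pqr`, ...) and a JSON manifest
#' mapping each file to its reaction-coordinate value, plus the seed and
#' generation parameters when an [ensemble_spec()] is supplied.
#'
#' @param ensemble List of `list(system =, d =)` snapshots.
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix.
#' @param spec Optional [ensemble_spec()] echoed into the manifest.
#' @return Invisibly, the manifest path.
#' @export
write_ensemble_pqr <- function(ensemble, dir, prefix = "snapshot",
                               spec = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(length(ensemble))
  for (k in seq_along(ensemble)) {
    files[k] <- sprintf("%s_%04d.pqr", prefix, k)
    write_pqr(ensemble[[k]]$system, file.path(dir, files[k]))
  }
  manifest <- list(
    files = files,
    d = vapply(ensemble, function(s) s$d, numeric(1)),
    spec = if (is.null(spec)) NULL else unclass(spec))
  mpath <- file.path(dir, paste0(prefix, "_manifest.json"))
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(mpath)
}

#' Write a profile table as CSV with a metadata header
#'
#' The header is a block of `# key: value` lines (JSON-encoded values)
#' followed by an ordinary CSV body, so the file round-trips through
#' [read_profile_csv()] and remains readable by any CSV tool that skips
#' comment lines.
#'
#' @param profile A `profile_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_profile_csv <- function(profile, path) {
  stopifnot(inherits(profile, "profile_table"))
  meta <- profile_meta(profile)
  con <- file(path, "w")
  on.exit(close(con))
  for (key in names(meta)) {
    val <- meta[[key]]
    if (is.null(val)) next
    # named atomic vectors (e.g. radius overrides) survive as JSON objects
    if (is.atomic(val) && !is.null(names(val))) val <- as.list(val)
    writeLines(sprintf("# %s: %s", key,
                       jsonlite::toJSON(val, auto_unbox = TRUE,
                                        digits = NA)), con)
  }
  utils::write.csv(as.data.frame(profile), con, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Read a profile table written by [write_profile_csv()]
#'
#' @param path Path to the CSV.
#' @return A `profile_table` with restored metadata.
#' @export
read_profile_csv <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- grep("^# ", lines, value = TRUE)
  meta <- list()
  for (h in hdr) {
    m <- regmatches(h, regexec("^# ([^:]+): (.*)$", h))[[1L]]
    if (length(m) == 3L) {
      val <- tryCatch(jsonlite::fromJSON(m[3L], simplifyVector = TRUE),
                      error = function(e) m[3L])
      if (is.list(val) && length(val) > 0 &&
          all(vapply(val, function(x) is.numeric(x) && length(x) == 1L,
                     TRUE))) {
        val <- unlist(val)
      }
      meta[[m[2L]]] <- val
    }
  }
  df <- utils::read.csv(textConnection(lines[!grepl("^# ", lines)]))
  profile_table(df, meta = meta)
}

#' Write a set of scan profiles plus a JSON summary
#'
#' One CSV per profile (file names embed the setting labels produced by
#' [parameter_scan()]) and a `summary.json` echoing the configuration and
#' listing the files, so a persisted run re-executes to identical outputs.
#'
#' @param profiles Named list of `profile_table`s (or an empty list, in
#'   which case only the summary is written).
#' @param out_dir Output directory (created if needed).
#' @param config Optional [gb_config()] echoed into the summary.
#' @return Invisibly, the summary path.
#' @export
write_results <- function(profiles, out_dir, config = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (length(profiles) > 0L && is.null(names(profiles))) {
    names(profiles) <- sprintf("profile_%03d", seq_along(profiles))
  }
  files <- character(0)
  for (nm in names(profiles)) {
    fn <- paste0(gsub("[^A-Za-z0-9_.=-]+", "-", nm), ".csv")
    write_profile_csv(profiles[[nm]], file.path(out_dir, fn))
    files <- c(files, fn)
  }
  summary_path <- file.path(out_dir, "summary.json")
  jsonlite::write_json(
    list(files = as.list(files),
         config = if (is.null(config)) NULL else unclass(config)),
    summary_path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(summary_path)
}
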