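# The dihedral_trajectory container and its delimited-text round trip.

#' Dihedral trajectory container
#'
#' Per-frame, per-site dihedral angle series with per-frame boost energies.
#' Angles are stored in degrees, wrapped to (-180, 180]. This is the
#' universal input to the reweighting and classification stages.
#'
#' @param omega Numeric matrix (frames x sites) of peptide-bond dihedrals in
#'   degrees; a vector is treated as a single site. Column names label sites.
#' @param dt_ps Time step between consecutive frames, in picoseconds.
#' @param deltaV Per-frame total boost energy in kcal/mol (default all zero).
#' @param phi,psi,chi2 Optional matrices of backbone/side-chain dihedrals with
#'   the same dimensions as \code{omega}.
#' @param temperature Temperature in Kelvin.
#' @param replicate Replicate label (character or integer).
#' @return An object of class \code{dihedral_trajectory}.
#' @export
dihedral_trajectory <- function(omega, dt_ps = 0.1, deltaV = NULL,
                                phi = NULL, psi = NULL, chi2 = NULL,
                                temperature = 300, replicate = "r1") {
  as_sites <- function(x, nm) {
    if (is.null(x)) return(NULL)
    if (is.vector(x)) x <- matrix(x, ncol = 1)
    if (is.null(colnames(x))) {
      colnames(x) <- paste0("site", seq_len(ncol(x)))
    }
    if (any(!is.finite(x))) stop("non-finite values in '", nm, "'")
    matrix(wrap_angle(x), nrow = nrow(x), ncol = ncol(x),
           dimnames = dimnames(x))
  }
  omega <- as_sites(omega, "omega")
  phi <- as_sites(phi, "phi"); psi <- as_sites(psi, "psi")
  chi2 <- as_sites(chi2, "chi2")
  nf <- nrow(omega)
  if (is.null(deltaV)) deltaV <- numeric(nf)
  if (length(deltaV) != nf) stop("'deltaV' length must equal the frame count")
  if (any(!is.finite(deltaV)) || any(deltaV < -1e-12)) {
    stop("'deltaV' must be finite and >= 0")
  }
  deltaV <- pmax(deltaV, 0)
  for (ch in list(phi, psi, chi2)) {
    if (!is.null(ch) && !identical(dim(ch), dim(omega))) {
      stop("all angle channels must share the dimensions of 'omega'")
    }
  }
  if (!is.finite(dt_ps) || dt_ps <= 0) stop("'dt_ps' must be > 0")
  structure(list(omega = omega, phi = phi, psi = psi, chi2 = chi2,
                 deltaV = deltaV, dt_ps = dt_ps, temperature = temperature,
                 replicate = as.character(replicate)),
            class = "dihedral_trajectory")
}

#' @export
print.dihedral_trajectory <- function(x, ...) {
  cat(sprintf(
    "Dihedral trajectory: %d frames x %d site(s), dt = %g ps, T = %g K (%s)\n",
    nrow(x$omega), ncol(x$omega), x$dt_ps, x$temperature, x$replicate))
  cat("  channels:", paste(c("omega", "phi", "psi", "chi2")[
    !vapply(list(x$omega, x$phi, x$psi, x$chi2), is.null, logical(1))],
    collapse = ", "), "\n")
  cat(sprintf("  deltaV: mean %.3f, max %.3f kcal/mol\n",
              mean(x$deltaV), max(x$deltaV)))
  invisible(x)
}

#' Number of frames / sites
#' @param x A \code{dihedral_trajectory}.
#' @return Integer count.
#' @export
n_frames <- function(x) nrow(x$omega)

#' @rdname n_frames
#' @export
n_sites <- function(x) ncol(x$omega)

#' Site labels of a trajectory
#' @param x A \code{dihedral_trajectory}.
#' @return Character vector of site names.
#' @export
site_names <- function(x) colnames(x$omega)

# autodetect comma vs tab from the first non-comment line
detect_sep <- function(path) {
  if (!file.exists(path)) stop("file not found: '", path, "'")
  ln <- readLines(path, n = 50L, warn = FALSE)
  ln <- ln[!startsWith(trimws(ln), "#") & nzchar(trimws(ln))]
  if (length(ln) == 0) stop("no data lines in '", path, "'")
  if (lengths(regmatches(ln[1], gregexpr("\t", ln[1]))) > 0) "\t" else ","
}

#' Write a trajectory to delimited text
#'
#' One row per frame with columns \code{frame}, \code{time_ps},
#' \code{omega_<site>} (and \code{phi_}/\code{psi_}/\code{chi2_} where
#' present) and \code{deltaV_kcal_mol}. Metadata (time step, temperature,
#' replicate) goes into \code{#}-prefixed header comments so the table
#' round-trips through \code{\link{read_trajectory}}.
#'
#' @param traj A \code{\link{dihedral_trajectory}}.
#' @param path Output file path.
#' @param sep Field separator, \code{","} (default) or \code{"\t"}.
#' @return \code{path}, invisibly.
#' @export
write_trajectory <- function(traj, path, sep = ",") {
  stopifnot(inherits(traj, "dihedral_trajectory"))
  nf <- n_frames(traj)
  df <- data.frame(frame = seq_len(nf) - 1L,
                   time_ps = (seq_len(nf) - 1L) * traj$dt_ps)
  for (ch in c("omega", "phi", "psi", "chi2")) {
    m <- traj[[ch]]
    if (!is.null(m)) {
      cn <- paste0(ch, "_", colnames(m))
      df[cn] <- as.data.frame(m)
    }
  }
  df$deltaV_kcal_mol <- traj$deltaV
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# dt_ps=%.17g", traj$dt_ps),
               sprintf("# temperature_K=%.17g", traj$temperature),
               sprintf("# replicate=%s", traj$replicate)), con)
  utils::write.table(format(df, digits = 17, trim = TRUE, scientific = FALSE),
                     con, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a trajectory from delimited text
#'
#' Accepts comma- or tab-separated tables (autodetected) with a mandatory
#' header row; \code{#} comment lines are ignored except for the metadata
#' comments written by \code{\link{write_trajectory}}, which are honoured
#' when present. Angles are wrapped into (-180, 180].
#'
#' @param path Input file path.
#' @param dt_ps Time step override; if \code{NA} (default) it is taken from a
#'   metadata comment or inferred from the \code{time_ps} column.
#' @param temperature,replicate Overrides for metadata not stored in the file.
#' @return A \code{\link{dihedral_trajectory}}.
#' @export
read_trajectory <- function(path, dt_ps = NA, temperature = NA,
                            replicate = NA) {
  sep <- detect_sep(path)
  meta <- grep("^#", readLines(path, warn = FALSE), value = TRUE)
  meta_val <- function(key) {
    hit <- grep(paste0("^#\\s*", key, "="), meta, value = TRUE)
    if (length(hit)) sub(paste0("^#\\s*", key, "="), "", hit[1]) else NA
  }
  df <- utils::read.table(path, header = TRUE, sep = sep, comment.char = "#",
                          check.names = FALSE, stringsAsFactors = FALSE)
  req <- c("frame", "time_ps")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("missing required column(s): ",
                         paste(miss, collapse = ", "))
  chan <- function(prefix) {
    cn <- grep(paste0("^", prefix, "_"), names(df), value = TRUE)
    if (!length(cn)) return(NULL)
    m <- as.matrix(df[cn])
    colnames(m) <- sub(paste0("^", prefix, "_"), "", cn)
    m
  }
  om <- chan("omega")
  if (is.null(om)) stop("no omega_<site> columns found")
  if (is.na(dt_ps)) {
    dt_ps <- suppressWarnings(as.numeric(meta_val("dt_ps")))
    if (is.na(dt_ps)) {
      dt_ps <- if (nrow(df) > 1) stats::median(diff(df$time_ps)) else 1
    }
  }
  if (is.na(temperature)) {
    temperature <- suppressWarnings(as.numeric(meta_val("temperature_K")))
    if (is.na(temperature)) temperature <- 300
  }
  if (is.na(replicate)) {
    replicate <- meta_val("replicate")
    if (is.na(replicate)) replicate <- "r1"
  }
  dv <- if ("deltaV_kcal_mol" %in% names(df)) df$deltaV_kcal_mol else NULL
  dihedral_trajectory(om, dt_ps = dt_ps, deltaV = dv,
                      phi = chan("phi"), psi = chan("psi"),
                      chi2 = chan("chi2"),
                      temperature = temperature, replicate = replicate)
}
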