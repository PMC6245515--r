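# Restraint construction: flat-bottom torsion wells from predicted angles,
# two-sigmoid pairwise potentials, and contact wells from ranked pairs.

#' Flat-bottom torsion restraints from predicted angles
#'
#' Per residue, builds circular ranges `[pred - delta, pred + delta]` for phi
#' and psi. Inside the range the penalty is zero; outside it grows as
#' `k_tor * excess^2`, where `excess` is the minimal circular distance to the
#' range edge in degrees.
#'
#' @param pred a `torsion_prediction` (or data.frame with `phi`, `psi`
#'   columns in degrees).
#' @param delta half-width of the flat bottom in degrees (default 20).
#' @param k_tor wall stiffness in energy / degree^2 (default 0.05).
#' @return object of class `torsion_restraints`: data.frame with columns
#'   `phi_center`, `psi_center`, `phi_lo`, `phi_hi`, `psi_lo`, `psi_hi`;
#'   attributes `delta`, `k_tor`.
#' @export
torsion_ranges <- function(pred, delta = 20, k_tor = 0.05) {
  stopifnot(delta > 0, k_tor >= 0)
  phi <- wrap_angle(pred$phi)
  psi <- wrap_angle(pred$psi)
  out <- data.frame(phi_center = phi, psi_center = psi,
                    phi_lo = wrap_angle(phi - delta),
                    phi_hi = wrap_angle(phi + delta),
                    psi_lo = wrap_angle(psi - delta),
                    psi_hi = wrap_angle(psi + delta))
  structure(out, delta = delta, k_tor = k_tor,
            class = c("torsion_restraints", "data.frame"))
}

#' Flat-bottom torsion penalty
#'
#' @param angle angle(s) in degrees.
#' @param center well center in degrees.
#' @param delta flat-bottom half-width in degrees.
#' @param k_tor stiffness (energy / degree^2).
#' @return penalty energy, vectorized over `angle`.
#' @export
torsion_penalty <- function(angle, center, delta = 20, k_tor = 0.05) {
  excess <- abs(wrap_angle(angle - center)) - delta
  k_tor * pmax(excess, 0)^2
}

#' Two-sigmoid pairwise potential
#'
#' \deqn{V(r) = e_{in}/(1 + \exp((r - r_{in})/w_{in})) +
#'       e_{out}/(1 + \exp((r - r_{out})/w_{out}))}
#' A repulsive inner term (`e_in > 0`) plus an attractive outer term
#' (`e_out < 0`) gives a soft excluded volume with a contact well between
#' `r_in` and `r_out`; the potential vanishes as `r` grows.
#'
#' @param r distance(s) in Angstrom.
#' @param e_in,r_in,w_in inner term height, midpoint, width.
#' @param e_out,r_out,w_out outer term depth, midpoint, width.
#' @return energy, vectorized over `r`.
#' @export
two_sigmoid_potential <- function(r, e_in, r_in, w_in, e_out, r_out, w_out) {
  stopifnot(w_in > 0, w_out > 0, r_in > 0, r_out > 0, all(r >= 0))
  sig <- function(e, x) {
    x <- pmin(pmax(x, -40), 40)
    e / (1 + exp(x))
  }
  sig(e_in, (r - r_in) / w_in) + sig(e_out, (r - r_out) / w_out)
}

#' Contact restraint well
#'
#' Single stabilizing sigmoid well for an inferred contact: strongly negative
#' below the contact radius, vanishing above it.
#' \deqn{V(r) = -depth / (1 + \exp((r - r_c)/width))}
#'
#' @param r Cbeta-Cbeta distance(s), Angstrom.
#' @param r_c contact radius (default 7.5 Angstrom).
#' @param depth well depth, > 0 (default 2).
#' @param width switching width in Angstrom (default 0.5).
#' @return energy, vectorized over `r`.
#' @export
contact_restraint_potential <- function(r, r_c = 7.5, depth = 2, width = 0.5) {
  stopifnot(depth > 0, width > 0, all(r >= 0))
  x <- pmin(pmax((r - r_c) / width, -40), 40)
  -depth / (1 + exp(x))
}

#' Pairwise contact-energy table
#'
#' Loads the packaged 20 x 20 residue-pair attraction depths used as the
#' outer-term energies `e_out` of the side-chain potential. The packaged
#' table is a synthetic hydrophobicity-derived stand-in (Kyte-Doolittle
#' based, more hydrophobic pairs more attractive, with a Cys-Cys bonus); a
#' user-supplied table in the same TSV layout can be given instead.
#'
#' @param path optional TSV path (20 x 20, row/column names the amino-acid
#'   one-letter codes). Default: the packaged synthetic table.
#' @return named 20 x 20 numeric matrix.
#' @export
contact_energy_table <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "contact_energies_synthetic.tsv",
                        package = "defold", mustWork = TRUE)
  m <- as.matrix(read.table(path, sep = "\t", check.names = FALSE))
  stopifnot(nrow(m) == 20L, ncol(m) == 20L)
  if (max(abs(m - t(m))) > 1e-8) stop("contact-energy table must be symmetric")
  m
}

# default interaction profiles; side-chain and H-bond constants follow the
# coarse-grained force-field settings (r_in for side chains is the uniform
# contact-radius default, see vignette)
default_profiles <- function() {
  list(
    side_chain = c(e_in = 3, r_in = 6.0, w_in = 0.2, r_out = 6.5, w_out = 0.2),
    hbond = c(e_in = 6, r_in = 1.4, w_in = 0.1, e_out = -4, r_out = 2.5,
              w_out = 0.125),
    contact = c(r_c = 7.5, depth = 2.0, width = 0.5),
    # opaque simulator configuration constants, carried verbatim
    simulator_knobs = c(hbond_energy = -4.0, sc_radial_scale_energy = 0.2,
                     sc_radial_scale_inverse_radius = 0.65,
                     sc_radial_scale_inverse_energy = 3.0)
  )
}

#' Assemble a restraint bundle
#'
#' Combines per-residue torsion restraints with per-pair contact wells into
#' the single object the sampler consumes, together with the side-chain and
#' hydrogen-bond interaction profiles.
#'
#' @param pred torsion predictions (data.frame `phi`, `psi`, one row per
#'   residue), or `NULL` for a contact-only bundle.
#' @param contacts a `contact_set` (may have zero rows).
#' @param sequence the amino-acid sequence the bundle restrains.
#' @param delta torsion flat-bottom half-width, degrees (default 20).
#' @param k_tor torsion wall stiffness (default 0.05 energy/deg^2).
#' @param contact_depth,contact_width,contact_radius contact-well parameters
#'   (defaults 2.0, 0.5 Angstrom, 7.5 Angstrom).
#' @param energy_table 20 x 20 pair-attraction table (default: packaged
#'   synthetic table).
#' @return object of class `restraint_bundle`.
#' @export
restraint_bundle <- function(pred, contacts, sequence,
                             delta = 20, k_tor = 0.05,
                             contact_depth = 2.0, contact_width = 0.5,
                             contact_radius = 7.5,
                             energy_table = NULL) {
  L <- nchar(sequence)
  if (!is.null(pred)) {
    if (nrow(pred) != L)
      stop("validation error: torsion predictions (", nrow(pred),
           ") do not match sequence length (", L, ")")
    torsion <- torsion_ranges(pred, delta = delta, k_tor = k_tor)
  } else torsion <- NULL
  contacts <- as.data.frame(contacts)[, intersect(c("i", "j", "score"),
                                                  names(as.data.frame(contacts))),
                                      drop = FALSE]
  if (nrow(contacts) > 0 &&
      (max(contacts$j) > L || min(contacts$i) < 1L))
    stop("validation error: contact index out of range for sequence length ", L)
  if (is.null(energy_table)) energy_table <- contact_energy_table()
  profiles <- default_profiles()
  profiles$contact <- c(r_c = contact_radius, depth = contact_depth,
                        width = contact_width)
  structure(list(sequence = sequence, torsion = torsion, contacts = contacts,
                 profiles = profiles, energy_table = energy_table,
                 delta = delta, k_tor = k_tor),
            class = "restraint_bundle")
}

#' @export
print.restraint_bundle <- function(x, ...) {
  cat("Restraint bundle for", nchar(x$sequence), "residues:\n")
  cat("  torsion wells:", if (is.null(x$torsion)) 0 else nrow(x$torsion),
      "residues, half-width", x$delta, "deg, k =", x$k_tor, "\n")
  cat("  contact wells:", nrow(x$contacts), "pairs (depth",
      x$profiles$contact[["depth"]], ", r_c",
      x$profiles$contact[["r_c"]], "A)\n")
  invisible(x)
}

#' Serialize a restraint bundle to TSV sections
#'
#' Human-readable two-section format: a `# TORSION` section (residue,
#' phi/psi centers, half-width, stiffness) and a `# CONTACT` section
#' (i, j, radius, depth, width).
#'
#' @param bundle a `restraint_bundle`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bundle <- function(bundle, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# SEQUENCE\t", bundle$sequence), con)
  writeLines(paste0("# TORSION\tdelta=", bundle$delta, "\tk=", bundle$k_tor),
             con)
  if (!is.null(bundle$torsion)) {
    tor <- data.frame(residue = seq_len(nrow(bundle$torsion)),
                      phi = round(bundle$torsion$phi_center, 3),
                      psi = round(bundle$torsion$psi_center, 3))
    write.table(tor, con, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  pc <- bundle$profiles$contact
  writeLines(sprintf("# CONTACT\tr_c=%g\tdepth=%g\twidth=%g",
                     pc[["r_c"]], pc[["depth"]], pc[["width"]]), con)
  if (nrow(bundle$contacts) > 0)
    write.table(bundle$contacts, con, sep = "\t", quote = FALSE,
                row.names = FALSE)
  invisible(path)
}
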