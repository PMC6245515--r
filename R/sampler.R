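# Coarse-grained backbone conformations (N/CA/C per residue, torsion-space
# parameterization with ideal bond geometry) and the restrained Metropolis
# Monte Carlo sampler. Geometry and energy kernels live in src/sampler.cpp;
# these wrappers own validation, classes, and I/O.

KD_HYDROPATHY <- c(A = 1.8, C = 2.5, D = -3.5, E = -3.5, F = 2.8, G = -0.4,
                   H = -3.2, I = 4.5, K = -3.9, L = 3.8, M = 1.9, N = -3.5,
                   P = -1.6, Q = -3.5, R = -4.5, S = -0.8, T = -0.7, V = 4.2,
                   W = -0.9, Y = -1.3)

new_backbone <- function(sequence, phi, psi, coords) {
  structure(list(sequence = sequence, phi = phi, psi = psi,
                 N = coords$N, CA = coords$CA, C = coords$C),
            class = "backbone")
}

#' Extended starting conformation
#'
#' Builds an all-extended chain (phi = psi = 180 degrees) with ideal bond
#' lengths and angles and a trans peptide bond.
#'
#' @param sequence amino-acid sequence (20 one-letter codes), length >= 2.
#' @return object of class `backbone`: `sequence`, `phi`, `psi` (degrees),
#'   and `N`, `CA`, `C` coordinate matrices (L x 3, Angstrom).
#' @export
build_extended <- function(sequence) {
  aa <- strsplit(toupper(sequence), "")[[1]]
  if (length(aa) < 2L) stop("input error: sequence must have >= 2 residues")
  bad <- setdiff(aa, names(KD_HYDROPATHY))
  if (length(bad))
    stop("input error: invalid residue letter(s): ", paste(bad, collapse = ", "))
  L <- length(aa)
  phi <- rep(180, L); psi <- rep(180, L)
  coords <- cpp_build_backbone(phi, psi)
  new_backbone(paste(aa, collapse = ""), phi, psi, coords)
}

#' @export
print.backbone <- function(x, ...) {
  cat("Backbone conformation:", nchar(x$sequence), "residues (",
      3 * nchar(x$sequence), "backbone atoms )\n")
  cat("  sequence:", x$sequence, "\n")
  invisible(x)
}

#' Rebuild a conformation from torsions
#'
#' Sets (phi, psi) for every residue and rebuilds all coordinates by forward
#' kinematics; bond lengths and angles stay at their ideal values.
#'
#' @param conf a `backbone`.
#' @param phi,psi numeric vectors of angles in degrees, one per residue.
#' @return the rebuilt `backbone`.
#' @export
set_torsions <- function(conf, phi, psi) {
  L <- nchar(conf$sequence)
  stopifnot(length(phi) == L, length(psi) == L)
  phi <- wrap_angle(phi); psi <- wrap_angle(psi)
  coords <- cpp_build_backbone(phi, psi)
  new_backbone(conf$sequence, phi, psi, coords)
}

#' Measure backbone torsions from coordinates
#'
#' Dihedrals are computed from the stored N/CA/C coordinates; the two
#' terminal angles that have no flanking atoms (phi of residue 1, psi of the
#' last residue) are taken from the conformation's stored parameters.
#'
#' @param conf a `backbone`.
#' @return data.frame with columns `phi`, `psi` in degrees.
#' @export
measure_torsions <- function(conf) {
  L <- nrow(conf$CA)
  m <- cpp_measure_torsions(conf$N, conf$CA, conf$C)
  phi <- wrap_angle(m[seq_len(L)]); psi <- wrap_angle(m[L + seq_len(L)])
  phi[1] <- conf$phi[1]; psi[L] <- conf$psi[L]
  data.frame(phi = phi, psi = psi)
}

#' Derived atom positions
#'
#' Carbonyl O, amide H, and an idealized virtual Cbeta are derived from the
#' backbone coordinates (the same construction the energy kernel uses). The
#' virtual Cbeta is placed for every residue, glycine included, so that
#' contact and burial terms are defined uniformly.
#'
#' @param conf a `backbone`.
#' @return list of L x 3 matrices `O`, `H`, `CB` (H of residue 1 is
#'   undefined and set to zero).
#' @export
derived_atoms <- function(conf) {
  cpp_derive_atoms(conf$N, conf$CA, conf$C, conf$psi)
}

#' Burial count of a residue
#'
#' Smoothly counts side-chain (Cbeta) neighbors of residue `i` within ~8
#' Angstrom, weighted toward the hemisphere above the residue's own
#' Calpha-to-Cbeta axis; sequence neighbors with |i - j| <= 2 are excluded.
#' Each partner contributes
#' `S(d - 8, 1) * S(-cos(theta) + 0.1, 1)` with `S(x, w) = 1/(1 + exp(x/w))`.
#'
#' @param conf a `backbone`.
#' @param i residue index (or vector of indices; default all residues).
#' @return numeric burial count(s).
#' @export
environment_count <- function(conf, i = seq_len(nchar(conf$sequence))) {
  atoms <- derived_atoms(conf)
  cb <- atoms$CB; ca <- conf$CA
  L <- nrow(cb)
  s <- function(x) 1 / (1 + exp(pmin(pmax(x, -40), 40)))
  vapply(i, function(ii) {
    axis <- cb[ii, ] - ca[ii, ]
    axis <- axis / sqrt(sum(axis^2))
    total <- 0
    for (j in seq_len(L)) {
      if (abs(ii - j) <= 2L) next
      rij <- cb[j, ] - cb[ii, ]
      d <- sqrt(sum(rij^2))
      cosang <- if (d > 0) sum(rij / d * axis) else 0
      total <- total + s(d - 8) * s(-cosang + 0.1)
    }
    total
  }, numeric(1))
}

#' Per-residue burial weights
#'
#' Hydrophobicity-signed weights for the environment energy term: burial is
#' favorable (negative weight) for hydrophobic residues and unfavorable for
#' polar ones, with uniform magnitude.
#'
#' @param sequence amino-acid sequence.
#' @param magnitude weight magnitude (default 0.1); 0 disables the term.
#' @return numeric vector of length `nchar(sequence)`.
#' @export
env_weights <- function(sequence, magnitude = 0.1) {
  aa <- strsplit(sequence, "")[[1]]
  -magnitude * sign(KD_HYDROPATHY[aa])
}

# assemble the parameter list consumed by the C++ energy kernel
build_energy_params <- function(bundle, term_weights = c(torsion = 1,
                                                         pairwise = 1,
                                                         environment = 1,
                                                         contact = 1),
                                env_magnitude = 0.1, min_sep = 3L) {
  L <- nchar(bundle$sequence)
  aa <- strsplit(bundle$sequence, "")[[1]]
  if (is.null(bundle$torsion)) {
    tor_phi <- rep(NA_real_, L); tor_psi <- rep(NA_real_, L)
  } else {
    tor_phi <- bundle$torsion$phi_center
    tor_psi <- bundle$torsion$psi_center
  }
  sc <- bundle$profiles$side_chain
  et <- bundle$energy_table
  sc_e_out <- et[aa, aa, drop = FALSE]
  pc <- bundle$profiles$contact
  nc <- nrow(bundle$contacts)
  list(tor_phi = as.numeric(tor_phi), tor_psi = as.numeric(tor_psi),
       tor_delta = bundle$delta, tor_k = bundle$k_tor,
       sc_profile = as.numeric(sc[c("e_in", "r_in", "w_in", "r_out", "w_out")]),
       sc_e_out = unname(sc_e_out),
       hb_profile = as.numeric(bundle$profiles$hbond[
         c("e_in", "r_in", "w_in", "e_out", "r_out", "w_out")]),
       env_w = as.numeric(env_weights(bundle$sequence, env_magnitude)),
       con_i = as.integer(bundle$contacts$i[seq_len(nc)]),
       con_j = as.integer(bundle$contacts$j[seq_len(nc)]),
       con_depth = rep(pc[["depth"]], nc),
       con_width = rep(pc[["width"]], nc),
       con_rc = rep(pc[["r_c"]], nc),
       term_weights = as.numeric(term_weights[c("torsion", "pairwise",
                                                "environment", "contact")]),
       min_sep = as.integer(min_sep))
}

#' Restraint energy of a conformation
#'
#' Additive breakdown of the coarse-grained energy: flat-bottom torsion
#' wells, pairwise side-chain + backbone hydrogen-bond two-sigmoid terms,
#' linear burial (environment) term, and contact restraint wells. Distances
#' are computed from the conformation's stored coordinates, so the energy is
#' invariant under rigid motions.
#'
#' @param conf a `backbone`.
#' @param bundle a `restraint_bundle` for the same sequence.
#' @param term_weights named weights for `torsion`, `pairwise`,
#'   `environment`, `contact`; a zero weight removes exactly that component.
#' @param env_magnitude burial weight magnitude (default 0.1).
#' @return object of class `energy_breakdown`: named numeric vector with
#'   components `torsion`, `pairwise`, `environment`, `contact`, `total`.
#' @export
total_energy <- function(conf, bundle,
                         term_weights = c(torsion = 1, pairwise = 1,
                                          environment = 1, contact = 1),
                         env_magnitude = 0.1) {
  if (nchar(conf$sequence) != nchar(bundle$sequence))
    stop("validation error: conformation and bundle lengths differ")
  params <- build_energy_params(bundle, term_weights, env_magnitude)
  e <- cpp_energy_coords(conf$N, conf$CA, conf$C, conf$phi, conf$psi, params)
  structure(e, class = "energy_breakdown")
}

#' @export
print.energy_breakdown <- function(x, ...) {
  cat("Energy breakdown:\n")
  for (nm in names(x)) cat(sprintf("  %-12s %10.4f\n", nm, x[[nm]]))
  invisible(x)
}

#' Run one restrained Metropolis Monte Carlo trajectory
#'
#' Torsion-space Metropolis chain targeting `exp(-V/T)`: each step perturbs
#' one randomly chosen phi or psi angle by a Gaussian proposal and accepts
#' with probability `min(1, exp(-dV/T))`. Bond lengths and angles never
#' change. Frames are captured every `capture_every` steps; runs are
#' bit-reproducible for a fixed seed.
#'
#' @param conf0 starting `backbone`.
#' @param bundle a `restraint_bundle`.
#' @param steps number of MC steps.
#' @param capture_every frame capture interval in steps (default 500).
#' @param temperature sampling temperature in energy units (default 1).
#' @param seed RNG seed.
#' @param sigma proposal standard deviation in degrees (default 5).
#' @param term_weights,env_magnitude passed to the energy (see
#'   [total_energy()]).
#' @return object of class `cg_trajectory`: frame matrices `phi`, `psi`
#'   (frames x residues, degrees), per-frame `energies`, `capture_every`,
#'   `seed`, `temperature`, `acceptance_rate`, `sequence`.
#' @export
run_simulation <- function(conf0, bundle, steps, capture_every = 500L,
                           temperature = 1.0, seed = 1L, sigma = 5,
                           term_weights = c(torsion = 1, pairwise = 1,
                                            environment = 1, contact = 1),
                           env_magnitude = 0.1) {
  stopifnot(steps >= capture_every, capture_every >= 1L)
  params <- build_energy_params(bundle, term_weights, env_magnitude)
  set.seed(seed)
  res <- cpp_run_mc(conf0$phi, conf0$psi, params, as.integer(steps),
                    as.integer(capture_every), temperature, sigma)
  structure(list(phi = res$phi, psi = res$psi, energies = res$energies,
                 capture_every = as.integer(capture_every),
                 seed = as.integer(seed), temperature = temperature,
                 acceptance_rate = res$acceptance_rate,
                 sequence = conf0$sequence),
            class = "cg_trajectory")
}

#' @export
print.cg_trajectory <- function(x, ...) {
  cat("Trajectory:", nrow(x$phi), "frames x", ncol(x$phi), "residues",
      "(capture every", x$capture_every, "steps, T =", x$temperature, ")\n")
  if (is.finite(x$acceptance_rate))
    cat("  acceptance rate:", round(x$acceptance_rate, 3), "\n")
  invisible(x)
}

#' Number of captured frames
#' @param traj a `cg_trajectory`.
#' @return integer frame count.
#' @export
n_frames <- function(traj) nrow(traj$phi)

#' Rebuild the conformation of one captured frame
#' @param traj a `cg_trajectory`.
#' @param k frame index.
#' @return a `backbone`.
#' @export
frame_conformation <- function(traj, k) {
  stopifnot(k >= 1L, k <= n_frames(traj))
  coords <- cpp_build_backbone(traj$phi[k, ], traj$psi[k, ])
  new_backbone(traj$sequence, traj$phi[k, ], traj$psi[k, ], coords)
}

#' Run an ensemble of independent trajectories
#'
#' Launches `n_traj` trajectories from the same starting conformation with
#' distinct seeds. Trajectories are mutually independent, so the result does
#' not depend on execution order.
#'
#' @param conf0 starting `backbone`.
#' @param bundle a `restraint_bundle`.
#' @param n_traj number of trajectories (default 500).
#' @param steps,capture_every,temperature,sigma,term_weights,env_magnitude
#'   see [run_simulation()].
#' @param seeds integer vector of seeds (default `base_seed + 1:n_traj`).
#' @param base_seed offset for default seeds (default 0).
#' @return list of `cg_trajectory` objects.
#' @export
run_ensemble <- function(conf0, bundle, n_traj = 500L, steps,
                         capture_every = 500L, temperature = 1.0,
                         seeds = NULL, base_seed = 0L, sigma = 5,
                         term_weights = c(torsion = 1, pairwise = 1,
                                          environment = 1, contact = 1),
                         env_magnitude = 0.1) {
  if (is.null(seeds)) seeds <- base_seed + seq_len(n_traj)
  if (anyDuplicated(seeds)) warning("duplicate seeds in ensemble")
  stopifnot(length(seeds) == n_traj)
  lapply(seeds, function(s)
    run_simulation(conf0, bundle, steps, capture_every, temperature,
                   seed = s, sigma = sigma, term_weights = term_weights,
                   env_magnitude = env_magnitude))
}

#' Write conformations as a (multi-model) PDB file
#'
#' Minimal PDB writer: backbone N, CA, C plus derived O and CB per residue,
#' one MODEL block per conformation.
#'
#' @param confs a `backbone`, a list of them, or a `cg_trajectory` (all
#'   frames written).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(confs, path) {
  if (inherits(confs, "backbone")) confs <- list(confs)
  if (inherits(confs, "cg_trajectory"))
    confs <- lapply(seq_len(n_frames(confs)), frame_conformation,
                    traj = confs)
  aa3 <- c(A = "ALA", C = "CYS", D = "ASP", E = "GLU", F = "PHE", G = "GLY",
           H = "HIS", I = "ILE", K = "LYS", L = "LEU", M = "MET", N = "ASN",
           P = "PRO", Q = "GLN", R = "ARG", S = "SER", T = "THR", V = "VAL",
           W = "TRP", Y = "TYR")
  con <- file(path, "w")
  on.exit(close(con))
  for (m in seq_along(confs)) {
    conf <- confs[[m]]
    aa <- strsplit(conf$sequence, "")[[1]]
    atoms <- derived_atoms(conf)
    if (length(confs) > 1L) writeLines(sprintf("MODEL     %4d", m), con)
    serial <- 0L
    for (i in seq_along(aa)) {
      for (at in c("N", "CA", "C", "O", "CB")) {
        xyz <- switch(at, N = conf$N[i, ], CA = conf$CA[i, ], C = conf$C[i, ],
                      O = atoms$O[i, ], CB = atoms$CB[i, ])
        serial <- serial + 1L
        writeLines(sprintf(
          "ATOM  %5d %-4s%3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
          serial, paste0(" ", at), aa3[[aa[i]]], i, xyz[1], xyz[2], xyz[3],
          substr(at, 1, 1)), con)
      }
    }
    writeLines(if (length(confs) > 1L) c("ENDMDL") else "END", con)
  }
  if (length(confs) > 1L) writeLines("END", con)
  invisible(path)
}

#' Read Calpha coordinates from a PDB file
#'
#' Minimal reader for evaluation references: returns the CA trace of the
#' first model.
#'
#' @param path PDB file path.
#' @return L x 3 coordinate matrix.
#' @export
read_pdb_ca <- function(path) {
  lines <- readLines(path, warn = FALSE)
  end1 <- grep("^ENDMDL", lines)[1]
  if (!is.na(end1)) lines <- lines[seq_len(end1)]
  ca <- lines[grepl("^ATOM", lines) &
                trimws(substr(lines, 13, 16)) == "CA"]
  if (length(ca) == 0L) stop("input error: no CA atoms in ", path)
  cbind(x = as.numeric(substr(ca, 31, 38)),
        y = as.numeric(substr(ca, 39, 46)),
        z = as.numeric(substr(ca, 47, 54)))
}
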