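# Seeded synthetic generators: planted Potts models and MSAs sampled from
# them, idealized toy folds with known contacts/torsions, normalized feature
# tables, and mock trajectory ensembles. These make every pipeline stage
# testable offline, with known ground truth.

#' Construct a Potts model with planted couplings
#'
#' Builds a q-state model whose couplings are zero everywhere except on
#' `n_pairs` randomly chosen site pairs (separation >= 2), where a
#' ferromagnetic block `e_ij(a, a) = strength` is planted. Fields are drawn
#' from a zero-mean Gaussian. The planted pairs are the ground truth that
#' coupling inference should recover.
#'
#' @param L number of sites (default 12).
#' @param q number of states (default 4).
#' @param n_pairs number of planted coupled pairs (default 6).
#' @param strength coupling strength on matching states (default 2).
#' @param field_sd standard deviation of the random fields (default 0.3).
#' @param seed RNG seed.
#' @return object of class `planted_potts`: list with `model` (a
#'   `potts_model` over the q-letter sub-alphabet), `pairs` (data.frame i, j),
#'   `strength`, `seed`.
#' @export
plant_potts <- function(L = 12L, q = 4L, n_pairs = 6L, strength = 2,
                        field_sd = 0.3, seed = 1L) {
  stopifnot(L >= 4L, q >= 2L, n_pairs >= 1L, strength > 0)
  set.seed(seed)
  eligible <- which(upper.tri(matrix(0, L, L)), arr.ind = TRUE)
  eligible <- eligible[abs(eligible[, 1] - eligible[, 2]) >= 2L, , drop = FALSE]
  stopifnot(nrow(eligible) >= n_pairs)
  sel <- sort(sample.int(nrow(eligible), n_pairs))
  pairs <- data.frame(i = eligible[sel, 1], j = eligible[sel, 2])
  h <- matrix(rnorm(L * q, 0, field_sd), L, q)
  J <- matrix(0, L * q, L * q)
  for (p in seq_len(n_pairs)) {
    blk <- diag(strength, q)
    bi <- ((pairs$i[p] - 1L) * q + 1L):(pairs$i[p] * q)
    bj <- ((pairs$j[p] - 1L) * q + 1L):(pairs$j[p] * q)
    J[bi, bj] <- blk
    J[bj, bi] <- t(blk)
  }
  model <- structure(list(h = h, e = J, L = L, q = q, gauge = "planted",
                          reg = c(lambda_h = 0, lambda_e = 0),
                          convergence = NULL),
                     class = "potts_model")
  structure(list(model = model, pairs = pairs, strength = strength,
                 seed = seed),
            class = "planted_potts")
}

#' Sample an alignment from a Potts model
#'
#' Draws `n` sequences from the Boltzmann distribution of a q-state Potts
#' model and returns them as an `msa` over the first q letters of the
#' amino-acid alphabet. Systems small enough to enumerate (`q^L <= 2^20`)
#' are sampled exactly from the full state distribution; larger systems use
#' `n` independent vectorized Gibbs chains with a burn-in.
#'
#' @param planted a `planted_potts` (or a bare `potts_model`).
#' @param n number of sequences.
#' @param seed RNG seed.
#' @param burn_in Gibbs burn-in sweeps (default 200; ignored for exact
#'   sampling).
#' @return an `msa` with `n` rows and `L` columns.
#' @export
sample_potts_msa <- function(planted, n, seed = 1L, burn_in = 200L) {
  model <- if (inherits(planted, "planted_potts")) planted$model else planted
  stopifnot(inherits(model, "potts_model"), n >= 1L)
  L <- model$L; q <- model$q
  set.seed(seed)
  if (q^L <= 2^20) {
    enc <- sample_potts_exact(model, n)
  } else {
    enc <- sample_potts_gibbs(model, n, burn_in)
  }
  letters20 <- AA_ALPHABET[seq_len(q)]
  seqs <- apply(enc, 1L, function(r) paste(letters20[r], collapse = ""))
  new_msa(seqs, ids = sprintf("synth%05d", seq_len(n)))
}

# exact enumeration: probabilities over all q^L states
sample_potts_exact <- function(model, n) {
  L <- model$L; q <- model$q
  states <- as.matrix(expand.grid(rep(list(seq_len(q)), L)))
  X <- onehot_design(states, q)
  E <- rowSums((X %*% model$e) * X) / 2 +
    X %*% as.vector(t(model$h))
  p <- exp(E - max(E)); p <- p / sum(p)
  draw <- sample.int(nrow(states), n, replace = TRUE, prob = p)
  states[draw, , drop = FALSE]
}

# n independent chains, updated site-by-site in a vectorized sweep
sample_potts_gibbs <- function(model, n, burn_in) {
  L <- model$L; q <- model$q
  enc <- matrix(sample.int(q, n * L, replace = TRUE), n, L)
  X <- onehot_design(enc, q)
  hmat <- model$h
  for (sweep in seq_len(burn_in)) {
    for (i in seq_len(L)) {
      idx <- ((i - 1L) * q + 1L):(i * q)
      logits <- X %*% model$e[, idx, drop = FALSE]
      logits <- sweep(logits, 2L, hmat[i, ], `+`)
      logits <- logits - apply(logits, 1L, max)
      P <- exp(logits); P <- P / rowSums(P)
      u <- runif(n)
      cp <- t(apply(P, 1L, cumsum))
      newstate <- max.col(cp >= u, ties.method = "first")
      enc[, i] <- newstate
      X[, idx] <- 0
      X[cbind(seq_len(n), (i - 1L) * q + newstate)] <- 1
    }
  }
  enc
}

#' Idealized toy fold with known contacts and torsions
#'
#' Deterministic miniature folds built from ideal backbone geometry:
#' `"hairpin"` is a two-strand antiparallel beta hairpin joined by a
#' two-residue turn; `"helix-bundle"` is two alpha helices joined by a short
#' loop. Native contacts (Cbeta pairs within 7.5 Angstrom, separation >= 3)
#' and native torsions are recomputed from the built coordinates.
#'
#' @param kind `"hairpin"` or `"helix-bundle"`.
#' @param L chain length (default 16, minimum 8).
#' @param seed RNG seed for the hydrophobic/polar sequence pattern.
#' @return object of class `toy_fold`: list with `conformation`
#'   (a `backbone`), `sequence`, `contacts` (data.frame i, j, distance),
#'   `torsions` (data.frame phi, psi), `kind`.
#' @export
make_toy_fold <- function(kind = c("hairpin", "helix-bundle"), L = 16L,
                          seed = 1L) {
  kind <- match.arg(kind)
  stopifnot(L >= 8L)
  set.seed(seed)
  sequence <- paste(sample(c("A", "L", "V", "S", "T", "G", "K", "E"), L,
                           replace = TRUE), collapse = "")
  phi <- numeric(L); psi <- numeric(L)
  if (kind == "hairpin") {
    half <- L %/% 2L
    strand_phi <- -120; strand_psi <- 125
    phi[] <- strand_phi; psi[] <- strand_psi
    # type-I'-like two-residue turn at the chain middle
    phi[half] <- 55;  psi[half] <- 45
    phi[half + 1L] <- 80; psi[half + 1L] <- 5
  } else {
    helix_phi <- -57; helix_psi <- -47
    phi[] <- helix_phi; psi[] <- helix_psi
    mid <- L %/% 2L
    # three-residue loop reversing the chain direction between the helices
    phi[mid - 1L] <- -90; psi[mid - 1L] <- 120
    phi[mid]      <- 75;  psi[mid]      <- 30
    phi[mid + 1L] <- -130; psi[mid + 1L] <- 70
  }
  conf <- build_extended(sequence)
  conf <- set_torsions(conf, phi, psi)
  tor <- measure_torsions(conf)
  contacts <- native_contacts(conf)
  structure(list(conformation = conf, sequence = sequence,
                 contacts = contacts, torsions = tor, kind = kind),
            class = "toy_fold")
}

#' Native Cbeta contacts of a conformation
#'
#' @param conf a `backbone` conformation.
#' @param cutoff contact distance in Angstrom (default 7.5).
#' @param min_separation minimum |i - j| (default 3).
#' @return data.frame with columns `i`, `j`, `distance`.
#' @export
native_contacts <- function(conf, cutoff = 7.5, min_separation = 3L) {
  cb <- derived_atoms(conf)$CB
  L <- nrow(cb)
  d <- as.matrix(stats::dist(cb))
  idx <- which(upper.tri(d), arr.ind = TRUE)
  idx <- idx[abs(idx[, 1] - idx[, 2]) >= min_separation, , drop = FALSE]
  keep <- d[idx] <= cutoff
  data.frame(i = idx[keep, 1], j = idx[keep, 2], distance = d[idx][keep])
}

#' Synthetic per-residue feature table
#'
#' Emulates the 24-column per-residue input of the torsion predictor
#' (20 position scores + 3 secondary-structure probabilities + 1 solvent
#' accessibility), all in [0, 1]. Rule `"random"` draws uniform noise;
#' `"angle-linked"` additionally embeds `(sin, cos)` of target torsions,
#' rescaled to [0, 1], into the first four columns so that the angles are
#' recoverable from the features by construction.
#'
#' @param L number of residues.
#' @param rule `"random"` or `"angle-linked"`.
#' @param seed RNG seed.
#' @return list with `features` (L x 24 matrix) and, for `"angle-linked"`,
#'   `torsions` (data.frame phi, psi in degrees).
#' @export
make_feature_table <- function(L, rule = c("random", "angle-linked"),
                               seed = 1L) {
  rule <- match.arg(rule)
  set.seed(seed)
  features <- matrix(runif(L * 24), L, 24)
  colnames(features) <- c(paste0("pssm", 1:20), paste0("ss", 1:3), "sa")
  torsions <- NULL
  if (rule == "angle-linked") {
    # targets drawn near the two populated Ramachandran basins
    basin <- sample(c(TRUE, FALSE), L, replace = TRUE)
    phi <- ifelse(basin, rnorm(L, -63, 12), rnorm(L, -110, 15))
    psi <- ifelse(basin, rnorm(L, -42, 12), rnorm(L, 130, 15))
    phi <- wrap_angle(phi); psi <- wrap_angle(psi)
    rad <- pi / 180
    features[, 1] <- (sin(phi * rad) + 1) / 2
    features[, 2] <- (cos(phi * rad) + 1) / 2
    features[, 3] <- (sin(psi * rad) + 1) / 2
    features[, 4] <- (cos(psi * rad) + 1) / 2
    torsions <- data.frame(phi = phi, psi = psi)
  }
  out <- list(features = features, torsions = torsions, rule = rule,
              seed = seed)
  class(out) <- "feature_table"
  out
}

#' Write / read a feature table as whitespace-delimited text
#' @param features L x 24 numeric matrix (or a `feature_table`).
#' @param path file path.
#' @return `path` invisibly; `read_feature_table` returns the matrix.
#' @export
write_feature_table <- function(features, path) {
  if (inherits(features, "feature_table")) features <- features$features
  write.table(round(features, 6), path, sep = " ", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  m <- as.matrix(read.table(path, header = TRUE, check.names = FALSE))
  if (ncol(m) != 24L)
    stop("format error: feature table must have 24 columns, found ", ncol(m))
  if (any(m < 0 | m > 1))
    stop("validation error: feature values must lie in [0, 1]")
  m
}

#' Mock trajectory ensemble around a base fold
#'
#' Generates `n_traj` trajectories of `n_frames` frames whose torsions are
#' the base fold's torsions plus independent Gaussian noise (degrees). Useful
#' for exercising pooling/clustering without running the sampler.
#'
#' @param n_traj number of trajectories.
#' @param n_frames frames per trajectory.
#' @param base a `toy_fold` (or a `backbone`) providing base torsions.
#' @param noise per-angle noise standard deviation in degrees (default 3).
#' @param seed RNG seed.
#' @return list of `cg_trajectory` objects.
#' @export
make_mock_trajectories <- function(n_traj, n_frames, base, noise = 3,
                                   seed = 1L) {
  stopifnot(n_traj >= 1L, n_frames >= 1L)
  conf <- if (inherits(base, "toy_fold")) base$conformation else base
  tor <- measure_torsions(conf)
  L <- nrow(tor)
  set.seed(seed)
  lapply(seq_len(n_traj), function(t) {
    phi <- matrix(wrap_angle(rep(tor$phi, each = n_frames) +
                               rnorm(n_frames * L, 0, noise)), n_frames, L)
    psi <- matrix(wrap_angle(rep(tor$psi, each = n_frames) +
                               rnorm(n_frames * L, 0, noise)), n_frames, L)
    structure(list(phi = phi, psi = psi,
                   energies = rep(NA_real_, n_frames),
                   capture_every = 1L, seed = seed + t, temperature = NA_real_,
                   acceptance_rate = NA_real_, sequence = conf$sequence),
              class = "cg_trajectory")
  })
}

# wrap degrees into (-180, 180]
wrap_angle <- function(a) {
  out <- ((a + 180) %% 360) - 180
  out[out == -180] <- 180
  out
}
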