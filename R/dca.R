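# Direct coupling analysis: weighted frequencies, pseudo-likelihood Potts
# fit, direct information, and contact ranking.

#' Weighted single-site and pairwise frequencies
#'
#' Computes reweighted empirical marginals over the 21-state alphabet
#' (20 amino acids + gap) with a uniform pseudocount mixture:
#' `f = (1 - lambda) f_obs + lambda / q` per site and `lambda / q^2` per
#' state pair.
#'
#' @param msa an `msa` object (trimmed).
#' @param weights a `seq_weights` object, or `NULL` for uniform weights.
#' @param lambda pseudocount fraction in [0, 1).
#' @param q alphabet size (default 21: 20 amino acids + gap). A smaller q
#'   restricts to the first q alphabet letters, for reduced-alphabet
#'   analyses.
#' @return object of class `site_freqs`: `fi` (L x q), `fij` (Lq x Lq block
#'   matrix; block (i, j) holds the q x q pair table), `L`, `q`, `lambda`.
#' @export
site_frequencies <- function(msa, weights = NULL, lambda = 0,
                             q = GAP_STATE) {
  stopifnot(lambda >= 0, lambda < 1)
  enc <- msa_encode(msa)
  if (max(enc) > q)
    stop("alphabet size q = ", q, " too small for the alignment states")
  n <- nrow(enc); L <- ncol(enc)
  w <- if (is.null(weights)) rep(1, n) else weights$weights
  stopifnot(length(w) == n)
  w <- w / sum(w)
  X <- onehot_design(enc, q)           # n x Lq
  fi_flat <- colSums(X * w)            # length Lq
  fij <- crossprod(X, X * w)           # Lq x Lq
  fi <- matrix(fi_flat, nrow = L, ncol = q, byrow = TRUE)
  if (lambda > 0) {
    fi <- (1 - lambda) * fi + lambda / q
    fij <- (1 - lambda) * fij + lambda / q^2
    # diagonal blocks represent f_ii(A, B) = delta_AB f_i(A)
    for (i in seq_len(L)) {
      idx <- block_idx(i, q)
      fij[idx, idx] <- diag(fi[i, ], q)
    }
  }
  structure(list(fi = fi, fij = fij, L = L, q = q, lambda = lambda),
            class = "site_freqs")
}

#' Pair-frequency block accessor
#' @param freqs a `site_freqs` object.
#' @param i,j site indices.
#' @return q x q matrix of pair frequencies f_ij(A, B).
#' @export
pair_freq <- function(freqs, i, j) {
  freqs$fij[block_idx(i, freqs$q), block_idx(j, freqs$q)]
}

block_idx <- function(i, q) ((i - 1L) * q + 1L):(i * q)

# one-hot design matrix: row s has a 1 at column (i-1)*q + a_i^s
onehot_design <- function(enc, q) {
  n <- nrow(enc); L <- ncol(enc)
  X <- matrix(0, n, L * q)
  cols <- sweep(enc, 2L, (seq_len(L) - 1L) * q, `+`)
  X[cbind(rep(seq_len(n), L), as.vector(cols))] <- 1
  X
}

#' Fit a Potts model by pseudo-likelihood maximization
#'
#' Maximizes the L2-regularized sum of weighted per-site conditional
#' log-likelihoods of the pairwise maximum-entropy model
#' \deqn{P(A_1..A_L) \propto \exp(\sum_{i<j} e_{ij}(A_i, A_j) + \sum_i h_i(A_i))}
#' using `stats::optim(method = "L-BFGS-B")` from a zero initialization, and
#' returns the fit in the zero-sum gauge.
#'
#' @param msa an `msa` object.
#' @param weights `seq_weights` or `NULL`.
#' @param lambda_h L2 strength on fields (default 0.01).
#' @param lambda_e L2 strength on couplings; default `0.01 * (L - 1)`,
#'   scaling with the number of sites coupled to each position.
#' @param maxit maximum L-BFGS iterations (default 500).
#' @param factr `optim` convergence factor (default 1e9, i.e. ~1e-7 relative).
#' @param q alphabet size (default 21; see [site_frequencies()]).
#' @return object of class `potts_model`: `h` (L x q), `e` (Lq x Lq symmetric
#'   block matrix, zero diagonal blocks), `L`, `q`, `gauge`, `reg`,
#'   `convergence` (optim diagnostics).
#' @export
fit_plm <- function(msa, weights = NULL, lambda_h = 0.01, lambda_e = NULL,
                    maxit = 500L, factr = 1e9, q = GAP_STATE) {
  enc <- msa_encode(msa)
  if (max(enc) > q)
    stop("alphabet size q = ", q, " too small for the alignment states")
  n <- nrow(enc); L <- ncol(enc)
  if (L < 2L) stop("need at least 2 alignment columns")
  if (is.null(lambda_e)) lambda_e <- 0.01 * (L - 1)
  w <- if (is.null(weights)) rep(1, n) else weights$weights
  w <- w / sum(w)
  X <- onehot_design(enc, q)
  Y <- X                      # observed one-hot, same layout
  pairs <- which(upper.tri(matrix(0, L, L)), arr.ind = TRUE)
  pairs <- pairs[order(pairs[, 1], pairs[, 2]), , drop = FALSE]
  n_pair <- nrow(pairs)
  n_par <- L * q + n_pair * q * q

  unpack <- function(theta) {
    h <- matrix(theta[seq_len(L * q)], L, q, byrow = TRUE)
    J <- matrix(0, L * q, L * q)
    off <- L * q
    for (p in seq_len(n_pair)) {
      i <- pairs[p, 1]; j <- pairs[p, 2]
      blk <- matrix(theta[off + seq_len(q * q)], q, q)
      J[block_idx(i, q), block_idx(j, q)] <- blk
      J[block_idx(j, q), block_idx(i, q)] <- t(blk)
      off <- off + q * q
    }
    list(h = h, J = J)
  }

  # negative pseudo-log-likelihood and gradient, both from one shared forward
  # pass; cached between the paired fn/gr calls optim makes
  cache <- new.env(parent = emptyenv())
  forward <- function(theta) {
    if (!is.null(cache$theta) && identical(cache$theta, theta)) return()
    par <- unpack(theta)
    E <- X %*% par$J                          # n x Lq conditional energies
    E <- E + matrix(as.vector(t(par$h)), n, L * q, byrow = TRUE)
    nll <- 0
    G <- matrix(0, n, L * q)                  # P - Y, weighted
    for (i in seq_len(L)) {
      idx <- block_idx(i, q)
      Ei <- E[, idx, drop = FALSE]
      m <- apply(Ei, 1L, max)
      lse <- m + log(rowSums(exp(Ei - m)))
      obs <- rowSums(Ei * Y[, idx, drop = FALSE])
      nll <- nll - sum(w * (obs - lse))
      P <- exp(Ei - lse)
      G[, idx] <- w * (P - Y[, idx, drop = FALSE])
    }
    gh <- matrix(colSums(G), L, q, byrow = TRUE) + 2 * lambda_h * par$h
    GJ <- crossprod(X, G)                     # Lq x Lq
    ge <- numeric(n_pair * q * q)
    off <- 0
    for (p in seq_len(n_pair)) {
      i <- pairs[p, 1]; j <- pairs[p, 2]
      blk <- GJ[block_idx(i, q), block_idx(j, q)] +
             t(GJ[block_idx(j, q), block_idx(i, q)]) +
             2 * lambda_e * par$J[block_idx(i, q), block_idx(j, q)]
      ge[off + seq_len(q * q)] <- blk
      off <- off + q * q
    }
    e_blocks <- J_upper(par$J, pairs, q)
    cache$theta <- theta
    cache$value <- nll + lambda_h * sum(par$h^2) + lambda_e * sum(e_blocks^2)
    cache$grad <- c(as.vector(t(gh)), ge)
  }
  fn <- function(theta) { forward(theta); cache$value }
  gr <- function(theta) { forward(theta); cache$grad }

  opt <- optim(numeric(n_par), fn, gr, method = "L-BFGS-B",
               control = list(maxit = maxit, factr = factr))
  if (opt$convergence != 0 && opt$convergence != 1)
    stop("convergence error in pseudo-likelihood fit: code ", opt$convergence,
         " (", opt$message, "); |grad| = ",
         format(sqrt(sum(gr(opt$par)^2)), digits = 4))
  par <- unpack(opt$par)
  model <- structure(list(h = par$h, e = par$J, L = L, q = q, gauge = "fit",
                          reg = c(lambda_h = lambda_h, lambda_e = lambda_e),
                          convergence = opt[c("convergence", "counts", "value")]),
                     class = "potts_model")
  gauge_zero_sum(model)
}

J_upper <- function(J, pairs, q) {
  out <- numeric(nrow(pairs) * q * q); off <- 0
  for (p in seq_len(nrow(pairs))) {
    out[off + seq_len(q * q)] <-
      J[block_idx(pairs[p, 1], q), block_idx(pairs[p, 2], q)]
    off <- off + q * q
  }
  out
}

#' Convert a Potts model to the zero-sum gauge
#'
#' Reparameterizes so every coupling block has zero row and column means and
#' every field has zero mean, absorbing the shifts into the fields; the
#' probability model is unchanged.
#'
#' @param model a `potts_model`.
#' @return the re-gauged `potts_model` (`gauge = "zero-sum"`).
#' @export
gauge_zero_sum <- function(model) {
  L <- model$L; q <- model$q
  h <- model$h; J <- model$e
  J0 <- matrix(0, L * q, L * q)
  for (i in seq_len(L - 1L)) for (j in (i + 1L):L) {
    blk <- J[block_idx(i, q), block_idx(j, q)]
    rm <- rowMeans(blk); cm <- colMeans(blk); mm <- mean(blk)
    b0 <- blk - outer(rm, rep(1, q)) - outer(rep(1, q), cm) + mm
    J0[block_idx(i, q), block_idx(j, q)] <- b0
    J0[block_idx(j, q), block_idx(i, q)] <- t(b0)
    h[i, ] <- h[i, ] + (rm - mm)
    h[j, ] <- h[j, ] + (cm - mm)
  }
  h <- h - rowMeans(h)
  model$h <- h; model$e <- J0; model$gauge <- "zero-sum"
  model
}

#' Coupling block accessor
#' @param model a `potts_model`.
#' @param i,j site indices.
#' @return q x q coupling matrix e_ij(A, B).
#' @export
coupling <- function(model, i, j) {
  model$e[block_idx(i, model$q), block_idx(j, model$q)]
}

#' @export
print.potts_model <- function(x, ...) {
  cat("Potts model: L =", x$L, ", q =", x$q, ", gauge =", x$gauge, "\n")
  cat("  regularization: lambda_h =", x$reg[["lambda_h"]],
      ", lambda_e =", format(x$reg[["lambda_e"]], digits = 4), "\n")
  if (!is.null(x$convergence))
    cat("  optimizer: ", x$convergence$counts[["function"]],
        " evaluations, objective ", format(x$convergence$value, digits = 6),
        "\n", sep = "")
  invisible(x)
}

#' Direct information matrix
#'
#' For each site pair builds the two-site direct distribution
#' \deqn{P^{dir}_{ij}(A,B) \propto \exp(e_{ij}(A,B)) \mu_i(A) \mu_j(B)}
#' with auxiliary single-site factors `mu` fixed-point-iterated so the
#' marginals of `P^dir` match the empirical single-site frequencies, then
#' scores the pair by the Kullback-Leibler divergence of `P^dir` from the
#' product of marginals. Gauge-invariant; diagonal is zero.
#'
#' @param model a `potts_model`.
#' @param freqs a `site_freqs` object with matching L and q (a small
#'   pseudocount, e.g. `lambda = 0.01`, keeps the fixed point well-behaved on
#'   sparse columns).
#' @param tol fixed-point tolerance (default 1e-6).
#' @param max_iter maximum fixed-point iterations per pair (default 500).
#' @return object of class `di_matrix`: symmetric non-negative L x L matrix.
#' @export
direct_information <- function(model, freqs, tol = 1e-6, max_iter = 500L) {
  stopifnot(model$L == freqs$L, model$q == freqs$q)
  L <- model$L; q <- model$q
  di <- matrix(0, L, L)
  for (i in seq_len(L - 1L)) for (j in (i + 1L):L) {
    W <- exp(coupling(model, i, j))
    fi <- pmax(freqs$fi[i, ], 1e-12); fi <- fi / sum(fi)
    fj <- pmax(freqs$fi[j, ], 1e-12); fj <- fj / sum(fj)
    mu1 <- rep(1 / q, q); mu2 <- rep(1 / q, q)
    ok <- FALSE
    for (it in seq_len(max_iter)) {
      new1 <- fi / as.vector(W %*% mu2);  new1 <- new1 / sum(new1)
      new2 <- fj / as.vector(crossprod(W, new1)); new2 <- new2 / sum(new2)
      delta <- max(abs(new1 - mu1), abs(new2 - mu2))
      mu1 <- new1; mu2 <- new2
      if (delta < tol) { ok <- TRUE; break }
    }
    if (!ok) stop("numeric error: direct-distribution fixed point did not ",
                  "converge for pair (", i, ", ", j, ")")
    P <- W * outer(mu1, mu2)
    P <- P / sum(P)
    ref <- outer(fi, fj)
    di[i, j] <- di[j, i] <- sum(P * log(P / ref))
  }
  structure(di, class = c("di_matrix", "matrix"))
}

#' APC-corrected Frobenius coupling score
#'
#' Alternative contact ranking: the Frobenius norm of each zero-sum-gauge
#' coupling block over the 20 amino-acid states (gap excluded), with the
#' average-product correction applied.
#'
#' @param model a `potts_model`.
#' @return symmetric L x L score matrix of class `di_matrix`.
#' @export
apc_frobenius <- function(model) {
  model <- gauge_zero_sum(model)
  L <- model$L
  fn <- matrix(0, L, L)
  # exclude the gap state from the norm for the full alphabet only
  aa <- if (model$q == GAP_STATE) seq_len(model$q - 1L) else seq_len(model$q)
  for (i in seq_len(L - 1L)) for (j in (i + 1L):L)
    fn[i, j] <- fn[j, i] <- sqrt(sum(coupling(model, i, j)[aa, aa]^2))
  means_i <- rowSums(fn) / (L - 1)
  mean_all <- sum(fn) / (L * (L - 1))
  apc <- outer(means_i, means_i) / mean_all
  out <- fn - apc
  diag(out) <- 0
  structure(out, class = c("di_matrix", "matrix"))
}

#' Rank residue pairs by coupling score
#'
#' Selects the `k` highest-scoring pairs with sequence separation
#' `|i - j| >= min_separation`; ties are broken by ascending `(i, j)`.
#'
#' @param di an L x L score matrix (`di_matrix`).
#' @param min_separation minimum |i - j| (default 5).
#' @param k number of pairs to keep; default `2 * L`, the standard restraint
#'   budget of two contacts per residue.
#' @return object of class `contact_set`: data.frame with columns `i`, `j`,
#'   `score`, sorted by descending score; attributes `min_separation`, `L`.
#' @export
rank_contacts <- function(di, min_separation = 5L, k = NULL) {
  stopifnot(min_separation >= 1L)
  L <- nrow(di)
  if (is.null(k)) k <- 2L * L
  idx <- which(upper.tri(di), arr.ind = TRUE)
  idx <- idx[abs(idx[, 1] - idx[, 2]) >= min_separation, , drop = FALSE]
  if (nrow(idx) < k) {
    warning("only ", nrow(idx), " eligible pairs available (requested ", k, ")")
    k <- nrow(idx)
  }
  scores <- di[idx]
  ord <- order(-scores, idx[, 1], idx[, 2])
  sel <- head(ord, k)
  out <- data.frame(i = idx[sel, 1], j = idx[sel, 2], score = scores[sel])
  structure(out, min_separation = as.integer(min_separation), L = L,
            class = c("contact_set", "data.frame"))
}

#' Write contacts in CASP RR style
#'
#' One line per pair: `i j d_low d_high score`, preceded by a `PFRMAT RR`
#' header line.
#'
#' @param contacts a `contact_set`.
#' @param path output file path.
#' @param d_low,d_high distance bounds written on every line (defaults 0 and
#'   8 Angstrom).
#' @return `path`, invisibly.
#' @export
write_contacts <- function(contacts, path, d_low = 0, d_high = 8) {
  if (nrow(contacts) > 0 && any(contacts$i >= contacts$j))
    stop("validation error: contact lines require i < j")
  lines <- c("PFRMAT RR",
             if (nrow(contacts) > 0)
               sprintf("%d %d %g %g %.6g", contacts$i, contacts$j,
                       d_low, d_high, contacts$score))
  writeLines(lines, path)
  invisible(path)
}

#' Read a CASP RR contact file written by [write_contacts()]
#' @param path file path.
#' @return a `contact_set` (min_separation attribute recomputed from pairs).
#' @export
read_contacts <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^(PFRMAT|TARGET|MODEL|END)", lines) & nzchar(lines)]
  if (length(lines) == 0L) {
    out <- data.frame(i = integer(), j = integer(), score = numeric())
  } else {
    f <- read.table(text = lines, col.names = c("i", "j", "d_low", "d_high",
                                                "score"))
    out <- f[, c("i", "j", "score")]
  }
  ms <- if (nrow(out)) min(abs(out$i - out$j)) else 1L
  structure(out, min_separation = as.integer(ms), L = if (nrow(out)) max(out$j) else 0L,
            class = c("contact_set", "data.frame"))
}

#' Write a score matrix as TSV
#' @param di an L x L `di_matrix`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_di_matrix <- function(di, path) {
  write.table(round(unclass(di), 8), path, sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
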