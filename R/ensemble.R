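# Model selection: pool trajectory tails, cluster by Calpha RMSD (greedy
# neighbor-count clustering), select top centroids, score against a
# reference.

#' Pool the last frames of every trajectory
#'
#' Collects the final `last_n` captured frames of each trajectory into a
#' single structure pool with (trajectory, frame) provenance.
#'
#' @param trajectories list of `cg_trajectory` objects.
#' @param last_n frames to take from each tail (default 50).
#' @return object of class `structure_pool`: `phi`/`psi` matrices
#'   (pool x residues), `provenance` (data.frame `traj_id`, `frame_id`),
#'   `energies`, `sequence`.
#' @export
pool_frames <- function(trajectories, last_n = 50L) {
  stopifnot(last_n >= 1L)
  for (t in seq_along(trajectories)) {
    nf <- n_frames(trajectories[[t]])
    if (nf < last_n)
      stop("short trajectory ", t, ": has ", nf, " frames, need ", last_n)
  }
  phi <- do.call(rbind, lapply(trajectories, function(tr)
    tr$phi[(n_frames(tr) - last_n + 1L):n_frames(tr), , drop = FALSE]))
  psi <- do.call(rbind, lapply(trajectories, function(tr)
    tr$psi[(n_frames(tr) - last_n + 1L):n_frames(tr), , drop = FALSE]))
  energies <- unlist(lapply(trajectories, function(tr)
    tr$energies[(n_frames(tr) - last_n + 1L):n_frames(tr)]))
  prov <- data.frame(
    traj_id = rep(seq_along(trajectories), each = last_n),
    frame_id = unlist(lapply(trajectories, function(tr)
      (n_frames(tr) - last_n + 1L):n_frames(tr))))
  structure(list(phi = phi, psi = psi, provenance = prov,
                 energies = energies,
                 sequence = trajectories[[1]]$sequence),
            class = "structure_pool")
}

#' Pool size
#' @param pool a `structure_pool`.
#' @return number of pooled structures.
#' @export
pool_size <- function(pool) nrow(pool$phi)

#' @export
print.structure_pool <- function(x, ...) {
  cat("Structure pool:", pool_size(x), "conformations from",
      length(unique(x$provenance$traj_id)), "trajectories\n")
  invisible(x)
}

#' Calpha coordinates of one pooled structure
#' @param pool a `structure_pool`.
#' @param k pool index.
#' @return L x 3 CA coordinate matrix.
#' @export
pool_ca <- function(pool, k) {
  cpp_build_backbone(pool$phi[k, ], pool$psi[k, ])$CA
}

#' Minimal RMSD after optimal rigid superposition
#'
#' Kabsch algorithm: centers both coordinate sets, finds the optimal
#' rotation by singular value decomposition (with the reflection guard), and
#' returns the root-mean-square Calpha deviation.
#'
#' @param A,B n x 3 coordinate matrices, n >= 3.
#' @return RMSD in Angstrom.
#' @export
kabsch_rmsd <- function(A, B) {
  if (!all(dim(A) == dim(B))) stop("coordinate sets differ in size")
  stopifnot(nrow(A) >= 3L)
  fit <- kabsch_fit(A, B)
  sqrt(mean(rowSums((fit$A_rot - fit$B_c)^2)))
}

# superimpose A onto B; returns rotated/centered A and centered B
kabsch_fit <- function(A, B, weights = NULL) {
  if (is.null(weights)) weights <- rep(1, nrow(A))
  w <- weights / sum(weights)
  cA <- colSums(A * w); cB <- colSums(B * w)
  A_c <- sweep(A, 2L, cA); B_c <- sweep(B, 2L, cB)
  H <- crossprod(A_c * w, B_c)
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  list(A_rot = A_c %*% t(R), B_c = B_c, R = R)
}

#' Template-modelling score
#'
#' Length-normalized structural similarity in (0, 1]:
#' \deqn{TM = \max \frac{1}{L}\sum_i \frac{1}{1 + (d_i/d_0)^2}}
#' with `d0 = 1.24 (L - 15)^{1/3} - 1.8`. The maximum is taken over
#' superpositions refined iteratively: starting from the global Kabsch fit
#' (and from fits of chain fragments), the structure is repeatedly
#' re-superimposed on the residue subset currently within a distance cutoff
#' until the aligned set is stable.
#'
#' @param model,reference L x 3 Calpha coordinate matrices (equal L).
#' @return TM-score.
#' @export
tm_score <- function(model, reference) {
  if (!all(dim(model) == dim(reference)))
    stop("model and reference differ in size")
  L <- nrow(model)
  d0 <- 1.24 * (L - 15)^(1/3) - 1.8
  if (L <= 15 || !is.finite(d0) || d0 < 0.5) {
    warning("chain too short for the standard d0; applying floor d0 = 0.5")
    d0 <- 0.5
  }
  score_of <- function(sub) {
    # iterative refinement from a seed subset of aligned residues
    best <- 0
    for (iter in 1:20) {
      if (length(sub) < 3L) break
      fit <- kabsch_fit(model[sub, , drop = FALSE],
                        reference[sub, , drop = FALSE])
      # apply the fitted superposition to the full chain
      cA <- colMeans(model[sub, , drop = FALSE])
      cB <- colMeans(reference[sub, , drop = FALSE])
      M <- sweep(model, 2L, cA) %*% t(fit$R)
      Rf <- sweep(reference, 2L, cB)
      d <- sqrt(rowSums((M - Rf)^2))
      sc <- mean(1 / (1 + (d / d0)^2))
      best <- max(best, sc)
      new_sub <- which(d < max(d0, 3))
      if (identical(new_sub, sub)) break
      sub <- new_sub
    }
    best
  }
  seeds <- list(seq_len(L))
  half <- L %/% 2L
  if (half >= 3L) seeds <- c(seeds, list(seq_len(half), (L - half + 1L):L))
  max(vapply(seeds, score_of, numeric(1)))
}

#' Pairwise Calpha RMSD matrix of a pool
#'
#' @param pool a `structure_pool` (or list of L x 3 CA matrices).
#' @param stride keep every `stride`-th structure (default 1; use > 1 to
#'   sub-sample large pools).
#' @return list with `rmsd` (symmetric matrix), `index` (pool indices used).
#' @export
pool_rmsd_matrix <- function(pool, stride = 1L) {
  if (inherits(pool, "structure_pool")) {
    idx <- seq(1L, pool_size(pool), by = stride)
    cas <- lapply(idx, pool_ca, pool = pool)
  } else {
    idx <- seq(1L, length(pool), by = stride)
    cas <- pool[idx]
  }
  n <- length(cas)
  if (n > 5000L)
    warning("computing ", n, "^2 pairwise RMSDs; consider a stride")
  m <- matrix(0, n, n)
  for (a in seq_len(n - 1L)) for (b in (a + 1L):n)
    m[a, b] <- m[b, a] <- kabsch_rmsd(cas[[a]], cas[[b]])
  list(rmsd = m, index = idx)
}

#' Greedy RMSD clustering
#'
#' Neighbor-count clustering on the pairwise Calpha RMSD matrix: repeatedly
#' take the unassigned structure with the most unassigned neighbors within
#' `cutoff` as a cluster (center plus neighbors) and remove it from play.
#' Clusters are ordered by size (descending), ties broken by lower centroid
#' energy when energies are available, then by first occurrence. The
#' centroid of a cluster is the member minimizing mean RMSD to the other
#' members; tightness is that mean RMSD.
#'
#' @param pool a `structure_pool` or a list of CA coordinate matrices.
#' @param cutoff neighbor cutoff in Angstrom (default 3.5).
#' @param stride pool sub-sampling stride (default 1).
#' @return object of class `cluster_result`: `labels` (per pooled structure,
#'   in pool order), `clusters` (data.frame `cluster`, `size`, `centroid`,
#'   `tightness`), `index` (pool indices clustered), `rmsd` matrix.
#' @export
cluster_pool <- function(pool, cutoff = 3.5, stride = 1L) {
  pm <- pool_rmsd_matrix(pool, stride)
  m <- pm$rmsd
  n <- nrow(m)
  energies <- if (inherits(pool, "structure_pool"))
    pool$energies[pm$index] else rep(NA_real_, n)
  labels <- integer(n)
  remaining <- rep(TRUE, n)
  cl <- 0L
  adj <- m <= cutoff
  while (any(remaining)) {
    cl <- cl + 1L
    counts <- colSums(adj[remaining, remaining, drop = FALSE])
    center <- which(remaining)[which.max(counts)]
    members <- which(remaining & adj[center, ])
    labels[members] <- cl
    remaining[members] <- FALSE
  }
  stats <- lapply(seq_len(cl), function(k) {
    mem <- which(labels == k)
    if (length(mem) == 1L) {
      centroid <- mem; tight <- 0
    } else {
      mean_rmsd <- rowMeans(m[mem, mem, drop = FALSE]) * length(mem) /
        (length(mem) - 1L)
      centroid <- mem[which.min(mean_rmsd)]
      tight <- min(mean_rmsd)
    }
    data.frame(cluster = k, size = length(mem), centroid = centroid,
               tightness = tight,
               centroid_energy = energies[centroid])
  })
  stats <- do.call(rbind, stats)
  ord <- order(-stats$size,
               ifelse(is.na(stats$centroid_energy), Inf,
                      stats$centroid_energy),
               stats$cluster)
  stats <- stats[ord, , drop = FALSE]
  relabel <- match(seq_len(cl), stats$cluster)
  stats$cluster <- seq_len(cl)
  rownames(stats) <- NULL
  structure(list(labels = relabel[labels], clusters = stats,
                 index = pm$index, rmsd = m),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat("RMSD clustering:", nrow(x$clusters), "clusters over",
      length(x$labels), "structures\n")
  print(head(x$clusters, 10))
  invisible(x)
}

#' Top-cluster centroid structures
#'
#' @param clusters a `cluster_result`.
#' @param pool the pool that was clustered.
#' @param k number of clusters (default 5); clamped with a warning when
#'   fewer exist.
#' @return list of `backbone` conformations (centroids of the k largest
#'   clusters, largest first).
#' @export
top_centroids <- function(clusters, pool, k = 5L) {
  avail <- nrow(clusters$clusters)
  if (avail < k) {
    warning("only ", avail, " clusters available (requested ", k, ")")
    k <- avail
  }
  lapply(seq_len(k), function(r) {
    pool_idx <- clusters$index[clusters$clusters$centroid[r]]
    coords <- cpp_build_backbone(pool$phi[pool_idx, ], pool$psi[pool_idx, ])
    new_backbone(pool$sequence, pool$phi[pool_idx, ], pool$psi[pool_idx, ],
                 coords)
  })
}

#' Model-selection report
#'
#' Summarizes the clustering: per-cluster size and tightness, the
#' centroid-of-largest-cluster model and, when a reference CA trace is
#' given, the Calpha RMSD and TM-score of each centroid plus the best-RMSD
#' pool member.
#'
#' @param clusters a `cluster_result`.
#' @param pool the clustered `structure_pool`.
#' @param reference optional L x 3 reference CA coordinates.
#' @param k number of top clusters to report (default 5).
#' @return object of class `model_report`: data.frame of per-cluster rows;
#'   attributes `centroids` (list of `backbone`), `best` (list with
#'   `pool_index`, `rmsd`, `conformation`; reference runs only).
#' @export
model_report <- function(clusters, pool, reference = NULL, k = 5L) {
  cents <- top_centroids(clusters, pool, k)
  k <- length(cents)
  df <- clusters$clusters[seq_len(k),
                          c("cluster", "size", "centroid", "tightness")]
  best <- NULL
  if (!is.null(reference)) {
    df$rmsd <- vapply(cents, function(cf) kabsch_rmsd(cf$CA, reference),
                      numeric(1))
    df$tm_score <- vapply(cents, function(cf) tm_score(cf$CA, reference),
                          numeric(1))
    all_rmsd <- vapply(seq_len(pool_size(pool)), function(i)
      kabsch_rmsd(pool_ca(pool, i), reference), numeric(1))
    bi <- which.min(all_rmsd)
    coords <- cpp_build_backbone(pool$phi[bi, ], pool$psi[bi, ])
    best <- list(pool_index = bi, rmsd = all_rmsd[bi],
                 tm_score = tm_score(coords$CA, reference),
                 conformation = new_backbone(pool$sequence, pool$phi[bi, ],
                                             pool$psi[bi, ], coords))
  }
  structure(df, centroids = cents, best = best,
            class = c("model_report", "data.frame"))
}

#' @export
print.model_report <- function(x, ...) {
  cat("Model report (top", nrow(x), "clusters):\n")
  print.data.frame(x, digits = 4)
  best <- attr(x, "best")
  if (!is.null(best))
    cat(sprintf("best pool model: #%d, RMSD %.3f A, TM %.3f\n",
                best$pool_index, best$rmsd, best$tm_score))
  invisible(x)
}

#' Write a model report as TSV
#' @param report a `model_report`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  write.table(as.data.frame(report), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
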