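# pooling, superposition metrics, clustering, model reports

test_that("tail pooling preserves counts, order and provenance", {
  hp <- make_toy_fold("hairpin", 12, seed = 1)
  trs <- make_mock_trajectories(10, 60, hp, noise = 2, seed = 2)
  pool <- pool_frames(trs, 50)
  expect_equal(pool_size(pool), 500L)
  expect_false(anyDuplicated(pool$provenance) > 0)
  expect_equal(unique(table(pool$provenance$traj_id)), 50L)

  # a trajectory of exactly last_n frames contributes all frames in order
  one <- make_mock_trajectories(1, 50, hp, noise = 1, seed = 3)
  p1 <- pool_frames(one, 50)
  expect_equal(p1$phi, one[[1]]$phi)
  expect_equal(p1$provenance$frame_id, 1:50)

  # last_n = 1 keeps final frames only
  pl <- pool_frames(trs, 1)
  expect_equal(pool_size(pl), 10L)
  expect_equal(pl$phi[1, ], trs[[1]]$phi[60, ])

  expect_error(pool_frames(trs, 61), "short trajectory 1")
})

test_that("Kabsch RMSD is zero on rigid copies and symmetric", {
  hp <- make_toy_fold("hairpin", 14, seed = 4)
  A <- hp$conformation$CA
  expect_equal(kabsch_rmsd(A, A), 0)
  expect_lt(kabsch_rmsd(A, rigid_transform(A, 5)), 1e-8)
  set.seed(6)
  B <- A + matrix(rnorm(nrow(A) * 3, 0, 1), nrow(A), 3)
  expect_equal(kabsch_rmsd(A, B), kabsch_rmsd(B, A), tolerance = 1e-12)
  expect_gte(kabsch_rmsd(A, B), 0)
  expect_error(kabsch_rmsd(A, B[1:5, ]), "size")
})

test_that("Kabsch matches a planar rotation-grid oracle", {
  # planar toy: the optimal superposition is a rotation about z, so a fine
  # 1-D grid search over that angle is an independent oracle
  set.seed(7)
  A <- cbind(matrix(runif(16, -5, 5), 8, 2), 0)
  B <- A + cbind(matrix(rnorm(16, 0, 0.3), 8, 2), 0)
  grid_oracle <- function(A, B) {
    Ac <- sweep(A, 2, colMeans(A)); Bc <- sweep(B, 2, colMeans(B))
    best <- Inf
    for (th in seq(0, 2 * pi, length.out = 72001)) {
      R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1),
                  3, 3)
      best <- min(best, sqrt(mean(rowSums((Ac %*% R - Bc)^2))))
    }
    best
  }
  expect_equal(kabsch_rmsd(A, B), grid_oracle(A, B), tolerance = 1e-3)
})

test_that("Kabsch agrees with the bio3d reference implementation", {
  skip_if_not_installed("bio3d")
  hp <- make_toy_fold("helix-bundle", 16, seed = 8)
  A <- hp$conformation$CA
  set.seed(9)
  B <- rigid_transform(A + matrix(rnorm(48, 0, 0.8), 16, 3), 10)
  ref <- bio3d::rmsd(as.vector(t(A)), as.vector(t(B)), fit = TRUE)
  # bio3d rounds its RMSD to 3 decimals
  expect_equal(kabsch_rmsd(A, B), ref, tolerance = 1e-3)
})

test_that("TM-score identities and monotonicity hold", {
  hp <- make_toy_fold("hairpin", 16, seed = 11)
  A <- hp$conformation$CA
  expect_equal(suppressWarnings(tm_score(A, A)), 1.0)
  # the d0 floor warning fires for short chains
  expect_warning(tm_score(A, A), "d0")
  # a random coil scores strictly below the self-score
  set.seed(12)
  coil <- set_torsions(build_extended(hp$sequence),
                       runif(16, -180, 180), runif(16, -180, 180))
  expect_lt(suppressWarnings(tm_score(coil$CA, A)), 1.0)
  # shrinking per-residue deviations on a fixed superposition raises the score
  d20 <- suppressWarnings(tm_score(A + 2.0, A))    # translation is removed
  set.seed(13)
  noise <- matrix(rnorm(48), 16, 3)
  s_big <- suppressWarnings(tm_score(A + 1.0 * noise, A))
  s_small <- suppressWarnings(tm_score(A + 0.2 * noise, A))
  expect_gt(s_small, s_big)
  expect_equal(d20, 1.0)                            # pure translation
})

test_that("greedy clustering separates constructed basins deterministically", {
  hp <- make_toy_fold("hairpin", 12, seed = 14)
  hb <- make_toy_fold("helix-bundle", 12, seed = 14)
  t1 <- make_mock_trajectories(3, 20, hp, noise = 2, seed = 15)
  t2 <- make_mock_trajectories(2, 20, hb, noise = 2, seed = 16)
  pool <- pool_frames(c(t1, t2), 20)
  cl <- cluster_pool(pool, cutoff = 3.5)
  expect_equal(cl$clusters$size, c(60L, 40L))
  # hairpin frames all land in cluster 1, bundle frames in cluster 2
  expect_equal(unique(cl$labels[1:60]), 1L)
  expect_equal(unique(cl$labels[61:100]), 2L)
  expect_true(all(cl$clusters$tightness >= 0))

  # identical structures collapse to one zero-tightness cluster
  t0 <- make_mock_trajectories(1, 10, hp, noise = 0, seed = 17)
  cl0 <- cluster_pool(pool_frames(t0, 10), cutoff = 3.5)
  expect_equal(nrow(cl0$clusters), 1L)
  expect_equal(cl0$clusters$size, 10L)
  expect_equal(cl0$clusters$tightness, 0)

  # labels are invariant under pool permutation (up to relabeling)
  t2b <- pool_frames(c(t2, t1), 20)
  cl2 <- cluster_pool(t2b, cutoff = 3.5)
  expect_equal(cl2$clusters$size, c(60L, 40L))
  expect_equal(unique(cl2$labels[41:100]), 1L)
})

test_that("model reports rank centroids and best models correctly", {
  hp <- make_toy_fold("hairpin", 12, seed = 18)
  trs <- make_mock_trajectories(4, 20, hp, noise = 2, seed = 19)
  pool <- pool_frames(trs, 20)
  cl <- cluster_pool(pool, cutoff = 3.5)
  expect_warning(rep0 <- model_report(cl, pool, k = 5), "clusters available")
  expect_false("rmsd" %in% names(rep0))          # no reference, no RMSD

  ref <- hp$conformation$CA
  rep1 <- suppressWarnings(model_report(cl, pool, reference = ref, k = 1))
  best <- attr(rep1, "best")
  expect_lte(best$rmsd, rep1$rmsd[1])            # best-of-pool <= centroid
  # reference equal to a pool member: best RMSD ~ noise floor, well below 1 A
  expect_lt(best$rmsd, 1.5)
  p <- tempfile(fileext = ".tsv")
  write_report(rep1, p)
  expect_true(file.exists(p))
})
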