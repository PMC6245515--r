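# coarse-grained backbone geometry and the Metropolis sampler

test_that("extended chains have ideal geometry and (180, 180) torsions", {
  conf <- build_extended("ACDEF")
  expect_equal(nrow(conf$N) + nrow(conf$CA) + nrow(conf$C), 15L)
  dca <- sqrt(rowSums((conf$CA[-1, ] - conf$CA[-5, ])^2))
  expect_true(all(abs(dca - 3.80) < 0.05))     # trans virtual bond length
  tor <- measure_torsions(conf)
  expect_equal(tor$phi, rep(180, 5), tolerance = 1e-6)
  expect_equal(tor$psi, rep(180, 5), tolerance = 1e-6)

  expect_error(build_extended("ACB#"), "invalid residue")
  expect_error(build_extended("A"), ">= 2")
})

test_that("torsion setting round-trips and only moves downstream atoms", {
  conf <- build_extended("ACDEFGHIKLMN")
  set.seed(2)
  phi <- runif(12, -180, 180); psi <- runif(12, -180, 180)
  conf2 <- set_torsions(conf, phi, psi)
  tor <- measure_torsions(conf2)
  expect_equal(tor$phi[-1], phi[-1], tolerance = 1e-6)
  expect_equal(tor$psi[-12], psi[-12], tolerance = 1e-6)

  # identity set leaves coordinates untouched
  conf3 <- set_torsions(conf2, phi, psi)
  expect_equal(conf3$CA, conf2$CA, tolerance = 1e-12)

  # kinematic chain: changing psi of residue 7 moves nothing up to C(7)
  psi2 <- psi; psi2[7] <- psi[7] + 40
  conf4 <- set_torsions(conf2, phi, psi2)
  expect_equal(conf4$CA[1:7, ], conf2$CA[1:7, ], tolerance = 1e-12)
  expect_equal(conf4$C[1:7, ], conf2$C[1:7, ], tolerance = 1e-12)
  expect_gt(max(abs(conf4$CA[8:12, ] - conf2$CA[8:12, ])), 0.1)

  # helical torsions compact the chain relative to extended
  helix <- set_torsions(conf, rep(-57, 12), rep(-47, 12))
  d13_helix <- sqrt(sum((helix$CA[4, ] - helix$CA[1, ])^2))
  d13_ext <- sqrt(sum((conf$CA[4, ] - conf$CA[1, ])^2))
  expect_lt(d13_helix, d13_ext)
})

test_that("derived atoms sit at ideal distances from their hosts", {
  conf <- set_torsions(build_extended("ALKSET"), rep(-63, 6), rep(-42, 6))
  at <- derived_atoms(conf)
  expect_equal(sqrt(sum((at$CB[3, ] - conf$CA[3, ])^2)), 1.53,
               tolerance = 0.01)
  expect_equal(sqrt(sum((at$O[3, ] - conf$C[3, ])^2)), 1.231,
               tolerance = 1e-6)
  expect_equal(sqrt(sum((at$H[3, ] - conf$N[3, ])^2)), 1.01,
               tolerance = 1e-6)
})

test_that("burial counts follow the exclusion rule and compactness", {
  short <- build_extended("ALK")
  expect_lt(max(environment_count(short)), 1e-3)   # no |i-j| > 2 partners

  hp <- make_toy_fold("hairpin", 16, seed = 1)
  compact <- environment_count(hp$conformation)
  extended <- environment_count(build_extended(hp$sequence))
  interior <- 5:12
  expect_true(all(compact[interior] > extended[interior]))
})

test_that("energy decomposes additively and respects term switches", {
  pred <- data.frame(phi = c(-60, -60), psi = c(-45, -45))
  b <- restraint_bundle(pred, empty_contacts(), "AL")
  conf <- set_torsions(build_extended("AL"), c(-60, -60), c(-45, -45))
  e <- total_energy(conf, b, env_magnitude = 0)
  # torsions inside wells, no eligible pairs, env off, no contacts
  expect_equal(e[["torsion"]], 0)
  expect_equal(e[["environment"]], 0)
  expect_equal(e[["contact"]], 0)
  expect_equal(e[["total"]],
               sum(e[c("torsion", "pairwise", "environment", "contact")]))

  # zeroing one term's weight removes exactly that component
  hp <- make_toy_fold("hairpin", 16, seed = 1)
  cb <- restraint_bundle(hp$torsions,
                         contacts_from_df(cbind(hp$contacts[1:5, 1:2],
                                                score = 1)),
                         hp$sequence)
  full <- total_energy(hp$conformation, cb)
  for (term in c("torsion", "pairwise", "environment", "contact")) {
    w <- c(torsion = 1, pairwise = 1, environment = 1, contact = 1)
    w[term] <- 0
    off <- total_energy(hp$conformation, cb, term_weights = w)
    expect_equal(off[[term]], 0)
    others <- setdiff(c("torsion", "pairwise", "environment", "contact"),
                      term)
    expect_equal(unclass(off)[others], unclass(full)[others])
  }
})

test_that("contact term equals the closed-form well at the measured distance", {
  hp <- make_toy_fold("hairpin", 16, seed = 1)
  pair <- hp$contacts[1, ]
  cb <- restraint_bundle(NULL, contacts_from_df(
    data.frame(i = pair$i, j = pair$j, score = 1)), hp$sequence)
  at <- derived_atoms(hp$conformation)
  d <- sqrt(sum((at$CB[pair$i, ] - at$CB[pair$j, ])^2))
  e <- total_energy(hp$conformation, cb, env_magnitude = 0)
  expect_equal(e[["contact"]], contact_restraint_potential(d),
               tolerance = 1e-9)
})

test_that("energy is invariant under rigid motions of the coordinates", {
  hp <- make_toy_fold("hairpin", 16, seed = 1)
  b <- restraint_bundle(hp$torsions, contacts_from_df(
    cbind(hp$contacts[, 1:2], score = 1)), hp$sequence)
  e1 <- total_energy(hp$conformation, b)
  conf2 <- hp$conformation
  for (nm in c("N", "CA", "C")) conf2[[nm]] <- rigid_transform(conf2[[nm]], 4)
  e2 <- total_energy(conf2, b)
  expect_equal(unclass(e1), unclass(e2), tolerance = 1e-8)
})

test_that("the Metropolis chain is seeded, reproducible, and monotone at T=0", {
  hp <- make_toy_fold("hairpin", 16, seed = 1)
  b <- restraint_bundle(hp$torsions, contacts_from_df(
    cbind(hp$contacts[, 1:2], score = 1)), hp$sequence)
  ext <- build_extended(hp$sequence)
  t1 <- run_simulation(ext, b, steps = 3000, capture_every = 100, seed = 3)
  t2 <- run_simulation(ext, b, steps = 3000, capture_every = 100, seed = 3)
  expect_identical(t1$phi, t2$phi)
  expect_identical(t1$energies, t2$energies)
  t3 <- run_simulation(ext, b, steps = 3000, capture_every = 100, seed = 4)
  expect_false(identical(t1$phi, t3$phi))

  # captured energies match recomputation from the frames
  k <- n_frames(t1)
  e <- total_energy(frame_conformation(t1, k), b)
  expect_equal(e[["total"]], t1$energies[k], tolerance = 1e-6)

  # zero temperature accepts only downhill moves
  t0 <- run_simulation(ext, b, steps = 3000, capture_every = 10,
                       temperature = 0, seed = 5)
  expect_true(all(diff(t0$energies) <= 1e-9))
})

test_that("a single free torsion samples its Boltzmann variance", {
  # quadratic well (vanishing flat bottom) on one angle; T/(2k) variance
  pred <- data.frame(phi = c(0, 0), psi = c(0, 0))
  b <- restraint_bundle(pred, empty_contacts(), "AL", delta = 1e-9,
                        k_tor = 0.05)
  start <- set_torsions(build_extended("AL"), c(0, 0), c(0, 0))
  tr <- run_simulation(start, b, steps = 2e5, capture_every = 10,
                       temperature = 1, seed = 6, env_magnitude = 0)
  v <- var(tr$psi[, 1])
  expect_lt(abs(v - 10) / 10, 0.10)       # T/(2k) = 10 deg^2
})

test_that("shell occupancies match the Boltzmann weights of a flat-bottom well", {
  # flat-bottom well discretized into two shells: the flat interior
  # (V = 0) and an outer shell where V = k (|x| - delta)^2; their occupancy
  # ratio must match the integrated Boltzmann weights
  delta <- 30; k <- 0.005
  pred <- data.frame(phi = c(0, 0), psi = c(0, 0))
  b <- restraint_bundle(pred, empty_contacts(), "AL", delta = delta,
                        k_tor = k)
  start <- set_torsions(build_extended("AL"), c(0, 0), c(0, 0))
  tr <- run_simulation(start, b, steps = 5e5, capture_every = 5,
                       temperature = 1, seed = 7, env_magnitude = 0)
  x <- abs(tr$psi[, 1])
  p_out <- mean(x >= 50 & x <= 70)
  p_in <- mean(x <= delta)
  grid <- seq(50, 70, 0.01)
  expected <- 2 * mean(exp(-k * (grid - delta)^2)) * 20 / (2 * delta)
  expect_lt(abs(p_out / p_in - expected) / expected, 0.30)
})

test_that("ensembles are independent and order-insensitive", {
  hp <- make_toy_fold("hairpin", 12, seed = 2)
  b <- restraint_bundle(hp$torsions, empty_contacts(), hp$sequence)
  ext <- build_extended(hp$sequence)
  ens <- run_ensemble(ext, b, n_traj = 3, steps = 500, capture_every = 100,
                      seeds = c(11, 12, 13))
  expect_length(ens, 3L)
  ens_perm <- run_ensemble(ext, b, n_traj = 3, steps = 500,
                           capture_every = 100, seeds = c(13, 11, 12))
  expect_identical(ens[[1]]$phi, ens_perm[[2]]$phi)
  expect_identical(ens[[3]]$phi, ens_perm[[1]]$phi)
  expect_warning(run_ensemble(ext, b, n_traj = 2, steps = 200,
                              capture_every = 100, seeds = c(1, 1)),
                 "duplicate")
})

test_that("folding with native restraints collapses from the extended start", {
  hp <- make_toy_fold("hairpin", 16, seed = 1)
  b <- restraint_bundle(hp$torsions, contacts_from_df(
    cbind(hp$contacts[, 1:2], score = 1)), hp$sequence)
  ext <- build_extended(hp$sequence)
  rg <- function(ca) sqrt(mean(rowSums(sweep(ca, 2, colMeans(ca))^2)))
  ens <- run_ensemble(ext, b, n_traj = 3, steps = 10000,
                      capture_every = 500, seeds = 21:23)
  rg_final <- vapply(ens, function(tr)
    rg(frame_conformation(tr, n_frames(tr))$CA), numeric(1))
  expect_lt(mean(rg_final), rg(ext$CA))
})

test_that("PDB output preserves coordinates through a read round-trip", {
  hp <- make_toy_fold("hairpin", 10, seed = 3)
  p <- tempfile(fileext = ".pdb")
  write_pdb(hp$conformation, p)
  ca <- read_pdb_ca(p)
  expect_equal(unname(ca), unname(hp$conformation$CA), tolerance = 1e-3)
  # multi-model output: one MODEL block per frame
  trs <- make_mock_trajectories(1, 3, hp, noise = 1, seed = 4)
  p2 <- tempfile(fileext = ".pdb")
  write_pdb(trs[[1]], p2)
  expect_equal(sum(grepl("^MODEL", readLines(p2))), 3L)
})
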