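# coupling inference: frequencies, pseudo-likelihood fit, direct
# information, contact ranking

test_that("weighted site frequencies obey indicator, mixing and symmetry rules", {
  m <- new_msa(rep("AC", 5))
  f <- site_frequencies(m, lambda = 0)
  expect_equal(f$fi[1, 1], 1)                    # f_1(A) = 1
  expect_equal(f$fi[2, 2], 1)                    # f_2(C) = 1

  m2 <- new_msa(c("A", "C"))
  f2 <- site_frequencies(m2, lambda = 0)
  expect_equal(f2$fi[1, 1:2], c(0.5, 0.5))

  # pseudocount mixing: f_obs(A) = 1, lambda = 0.5, q = 21
  f3 <- site_frequencies(m, lambda = 0.5)
  expect_equal(f3$fi[1, 1], 0.5 + 0.5 / 21)

  # normalization and pair symmetry
  expect_equal(rowSums(f3$fi), rep(1, 2))
  pf <- pair_freq(f3, 1, 2)
  expect_equal(sum(pf), 1)
  expect_equal(pf, t(pair_freq(f3, 2, 1)))
})

test_that("pseudo-likelihood fit matches a brute-force oracle on a 2x2 system", {
  # binary two-column alignment with strong positive correlation
  rows <- c(rep("AA", 40), rep("AC", 10), rep("CA", 10), rep("CC", 40))
  msa <- new_msa(rows)
  fit <- fit_plm(msa, q = 2L, lambda_h = 0.01, lambda_e = 0.01)

  # independent oracle: regularized negative pseudo-log-likelihood computed
  # by direct enumeration, minimized by coarse grid + local refinement
  counts <- table(factor(rows, levels = c("AA", "AC", "CA", "CC")))
  enc <- rbind(c(1, 1), c(1, 2), c(2, 1), c(2, 2))
  npll <- function(theta) {
    h <- matrix(theta[1:4], 2, 2, byrow = TRUE)   # h[i, state]
    e <- matrix(theta[5:8], 2, 2)                 # e[a1, a2]
    tot <- 0
    for (s in 1:4) {
      a <- enc[s, ]
      # site 1 conditional
      z1 <- h[1, ] + e[, a[2]]
      # site 2 conditional
      z2 <- h[2, ] + e[a[1], ]
      ll <- (z1[a[1]] - log(sum(exp(z1)))) + (z2[a[2]] - log(sum(exp(z2))))
      tot <- tot - counts[s] / sum(counts) * ll
    }
    tot + 0.01 * sum(h^2) + 0.01 * sum(e^2)
  }
  # coarse grid over the zero-sum degrees of freedom to locate the basin
  grid <- expand.grid(a = seq(-1, 1, 0.25), b = seq(-1, 1, 0.25),
                      c = seq(-1, 1, 0.25))
  vals <- apply(grid, 1, function(g)
    npll(c(g[1], -g[1], g[2], -g[2], g[3], -g[3], -g[3], g[3])))
  g0 <- as.numeric(grid[which.min(vals), ])
  start <- c(g0[1], -g0[1], g0[2], -g0[2], g0[3], -g0[3], -g0[3], g0[3])
  opt <- optim(start, npll, method = "BFGS",
               control = list(maxit = 2000, reltol = 1e-14))
  # zero-sum reduction of the oracle optimum (done inline, independently)
  h_o <- matrix(opt$par[1:4], 2, 2, byrow = TRUE)
  e_o <- matrix(opt$par[5:8], 2, 2)
  rm_ <- rowMeans(e_o); cm_ <- colMeans(e_o); mm_ <- mean(e_o)
  e0 <- e_o - outer(rm_, c(1, 1)) - outer(c(1, 1), cm_) + mm_
  h_o[1, ] <- h_o[1, ] + (rm_ - mm_); h_o[2, ] <- h_o[2, ] + (cm_ - mm_)
  h_o <- h_o - rowMeans(h_o)

  expect_lt(max(abs(coupling(fit, 1, 2) - e0)), 1e-3)
  expect_lt(max(abs(fit$h - h_o)), 1e-3)
})

test_that("re-gauging after a constant field shift returns the same model", {
  msa <- new_msa(c(rep("AC", 6), rep("CA", 4), rep("CC", 2)))
  fit <- fit_plm(msa, q = 2L)
  shifted <- fit
  shifted$h <- fit$h + 3.7          # constant added to every h_i(A)
  regauged <- gauge_zero_sum(shifted)
  expect_equal(regauged$h, fit$h, tolerance = 1e-10)
  expect_equal(regauged$e, fit$e, tolerance = 1e-10)
})

test_that("statistically independent columns yield only noise-level couplings", {
  # sample from a model with zero couplings (fields only)
  pl <- plant_potts(L = 6, q = 3, n_pairs = 1, strength = 1e-9,
                    field_sd = 0.5, seed = 11)
  msa <- sample_potts_msa(pl, 1500, seed = 12)
  fit <- fit_plm(msa, q = 3L)
  frob <- vapply(1:5, function(i) max(vapply((i + 1):6, function(j)
    sqrt(sum(coupling(fit, i, j)^2)), numeric(1))), numeric(1))
  expect_lt(max(frob), 0.35)        # noise threshold for n = 1500

  # permutation null: shuffling each column kills any residual signal just
  # as effectively, so the fitted couplings are not significant against it
  set.seed(13)
  perm_aln <- apply(msa$aln, 2, sample)
  msa_p <- new_msa(apply(perm_aln, 1, paste, collapse = ""))
  fit_p <- fit_plm(msa_p, q = 3L)
  frob_p <- max(vapply(1:5, function(i) max(vapply((i + 1):6, function(j)
    sqrt(sum(coupling(fit_p, i, j)^2)), numeric(1))), numeric(1)))
  expect_lt(max(frob), 3 * frob_p)
})

test_that("direct information matches its closed form and is symmetric", {
  # zero couplings give exactly zero DI
  pl <- plant_potts(L = 5, q = 2, n_pairs = 1, strength = 1e-12, seed = 2)
  freqs <- structure(list(fi = matrix(0.5, 5, 2), L = 5, q = 2, lambda = 0),
                     class = "site_freqs")
  di0 <- direct_information(pl$model, freqs)
  expect_lt(max(abs(di0)), 1e-15)

  # q = 2 single pair with known coupling and uniform marginals: by
  # symmetry the matched distribution is exp(e)/Z, so DI has a closed form
  cpl <- 0.8
  model <- structure(list(
    h = matrix(0, 2, 2),
    e = rbind(cbind(matrix(0, 2, 2), matrix(c(cpl, -cpl, -cpl, cpl), 2, 2)),
              cbind(matrix(c(cpl, -cpl, -cpl, cpl), 2, 2), matrix(0, 2, 2))),
    L = 2, q = 2, gauge = "zero-sum", reg = c(lambda_h = 0, lambda_e = 0)),
    class = "potts_model")
  fr2 <- structure(list(fi = matrix(0.5, 2, 2), L = 2, q = 2, lambda = 0),
                   class = "site_freqs")
  di <- direct_information(model, fr2)
  W <- exp(matrix(c(cpl, -cpl, -cpl, cpl), 2, 2))
  P <- W / sum(W)
  di_oracle <- sum(P * log(P / 0.25))    # direct summation over 4 outcomes
  expect_equal(di[1, 2], di_oracle, tolerance = 1e-9)
  expect_equal(unclass(di), t(unclass(di)))
  expect_equal(diag(di), c(0, 0))
})

test_that("DI is invariant under gauge transformations of the couplings", {
  pl <- plant_potts(L = 6, q = 3, n_pairs = 2, strength = 1.5, seed = 4)
  msa <- sample_potts_msa(pl, 800, seed = 5)
  fit <- fit_plm(msa, q = 3L)
  freqs <- site_frequencies(msa, lambda = 0.02, q = 3L)
  di1 <- direct_information(fit, freqs)
  # shift a coupling block by a row function and absorb it into the field
  shifted <- fit
  fvec <- c(0.5, -0.2, 0.9)
  bi <- 1:3; bj <- 4:6
  shifted$e[bi, bj] <- shifted$e[bi, bj] + outer(fvec, rep(1, 3))
  shifted$e[bj, bi] <- t(shifted$e[bi, bj])
  shifted$h[1, ] <- shifted$h[1, ] - fvec
  di2 <- direct_information(gauge_zero_sum(shifted), freqs)
  expect_equal(unclass(di1), unclass(di2), tolerance = 1e-6)
})

test_that("stronger coupling regularization shrinks fitted couplings", {
  pl <- plant_potts(L = 5, q = 3, n_pairs = 2, strength = 1.5, seed = 6)
  msa <- sample_potts_msa(pl, 600, seed = 7)
  norms <- vapply(c(0.01, 0.1, 1), function(le) {
    fit <- fit_plm(msa, q = 3L, lambda_e = le)
    sqrt(sum(fit$e^2))
  }, numeric(1))
  expect_true(all(diff(norms) < 0))
})

test_that("contact ranking respects separation, count, and tie-breaks", {
  L <- 10
  set.seed(8)
  di <- matrix(runif(L * L), L, L); di <- (di + t(di)) / 2; diag(di) <- 0
  di <- structure(di, class = c("di_matrix", "matrix"))
  cs <- rank_contacts(di, min_separation = 1, k = 2 * L)
  expect_equal(nrow(cs), 20L)
  expect_true(all(abs(cs$i - cs$j) >= 1))
  expect_true(all(diff(cs$score) <= 1e-12))

  di2 <- di; di2[3, 9] <- di2[9, 3] <- 10
  cs2 <- rank_contacts(structure(di2, class = class(di)), 1)
  expect_equal(c(cs2$i[1], cs2$j[1]), c(3, 9))

  # all-equal scores: selection is the lexicographically first eligible pairs
  flat <- structure(matrix(1, 6, 6) - diag(6), class = class(di))
  cs3 <- rank_contacts(flat, min_separation = 2, k = 3)
  expect_equal(cs3$i, c(1, 1, 1))
  expect_equal(cs3$j, c(3, 4, 5))

  # too few eligible pairs: return all with a warning
  expect_warning(cs4 <- rank_contacts(flat, min_separation = 5, k = 3),
                 "eligible")
  expect_equal(nrow(cs4), 1L)
})

test_that("contact files round-trip through the RR format", {
  cs <- contacts_from_df(data.frame(i = c(2L, 1L), j = c(10L, 7L),
                                    score = c(1.5, 0.25)))
  p <- tempfile(fileext = ".rr")
  write_contacts(cs, p)
  back <- read_contacts(p)
  expect_equal(back$i, cs$i)
  expect_equal(back$score, cs$score)

  expect_error(write_contacts(contacts_from_df(
    data.frame(i = 5L, j = 2L, score = 1)), tempfile()), "i < j")

  p2 <- tempfile()
  write_contacts(empty_contacts(), p2)
  expect_equal(readLines(p2), "PFRMAT RR")
  expect_equal(nrow(read_contacts(p2)), 0L)
})

test_that("APC-corrected Frobenius ranking also finds planted pairs", {
  pl <- plant_potts(L = 8, q = 3, n_pairs = 2, strength = 2, seed = 9)
  msa <- sample_potts_msa(pl, 1000, seed = 10)
  fit <- fit_plm(msa, q = 3L)
  sc <- apc_frobenius(fit)
  top <- rank_contacts(sc, min_separation = 2, k = 2)
  expect_setequal(paste(top$i, top$j), paste(pl$pairs$i, pl$pairs$j))
})
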