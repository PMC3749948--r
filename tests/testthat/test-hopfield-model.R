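test_that("log-score reproduces the two-site worked examples", {
  L <- 5L; q <- 4L
  i <- 2L; j <- 4L; A <- 2L; B <- 3L
  opp <- two_site_pattern(L, q, i, A, j, B, c = 1)            # +1 / -1
  eqs <- two_site_pattern(L, q, i, A, j, B, c = 1, equal_sign = TRUE)
  other <- 4L  # a state different from both favored ones
  seq_no_no <- rep(other, L)
  seq_yes_no <- replace(seq_no_no, i, A)
  seq_no_yes <- replace(seq_no_no, j, B)
  seq_yes_yes <- replace(seq_yes_no, j, B)
  # opposite-sign components: XOR scores 0 / 1 / 1 / 0
  expect_equal(log_score(seq_no_no, opp), 0)
  expect_equal(log_score(seq_yes_no, opp), 1)
  expect_equal(log_score(seq_no_yes, opp), 1)
  expect_equal(log_score(seq_yes_yes, opp), 0)
  # equal-sign components: 0 / 1 / 1 / 4
  expect_equal(log_score(seq_no_no, eqs), 0)
  expect_equal(log_score(seq_yes_no, eqs), 1)
  expect_equal(log_score(seq_no_yes, eqs), 1)
  expect_equal(log_score(seq_yes_yes, eqs), 4)
  # invariance under a global sign flip
  flipped <- opp; flipped$xi <- -flipped$xi
  expect_equal(log_score(seq_yes_no, flipped), log_score(seq_yes_no, opp))
  expect_error(log_score(rep(1L, 3), opp), "length")
})

test_that("couplings are signed pattern outer products with gauge and symmetry", {
  pat <- two_site_pattern(6, 4, 1, 2, 4, 3, c = 1.5)   # repulsive
  mod <- build_couplings(list(pat))
  q <- 4L
  blk <- mod$e[0 * q + 1:q, 3 * q + 1:q]
  expect_equal(blk[2, 3], -1.5 * (-1.5))   # - xi_i(a) xi_j(b)
  expect_equal(sum(mod$e != 0), 2L)        # one entry and its transpose
  expect_equal(mod$e, t(mod$e))
  # gauge: q-th row/column of every block zero; diagonal blocks zero
  for (i in 1:6) {
    expect_true(all(mod$e[(i - 1) * q + q, ] == 0))
    expect_true(all(mod$e[, (i - 1) * q + q] == 0))
    expect_true(all(mod$e[(i - 1) * q + 1:q, (i - 1) * q + 1:q] == 0))
  }
  expect_error(build_couplings(list(pat, two_site_pattern(5, 4, 1, 2, 3, 3))),
               "same L and q")
})

test_that("full-rank couplings equal the mean-field inversion oracle", {
  for (seed in c(2, 17)) {
    m <- random_msa(6, 4, 200, seed = seed)
    fr <- compute_frequencies(m, compute_weights(m, 0.2), 0.5)
    C <- compute_covariance(fr)
    sp <- compute_pearson(C)
    mod <- build_couplings(select_patterns(sp, length(sp$eigvals)))
    Cinv <- solve(C)
    q <- 4L; r <- 3L
    worst <- 0
    for (i in 1:5) for (j in (i + 1):6) {
      eblk <- mod$e[(i - 1) * q + 1:r, (j - 1) * q + 1:r]
      oblk <- -Cinv[(i - 1) * r + 1:r, (j - 1) * r + 1:r]
      worst <- max(worst, max(abs(eblk - oblk)))
    }
    expect_lt(worst, 1e-8)
  }
})

test_that("couplings are invariant under the basis choice in degenerate subspaces", {
  # conserved MSA has an (L-1)-fold degenerate eigenvalue: rotate its
  # basis and check the couplings do not move
  m <- conserved_msa(6, 4, M = 4, sequence = c(1L, 2L, 3L, 1L, 2L, 3L))
  fr <- compute_frequencies(m, compute_weights(m, 0.2), 0.5)
  sp <- compute_pearson(compute_covariance(fr))
  lam_small <- min(sp$eigvals)
  deg <- which(abs(sp$eigvals - lam_small) < 1e-10)
  mod1 <- build_couplings(suppressWarnings(select_patterns(sp, length(sp$eigvals))))
  set.seed(1)
  Q <- qr.Q(qr(matrix(rnorm(length(deg)^2), length(deg))))
  sp2 <- sp
  sp2$eigvecs[, deg] <- sp$eigvecs[, deg] %*% Q
  mod2 <- build_couplings(suppressWarnings(select_patterns(sp2, length(sp$eigvals))))
  expect_equal(mod1$e, mod2$e, tolerance = 1e-10)
})

test_that("fields reduce to the PSSM solution and respect the gauge", {
  m <- random_msa(4, 3, 100, seed = 5)
  fr <- compute_frequencies(m, NULL, 0.5)
  zero_mod <- coupling_model(matrix(0, 12, 12), L = 4L, q = 3L, rank = 0L)
  mod <- fit_fields(fr, zero_mod)
  expect_equal(mod$h, log(fr$f1 / fr$f1[, 3]) - 0, tolerance = 1e-14)
  expect_equal(mod$h[, 3], rep(0, 4))
  # PSSM fields reproduce the frequencies exactly under enumeration
  en <- enumerate_distribution(mod)
  expect_equal(en$f1, fr$f1, tolerance = 1e-12)
})

test_that("mean-field fields approximate weak-coupling marginals", {
  # L = 2, q = 2 toy with |e| <= 0.1: marginals of the exact model match
  # the target frequencies within 5%
  f1 <- rbind(c(0.6, 0.4), c(0.3, 0.7))
  freqs <- structure(list(f1 = f1, f2 = NULL, pseudocount_fraction = 0,
                          M_eff = 1, L = 2L, q = 2L), class = "hp_freqs")
  e <- matrix(0, 4, 4)
  e[1, 3] <- 0.1; e[3, 1] <- 0.1   # e_12(1,1) = 0.1, gauge rows stay zero
  mod <- fit_fields(freqs, coupling_model(e, L = 2L, q = 2L))
  en <- enumerate_distribution(mod)
  expect_equal(en$f1, f1, tolerance = 0.05)
})

test_that("enumeration normalizes, factorizes without couplings, and encodes XOR", {
  # zero couplings: P factorizes over positions
  h <- rbind(c(0.5, 0, -0.2), c(0, 0.3, 0))
  mod <- coupling_model(matrix(0, 6, 6), h, L = 2L, q = 3L)
  en <- enumerate_distribution(mod)
  expect_equal(sum(en$P), 1, tolerance = 1e-14)
  P1 <- exp(h[1, ]) / sum(exp(h[1, ]))
  P2 <- exp(h[2, ]) / sum(exp(h[2, ]))
  # expand.grid varies the first site fastest, matching outer()
  expect_equal(en$P, as.vector(outer(P1, P2)), tolerance = 1e-12,
               ignore_attr = TRUE)
  # single attractive pattern: co-occurrence above independence
  att <- two_site_pattern(2, 3, 1, 1, 2, 2, c = 0.8, equal_sign = TRUE,
                          sign = "attractive")
  en_a <- enumerate_distribution(build_couplings(list(att)))
  joint <- en_a$f2[1, 3 + 2]
  expect_gt(joint, en_a$f1[1, 1] * en_a$f1[2, 2])
  # single repulsive opposite-sign pattern: XOR configurations suppressed
  rep_pat <- two_site_pattern(2, 3, 1, 1, 2, 2, c = 0.8)
  en_r <- enumerate_distribution(build_couplings(list(rep_pat)))
  # P(A at 1, not B at 2) is depleted relative to independence
  pA <- en_r$f1[1, 1]; pB <- en_r$f1[2, 2]
  p_xor <- pA - en_r$f2[1, 3 + 2]
  expect_lt(p_xor, pA * (1 - pB))
  expect_error(enumerate_distribution(coupling_model(matrix(0, 5 * 21, 5 * 21),
                                                     L = 5L, q = 21L)),
               "guard")
})

test_that("exact marginals are consistent between f1 and f2", {
  pat <- two_site_pattern(3, 3, 1, 2, 3, 1, c = 0.7)
  h <- matrix(rnorm(9, sd = 0.3), 3, 3); h[, 3] <- 0
  mod <- coupling_model(build_couplings(list(pat))$e, h, L = 3L, q = 3L)
  en <- enumerate_distribution(mod)
  for (i in 1:3) for (j in 1:3) {
    blk <- en$f2[(i - 1) * 3 + 1:3, (j - 1) * 3 + 1:3]
    expect_equal(rowSums(blk), en$f1[i, ], tolerance = 1e-12)
  }
})

test_that("Gibbs sampling is deterministic per seed and matches enumeration", {
  pat <- two_site_pattern(4, 3, 1, 2, 3, 1, c = 1)
  mod <- build_couplings(list(pat))
  s1 <- gibbs_sample(mod, 50, seed = 11, burn_in = 50, thin = 2)
  s2 <- gibbs_sample(mod, 50, seed = 11, burn_in = 50, thin = 2)
  expect_identical(s1$data, s2$data)
  s3 <- gibbs_sample(mod, 50, seed = 12, burn_in = 50, thin = 2)
  expect_false(identical(s1$data, s3$data))

  # zero-coupling model: empirical f1 within 3 SE of the PSSM marginals
  h <- rbind(c(0.7, 0, -0.4), c(0, 0.5, 0), c(-0.3, 0.2, 0))
  pssm <- coupling_model(matrix(0, 9, 9), h, L = 3L, q = 3L)
  n <- 20000L
  smp <- gibbs_sample(pssm, n, seed = 7, burn_in = 200, thin = 2)
  exact <- enumerate_distribution(pssm)$f1
  for (i in 1:3) {
    emp <- tabulate(smp$data[, i], 3) / n
    se <- sqrt(exact[i, ] * (1 - exact[i, ]) / n)
    expect_true(all(abs(emp - exact[i, ]) <= 3 * se + 1e-9))
  }
})

test_that("interaction likelihood ratio is 0 at p=0, 1 at full rank, monotone", {
  m <- random_msa(5, 3, 70, seed = 44)
  fr <- compute_frequencies(m, NULL, 0.5)
  sp <- compute_pearson(compute_covariance(fr))
  n <- length(sp$eigvals)
  ratios <- vapply(0:n, function(p) interaction_likelihood_ratio(sp, p),
                   numeric(1))
  expect_equal(ratios[1], 0)
  expect_equal(ratios[n + 1], 1)
  expect_true(all(diff(ratios) >= -1e-12))
  # closed-form check on a synthetic spectrum
  s <- function(l) (l - 1 - log(l)) / 2
  lams <- c(4, 1.2, 1.0, 0.1)
  spf <- structure(list(Gamma = diag(lams), eigvals = lams,
                        eigvecs = diag(4),
                        D_sqrt = rep(list(matrix(1, 1, 1)), 4),
                        D_sqrt_inv = rep(list(matrix(1, 1, 1)), 4),
                        L = 4L, q = 2L), class = "hp_spectrum")
  expect_equal(interaction_likelihood_ratio(spf, 2),
               (s(0.1) + s(4)) / (s(0.1) + s(4) + s(1.2) + s(1.0)))
})

test_that("model serialization round-trips bit-exactly", {
  pat <- two_site_pattern(5, 4, 2, 3, 5, 1, c = sqrt(2))
  mod <- build_couplings(list(pat))
  mod$h <- matrix(rnorm(20), 5, 4); mod$h[, 4] <- 0
  f <- withr::local_tempfile(fileext = ".txt")
  write_model(mod, f)
  mod2 <- read_model(f)
  expect_identical(mod2$e, mod$e)
  expect_identical(mod2$h, mod$h)
  expect_identical(mod2$L, mod$L)
  expect_identical(mod2$rank, mod$rank)
})
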