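test_that("SVD initialization reproduces simple matrices exactly", {
  M <- diag(c(3, 2, 1))
  init <- svd_initialize(M, k = 3)
  expect_equal(init$singular_values, c(3, 2, 1))
  expect_lt(max(abs(init$W0 %*% init$chi0 - M)), 1e-12)
  # rank-1 input: second singular value vanishes
  M1 <- outer(c(1, 2, 3, 4), c(2, 1, 0.5))
  init1 <- svd_initialize(M1, k = 2)
  expect_lte(init1$singular_values[2] / init1$singular_values[1], 1e-10)
  # deterministic sign convention: dominant entry of each column positive
  expect_true(all(apply(init$W0, 2, function(x) x[which.max(abs(x))]) > 0))
})

test_that("initialization validates its inputs", {
  expect_error(svd_initialize(matrix(1:6, 2, 3), k = 3), "exceeds")
  expect_error(svd_initialize(matrix(c(-1, 1, 1, 1), 2, 2), k = 1),
               "non-negative")
})

test_that("rank suggestion finds the dominant singular-value drop-off", {
  est <- estimate_rank(c(3, 2, 1e-9))
  expect_identical(est$suggestion, 2L)
  expect_true(est$confident)
  flat <- estimate_rank(c(5, 5, 5))
  expect_false(flat$confident)
  expect_error(estimate_rank(c(0, 0)), "zero")
  expect_error(estimate_rank(5), "at least 2")
  # noiseless 4-species branched dataset suggests rank 4
  ds4 <- assemble_dataset("branched_first_order4", seed = 1)
  init <- svd_initialize(ds4$M, k = 10)
  expect_identical(estimate_rank(init$singular_values)$suggestion, 4L)
})

test_that("penalties reproduce their defining formulas", {
  W <- matrix(c(0, 1, 2, 3), 2, 2)
  expect_identical(penalty_nonneg_spectra(W), 0)
  expect_identical(penalty_nonneg_spectra(W - 0.1), 0.1^2)
  Wpos <- matrix(c(0.5, 1, 2, 3), 2, 2)
  expect_identical(penalty_nonneg_spectra(Wpos), 0.25)

  chi <- matrix(c(0, 1, 2, 3), 2, 2)
  expect_identical(penalty_nonneg_kinetics(chi), 0)
  expect_identical(penalty_nonneg_kinetics(chi - 0.2), 0.2)
  expect_identical(penalty_nonneg_kinetics(chi + 0.3), 0)

  # disjoint support: zero overlap in the normalized mode
  Wd <- cbind(c(1, 2, 0, 0), c(0, 0, 3, 1))
  cfg1 <- penalty_config(overlap_weight = 1)
  expect_identical(penalty_overlap(Wd, cfg1), 0)
  # identical columns: cosine 1
  Wi <- cbind(c(1, 2, 3, 0), c(1, 2, 3, 0))
  expect_equal(penalty_overlap(Wi, cfg1), 1)
  # zero weight annihilates the penalty in either mode
  expect_identical(penalty_overlap(Wi, penalty_config(overlap_weight = 0)), 0)
  expect_identical(penalty_overlap(Wi, penalty_config(
    overlap_weight = 0, overlap_mode = "literal_gram")), 0)
  # literal mode: Frobenius norm of |W|'|W|, diagonal included
  G <- crossprod(abs(Wi))
  expect_equal(penalty_overlap(Wi, penalty_config(
    overlap_weight = 0.5, overlap_mode = "literal_gram")),
    0.5 * norm(G, "F"))
  expect_error(penalty_overlap(cbind(c(0, 0), c(1, 1)), cfg1), "zero")
})

test_that("objective vanishes at an ideal factorization and is symmetric", {
  toy <- make_r2_toy()
  cfg <- penalty_config(overlap_weight = 1)
  v <- nmf_objective(diag(2), toy$W, toy$chi, cfg)
  expect_equal(v, 0)
  # simultaneous permutation leaves the objective unchanged
  withr::with_seed(11, {
    for (i in 1:5) {
      A <- matrix(runif(4, -1, 1), 2, 2)
      if (rcond(A) < 1e-6) next
      P <- matrix(c(0, 1, 1, 0), 2, 2)
      expect_equal(nmf_objective(A %*% P, toy$W, toy$chi, cfg),
                   nmf_objective(A, toy$W, toy$chi, cfg), tolerance = 1e-12)
    }
  })
  # near-singular transformation yields the sentinel, not an error
  As <- matrix(c(1, 1, 1, 1 + 1e-12), 2, 2)
  expect_identical(nmf_objective(As, toy$W, toy$chi, cfg), cfg$sentinel)
  expect_error(nmf_objective(diag(3), toy$W, toy$chi, cfg), "shape")
})

test_that("reconstruction is exact and rejects singular transforms", {
  toy <- make_r2_toy()
  init <- svd_initialize(toy$M, k = 2)
  rec <- reconstruct(init$W0, init$chi0, diag(2))
  expect_identical(rec$W, init$W0)
  expect_identical(rec$chi, init$chi0)
  A <- diag(c(2, 0.5))
  rec2 <- reconstruct(init$W0, init$chi0, A)
  expect_equal(rec2$W, init$W0 %*% A)
  expect_equal(rec2$chi[1, ], init$chi0[1, ] / 2)
  expect_equal(rec2$chi[2, ], init$chi0[2, ] * 2)
  expect_lt(norm(rec2$W %*% rec2$chi - init$W0 %*% init$chi0, "F"),
            1e-10 * norm(toy$M, "F"))
  expect_error(reconstruct(init$W0, init$chi0, matrix(1, 2, 2)),
               "condition cap")
})

test_that("reconstruction invariance holds for random accepted transforms", {
  toy <- make_r2_toy()
  init <- svd_initialize(toy$M, k = 2)
  ref <- norm(init$W0 %*% init$chi0, "F")
  withr::with_seed(21, {
    for (i in 1:20) {
      A <- matrix(runif(4, -2, 2), 2, 2)
      if (rcond(A) < 1e-8) next
      rec <- reconstruct(init$W0, init$chi0, A)
      expect_lt(norm(rec$W %*% rec$chi - init$W0 %*% init$chi0, "F"),
                1e-8 * ref)
    }
  })
})

test_that("a one-component problem recovers the sign flip", {
  grid <- seq(100, 300, length.out = 60)
  w <- lorentzian_spectrum(data.frame(center = 200, hwhm = 10,
                                      amplitude = 1), grid)
  times <- seq(0, 10, length.out = 30)
  tr <- exp(-0.2 * times)
  fit <- optimize_transform(W0 = cbind(-w), chi0 = rbind(-tr),
                            cfg = penalty_config(), restarts = 20, seed = 1)
  expect_true(all(fit$W >= 0))
  expect_true(all(fit$chi >= 0))
  expect_lt(fit$objective, 1e-6)
  expect_lt(fit$A[1, 1], 0)
})

test_that("multi-start bookkeeping is deterministic and non-increasing", {
  toy <- make_r2_toy()
  init <- svd_initialize(toy$M, k = 2)
  f1 <- optimize_transform(init$W0, init$chi0, restarts = 8, seed = 5)
  f2 <- optimize_transform(init$W0, init$chi0, restarts = 8, seed = 5)
  expect_identical(f1$restart_log, f2$restart_log)
  expect_identical(f1$A, f2$A)
  expect_true(all(diff(f1$running_best) <= 0))
  expect_identical(f1$running_best, cummin(f1$restart_log))
  expect_error(optimize_transform(init$W0, init$chi0, restarts = 0), ">= 1")
})

test_that("decompose recovers the components of a noiseless benchmark", {
  ds <- cached("uncorr_small", {
    # reduced grids keep the unit test quick; the full-size benchmark is
    # exercised by the acceptance suite
    assemble_dataset("uncorrelated3",
                     spectral_grid = seq(200, 1800, length.out = 300),
                     time_grid = seq(0, 171, length.out = 60), seed = 1)
  })
  fit <- decompose(ds$M, rank = 3, restarts = 60, seed = 2)
  m <- match_components(fit$W, fit$chi, ds$W_true, ds$chi_true)
  expect_gt(min(m$cos_spectra), 0.98)
  expect_identical(sort(m$permutation), 1:3)
})
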