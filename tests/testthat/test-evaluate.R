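test_that("display normalization scales to unit maxima and preserves the product", {
  toy <- make_r2_toy()
  W <- toy$W %*% diag(c(3, 0.2))
  chi <- diag(c(1 / 3, 5)) %*% toy$chi
  nrm <- normalize_for_display(W, chi)
  expect_equal(unname(apply(nrm$W, 2, max)), c(1, 1))
  expect_lt(norm(nrm$W %*% nrm$chi - W %*% chi, "F"),
            1e-10 * norm(W %*% chi, "F"))
  again <- normalize_for_display(nrm$W, nrm$chi)
  expect_equal(again$W, nrm$W)
  expect_equal(again$chi, nrm$chi)
  expect_error(normalize_for_display(cbind(toy$W[, 1], 0), chi), "zero")
})

test_that("anchoring rescales component pairs without changing the product", {
  toy <- make_r2_toy()
  W <- toy$W; chi <- toy$chi
  chi[1, 1] <- 0.5
  out <- anchor_to_reference(W, chi, list(
    list(component = 1, quantity = "kinetic", index = 1, value = 1)))
  expect_equal(out$chi[1, ], chi[1, ] * 2)
  expect_equal(out$W[, 1], W[, 1] / 2)
  expect_lt(norm(out$W %*% out$chi - W %*% chi, "F"),
            1e-10 * norm(W %*% chi, "F"))
  # no anchors: identity
  id <- anchor_to_reference(W, chi)
  expect_identical(id$W, W)
  # spectrum-maximum anchor
  sm <- anchor_to_reference(W, chi, list(
    list(component = 2, quantity = "spectrum_max", value = 7)))
  expect_equal(max(sm$W[, 2]), 7)
  expect_error(anchor_to_reference(W, chi, list(
    list(component = 1, quantity = "kinetic", index = 1, value = -1))),
    "> 0")
  expect_error(anchor_to_reference(W, chi, list(
    list(component = 1, quantity = "kinetic", index = 1, value = 1),
    list(component = 1, quantity = "spectrum_max", value = 1))),
    "one anchor")
})

test_that("component matching resolves permutation and scale", {
  ds <- assemble_dataset("uncorrelated3",
                         spectral_grid = seq(200, 1800, length.out = 200),
                         time_grid = seq(0, 171, length.out = 40), seed = 2)
  p <- c(2L, 3L, 1L)
  W_est <- ds$W_true[, p]
  chi_est <- ds$chi_true[p, ]
  m <- match_components(W_est, chi_est, ds$W_true, ds$chi_true)
  expect_identical(m$permutation, p)
  expect_equal(m$cos_spectra, rep(1, 3), tolerance = 1e-12)
  # scaled column: scale recovered, similarity still 1
  W_s <- ds$W_true; W_s[, 2] <- 5 * W_s[, 2]
  m2 <- match_components(W_s, ds$chi_true, ds$W_true, ds$chi_true)
  expect_identical(m2$permutation, 1:3)
  expect_equal(m2$scales[2], 5)
  expect_equal(m2$cos_spectra[2], 1, tolerance = 1e-12)
  expect_error(match_components(ds$W_true[, 1:2], ds$chi_true[1:2, ],
                                ds$W_true, ds$chi_true), "differ")
})

test_that("matching agrees with exhaustive permutation enumeration", {
  ds <- assemble_dataset("uncorrelated3",
                         spectral_grid = seq(200, 1800, length.out = 200),
                         time_grid = seq(0, 171, length.out = 40), seed = 2)
  withr::with_seed(31, {
    for (rep in 1:3) {
      A <- matrix(runif(9, -1, 1), 3, 3)
      while (rcond(A) < 1e-3) A <- matrix(runif(9, -1, 1), 3, 3)
      W_est <- ds$W_true %*% A
      chi_est <- solve(A, ds$chi_true)
      m <- match_components(W_est, chi_est, ds$W_true, ds$chi_true)
      # independent oracle: enumerate all assignments recursively
      best <- NULL; best_score <- -Inf
      for (p in enumerate_permutations(3)) {
        score <- sum(vapply(1:3, function(i) {
          x <- W_est[, i]; y <- ds$W_true[, p[i]]
          abs(sum(x * y) / sqrt(sum(x^2) * sum(y^2)))
        }, numeric(1)))
        if (score > best_score) { best_score <- score; best <- p }
      }
      expect_identical(m$permutation, as.integer(best))
    }
  })
})

test_that("biexponential fit recovers the generating first-order rates", {
  times <- default_time_grid()
  tr <- simulate_first_order_branched(
    kinetic_scenario("branched_first_order3"), times)
  fit <- fit_biexponential(tr["B", ], times)
  expect_lt(abs(fit$rate_rise - 0.15), 1e-4)
  expect_lt(abs(fit$rate_decay - 0.01), 1e-4)
  # scale invariance
  fit2 <- fit_biexponential(17.3 * tr["B", ], times)
  expect_equal(fit2$rate_decay, fit$rate_decay, tolerance = 1e-8)
  expect_equal(fit2$rate_rise, fit$rate_rise, tolerance = 1e-8)
  # 1% noise: decay rate still within 10%
  noisy <- pmax(tr["B", ] + withr::with_seed(8,
    rnorm(length(times), sd = 0.01 * max(tr["B", ]))), 0)
  fitn <- fit_biexponential(noisy, times)
  expect_lt(abs(fitn$rate_decay - 0.01) / 0.01, 0.1)
  expect_error(fit_biexponential(rep(0, length(times)), times), "trivial")
})

test_that("second-order rate refit is self-consistent and scale-free", {
  times <- default_time_grid()
  tr <- simulate_second_order(kinetic_scenario("second_order3"),
                              times)[c("B", "C", "D"), ]
  fit <- fit_second_order_rates(tr, times)
  expect_equal(fit$k1, 0.05, tolerance = 1e-3)
  expect_equal(fit$k2, 0.025, tolerance = 1e-3)
  expect_equal(fit$k3, 0.1, tolerance = 1e-3)
  # per-species rescaling leaves the rate estimates unchanged
  tr_s <- diag(c(2.5, 0.3, 11)) %*% tr
  fit2 <- fit_second_order_rates(tr_s, times)
  expect_equal(fit2$k3, fit$k3, tolerance = 1e-6)
  expect_equal(fit2$scales, fit$scales * c(2.5, 0.3, 11), tolerance = 1e-4)
})
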