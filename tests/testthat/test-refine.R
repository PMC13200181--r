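test_that("window penalties integrate off-species intensity as declared", {
  grid <- seq(0, 100, by = 1)
  W <- cbind(rep(0, 101), rep(0, 101))
  # species 2 carries a unit-height rectangle spanning width 10 inside
  # species 1's exclusive window
  W[grid >= 40 & grid <= 50, 2] <- 1
  spec <- refinement_spec(1, exclusive = list(c(30, 60)))
  v <- window_penalties(W, spec, grid)
  expect_equal(unname(v["v_m"]), 10, tolerance = 0.11)  # trapezoidal edges
  expect_identical(unname(v["v_m_prime"]), 0)           # no absence windows
  # clean exclusive window: zero penalty
  clean <- refinement_spec(2, exclusive = list(c(0, 20)))
  expect_identical(unname(window_penalties(W, clean, grid)["v_m"]), 0)
  # absence windows enter negated, as defined
  ab <- refinement_spec(1, absence = list(c(39, 51)))
  expect_lt(unname(window_penalties(W, ab, grid)["v_m_prime"]), -9)
  # and positively in the penalize-self reading
  ab2 <- refinement_spec(2, absence = list(c(39, 51)))
  expect_gt(unname(window_penalties(W, ab2, grid,
                                    penalize_self = TRUE)["v_m"] +
            window_penalties(W, ab2, grid,
                             penalize_self = TRUE)["v_m_prime"]), 9)
  expect_error(window_penalties(W, refinement_spec(1,
    exclusive = list(c(90, 120))), grid), "outside")
})

# fixture: stage-one solution with species-1 intensity deliberately mixed
# into species 2's spectrum
make_contaminated_fit <- function() {
  ds <- assemble_dataset("branched_first_order3", seed = 1)
  init <- svd_initialize(ds$M, k = 3)
  # map the SVD factors onto the ground truth, then contaminate: C's
  # column picks up 30% of B's spectrum
  A_true <- qr.solve(init$W0, ds$W_true)
  mix <- diag(3)
  iB <- which(ds$species == "B")
  iC <- which(ds$species == "C")
  mix[iB, iC] <- 0.3
  A_f <- A_true %*% mix
  fit <- structure(list(W = init$W0 %*% A_f, chi = solve(A_f, init$chi0),
                        A = A_f, r = 3L, seed = 1L, cfg = penalty_config(),
                        W0 = init$W0, chi0 = init$chi0,
                        restart_log = numeric(0)),
                   class = "nmf_fit")
  list(ds = ds, fit = fit, iB = iB, iC = iC)
}

test_that("bounded refinement cleans an exclusive window of a contaminated fit", {
  fx <- make_contaminated_fit()
  grid <- fx$ds$spectral_grid
  # B's 500-band is exclusive to B: C's bands sit at 540/820/1360
  win <- c(480, 520)
  spec <- refinement_spec(fx$iB, exclusive = list(win))
  before <- trap_int(grid, abs(fx$fit$W[, fx$iC]), win[1], win[2])
  ref <- refine_bounded(fx$fit, spec, grid, bound_delta = 0.5)
  after <- trap_int(grid, abs(ref$W[, fx$iC]), win[1], win[2])
  expect_lt(after, 0.5 * before)
  expect_lte(ref$refine_objective, ref$refine_objective_start)
  # the exact factorization is preserved through refinement
  expect_lt(norm(ref$W %*% ref$chi - fx$fit$W0 %*% fx$fit$chi0, "F"),
            1e-8 * norm(fx$ds$M, "F"))
})

test_that("refinement is the identity when already optimal or tightly bounded", {
  # disjoint-support toy: a window on component 1's support where
  # component 2 is exactly zero is already optimal
  toy <- make_r2_toy()
  fit <- structure(list(W = toy$W, chi = toy$chi, A = diag(2), r = 2L,
                        seed = 1L, cfg = penalty_config(),
                        W0 = toy$W, chi0 = toy$chi,
                        restart_log = numeric(0)),
                   class = "nmf_fit")
  spec <- refinement_spec(1, exclusive = list(c(120, 180)))
  v <- window_penalties(toy$W, spec, toy$grid)
  expect_identical(unname(v["v_m"]), 0)
  ref <- refine_bounded(fit, spec, toy$grid, bound_delta = 0.2)
  expect_identical(ref$A, fit$A)
  expect_identical(ref$refine_objective, 0)
  # shrinking the box collapses the refinement onto the start point
  fx <- make_contaminated_fit()
  spec2 <- refinement_spec(fx$iB, exclusive = list(c(480, 520)))
  tight <- refine_bounded(fx$fit, spec2, fx$ds$spectral_grid,
                          bound_delta = 1e-9)
  expect_lt(max(abs(tight$A - fx$fit$A)), 1e-6)
})

test_that("refinement requires windows and a positive box", {
  fx <- make_contaminated_fit()
  expect_error(refine_bounded(fx$fit, refinement_spec(1),
                              fx$ds$spectral_grid), "skip")
  expect_error(refine_bounded(fx$fit,
                              refinement_spec(1, exclusive = list(c(480, 520))),
                              fx$ds$spectral_grid, bound_delta = 0),
               "bound_delta")
})
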