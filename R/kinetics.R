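#' Declare a benchmark kinetic scenario
#'
#' Four benchmark scenarios are provided.  `uncorrelated3` uses arbitrary
#' smooth time traces that follow no kinetic model.  The two
#' `branched_first_order` scenarios describe a branched reaction
#' A -> B -> D and A -> C -> D with first-order steps; in the 3-species
#' variant the educt A is Raman silent (it contributes to the kinetics but
#' not to the spectra), in the 4-species variant A is Raman active.
#' `second_order3` replaces the consumption of the intermediates by a
#' bimolecular step B + C -> D (A again Raman silent).
#'
#' Two readings of the branched first-order scheme are available via
#' `variant`.  `"as_printed"` integrates a literal variant whose equation
#' for species D carries a `+k4*I_D` production term; that system diverges
#' and never consumes species C, so it is kept only for comparison.  The
#' default `"mass_conserving"` closes the scheme chemically
#' (`dC/dt = k2*A - k4*C`, `dD/dt = k3*B + k4*C`), so that the total
#' concentration is conserved.  The two variants have identical equations
#' for species A and B.
#'
#' @param name one of `"uncorrelated3"`, `"branched_first_order3"`,
#'   `"branched_first_order4"`, `"second_order3"`.
#' @param rate_constants named numeric vector overriding the scenario
#'   defaults (`k1`, `k2`, `k3` and, for first-order scenarios, `k4`).
#'   All rates must be non-negative.
#' @param initial_values named numeric vector of initial concentrations
#'   (default A = 1, all others 0).  Must be non-negative.
#' @param variant `"mass_conserving"` (default) or `"as_printed"`; only
#'   meaningful for the first-order scenarios.
#' @return an object of class `"kinetic_scenario"`.
#' @export
kinetic_scenario <- function(name = c("uncorrelated3",
                                      "branched_first_order3",
                                      "branched_first_order4",
                                      "second_order3"),
                             rate_constants = NULL,
                             initial_values = NULL,
                             variant = c("mass_conserving", "as_printed")) {
  name <- match.arg(name)
  variant <- match.arg(variant)
  defaults <- switch(name,
    uncorrelated3 = list(
      rates = NULL, init = NULL, species = paste0("S", 1:3), silent = character()),
    branched_first_order3 = list(
      rates = c(k1 = 0.05, k2 = 0.1, k3 = 0.01, k4 = 0.1),
      init = c(A = 1, B = 0, C = 0, D = 0),
      species = c("A", "B", "C", "D"), silent = "A"),
    branched_first_order4 = list(
      rates = c(k1 = 0.05, k2 = 0.1, k3 = 0.01, k4 = 0.1),
      init = c(A = 1, B = 0, C = 0, D = 0),
      species = c("A", "B", "C", "D"), silent = character()),
    second_order3 = list(
      rates = c(k1 = 0.05, k2 = 0.025, k3 = 0.1),
      init = c(A = 1, B = 0, C = 0, D = 0),
      species = c("A", "B", "C", "D"), silent = "A"))
  rates <- defaults$rates
  if (!is.null(rate_constants)) {
    if (is.null(rates))
      stop("scenario 'uncorrelated3' has no rate constants", call. = FALSE)
    rates[names(rate_constants)] <- rate_constants
  }
  if (!is.null(rates) && any(rates < 0))
    stop("rate constants must be non-negative", call. = FALSE)
  init <- defaults$init
  if (!is.null(initial_values)) {
    if (is.null(init))
      stop("scenario 'uncorrelated3' has no kinetic initial values",
           call. = FALSE)
    init[names(initial_values)] <- initial_values
  }
  if (!is.null(init) && any(init < 0))
    stop("initial values must be non-negative", call. = FALSE)
  structure(list(name = name, rate_constants = rates, initial_values = init,
                 species = defaults$species, raman_silent = defaults$silent,
                 variant = variant),
            class = "kinetic_scenario")
}

#' @export
print.kinetic_scenario <- function(x, ...) {
  cat("Kinetic scenario:", x$name, "\n")
  if (!is.null(x$rate_constants))
    cat("  rates:  ", paste(names(x$rate_constants), x$rate_constants,
                            sep = " = ", collapse = ", "), "\n")
  if (length(x$raman_silent))
    cat("  Raman-silent species:", paste(x$raman_silent, collapse = ", "), "\n")
  if (x$name %in% c("branched_first_order3", "branched_first_order4"))
    cat("  variant:", x$variant, "\n")
  invisible(x)
}

#' Integrate the branched first-order reaction system
#'
#' Solves the linear ODE system of the branched scheme A -> B -> D,
#' A -> C -> D with the scenario's rate constants and initial values, on
#' the supplied time grid.  Species A always obeys
#' \eqn{dI_A/dt = -(k_1 + k_2) I_A} and species B
#' \eqn{dI_B/dt = k_1 I_A - k_3 I_B}; the equations for C and D depend on
#' the scenario `variant` (see [kinetic_scenario()]).
#'
#' @param scenario a first-order [kinetic_scenario()].
#' @param times strictly increasing time grid.
#' @return numeric matrix with one row per species (named) and one column
#'   per time point.
#' @export
simulate_first_order_branched <- function(scenario, times) {
  stopifnot(inherits(scenario, "kinetic_scenario"))
  if (!scenario$name %in% c("branched_first_order3", "branched_first_order4"))
    stop("scenario is not a branched first-order scenario", call. = FALSE)
  assert_time_grid(times)
  k <- scenario$rate_constants
  as_printed <- identical(scenario$variant, "as_printed")
  rhs <- function(t, y, parms) {
    dA <- -(k[["k1"]] + k[["k2"]]) * y[1]
    dB <- k[["k1"]] * y[1] - k[["k3"]] * y[2]
    if (as_printed) {
      dC <- k[["k2"]] * y[1] - k[["k3"]] * y[3]
      dD <- k[["k3"]] * y[2] + k[["k4"]] * y[4]
    } else {
      dC <- k[["k2"]] * y[1] - k[["k4"]] * y[3]
      dD <- k[["k3"]] * y[2] + k[["k4"]] * y[3]
    }
    list(c(dA, dB, dC, dD))
  }
  integrate_scenario(rhs, scenario, times)
}

#' Integrate the mixed first/second-order reaction system
#'
#' Solves the nonlinear system in which the educt A branches into
#' intermediates B and C by first-order steps and the product D is formed
#' by the bimolecular combination B + C -> D:
#' \deqn{dI_A/dt = -(k_1+k_2) I_A, \quad dI_B/dt = k_1 I_A - k_3 I_B I_C,}
#' \deqn{dI_C/dt = k_2 I_A - k_3 I_B I_C, \quad dI_D/dt = k_3 I_B I_C.}
#' The system is integrated numerically (lsoda, absolute and relative
#' tolerance 1e-10).
#'
#' @inheritParams simulate_first_order_branched
#' @param scenario a [kinetic_scenario()] with name `"second_order3"`.
#' @return numeric matrix, species in rows, time points in columns.
#' @export
simulate_second_order <- function(scenario, times) {
  stopifnot(inherits(scenario, "kinetic_scenario"))
  if (!identical(scenario$name, "second_order3"))
    stop("scenario is not 'second_order3'", call. = FALSE)
  assert_time_grid(times)
  k <- scenario$rate_constants
  rhs <- function(t, y, parms) {
    bc <- k[["k3"]] * y[2] * y[3]
    list(c(-(k[["k1"]] + k[["k2"]]) * y[1],
           k[["k1"]] * y[1] - bc,
           k[["k2"]] * y[1] - bc,
           bc))
  }
  integrate_scenario(rhs, scenario, times)
}

# shared deSolve wrapper: integrates from the scenario's initial values,
# checks the integrator succeeded, clips integration jitter at zero
integrate_scenario <- function(rhs, scenario, times, tol = 1e-10) {
  y0 <- scenario$initial_values
  sol <- deSolve::ode(y = y0, times = times, func = rhs, parms = NULL,
                      method = "lsoda", rtol = tol, atol = tol)
  if (!is.null(attr(sol, "istate")) && attr(sol, "istate")[1] < 0)
    stop("ODE integrator failed to meet its tolerance", call. = FALSE)
  traces <- t(unname(sol[, -1, drop = FALSE]))
  rownames(traces) <- names(y0)
  if (min(traces) < -1e-6)
    stop("integrated traces are substantially negative; check rate constants",
         call. = FALSE)
  traces[traces < 0] <- 0
  traces
}

#' Generate arbitrary smooth non-negative time traces
#'
#' Builds kinetic traces that deliberately follow no kinetic model: each
#' trace is a sum of two Gaussian bumps and one logistic step with seeded
#' random centers, widths and amplitudes.  Traces are strictly
#' non-negative, smooth, pairwise linearly independent (generically) and
#' fully determined by the seed.
#'
#' @param n_components number of traces (>= 1).
#' @param times strictly increasing time grid.
#' @param seed integer seed controlling the random placements.
#' @return numeric matrix, `n_components` rows by `length(times)` columns.
#' @export
make_uncorrelated_traces <- function(n_components, times, seed = 1L) {
  if (n_components < 1L)
    stop("n_components must be >= 1", call. = FALSE)
  assert_time_grid(times)
  span <- diff(range(times))
  t0 <- min(times)
  withr::with_seed(seed, {
    traces <- matrix(0, nrow = n_components, ncol = length(times))
    for (i in seq_len(n_components)) {
      y <- numeric(length(times))
      for (b in 1:2) {                      # localized Gaussian bumps
        center <- t0 + runif(1, 0.05, 0.95) * span
        width <- runif(1, 0.06, 0.2) * span
        amp <- runif(1, 0.3, 1)
        y <- y + amp * exp(-((times - center) / width)^2)
      }
      mid <- t0 + runif(1, 0.2, 0.8) * span # slow logistic drift
      rate <- runif(1, 4, 12) / span
      amp <- runif(1, 0.1, 0.5)
      sgn <- sample(c(-1, 1), 1)
      y <- y + amp / (1 + exp(-sgn * rate * (times - mid)))
      traces[i, ] <- y
    }
    traces
  })
}
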