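# independent oracles and shared fixtures for the test suite

# fixed-step classical RK4 integrator, independent of deSolve
rk4_integrate <- function(deriv, y0, times, substeps = 1000L) {
  out <- matrix(NA_real_, nrow = length(y0), ncol = length(times))
  rownames(out) <- names(y0)
  y <- y0
  out[, 1] <- y
  for (i in seq_len(length(times) - 1L)) {
    h <- (times[i + 1L] - times[i]) / substeps
    t <- times[i]
    for (s in seq_len(substeps)) {
      k1 <- deriv(t, y)
      k2 <- deriv(t + h / 2, y + h / 2 * k1)
      k3 <- deriv(t + h / 2, y + h / 2 * k2)
      k4 <- deriv(t + h, y + h * k3)
      y <- y + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
      t <- t + h
    }
    out[, i + 1L] <- y
  }
  out
}

# recursive permutation enumeration, independent of the package internals:
# insert n at every position of every permutation of n - 1 elements
enumerate_permutations <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (p in enumerate_permutations(n - 1L))
    for (pos in 0:(n - 1L))
      out[[length(out) + 1L]] <- as.integer(append(p, n, after = pos))
  out
}

# small two-component toy with disjoint-support spectra and distinct traces
make_r2_toy <- function() {
  grid <- seq(100, 400, length.out = 80)
  times <- seq(0, 20, length.out = 40)
  W <- cbind(lorentzian_spectrum(data.frame(center = 150, hwhm = 8,
                                            amplitude = 1), grid),
             lorentzian_spectrum(data.frame(center = 330, hwhm = 8,
                                            amplitude = 1), grid))
  # truncate the far tails so the supports are numerically disjoint
  W[grid > 250, 1] <- 0
  W[grid < 250, 2] <- 0
  chi <- rbind(exp(-0.1 * times), 1 - exp(-0.2 * times))
  list(M = W %*% chi, W = W, chi = chi, grid = grid, times = times)
}

# independent windowed trapezoidal integral (mirrors the quadrature contract)
trap_int <- function(grid, y, a, b) {
  idx <- which(grid >= a & grid <= b)
  pracma::trapz(grid[idx], y[idx])
}

# memoized heavy pipeline runs shared between acceptance criteria
.pipeline_cache <- new.env(parent = emptyenv())
cached <- function(key, expr) {
  if (!exists(key, envir = .pipeline_cache))
    assign(key, force(expr), envir = .pipeline_cache)
  get(key, envir = .pipeline_cache)
}
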