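#' Default wavenumber grid for the synthetic scenarios
#'
#' 1000 evenly spaced points on a Raman-like wavenumber axis
#' (200--1800 cm^-1-like units).
#' @return numeric vector of length 1000.
#' @export
default_spectral_grid <- function() seq(200, 1800, length.out = 1000)

#' Default time grid for the synthetic scenarios
#'
#' 172 evenly spaced time points (0, 1, ..., 171 in arbitrary time units).
#' The span is long enough that the slowest default rate constant
#' (k3 = 0.01 per time unit) shows visible decay (exp(-0.01*171) ~ 0.18).
#' @return numeric vector of length 172.
#' @export
default_time_grid <- function() seq(0, 171, by = 1)

#' Default Lorentzian peak lists for a scenario
#'
#' Each Raman-active species carries 2--3 Lorentzian bands at
#' package-defined positions, chosen to realize the qualitative features
#' the benchmark scenarios are meant to probe:
#' partly overlapping bands within the uncorrelated scenario, very similar
#' band patterns for the intermediates B and C of the branched first-order
#' reaction (C's bands are B's shifted by 40 units), a spectrally separated
#' product D, and low overlap throughout the second-order scenario.  Every
#' species retains at least one band free of the others (separability).
#'
#' @param name scenario name, see [kinetic_scenario()].
#' @return named list (one element per Raman-active species) of peak data
#'   frames with columns `center`, `hwhm`, `amplitude`.
#' @export
default_peak_lists <- function(name = c("uncorrelated3",
                                        "branched_first_order3",
                                        "branched_first_order4",
                                        "second_order3")) {
  name <- match.arg(name)
  pk <- function(...) {
    m <- matrix(c(...), ncol = 3, byrow = TRUE)
    data.frame(center = m[, 1], hwhm = m[, 2], amplitude = m[, 3])
  }
  switch(name,
    uncorrelated3 = list(
      S1 = pk(400, 12, 1.0,   620, 10, 0.6,  1150, 15, 0.8),
      S2 = pk(520, 12, 0.9,   648, 12, 0.4,   810, 14, 1.0),
      S3 = pk(980, 12, 1.0,  1420, 16, 0.7,  1660, 10, 0.9)),
    branched_first_order3 = list(
      B = pk(500, 10, 1.0,   780, 12, 0.6,  1320, 14, 0.8),
      C = pk(540, 10, 0.9,   820, 12, 0.7,  1360, 14, 0.6),
      D = pk(1000, 12, 1.0, 1620, 14, 0.8)),
    branched_first_order4 = list(
      A = pk(300, 14, 0.9,   880, 10, 0.5,  1750, 10, 0.6),
      B = pk(500, 10, 1.0,   780, 12, 0.6,  1320, 14, 0.8),
      C = pk(540, 10, 0.9,   820, 12, 0.7,  1360, 14, 0.6),
      D = pk(1000, 12, 1.0, 1620, 14, 0.8)),
    second_order3 = list(
      B = pk(450, 10, 1.0,  1250, 12, 0.7),
      C = pk(700, 10, 0.9,  1450, 12, 0.8),
      D = pk(950, 10, 1.0,  1650, 12, 0.6)))
}

#' Assemble a synthetic dataset with known ground truth
#'
#' Builds the data matrix `M = W_true %*% chi_true` for a benchmark
#' scenario: component spectra are sums of Lorentzian bands
#' ([lorentzian_spectrum()]), kinetic traces come either from the
#' scenario's ODE system or, for `uncorrelated3`, from
#' [make_uncorrelated_traces()].  Raman-silent species are excluded from
#' both factors (they shape the kinetics of the visible species but do not
#' contribute a spectrum).  Optional i.i.d. Gaussian noise is added with
#' [add_noise()].
#'
#' @param scenario a [kinetic_scenario()] or a scenario name.
#' @param spectral_grid wavenumber grid (default [default_spectral_grid()]).
#' @param time_grid time grid (default [default_time_grid()]).
#' @param seed integer seed for the uncorrelated traces and the noise.
#' @param noise_sigma Gaussian noise standard deviation, as a fraction of
#'   `max(M)` (0 = noiseless).
#' @param peak_lists per-species peak data frames; default
#'   [default_peak_lists()].
#' @return object of class `"nmf_dataset"`: list with elements `M`,
#'   `W_true` (m x r), `chi_true` (r x n), `spectral_grid`, `time_grid`,
#'   `species` (Raman-active species names), `scenario`, `noise_sigma`,
#'   `seed`.
#' @examples
#' ds <- assemble_dataset("uncorrelated3", seed = 1)
#' dim(ds$M)  # 1000 x 172
#' @export
assemble_dataset <- function(scenario,
                             spectral_grid = default_spectral_grid(),
                             time_grid = default_time_grid(),
                             seed = 1L,
                             noise_sigma = 0,
                             peak_lists = NULL) {
  if (is.character(scenario)) scenario <- kinetic_scenario(scenario)
  stopifnot(inherits(scenario, "kinetic_scenario"))
  assert_spectral_grid(spectral_grid)
  assert_time_grid(time_grid)
  if (is.null(peak_lists)) peak_lists <- default_peak_lists(scenario$name)

  chi <- switch(scenario$name,
    uncorrelated3 = {
      tr <- make_uncorrelated_traces(length(scenario$species), time_grid,
                                     seed = seed)
      rownames(tr) <- scenario$species
      tr
    },
    branched_first_order3 = ,
    branched_first_order4 = simulate_first_order_branched(scenario, time_grid),
    second_order3 = simulate_second_order(scenario, time_grid))

  active <- setdiff(rownames(chi), scenario$raman_silent)
  missing <- setdiff(active, names(peak_lists))
  if (length(missing))
    stop("no peak list for Raman-active species: ",
         paste(missing, collapse = ", "), call. = FALSE)
  chi <- chi[active, , drop = FALSE]
  W <- vapply(active, function(sp)
    lorentzian_spectrum(peak_lists[[sp]], spectral_grid),
    numeric(length(spectral_grid)))
  M <- W %*% chi
  if (noise_sigma > 0)
    M <- add_noise(M, sigma = noise_sigma, seed = seed)
  structure(list(M = M, W_true = W, chi_true = chi,
                 spectral_grid = spectral_grid, time_grid = time_grid,
                 species = active, scenario = scenario,
                 noise_sigma = noise_sigma, seed = as.integer(seed)),
            class = "nmf_dataset")
}

#' @export
print.nmf_dataset <- function(x, ...) {
  cat(sprintf("Synthetic dataset '%s': %d x %d matrix, %d components\n",
              x$scenario$name, nrow(x$M), ncol(x$M), ncol(x$W_true)))
  cat(sprintf("  species: %s; noise sigma: %g; seed: %d\n",
              paste(x$species, collapse = ", "), x$noise_sigma, x$seed))
  invisible(x)
}

#' Add Gaussian noise to a data matrix
#'
#' Adds i.i.d. Gaussian noise with standard deviation `sigma * max(M)`.
#' By default the result is clipped at zero so the matrix stays a valid
#' non-negative input for the factorization.
#'
#' @param M numeric matrix.
#' @param sigma noise level as a fraction of the matrix maximum (>= 0).
#' @param seed integer seed.
#' @param clip clip negative entries at zero (default `TRUE`).
#' @return matrix of the same shape.
#' @export
add_noise <- function(M, sigma, seed = 1L, clip = TRUE) {
  assert_matrix(M)
  if (sigma < 0) stop("sigma must be >= 0", call. = FALSE)
  if (sigma == 0) return(M)
  out <- withr::with_seed(seed,
    M + rnorm(length(M), sd = sigma * max(M)))
  if (clip) out[out < 0] <- 0
  out
}

#' Add a smooth time-constant baseline to a data matrix
#'
#' Emulates a slowly varying background (e.g. fluorescence under Raman
#' bands): the same smooth baseline curve is added to every column.
#' `"broad_gaussian"` uses a wide Gaussian centered on the grid;
#' `"polynomial"` uses a gently decreasing quadratic.
#'
#' @param M numeric matrix (rows = wavenumbers).
#' @param amplitude peak baseline intensity (>= 0).
#' @param shape `"broad_gaussian"` (default) or `"polynomial"`.
#' @param grid wavenumber grid of the rows; defaults to row indices.
#' @return matrix of the same shape.
#' @export
add_background <- function(M, amplitude,
                           shape = c("broad_gaussian", "polynomial"),
                           grid = seq_len(nrow(M))) {
  assert_matrix(M)
  shape <- match.arg(shape)
  if (amplitude < 0) stop("amplitude must be >= 0", call. = FALSE)
  if (amplitude == 0) return(M)
  x <- (grid - min(grid)) / diff(range(grid))  # grid mapped to [0, 1]
  base <- switch(shape,
    broad_gaussian = amplitude * exp(-((x - 0.5) / 0.35)^2),
    polynomial = amplitude * (1 - 0.6 * x + 0.2 * x^2) / 1)
  M + base
}
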