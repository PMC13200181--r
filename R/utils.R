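# internal validation helpers shared across modules

assert_spectral_grid <- function(grid) {
  if (!is.numeric(grid) || length(grid) < 2L)
    stop("spectral grid must be numeric with at least 2 points", call. = FALSE)
  if (anyNA(grid) || any(!is.finite(grid)))
    stop("spectral grid contains non-finite values", call. = FALSE)
  if (any(diff(grid) <= 0))
    stop("spectral grid must be strictly increasing", call. = FALSE)
  invisible(grid)
}

assert_time_grid <- function(times) {
  if (!is.numeric(times) || length(times) < 2L)
    stop("time grid must be numeric with at least 2 points", call. = FALSE)
  if (anyNA(times) || any(!is.finite(times)))
    stop("time grid contains non-finite values", call. = FALSE)
  if (any(diff(times) <= 0))
    stop("time grid must be strictly increasing", call. = FALSE)
  invisible(times)
}

assert_matrix <- function(M, name = "M") {
  if (!is.matrix(M) || !is.numeric(M))
    stop(sprintf("'%s' must be a numeric matrix", name), call. = FALSE)
  if (anyNA(M) || any(!is.finite(M)))
    stop(sprintf("'%s' contains non-finite entries", name), call. = FALSE)
  invisible(M)
}

# trapezoidal integral of y over the sub-grid falling inside [a, b]
window_integral <- function(grid, y, a, b) {
  idx <- which(grid >= a & grid <= b)
  if (length(idx) < 2L)
    stop(sprintf("window [%g, %g] covers fewer than 2 grid points", a, b),
         call. = FALSE)
  pracma::trapz(grid[idx], y[idx])
}
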