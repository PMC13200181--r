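#' Declare spectral windows for the refinement stage
#'
#' A refinement spec attaches prior spectral knowledge to one species:
#' `exclusive` windows `[a, b]` are wavenumber intervals where only this
#' species is expected to contribute, `absence` windows `[c, d]` are
#' intervals where this species is expected not to contribute.
#'
#' @param species column index of the species in the spectral factor.
#' @param exclusive list of numeric `c(a, b)` intervals (may be empty).
#' @param absence list of numeric `c(c, d)` intervals (may be empty).
#' @return object of class `"refinement_spec"`.
#' @export
refinement_spec <- function(species, exclusive = list(), absence = list()) {
  check_iv <- function(iv, what) {
    lapply(iv, function(w) {
      if (length(w) != 2L || !is.numeric(w) || w[1] >= w[2])
        stop(sprintf("%s windows must be numeric intervals c(a, b) with a < b",
                     what), call. = FALSE)
      w
    })
  }
  structure(list(species = as.integer(species),
                 exclusive = check_iv(exclusive, "exclusive"),
                 absence = check_iv(absence, "absence")),
            class = "refinement_spec")
}

#' Window penalties for one species
#'
#' For species m with exclusive windows `[a, b]`, the penalty
#' \eqn{v_m = \sum_{i \neq m} \int_a^b |S_i(f)|\, df} integrates the
#' absolute intensity of all *other* species over the windows claimed by
#' m (trapezoidal rule on the native grid); it is zero when the windows
#' are clean.  For absence windows `[c, d]` the penalty as defined is
#' \eqn{v'_m = -\sum_{i \neq m} \int_c^d |S_i(f)|\, df}, i.e. other
#' species are rewarded for carrying the intensity there; with
#' `penalize_self = TRUE` the species' own intensity in its absence
#' windows is penalized (positively) instead.
#'
#' @param W spectral factor (m x r, species as columns).
#' @param spec a [refinement_spec()].
#' @param grid wavenumber grid of the rows of `W`.
#' @param penalize_self alternative absence-window reading (default
#'   `FALSE`, the definition above).
#' @return named numeric `c(v_m, v_m_prime)`.
#' @export
window_penalties <- function(W, spec, grid, penalize_self = FALSE) {
  stopifnot(inherits(spec, "refinement_spec"))
  assert_spectral_grid(grid)
  if (nrow(W) != length(grid))
    stop("W and grid disagree on the number of wavenumber points",
         call. = FALSE)
  m <- spec$species
  if (m < 1L || m > ncol(W))
    stop("species index outside the spectral factor", call. = FALSE)
  rng <- range(grid)
  check_window <- function(w) {
    if (w[1] < rng[1] || w[2] > rng[2])
      stop(sprintf("window [%g, %g] lies outside the spectral grid [%g, %g]",
                   w[1], w[2], rng[1], rng[2]), call. = FALSE)
  }
  others <- setdiff(seq_len(ncol(W)), m)
  v_m <- 0
  for (w in spec$exclusive) {
    check_window(w)
    for (i in others)
      v_m <- v_m + window_integral(grid, abs(W[, i]), w[1], w[2])
  }
  v_mp <- 0
  for (w in spec$absence) {
    check_window(w)
    if (penalize_self) {
      v_mp <- v_mp + window_integral(grid, abs(W[, m]), w[1], w[2])
    } else {
      for (i in others)
        v_mp <- v_mp - window_integral(grid, abs(W[, i]), w[1], w[2])
    }
  }
  c(v_m = v_m, v_m_prime = v_mp)
}

# combined refinement objective over one or several specs
refine_objective <- function(A, W0, specs, grid, penalize_self = FALSE) {
  W <- W0 %*% A
  sum(vapply(specs, function(sp)
    sum(window_penalties(W, sp, grid, penalize_self = penalize_self)),
    numeric(1)))
}

#' Bounded re-optimization with spectral windows
#'
#' Second optimization stage: starting from the transformation matrix of
#' a completed factorization, minimizes the window objective
#' `v = v_m + v'_m` (summed over the supplied specs) with a single
#' bounded downhill-simplex search.  The search is confined to the
#' element-wise box `|A - A_f| <= bound_delta * (|A_f| + median(|A_f|))`
#' around the stage-one solution `A_f` — the stage-one result is assumed
#' to be already close to the truth, and the box also keeps the negated
#' absence-window term bounded.  Candidate points are projected onto the
#' box before evaluation.  The returned solution never has a worse window
#' objective than `A_f`; if no strict improvement is found, `A_f` itself
#' is returned.
#'
#' @param fit an `"nmf_fit"` from [optimize_transform()] or
#'   [decompose()].
#' @param specs a [refinement_spec()] or a list of them (their objectives
#'   are summed).
#' @param grid wavenumber grid of the spectral rows.
#' @param bound_delta relative half-width of the search box (default
#'   0.2).
#' @param penalize_self see [window_penalties()].
#' @param maxit function-evaluation cap of the simplex search (default
#'   `400 * r^2`).
#' @return object of class `"nmf_refined"`: the input fit with updated
#'   `W`, `chi`, `A`, plus `refine_objective` (value after refinement),
#'   `refine_objective_start` (value at `A_f`), `bounds` (list of
#'   element-wise `lower`/`upper` matrices) and `specs`.
#' @export
refine_bounded <- function(fit, specs, grid, bound_delta = 0.2,
                           penalize_self = FALSE, maxit = NULL) {
  stopifnot(inherits(fit, "nmf_fit"))
  if (inherits(specs, "refinement_spec")) specs <- list(specs)
  if (length(specs) == 0L ||
      all(vapply(specs, function(s)
        length(s$exclusive) + length(s$absence) == 0L, logical(1))))
    stop("no spectral windows declared: skip the refinement stage",
         call. = FALSE)
  if (bound_delta <= 0) stop("bound_delta must be > 0", call. = FALSE)
  r <- fit$r
  if (is.null(maxit)) maxit <- 400L * r * r
  A_f <- fit$A
  half <- bound_delta * (abs(A_f) + median(abs(A_f)))
  lower <- A_f - half
  upper <- A_f + half
  cap <- fit$cfg$condition_cap
  sentinel <- fit$cfg$sentinel
  project <- function(par) pmin(pmax(par, as.vector(lower)),
                                as.vector(upper))
  fn <- function(par) {
    A <- matrix(project(par), r, r)
    rc <- rcond(A)
    if (!is.finite(rc) || rc < 1 / cap) return(sentinel)
    refine_objective(A, fit$W0, specs, grid, penalize_self = penalize_self)
  }
  v0 <- refine_objective(A_f, fit$W0, specs, grid,
                         penalize_self = penalize_self)
  res <- if (r == 1L) list(par = as.vector(A_f), value = v0) else
    optim(as.vector(A_f), fn, method = "Nelder-Mead",
          control = list(reltol = 1e-10, maxit = maxit))
  if (res$value < v0) {
    A_new <- matrix(project(res$par), r, r)
    v_new <- res$value
  } else {
    A_new <- A_f
    v_new <- v0
  }
  rec <- reconstruct(fit$W0, fit$chi0, A_new, condition_cap = cap)
  out <- fit
  out$W <- rec$W
  out$chi <- rec$chi
  out$A <- A_new
  out$penalties <- penalty_breakdown(A_new, fit$W0, fit$chi0, fit$cfg)
  out$objective <- sum(out$penalties)
  out$refine_objective <- v_new
  out$refine_objective_start <- v0
  out$bounds <- list(lower = lower, upper = upper)
  out$specs <- specs
  class(out) <- c("nmf_refined", "nmf_fit")
  out
}

#' @export
print.nmf_refined <- function(x, ...) {
  cat(sprintf("Refined factorization: rank %d\n", x$r))
  cat(sprintf("  window objective %.6g (was %.6g at the stage-one solution)\n",
              x$refine_objective, x$refine_objective_start))
  invisible(x)
}
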