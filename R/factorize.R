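#' SVD initialization of the factorization
#'
#' Computes a truncated singular value decomposition `M = U S V'` and
#' returns `W0 = U S` (spectral factor) and `chi0 = V'` (kinetic factor),
#' so that `W0 %*% chi0` is the best rank-`k` approximation of `M` and
#' reproduces `M` exactly when the numerical rank of `M` is at most `k`.
#' A deterministic sign convention is applied: the largest-magnitude entry
#' of each column of `W0` is made positive (flipping the matching row of
#' `chi0`), so results are reproducible across runs and platforms.
#'
#' @param M non-negative numeric data matrix (rows = wavenumbers,
#'   columns = time points).
#' @param k number of components to retain (default 10; must not exceed
#'   either matrix dimension).
#' @return object of class `"nmf_init"`: list with `W0` (m x k), `chi0`
#'   (k x n), `singular_values` (length k, non-increasing) and `k`.
#' @export
svd_initialize <- function(M, k = 10L) {
  assert_matrix(M)
  if (min(M) < 0)
    stop("data matrix has negative entries; the factorization requires a ",
         "non-negative input matrix", call. = FALSE)
  k <- as.integer(k)
  if (k < 1L || k > min(dim(M)))
    stop(sprintf("k = %d exceeds the matrix dimensions %d x %d",
                 k, nrow(M), ncol(M)), call. = FALSE)
  dec <- svd(M, nu = k, nv = k)
  d <- dec$d[seq_len(k)]
  W0 <- dec$u %*% diag(d, nrow = k)
  chi0 <- t(dec$v)
  for (j in seq_len(k)) {               # deterministic sign convention
    i <- which.max(abs(W0[, j]))
    if (W0[i, j] < 0) {
      W0[, j] <- -W0[, j]
      chi0[j, ] <- -chi0[j, ]
    }
  }
  structure(list(W0 = W0, chi0 = chi0, singular_values = d, k = k),
            class = "nmf_init")
}

#' @export
print.nmf_init <- function(x, ...) {
  cat(sprintf("SVD initialization: %d components for a %d x %d matrix\n",
              x$k, nrow(x$W0), ncol(x$chi0)))
  cat("singular values:\n")
  print(signif(x$singular_values, 4))
  invisible(x)
}

# truncate an nmf_init to rank r
truncate_factors <- function(init, r) {
  stopifnot(inherits(init, "nmf_init"))
  r <- as.integer(r)
  if (r < 1L || r > init$k)
    stop(sprintf("rank %d outside 1..%d", r, init$k), call. = FALSE)
  list(W0 = init$W0[, seq_len(r), drop = FALSE],
       chi0 = init$chi0[seq_len(r), , drop = FALSE])
}

#' Suggest the number of components from singular values
#'
#' Scans for the clearest drop-off in the singular-value sequence: the
#' suggestion is the index `i` maximizing `s_i / s_{i+1}`.  The choice of
#' rank remains a user decision; the suggestion is flagged as low
#' confidence when no ratio is at least `min_ratio`.
#'
#' @param singular_values non-increasing, non-negative numeric vector
#'   (length >= 2).
#' @param min_ratio smallest drop-off ratio counted as a clear gap
#'   (default 3).
#' @return list with `suggestion` (integer), `confident` (logical) and
#'   `table` (data frame of singular values and drop-off ratios).
#' @export
estimate_rank <- function(singular_values, min_ratio = 3) {
  s <- singular_values
  if (length(s) < 2L)
    stop("need at least 2 singular values", call. = FALSE)
  if (all(s == 0))
    stop("all singular values are zero", call. = FALSE)
  eps <- 1e-300
  ratios <- s[-length(s)] / pmax(s[-1], eps * s[1])
  suggestion <- which.max(ratios)
  structure(list(suggestion = as.integer(suggestion),
                 confident = max(ratios) >= min_ratio,
                 table = data.frame(component = seq_along(s),
                                    singular_value = s,
                                    dropoff_ratio = c(ratios, NA))),
            class = "rank_estimate")
}

#' @export
print.rank_estimate <- function(x, ...) {
  print(x$table, row.names = FALSE)
  cat(sprintf("suggested rank: %d%s\n", x$suggestion,
              if (x$confident) "" else " (low confidence: no clear drop-off)"))
  invisible(x)
}

#' Penalty configuration for the factorization objective
#'
#' The objective is `v = v1 + v2 + v3`: `v1` penalizes the squared
#' distance of the smallest entry of the spectral factor from zero, `v2`
#' the magnitude of the most negative entry of the kinetic factor, and
#' `v3` the overlap between component spectra, weighted by `0 <= a <= 1`.
#'
#' Two overlap modes are available.  The default `"normalized_offdiag"`
#' sums the cosine similarities of all pairs of absolute spectra: this is
#' invariant under rescaling of the factorization, which removes the scale
#' degeneracy of the raw Gram-matrix norm (shrinking all of `W` while
#' inflating `chi` would otherwise lower the penalty without changing the
#' factorization).  `"literal_gram"` takes the Frobenius norm of
#' `|W|' |W|` including the diagonal self-overlap terms.
#'
#' @param overlap_weight weighting coefficient `a` in `[0, 1]`
#'   (default 0.1).
#' @param overlap_mode `"normalized_offdiag"` (default) or
#'   `"literal_gram"`.
#' @param use_v1,use_v2,use_v3 include the individual penalties
#'   (all `TRUE` by default).
#' @param condition_cap largest accepted condition number of the
#'   transformation matrix (default 1e8).
#' @param sentinel objective value returned for transformation matrices
#'   beyond the condition cap (default 1e10); such points are made
#'   unattractive to the optimizer instead of raising an error.
#' @return object of class `"penalty_config"`.
#' @export
penalty_config <- function(overlap_weight = 0.1,
                           overlap_mode = c("normalized_offdiag",
                                            "literal_gram"),
                           use_v1 = TRUE, use_v2 = TRUE, use_v3 = TRUE,
                           condition_cap = 1e8, sentinel = 1e10) {
  overlap_mode <- match.arg(overlap_mode)
  if (overlap_weight < 0 || overlap_weight > 1)
    stop("overlap_weight must lie in [0, 1]", call. = FALSE)
  structure(list(overlap_weight = overlap_weight,
                 overlap_mode = overlap_mode,
                 use_v1 = use_v1, use_v2 = use_v2, use_v3 = use_v3,
                 condition_cap = condition_cap, sentinel = sentinel),
            class = "penalty_config")
}

#' Non-negativity penalty on the spectral factor
#'
#' `v1 = min(W)^2`: the squared smallest entry of the whole matrix.  Note
#' that a strictly positive minimum is penalized as well — the penalty
#' drives the global minimum of the spectral factor towards zero, i.e.
#' spectra whose baselines touch zero.
#'
#' @param W spectral factor (m x r).
#' @return non-negative scalar.
#' @export
penalty_nonneg_spectra <- function(W) min(W)^2

#' Non-negativity penalty on the kinetic factor
#'
#' `v2 = -min(min(chi), 0)`: the magnitude of the most negative entry,
#' zero when the kinetic factor is elementwise non-negative.
#'
#' @param chi kinetic factor (r x n).
#' @return non-negative scalar; zero iff `chi >= 0` everywhere.
#' @export
penalty_nonneg_kinetics <- function(chi) max(-min(chi), 0)

#' Spectral overlap penalty
#'
#' See [penalty_config()] for the two modes.  In the default normalized
#' mode the penalty is `a * sum_{i<j} cos(|W_i|, |W_j|)`; a single
#' component gives zero and a zero column is an error (its cosine is
#' undefined).  In `"literal_gram"` mode the penalty is
#' `a * ||\, |W|' |W| \,||_F`.
#'
#' @param W spectral factor (m x r).
#' @param cfg a [penalty_config()].
#' @return non-negative scalar.
#' @export
penalty_overlap <- function(W, cfg = penalty_config()) {
  stopifnot(inherits(cfg, "penalty_config"))
  a <- cfg$overlap_weight
  aW <- abs(W)
  G <- crossprod(aW)
  if (identical(cfg$overlap_mode, "literal_gram"))
    return(a * norm(G, "F"))
  nrm <- sqrt(diag(G))
  if (any(nrm == 0))
    stop("zero spectral column: cosine overlap is undefined", call. = FALSE)
  C <- G / tcrossprod(nrm)
  a * sum(C[upper.tri(C)])
}

#' Penalty objective over the transformation matrix
#'
#' For a candidate transformation matrix `A`, forms `W = W0 %*% A` and
#' solves `A %*% chi = chi0` for `chi` (no explicit inverse), then returns
#' the sum of the enabled penalties.  If `A`'s condition number exceeds
#' the configured cap (or a zero spectral column arises), the sentinel
#' value is returned so that the optimizer steers away from such points
#' without an exception.
#'
#' @param A r x r transformation matrix, or a numeric vector of length
#'   r^2 (column-major), as passed by the optimizer.
#' @param W0 truncated spectral initialization (m x r).
#' @param chi0 truncated kinetic initialization (r x n).
#' @param cfg a [penalty_config()].
#' @return scalar objective value `v = v1 + v2 + v3` (or the sentinel).
#' @export
nmf_objective <- function(A, W0, chi0, cfg = penalty_config()) {
  r <- ncol(W0)
  if (!is.matrix(A)) A <- matrix(A, r, r)
  if (nrow(A) != r || ncol(A) != r || nrow(chi0) != r)
    stop("shape mismatch between A, W0 and chi0", call. = FALSE)
  if (!all(is.finite(A))) return(cfg$sentinel)
  rc <- rcond(A)
  if (!is.finite(rc) || rc < 1 / cfg$condition_cap) return(cfg$sentinel)
  W <- W0 %*% A
  chi <- solve(A, chi0)
  v <- 0
  if (cfg$use_v1) v <- v + penalty_nonneg_spectra(W)
  if (cfg$use_v2) v <- v + penalty_nonneg_kinetics(chi)
  if (cfg$use_v3) {
    v3 <- tryCatch(penalty_overlap(W, cfg), error = function(e) NA_real_)
    if (is.na(v3)) return(cfg$sentinel)
    v <- v + v3
  }
  v
}

# penalty breakdown at a given A (assumes A within the condition cap)
penalty_breakdown <- function(A, W0, chi0, cfg) {
  W <- W0 %*% A
  chi <- solve(A, chi0)
  c(v1 = if (cfg$use_v1) penalty_nonneg_spectra(W) else 0,
    v2 = if (cfg$use_v2) penalty_nonneg_kinetics(chi) else 0,
    v3 = if (cfg$use_v3) penalty_overlap(W, cfg) else 0)
}

#' Multi-start optimization of the transformation matrix
#'
#' Runs `restarts` independent minimizations of the penalty objective
#' ([nmf_objective()]) over the entries of the r x r transformation
#' matrix.  Each restart initializes `A` with i.i.d. uniform entries on
#' `[-1, 1]` (redrawn while the condition cap is exceeded) and runs a
#' derivative-free downhill-simplex (Nelder-Mead) search.  The
#' factorization with the overall lowest objective across restarts is
#' returned; per-restart best values and the running best are logged.
#'
#' @param W0 truncated spectral initialization (m x r).
#' @param chi0 truncated kinetic initialization (r x n).
#' @param cfg a [penalty_config()].
#' @param restarts number of independent random restarts (default 1000).
#' @param seed integer seed making the whole search reproducible.
#' @param reltol relative convergence tolerance of each simplex search
#'   (default 1e-10).
#' @param maxit cap on function evaluations per restart (default
#'   `200 * r^2`).
#' @param polish re-run the simplex search once from the overall best
#'   point with a fresh simplex and a larger evaluation budget
#'   (default `TRUE`); deterministic, and never worsens the result.
#' @return object of class `"nmf_fit"`: list with `W` (m x r spectra as
#'   columns), `chi` (r x n kinetics as rows), `A` (the optimal
#'   transformation matrix), `objective`, `penalties` (named c(v1, v2,
#'   v3)), `restart_log` (per-restart best objective), `running_best`
#'   (non-increasing), `r`, `seed`, `cfg`, and the inputs `W0`, `chi0`.
#' @export
optimize_transform <- function(W0, chi0, cfg = penalty_config(),
                               restarts = 1000L, seed = 1L,
                               reltol = 1e-10, maxit = NULL,
                               polish = TRUE) {
  assert_matrix(W0, "W0"); assert_matrix(chi0, "chi0")
  r <- ncol(W0)
  if (nrow(chi0) != r)
    stop("W0 and chi0 disagree on the rank", call. = FALSE)
  restarts <- as.integer(restarts)
  if (restarts < 1L) stop("restarts must be >= 1", call. = FALSE)
  if (is.null(maxit)) maxit <- 200L * r * r
  fn <- function(par) nmf_objective(par, W0, chi0, cfg)
  withr::with_seed(seed, {
    best_val <- Inf
    best_par <- NULL
    log_vals <- numeric(restarts)
    for (i in seq_len(restarts)) {
      repeat {
        par0 <- runif(r * r, -1, 1)
        if (rcond(matrix(par0, r, r)) >= 1 / cfg$condition_cap) break
      }
      res <- if (r == 1L) {
        optim(par0, fn, method = "Brent", lower = -10, upper = 10)
      } else {
        optim(par0, fn, method = "Nelder-Mead",
              control = list(reltol = reltol, maxit = maxit))
      }
      log_vals[i] <- res$value
      if (res$value < best_val) {   # strict: first encountered wins ties
        best_val <- res$value
        best_par <- res$par
      }
    }
  })
  if (polish && r > 1L) {
    res <- optim(best_par, fn, method = "Nelder-Mead",
                 control = list(reltol = reltol, maxit = 10L * maxit))
    if (res$value < best_val) {
      best_val <- res$value
      best_par <- res$par
    }
  }
  A <- matrix(best_par, r, r)
  W <- W0 %*% A
  chi <- solve(A, chi0)
  structure(list(W = W, chi = chi, A = A, objective = best_val,
                 penalties = penalty_breakdown(A, W0, chi0, cfg),
                 restart_log = log_vals, running_best = cummin(log_vals),
                 r = r, seed = as.integer(seed), cfg = cfg,
                 W0 = W0, chi0 = chi0),
            class = "nmf_fit")
}

#' @export
print.nmf_fit <- function(x, ...) {
  cat(sprintf("NMF factorization: rank %d, %d restarts, seed %d\n",
              x$r, length(x$restart_log), x$seed))
  cat(sprintf("  objective %.6g  (v1 %.3g, v2 %.3g, v3 %.3g)\n",
              x$objective, x$penalties["v1"], x$penalties["v2"],
              x$penalties["v3"]))
  cat(sprintf("  min(W) = %.3g, min(chi) = %.3g\n", min(x$W), min(x$chi)))
  invisible(x)
}

#' Reconstruct spectra and kinetics from a transformation matrix
#'
#' `W = W0 %*% A`; `chi` solves `A %*% chi = chi0` (computed by linear
#' solve, never by forming the inverse).  The product `W %*% chi` equals
#' `W0 %*% chi0` up to round-off for every `A` within the condition cap —
#' the factorization is exact by construction.
#'
#' @inheritParams nmf_objective
#' @param condition_cap largest accepted condition number (default 1e8).
#' @return list with elements `W` and `chi`.
#' @export
reconstruct <- function(W0, chi0, A, condition_cap = 1e8) {
  r <- ncol(W0)
  if (!is.matrix(A)) A <- matrix(A, r, r)
  rc <- rcond(A)
  if (!is.finite(rc) || rc < 1 / condition_cap)
    stop(sprintf(paste0("transformation matrix exceeds the condition cap ",
                        "%.3g (estimated condition %.3g)"),
                 condition_cap, 1 / rc), call. = FALSE)
  list(W = W0 %*% A, chi = solve(A, chi0))
}

#' Full decomposition of a data matrix
#'
#' Convenience pipeline: SVD initialization, truncation to the requested
#' rank and multi-start optimization of the transformation matrix.  The
#' rank is a user decision; see [estimate_rank()] for the drop-off
#' heuristic.
#'
#' @param M non-negative data matrix, or an `"nmf_dataset"` from
#'   [assemble_dataset()].
#' @param rank number of components r.
#' @param k number of SVD components computed before truncation
#'   (default 10, reduced automatically for small matrices).
#' @inheritParams optimize_transform
#' @return an `"nmf_fit"` (see [optimize_transform()]) with the
#'   initialization stored in attribute fields `init`.
#' @examples
#' \donttest{
#' ds <- assemble_dataset("uncorrelated3", seed = 1)
#' fit <- decompose(ds$M, rank = 3, restarts = 50, seed = 1)
#' }
#' @export
decompose <- function(M, rank, k = 10L, cfg = penalty_config(),
                      restarts = 1000L, seed = 1L, reltol = 1e-10,
                      maxit = NULL, polish = TRUE) {
  if (inherits(M, "nmf_dataset")) M <- M$M
  k <- min(as.integer(k), dim(M))
  if (rank > k)
    stop("rank must not exceed the number of SVD components k",
         call. = FALSE)
  init <- svd_initialize(M, k = k)
  tf <- truncate_factors(init, rank)
  fit <- optimize_transform(tf$W0, tf$chi0, cfg = cfg, restarts = restarts,
                            seed = seed, reltol = reltol, maxit = maxit,
                            polish = polish)
  fit$init <- init
  fit
}
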