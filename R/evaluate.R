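#' Normalize spectra and kinetics for display
#'
#' Any exact factorization is determined only up to a positive diagonal
#' rescaling `W -> W C`, `chi -> C^{-1} chi`.  For visualization each
#' spectrum (column of `W`) is scaled to unit maximum and the matching
#' kinetic row is multiplied by the removed scale, leaving the product
#' `W %*% chi` unchanged.
#'
#' @param W spectral factor (m x r).
#' @param chi kinetic factor (r x n).
#' @return list with `W` (unit-maximum columns), `chi` and `scales` (the
#'   per-component maxima removed from `W`).
#' @export
normalize_for_display <- function(W, chi) {
  scales <- apply(W, 2, max)
  if (any(scales == 0))
    stop("zero spectral column cannot be normalized", call. = FALSE)
  list(W = sweep(W, 2, scales, "/"),
       chi = sweep(chi, 1, scales, "*"),
       scales = scales)
}

#' Rescale components to match reference values
#'
#' Pins the free per-component scale of a factorization to known
#' reference quantities, e.g. the maximum intensity of an assigned
#' spectroscopic line or the concentration of a species at one time
#' point.  Each anchor rescales one component pair (spectrum column and
#' kinetic row inversely), so the product is unchanged.
#'
#' @param W spectral factor (m x r).
#' @param chi kinetic factor (r x n).
#' @param anchors list of anchors, each a list with elements `component`
#'   (column index), `quantity` (`"kinetic"` to pin `chi[component,
#'   index]`, `"spectrum"` to pin `W[index, component]`, or
#'   `"spectrum_max"` to pin `max(W[, component])`; `index` ignored for
#'   the latter), `index`, and `value` (> 0).  At most one anchor per
#'   component.
#' @return list with rescaled `W` and `chi`.
#' @export
anchor_to_reference <- function(W, chi, anchors = list()) {
  if (length(anchors) == 0L) return(list(W = W, chi = chi))
  comps <- vapply(anchors, function(a) as.integer(a$component), integer(1))
  if (anyDuplicated(comps))
    stop("at most one anchor per component", call. = FALSE)
  for (a in anchors) {
    j <- as.integer(a$component)
    if (a$value <= 0) stop("anchor values must be > 0", call. = FALSE)
    current <- switch(a$quantity,
      kinetic = chi[j, a$index],
      spectrum = W[a$index, j],
      spectrum_max = max(W[, j]),
      stop("unknown anchor quantity: ", a$quantity, call. = FALSE))
    if (current == 0)
      stop("anchor references a zero quantity", call. = FALSE)
    f <- a$value / current
    if (identical(a$quantity, "kinetic")) {
      chi[j, ] <- chi[j, ] * f
      W[, j] <- W[, j] / f
    } else {
      W[, j] <- W[, j] * f
      chi[j, ] <- chi[j, ] / f
    }
  }
  list(W = W, chi = chi)
}

cosine_sim <- function(x, y) {
  nx <- sqrt(sum(x^2)); ny <- sqrt(sum(y^2))
  if (nx == 0 || ny == 0) return(NA_real_)
  sum(x * y) / (nx * ny)
}

# all permutations of 1..n (n <= 8), one per row
all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i)
    cbind(i, sub + (sub >= i))))
}

#' Match estimated components to a ground truth
#'
#' Resolves the permutation and scale ambiguity of the factorization:
#' finds the assignment of estimated to true components maximizing the
#' total spectral cosine similarity (exact assignment by enumeration of
#' all permutations, r <= 8), then determines a positive least-squares
#' scale per component (`W_est ~ scale * W_true`).  Kinetic cosine
#' similarities and relative RMSEs after rescaling are reported but not
#' used for the assignment — component spectra are normally easier to
#' evaluate than kinetics.
#'
#' @param W_est,chi_est estimated factors.
#' @param W_true,chi_true ground-truth factors with the same component
#'   count.
#' @return object of class `"component_match"`: list with `permutation`
#'   (index of the true component matched to each estimated one),
#'   `scales`, `cos_spectra`, `cos_kinetics`, `rmse_spectra`,
#'   `rmse_kinetics` (relative, after optimal scaling).
#' @export
match_components <- function(W_est, chi_est, W_true, chi_true) {
  r <- ncol(W_est)
  if (ncol(W_true) != r || nrow(chi_est) != r || nrow(chi_true) != r)
    stop("component counts of estimate and truth differ", call. = FALSE)
  if (r > 8L)
    stop("exact assignment implemented for r <= 8", call. = FALSE)
  S <- matrix(0, r, r)   # S[i, j]: |cos| of estimated i vs true j
  for (i in seq_len(r))
    for (j in seq_len(r))
      S[i, j] <- abs(cosine_sim(W_est[, i], W_true[, j]))
  perms <- all_permutations(r)
  scores <- apply(perms, 1, function(p) sum(S[cbind(seq_len(r), p)]))
  p <- as.integer(unname(perms[which.max(scores), ]))
  scales <- cs <- ck <- rs <- rk <- numeric(r)
  for (i in seq_len(r)) {
    j <- p[i]
    wt <- W_true[, j]; we <- W_est[, i]
    scales[i] <- sum(wt * we) / sum(wt * wt)   # least-squares W_est ~ s*W_true
    cs[i] <- cosine_sim(we, wt)
    ck[i] <- cosine_sim(chi_est[i, ], chi_true[j, ])
    rs[i] <- sqrt(mean((we / scales[i] - wt)^2)) / sqrt(mean(wt^2))
    st <- sum(chi_true[j, ] * chi_est[i, ]) / sum(chi_true[j, ]^2)
    rk[i] <- sqrt(mean((chi_est[i, ] / st - chi_true[j, ])^2)) /
      sqrt(mean(chi_true[j, ]^2))
  }
  structure(list(permutation = p, scales = scales, cos_spectra = cs,
                 cos_kinetics = ck, rmse_spectra = rs, rmse_kinetics = rk),
            class = "component_match")
}

#' @export
print.component_match <- function(x, ...) {
  df <- data.frame(estimated = seq_along(x$permutation),
                   true = x$permutation, scale = signif(x$scales, 4),
                   cos_spectrum = round(x$cos_spectra, 4),
                   cos_kinetics = round(x$cos_kinetics, 4))
  print(df, row.names = FALSE)
  invisible(x)
}

#' Fit a two-exponential shape to a kinetic trace
#'
#' Fits `c * (exp(-decay * t) - exp(-rise * t))` with `rise > decay > 0`
#' and `c > 0` by nonlinear least squares — the closed-form shape of a
#' first-order intermediate that is formed at rate `rise` and consumed at
#' rate `decay`.  The fit is scale-invariant: rescaling the trace by any
#' positive constant changes only `c`.
#'
#' @param trace non-negative, non-trivial kinetic trace.
#' @param times matching time grid.
#' @return list with `rate_rise`, `rate_decay`, `scale` and the fitted
#'   values `fitted`.
#' @export
fit_biexponential <- function(trace, times) {
  if (length(trace) != length(times))
    stop("trace and times differ in length", call. = FALSE)
  if (all(trace <= 0) || sd(trace) == 0)
    stop("trace is trivial; nothing to fit", call. = FALSE)
  sc <- max(trace)
  y <- trace / sc
  span <- diff(range(times))
  model <- function(p, t) exp(p[3]) * (exp(-exp(p[2]) * t) -
                                         exp(-exp(p[1]) * t))
  sse <- function(p) sum((y - model(p, times))^2)
  # coarse grid of rate guesses, then Nelder-Mead polish of the best
  guesses <- expand.grid(lr = log(c(2, 10, 50) / span),
                         ld = log(c(0.2, 1, 5) / span))
  best <- NULL
  for (g in seq_len(nrow(guesses))) {
    p0 <- c(guesses$lr[g], guesses$ld[g], 0)
    res <- optim(p0, sse, method = "Nelder-Mead",
                 control = list(maxit = 2000, reltol = 1e-12))
    if (is.null(best) || res$value < best$value) best <- res
  }
  p <- best$par
  rise <- exp(p[1]); decay <- exp(p[2]); cc <- exp(p[3]) * sc
  if (decay > rise) { tmp <- rise; rise <- decay; decay <- tmp }
  rel <- best$value / sum(y^2)
  if (!is.finite(rel) || rel > 0.25)
    stop(sprintf(paste0("biexponential fit did not converge (relative ",
                        "residual %.3g); trace may not follow a ",
                        "two-exponential shape"), rel), call. = FALSE)
  list(rate_rise = rise, rate_decay = decay, scale = cc,
       fitted = cc * (exp(-decay * times) - exp(-rise * times)))
}

#' Refit the second-order rate constants to recovered traces
#'
#' Least-squares fit of the mixed-order ODE system (see
#' [simulate_second_order()]) to recovered traces of the species B, C and
#' D.  The educt's initial concentration is fixed at `I_A(0) = 1`, while
#' each supplied trace carries a free positive output scale (recovered
#' kinetics are proportional, not equal, to concentrations); given
#' candidate rates the scales are profiled out linearly.  Rates are
#' optimized on the log scale by Nelder-Mead.
#'
#' @param traces 3 x n matrix with rows B, C, D (in that order).
#' @param times matching time grid.
#' @param start named starting rates (default `c(k1 = 0.05, k2 = 0.025,
#'   k3 = 0.1)` scaled search-friendly).
#' @return list with `k1`, `k2`, `k3`, `scales` (per-trace), and the
#'   relative residual `rel_residual`.
#' @export
fit_second_order_rates <- function(traces, times,
                                   start = c(k1 = 0.02, k2 = 0.02,
                                             k3 = 0.05)) {
  if (!is.matrix(traces) || nrow(traces) != 3L)
    stop("traces must be a 3 x n matrix with rows B, C, D", call. = FALSE)
  if (ncol(traces) != length(times))
    stop("traces and times disagree", call. = FALSE)
  model_traces <- function(k) {
    k <- unname(k)
    sc <- kinetic_scenario("second_order3",
                           rate_constants = c(k1 = k[1], k2 = k[2],
                                              k3 = k[3]))
    simulate_second_order(sc, times)[c("B", "C", "D"), , drop = FALSE]
  }
  sse <- function(logk) {
    k <- unname(exp(logk))
    if (any(!is.finite(k)) || any(k > 100)) return(1e10)
    mt <- tryCatch(model_traces(k), error = function(e) NULL)
    if (is.null(mt)) return(1e10)
    tot <- 0
    for (i in 1:3) {
      mm <- mt[i, ]; yy <- traces[i, ]
      s <- sum(mm * yy) / max(sum(mm * mm), 1e-300)  # profiled scale
      tot <- tot + sum((yy - s * mm)^2) / max(sum(yy^2), 1e-300)
    }
    tot
  }
  res <- optim(log(start), sse, method = "Nelder-Mead",
               control = list(maxit = 3000, reltol = 1e-12))
  if (!is.finite(res$value) || res$value > 0.5)
    stop(sprintf("second-order rate fit did not converge (residual %.3g)",
                 res$value), call. = FALSE)
  k <- exp(res$par)
  mt <- model_traces(k)
  scales <- vapply(1:3, function(i)
    sum(mt[i, ] * traces[i, ]) / sum(mt[i, ]^2), numeric(1))
  list(k1 = unname(k[1]), k2 = unname(k[2]), k3 = unname(k[3]),
       scales = scales, rel_residual = res$value)
}
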