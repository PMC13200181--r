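#' Preprocessing configuration
#'
#' Both preprocessing steps are disabled by default: whether smoothing or
#' baseline subtraction is appropriate depends on the individual dataset
#' (signal-to-noise ratio, presence of a fluorescence background) and is
#' left as an explicit user decision.
#'
#' @param smooth apply Savitzky-Golay smoothing (default `FALSE`).
#' @param smooth_window odd window length in points (default 11).
#' @param smooth_order polynomial order, must be smaller than the window
#'   (default 3).
#' @param baseline subtract a spline baseline (default `FALSE`).
#' @param baseline_knots spline degrees of freedom (>= 4, default 8).
#' @param baseline_floor floor the baseline-corrected matrix at zero
#'   (default `TRUE`).
#' @return object of class `"preprocess_config"`.
#' @export
preprocess_config <- function(smooth = FALSE, smooth_window = 11L,
                              smooth_order = 3L,
                              baseline = FALSE, baseline_knots = 8L,
                              baseline_floor = TRUE) {
  smooth_window <- as.integer(smooth_window)
  smooth_order <- as.integer(smooth_order)
  if (smooth_window %% 2L == 0L)
    stop("smooth_window must be odd", call. = FALSE)
  if (smooth_window <= smooth_order)
    stop("smooth_window must exceed smooth_order", call. = FALSE)
  if (baseline_knots < 4L)
    stop("baseline_knots must be >= 4", call. = FALSE)
  structure(list(smooth = smooth, smooth_window = smooth_window,
                 smooth_order = smooth_order, baseline = baseline,
                 baseline_knots = as.integer(baseline_knots),
                 baseline_floor = baseline_floor),
            class = "preprocess_config")
}

#' Savitzky-Golay smoothing along the wavenumber axis
#'
#' Smooths every column (spectrum) of the data matrix with a local
#' polynomial least-squares filter.  Polynomial signal up to the filter
#' order passes unchanged; high-frequency noise is attenuated.
#'
#' @param M numeric matrix, rows = wavenumbers, columns = time points.
#' @param cfg a [preprocess_config()] supplying window and order.
#' @return smoothed matrix of the same shape.
#' @export
smooth_savitzky_golay <- function(M, cfg = preprocess_config()) {
  assert_matrix(M)
  stopifnot(inherits(cfg, "preprocess_config"))
  if (cfg$smooth_window > nrow(M))
    stop("smoothing window exceeds the number of wavenumber points",
         call. = FALSE)
  apply(M, 2, signal::sgolayfilt, p = cfg$smooth_order,
        n = cfg$smooth_window)
}

#' Spline baseline subtraction
#'
#' Estimates a smooth baseline under the bands of every column and
#' subtracts it.  The baseline is an asymmetrically reweighted smoothing
#' spline: starting from an ordinary fit, points lying above the current
#' fit (band regions) are strongly down-weighted and the spline is
#' refitted, so that after a few passes the curve settles onto the
#' low-intensity support points between the bands.
#'
#' @param M numeric matrix, rows = wavenumbers.
#' @param cfg a [preprocess_config()]; `baseline_knots` sets the spline
#'   degrees of freedom and `baseline_floor` whether the result is floored
#'   at zero.
#' @param grid wavenumber grid of the rows; defaults to row indices.
#' @param iterations number of reweighting passes (default 20).
#' @param asymmetry weight given to points above the current fit relative
#'   to points below it (default 0.001).
#' @return baseline-corrected matrix of the same shape.
#' @export
subtract_baseline_spline <- function(M, cfg = preprocess_config(),
                                     grid = seq_len(nrow(M)),
                                     iterations = 20L, asymmetry = 0.001) {
  assert_matrix(M)
  stopifnot(inherits(cfg, "preprocess_config"))
  if (nrow(M) <= cfg$baseline_knots)
    stop("fewer wavenumber points than baseline knots", call. = FALSE)
  out <- M
  for (j in seq_len(ncol(M))) {
    y <- M[, j]
    w <- rep(1, length(y))
    fit <- rep(0, length(y))
    for (it in seq_len(iterations)) {
      fit <- predict(smooth.spline(grid, y, w = w, df = cfg$baseline_knots),
                     grid)$y
      w <- ifelse(y > fit, asymmetry, 1)
    }
    res <- y - fit
    if (cfg$baseline_floor) res[res < 0] <- 0
    out[, j] <- res
  }
  out
}

#' Apply the configured preprocessing pipeline
#'
#' Runs the enabled steps in order (smoothing, then baseline
#' subtraction).  With both steps disabled (the default) this is the
#' identity.
#'
#' @inheritParams smooth_savitzky_golay
#' @param grid wavenumber grid, used by the baseline step.
#' @return preprocessed matrix of the same shape.
#' @export
preprocess <- function(M, cfg = preprocess_config(),
                       grid = seq_len(nrow(M))) {
  stopifnot(inherits(cfg, "preprocess_config"))
  if (cfg$smooth) M <- smooth_savitzky_golay(M, cfg)
  if (cfg$baseline) M <- subtract_baseline_spline(M, cfg, grid = grid)
  M
}
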