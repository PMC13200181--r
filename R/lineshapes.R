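#' Evaluate a sum of Lorentzian lines on a wavenumber grid
#'
#' Component spectra are modelled as sums of Lorentzian bands
#' \eqn{A \gamma^2 / ((f - f_0)^2 + \gamma^2)}, where \eqn{f_0} is the band
#' center, \eqn{\gamma} the half width at half maximum and \eqn{A} the peak
#' amplitude (the value attained exactly at the center).
#'
#' @param peaks data frame with columns `center`, `hwhm` and `amplitude`,
#'   one row per band.  All half widths must be positive and all amplitudes
#'   non-negative.
#' @param grid strictly increasing numeric vector of wavenumber positions.
#' @return numeric vector of intensities, one per grid point; non-negative.
#' @examples
#' grid <- seq(400, 600, by = 1)
#' s <- lorentzian_spectrum(data.frame(center = 500, hwhm = 10,
#'                                     amplitude = 2), grid)
#' s[grid == 500]  # 2: the amplitude at the center
#' s[grid == 510]  # 1: half the amplitude one half-width away
#' @export
lorentzian_spectrum <- function(peaks, grid) {
  assert_spectral_grid(grid)
  if (is.null(peaks) || nrow(as.data.frame(peaks)) == 0L)
    stop("empty peak list: component spectrum is undefined", call. = FALSE)
  peaks <- as.data.frame(peaks)
  required <- c("center", "hwhm", "amplitude")
  if (!all(required %in% names(peaks)))
    stop("peaks must have columns 'center', 'hwhm', 'amplitude'",
         call. = FALSE)
  if (any(peaks$hwhm <= 0))
    stop("all half widths must be positive", call. = FALSE)
  if (any(peaks$amplitude < 0))
    stop("amplitudes must be non-negative", call. = FALSE)
  out <- numeric(length(grid))
  for (i in seq_len(nrow(peaks))) {
    g2 <- peaks$hwhm[i]^2
    out <- out + peaks$amplitude[i] * g2 / ((grid - peaks$center[i])^2 + g2)
  }
  out
}
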