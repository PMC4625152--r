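#' Estimate the grid carrier frequencies from a reference exposure
#'
#' Finds the dominant non-DC spectral peak along each frequency axis of the
#' 2-D power spectrum. Ties break toward the larger magnitude, then the
#' lower frequency. For a healthy grid the result agrees with the
#' configured \code{1/pitch_px} to within one frequency bin.
#'
#' @param reference numeric matrix, grid-only exposure.
#' @return \code{c(f_row, f_col)} in cycles/pixel.
#' @export
estimate_grid_frequency <- function(reference) {
  n <- dim(reference)
  Fm <- Mod(stats::fft(reference))
  dc <- Fm[1, 1]
  med <- stats::median(Fm[-1])
  # carrier along columns shows up on the row of zero row-frequency, and
  # vice versa; search positive frequencies only (spectrum is conjugate
  # symmetric for real images)
  pick <- function(line, nax) {
    ks <- 2:(floor(nax / 2) + 1)
    mags <- line[ks]
    mx <- max(mags)
    # thin wires put near-equal power at every harmonic multiple; take the
    # fundamental: the lowest frequency among near-maximal peaks
    k <- ks[mags >= 0.98 * mx][1]
    list(freq = (k - 1) / nax, mag = mx)
  }
  row_peak <- pick(Fm[, 1], n[1])
  col_peak <- pick(Fm[1, ], n[2])
  low <- min(row_peak$mag, col_peak$mag)
  if (low <= 5 * med || low <= 1e-9 * dc)
    stopf("no grid detected: strongest non-DC peak is not >= 5x the spectral median")
  c(f_row = row_peak$freq, f_col = col_peak$freq)
}

#' Define a harmonic extraction band
#'
#' @param order integer pair \code{(m, n)}: harmonic order along the row
#'   and column frequency axes. \code{(0,0)} is the zero-order (absorption)
#'   band; \code{(1,0)} and \code{(0,1)} are the first harmonics.
#' @param f0 carrier frequency \code{1/pitch_px} in cycles/pixel (scalar or
#'   \code{c(f_row, f_col)}).
#' @param halfwidth window half-width in cycles/pixel; defaults to
#'   \code{min(f0)/2} so adjacent bands never overlap.
#' @return an \code{sfhi_band} list with \code{center_freq} and
#'   \code{halfwidth}.
#' @export
harmonic_band <- function(order, f0, halfwidth = NULL) {
  f0 <- rep(as.numeric(f0), length.out = 2)
  if (is.null(halfwidth)) halfwidth <- min(f0) / 2
  if (halfwidth <= 0 || halfwidth > min(f0) / 2 + 1e-12)
    stopf("band halfwidth %.4g would overlap the neighbouring harmonic (max %.4g)",
          halfwidth, min(f0) / 2)
  center <- c(order[1] * f0[1], order[2] * f0[2])
  if (any(abs(center) + halfwidth > 0.5 + 1e-12))
    stopf("harmonic (%d,%d) at (%.3g,%.3g) cycles/px lies beyond Nyquist",
          order[1], order[2], center[1], center[2])
  structure(list(order = as.integer(order), center_freq = center,
                 halfwidth = halfwidth), class = "sfhi_band")
}

#' Extract the complex envelope of one spectral band
#'
#' Crops the half-open square window \code{[center - h, center + h)} from
#' the 2-D spectrum, re-centres it at DC (by the nearest integer bin shift)
#' and inverse-transforms at the original resolution, zero-padded. The
#' magnitude of the \code{(0,0)}-band envelope is a low-pass of the image;
#' the first-harmonic envelopes track the local carrier amplitude.
#'
#' @param image numeric matrix.
#' @param band an [harmonic_band()] object.
#' @return complex matrix of the same shape.
#' @export
extract_harmonic <- function(image, band) {
  stopifnot(inherits(band, "sfhi_band"))
  n <- dim(image)
  fr <- fft_freq(n[1]); fc <- fft_freq(n[2])
  rsel <- which(fr >= band$center_freq[1] - band$halfwidth &
                  fr < band$center_freq[1] + band$halfwidth)
  csel <- which(fc >= band$center_freq[2] - band$halfwidth &
                  fc < band$center_freq[2] + band$halfwidth)
  if (!length(rsel) || !length(csel))
    stopf("band window contains no frequency bins for a %dx%d image", n[1], n[2])
  Fi <- stats::fft(image)
  shift <- round(band$center_freq * n)
  Z <- matrix(0 + 0i, n[1], n[2])
  Z[((rsel - 1L - shift[1]) %% n[1]) + 1L,
    ((csel - 1L - shift[2]) %% n[2]) + 1L] <- Fi[rsel, csel]
  stats::fft(Z, inverse = TRUE) / (n[1] * n[2])
}

#' Demodulate one exposure pair into absorption and scatter images
#'
#' The single-shot reconstruction: with \eqn{M_{mn}(\cdot)} the envelope
#' magnitude of harmonic \eqn{(m,n)},
#' \deqn{absorption = -\ln\frac{M_{00}(S)}{M_{00}(R)}}
#' \deqn{scatter_h = -\ln\frac{M_{0,1}(S)/M_{00}(S)}{M_{0,1}(R)/M_{00}(R)}}
#' and \code{scatter_v} analogously with harmonic \eqn{(1,0)}. The
#' logarithmic ratio-of-ratios linearises Gaussian harmonic damping: a
#' uniform scatter blur of RMS width \eqn{\sigma} gives
#' \eqn{S = 2\pi^2\sigma^2 f_0^2} at carrier frequency \eqn{f_0}, and a
#' uniform optical depth \eqn{A} is recovered as-is. "Horizontal" scatter
#' is the damping of the carrier that varies along image columns, i.e.
#' x-rays deflected horizontally.
#'
#' @param sample sample exposure (matrix), same shape and grid as
#'   \code{reference}.
#' @param reference grid-only exposure (matrix).
#' @param pitch_px grid period in pixels; if \code{NULL} it is estimated
#'   from the reference via [estimate_grid_frequency()].
#' @param halfwidth band half-width in cycles/pixel (default
#'   \code{1/(2 pitch_px)}).
#' @return an object of class \code{sfhi_recon}: list with matrices
#'   \code{absorption}, \code{scatter_h}, \code{scatter_v}, the bands used,
#'   the carrier frequencies, and \code{margin} (one grid period; exclude
#'   it from quantitative statistics).
#' @export
reconstruct <- function(sample, reference, pitch_px = NULL, halfwidth = NULL) {
  if (!all(dim(sample) == dim(reference)))
    stopf("sample and reference shapes differ")
  f0 <- if (is.null(pitch_px)) estimate_grid_frequency(reference)
  else c(f_row = 1 / pitch_px, f_col = 1 / pitch_px)
  band00 <- harmonic_band(c(0, 0), f0, halfwidth)
  band_h <- harmonic_band(c(0, 1), f0, halfwidth)   # carrier along columns
  band_v <- harmonic_band(c(1, 0), f0, halfwidth)   # carrier along rows
  M00r <- Mod(extract_harmonic(reference, band00))
  if (any(M00r <= 0))
    stopf("flat-field error: zero-order envelope of the reference is not positive everywhere")
  Mhr <- Mod(extract_harmonic(reference, band_h))
  Mvr <- Mod(extract_harmonic(reference, band_v))
  if (mean(Mhr) < 1e-6 * mean(M00r) || mean(Mvr) < 1e-6 * mean(M00r))
    stopf("no grid detected: first-harmonic amplitude of the reference is ~0 (degenerate grid?)")
  M00s <- Mod(extract_harmonic(sample, band00))
  if (any(M00s <= 0))
    stopf("sample zero-order envelope is not positive everywhere")
  Mhs <- Mod(extract_harmonic(sample, band_h))
  Mvs <- Mod(extract_harmonic(sample, band_v))
  structure(list(
    absorption = -log(M00s / M00r),
    scatter_h = -log((Mhs / M00s) / (Mhr / M00r)),
    scatter_v = -log((Mvs / M00s) / (Mvr / M00r)),
    bands = list(zero = band00, h = band_h, v = band_v),
    carrier_freq = f0,
    margin = as.integer(ceiling(1 / min(f0)))), class = "sfhi_recon")
}

#' Invert the scatter metric to a Gaussian blur width
#'
#' Inverts \eqn{S = 2\pi^2\sigma^2 f_0^2}. Negative metric values (noise)
#' are clipped to zero; the number clipped is attached as attribute
#' \code{n_clipped} and reported in a warning.
#'
#' @param S scatter metric (scalar, vector or matrix).
#' @param f0 carrier frequency in cycles/pixel.
#' @return \eqn{\sigma = \sqrt{S / (2\pi^2 f_0^2)}} in pixels, same shape
#'   as \code{S}.
#' @export
scatter_to_sigma <- function(S, f0) {
  n_neg <- sum(S < 0)
  if (n_neg > 0) {
    warning(sprintf("clipped %d negative scatter values to zero", n_neg),
            call. = FALSE)
    S <- pmax(S, 0)
  }
  out <- sqrt(S / (2 * pi^2 * f0^2))
  attr(out, "n_clipped") <- n_neg
  out
}
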