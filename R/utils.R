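# internal helpers shared across modules

# DFT frequency axis in cycles/pixel; index 1 = DC, Nyquist mapped to -0.5
fft_freq <- function(n) {
  k <- seq_len(n) - 1L
  ifelse(k < n / 2, k, k - n) / n
}

# run expr with a fixed RNG seed without disturbing the caller's stream
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# unit-gain isotropic Gaussian blur, periodic boundary, exact transfer function
gauss_blur <- function(x, sigma) {
  if (sigma <= 0) return(x)
  n <- dim(x)
  f2 <- outer(fft_freq(n[1])^2, fft_freq(n[2])^2, "+")
  Re(stats::fft(stats::fft(x) * exp(-2 * pi^2 * sigma^2 * f2), inverse = TRUE)) /
    (n[1] * n[2])
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

#' Extract the interior of an image, excluding a border margin
#'
#' Quantitative statistics exclude a border of one grid period because the
#' periodic Fourier processing wraps image edges around.
#'
#' @param x numeric matrix.
#' @param margin number of pixels to drop on every side.
#' @return the interior submatrix.
#' @export
interior <- function(x, margin) {
  margin <- as.integer(margin)
  d <- dim(x)
  if (2L * margin >= min(d)) stopf("margin %d leaves no interior for a %dx%d image",
                                   margin, d[1], d[2])
  x[(margin + 1L):(d[1] - margin), (margin + 1L):(d[2] - margin), drop = FALSE]
}

# rotate a matrix 90 degrees counter-clockwise
rot90 <- function(x) t(x)[rev(seq_len(ncol(x))), , drop = FALSE]
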