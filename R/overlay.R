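#' Overlay rendering parameters
#'
#' @param colormap palette name passed to [grDevices::hcl.colors()]
#'   (default a perceptually uniform sequential map).
#' @param range scatter display range \code{c(lo, hi)}; \code{NULL} uses
#'   the scatter image's own min/max.
#' @param alpha blend weight of the colour layer, in \code{[0, 1]}.
#' @param threshold scatter value below which pixels stay pure grayscale.
#' @return an \code{sfhi_overlay_spec} list.
#' @export
overlay_spec <- function(colormap = "viridis", range = NULL, alpha = 0.5,
                         threshold = 0) {
  if (alpha < 0 || alpha > 1) stopf("alpha must lie in [0, 1]")
  if (!is.null(range) && range[1] >= range[2]) stopf("need range lo < hi")
  structure(list(colormap = colormap, range = range, alpha = alpha,
                 threshold = threshold), class = "sfhi_overlay_spec")
}

#' Dual-modality rendering: colour scatter over grayscale absorption
#'
#' Combines the resolution of the absorption image with the sensitivity of
#' the scatter image: the absorption image (min--max normalised) forms a
#' grayscale base; where the scatter metric exceeds the threshold, a
#' colour-mapped scatter layer is alpha-blended on top.
#'
#' @param absorption numeric matrix.
#' @param scatter numeric matrix, same shape.
#' @param spec an [overlay_spec()].
#' @return numeric array \code{rows x cols x 3}, channels in \code{[0, 1]}.
#' @export
overlay <- function(absorption, scatter, spec = overlay_spec()) {
  stopifnot(inherits(spec, "sfhi_overlay_spec"))
  if (!all(dim(absorption) == dim(scatter)))
    stopf("absorption and scatter shapes differ")
  rng <- if (is.null(spec$range)) range(scatter) else spec$range
  if (rng[1] >= rng[2]) rng <- c(rng[1], rng[1] + 1)  # constant image guard
  gmin <- min(absorption); gmax <- max(absorption)
  gray <- if (gmax > gmin) (absorption - gmin) / (gmax - gmin)
  else matrix(0, nrow(absorption), ncol(absorption))
  lut <- t(grDevices::col2rgb(grDevices::hcl.colors(256, spec$colormap)) / 255)
  s01 <- pmin(pmax((scatter - rng[1]) / (rng[2] - rng[1]), 0), 1)
  idx <- pmin(as.integer(s01 * 255) + 1L, 256L)
  hot <- scatter > spec$threshold
  a <- spec$alpha * hot
  out <- array(0, c(dim(absorption), 3L))
  for (ch in 1:3) {
    col_ch <- matrix(lut[idx, ch], nrow(absorption), ncol(absorption))
    out[, , ch] <- (1 - a) * gray + a * col_ch
  }
  out
}
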