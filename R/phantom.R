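#' Define an elliptical phantom region
#'
#' Regions are ellipses in pixel coordinates (0-based, row-major, origin at
#' the top-left corner, pixel centres at integer + 0.5). Each region adds an
#' attenuation optical depth and, optionally, a gold concentration that
#' drives small-angle scatter.
#'
#' @param name region label (e.g. "body", "liver", "tumor_1").
#' @param center \code{c(row, col)} of the ellipse centre, in pixels.
#' @param axes \code{c(semi_row, semi_col)} semi-axes in pixels.
#' @param angle_deg rotation of the ellipse in the row-col plane.
#' @param optical_depth attenuation line integral added inside the ellipse
#'   (dimensionless, >= 0).
#' @param gold_ugcm3 gold concentration inside the ellipse (ug/cm^3, >= 0).
#' @return a \code{sfhi_region} list.
#' @export
phantom_region <- function(name, center, axes, angle_deg = 0,
                           optical_depth = 0, gold_ugcm3 = 0) {
  if (optical_depth < 0) stopf("region '%s': optical_depth must be >= 0", name)
  if (gold_ugcm3 < 0) stopf("region '%s': negative gold concentration", name)
  if (any(axes <= 0)) stopf("region '%s': ellipse axes must be positive", name)
  structure(list(name = name, center = as.numeric(center),
                 axes = as.numeric(axes), angle_deg = angle_deg,
                 optical_depth = optical_depth, gold_ugcm3 = gold_ugcm3),
            class = "sfhi_region")
}

# pixel-centre mask of an ellipse; values in {0,1}
.ellipse_mask <- function(region, shape) {
  rows <- seq_len(shape[1]) - 0.5
  cols <- seq_len(shape[2]) - 0.5
  th <- region$angle_deg * pi / 180
  dr <- outer(rows - region$center[1], rep(1, shape[2]))
  dc <- outer(rep(1, shape[1]), cols - region$center[2])
  u <- cos(th) * dr + sin(th) * dc
  v <- -sin(th) * dr + cos(th) * dc
  (u / region$axes[1])^2 + (v / region$axes[2])^2 <= 1
}

.check_region_bounds <- function(region, shape) {
  th <- region$angle_deg * pi / 180
  er <- sqrt((region$axes[1] * cos(th))^2 + (region$axes[2] * sin(th))^2)
  ec <- sqrt((region$axes[1] * sin(th))^2 + (region$axes[2] * cos(th))^2)
  ok <- region$center[1] - er >= 0 && region$center[1] + er <= shape[1] &&
    region$center[2] - ec >= 0 && region$center[2] + ec <= shape[2]
  if (!ok) stopf("region '%s' extends outside the %dx%d canvas",
                 region$name, shape[1], shape[2])
}

#' Build a digital mouse phantom
#'
#' A phantom is a pair of per-pixel maps on a common canvas: the attenuation
#' optical depth \eqn{A(x,y)} (sum of the contributions of all overlapping
#' regions) and the gold concentration \eqn{c(x,y)}. Gold drives small-angle
#' scatter through the coupling \eqn{\sigma^2(x,y) = k\, c(x,y)}: harmonic
#' damping is then log-linear in concentration, the simplest model
#' consistent with the observed direct correlation between tissue gold
#' content and measured scatter intensity.
#'
#' @param shape \code{c(rows, cols)} canvas size in pixels.
#' @param regions list of [phantom_region()] objects (may be empty).
#' @param scatter_coupling \eqn{k}, blur variance per unit concentration
#'   (pixel^2 per ug/cm^3).
#' @return an object of class \code{sfhi_phantom} with fields
#'   \code{shape}, \code{optical_depth}, \code{gold_map},
#'   \code{scatter_coupling}, \code{regions}.
#' @examples
#' ph <- mouse_phantom(c(96, 96), list(
#'   phantom_region("body", c(48, 48), c(40, 40), optical_depth = 0.3),
#'   phantom_region("tumor_1", c(48, 30), c(8, 8), optical_depth = 0.1,
#'                  gold_ugcm3 = 26)
#' ), scatter_coupling = 0.05)
#' max(ph$gold_map)  # 26
#' @export
mouse_phantom <- function(shape, regions = list(), scatter_coupling = 0.05) {
  shape <- as.integer(shape)
  stopifnot(length(shape) == 2, all(shape > 0))
  if (scatter_coupling < 0) stopf("scatter_coupling must be >= 0")
  A <- matrix(0, shape[1], shape[2])
  gold <- matrix(0, shape[1], shape[2])
  for (rg in regions) {
    stopifnot(inherits(rg, "sfhi_region"))
    .check_region_bounds(rg, shape)
    m <- .ellipse_mask(rg, shape)
    A <- A + rg$optical_depth * m
    gold <- pmax(gold, rg$gold_ugcm3 * m)
  }
  structure(list(shape = shape, optical_depth = A, gold_map = gold,
                 scatter_coupling = scatter_coupling, regions = regions),
            class = "sfhi_phantom")
}

#' Per-pixel scatter blur width of a phantom
#'
#' @param phantom an [mouse_phantom()] object.
#' @return matrix of Gaussian blur RMS widths
#'   \eqn{\sigma(x,y) = \sqrt{k\, c(x,y)}} in pixels.
#' @export
scatter_sigma_map <- function(phantom) {
  stopifnot(inherits(phantom, "sfhi_phantom"))
  sqrt(phantom$scatter_coupling * phantom$gold_map)
}

#' Look up a phantom region's pixel mask by name
#'
#' @param phantom an [mouse_phantom()] object.
#' @param name region label.
#' @return logical matrix.
#' @export
region_mask <- function(phantom, name) {
  for (rg in phantom$regions) if (rg$name == name)
    return(.ellipse_mask(rg, phantom$shape))
  stopf("phantom has no region named '%s'", name)
}

# ---- serialization -------------------------------------------------------

#' Serialize phantom region definitions to a plain list
#'
#' Regions round-trip losslessly through this representation (and hence
#' through YAML/JSON).
#'
#' @param regions list of [phantom_region()] objects.
#' @return list of plain lists with fields name, center, axes, angle_deg,
#'   optical_depth, gold_ugcm3.
#' @export
regions_to_list <- function(regions) {
  lapply(regions, function(rg) list(
    name = rg$name, center = rg$center, axes = rg$axes,
    angle_deg = rg$angle_deg, optical_depth = rg$optical_depth,
    gold_ugcm3 = rg$gold_ugcm3))
}

#' @rdname regions_to_list
#' @param x a list as produced by [regions_to_list()] (or parsed from a
#'   config file).
#' @export
regions_from_list <- function(x) {
  lapply(x, function(r) phantom_region(
    name = r$name, center = unlist(r$center), axes = unlist(r$axes),
    angle_deg = if (is.null(r$angle_deg)) 0 else r$angle_deg,
    optical_depth = if (is.null(r$optical_depth)) 0 else r$optical_depth,
    gold_ugcm3 = if (is.null(r$gold_ugcm3)) 0 else r$gold_ugcm3))
}
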