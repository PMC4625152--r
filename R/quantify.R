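#' Define a region of interest
#'
#' Either an ellipse (like [phantom_region()], in 0-based pixel
#' coordinates) or an explicit logical pixel mask.
#'
#' @param name ROI label.
#' @param center,axes,angle_deg ellipse geometry (ignored when \code{mask}
#'   is given).
#' @param mask optional logical matrix; overrides the ellipse.
#' @param role \code{"target"} or \code{"control"}.
#' @return an \code{sfhi_roi} object.
#' @export
roi <- function(name, center = NULL, axes = NULL, angle_deg = 0, mask = NULL,
                role = c("target", "control")) {
  role <- match.arg(role)
  if (is.null(mask)) {
    if (is.null(center) || is.null(axes))
      stopf("roi '%s': supply either an ellipse (center, axes) or a mask", name)
    if (any(axes <= 0)) stopf("roi '%s': axes must be positive", name)
  }
  structure(list(name = name, center = center, axes = axes,
                 angle_deg = angle_deg, mask = mask, role = role),
            class = "sfhi_roi")
}

.roi_mask <- function(r, shape) {
  if (!is.null(r$mask)) {
    if (!all(dim(r$mask) == shape))
      stopf("roi '%s': mask shape differs from image", r$name)
    return(r$mask)
  }
  .ellipse_mask(phantom_region(r$name, r$center, r$axes, r$angle_deg), shape)
}

#' Pixel statistics over a region of interest
#'
#' @param image numeric matrix.
#' @param r an [roi()] object.
#' @return list with \code{mean}, \code{sd}, \code{n}.
#' @export
roi_stats <- function(image, r) {
  stopifnot(inherits(r, "sfhi_roi"))
  m <- .roi_mask(r, dim(image))
  vals <- image[m]
  if (!length(vals)) stopf("roi '%s' rasterizes to zero pixels", r$name)
  list(mean = mean(vals), sd = stats::sd(vals), n = length(vals))
}

#' Signal enhancement of a target ROI over a control ROI
#'
#' The figure of merit for contrast-agent labeling:
#' \deqn{enhancement = 100 \frac{\bar x_{target} - \bar x_{control}}{\bar x_{control}}\ \%}
#' It is invariant under rescaling of the whole image, so it can be read
#' off either the raw scatter metric or any linear display of it.
#'
#' @param image numeric matrix (absorption or scatter reconstruction).
#' @param target,control [roi()] objects.
#' @return list of class \code{sfhi_enhancement} with
#'   \code{target_mean}, \code{control_mean}, \code{enhancement_pct},
#'   \code{target_sd}, \code{control_sd}, \code{n_target}, \code{n_control}.
#' @export
signal_enhancement <- function(image, target, control) {
  ts <- roi_stats(image, target)
  cs <- roi_stats(image, control)
  if (abs(cs$mean) < 1e-12)
    stopf("control ROI mean is ~0: enhancement is undefined")
  structure(list(target_mean = ts$mean, control_mean = cs$mean,
                 enhancement_pct = 100 * (ts$mean - cs$mean) / cs$mean,
                 target_sd = ts$sd, control_sd = cs$sd,
                 n_target = ts$n, n_control = cs$n),
            class = "sfhi_enhancement")
}

#' Integrated optical density of a stain channel
#'
#' Background-subtracted densitometry: the sum, over pixels brighter than
#' the threshold, of intensity minus threshold. Captures both the stained
#' area and its brightness; monotone nondecreasing in either, nonincreasing
#' in the threshold. An empty above-threshold set gives 0.
#'
#' @param micrograph numeric matrix (grayscale stain channel).
#' @param threshold background level, \code{>= 0}.
#' @return scalar IOD.
#' @export
iod <- function(micrograph, threshold = 0) {
  if (threshold < 0) stopf("threshold must be >= 0")
  sum(pmax(micrograph - threshold, 0))
}

#' Enhancement factor of a target IOD over control IODs
#'
#' @param target_iod scalar measurement for the target condition.
#' @param control_iods numeric vector of control measurements (all > 0).
#' @return the factor \code{target_iod / mean(control_iods)} at full
#'   precision; use [report_factor()] for the printed integer form.
#' @export
enhancement_factor <- function(target_iod, control_iods) {
  if (!length(control_iods)) stopf("need at least one control measurement")
  if (any(control_iods <= 0)) stopf("control IODs must all be positive")
  target_iod / mean(control_iods)
}

#' Round a factor to the integer reported in summaries
#' @param x numeric factor(s).
#' @return nearest integer(s).
#' @export
report_factor <- function(x) round(x)

#' Ratios of labeled measurements to a reference entry
#'
#' Builds the kind of table used to compare contrast-agent uptake across
#' conditions: each measurement divided by the reference measurement
#' (reference-to-itself = 1.00), with uncertainties propagated in
#' quadrature and a 2-decimal display column (full precision retained).
#' An optional paired compartment (e.g. the liver corresponding to each
#' tumor) adds per-item cross-compartment ratios.
#'
#' @param measurements data.frame with columns \code{label}, \code{value}
#'   and optionally \code{sd}.
#' @param reference_label label of the reference row.
#' @param paired_compartment optional data.frame with columns \code{label},
#'   \code{value} matched by label (e.g. concentrations in a second organ).
#' @return data.frame of class \code{sfhi_ratio_table} with columns
#'   \code{label}, \code{value}, \code{sd}, \code{ratio},
#'   \code{ratio_display}, \code{ratio_sd}, and if paired,
#'   \code{paired_value}, \code{cross_ratio}, \code{cross_ratio_display}.
#' @export
ratio_table <- function(measurements, reference_label,
                        paired_compartment = NULL) {
  m <- as.data.frame(measurements)
  if (!all(c("label", "value") %in% names(m)))
    stopf("measurements need columns 'label' and 'value'")
  if (any(m$value <= 0)) stopf("measurements must be positive")
  if (!reference_label %in% m$label)
    stopf("reference label '%s' not found", reference_label)
  if (is.null(m$sd)) m$sd <- NA_real_
  ref <- m[m$label == reference_label, ][1, ]
  m$ratio <- m$value / ref$value
  m$ratio_display <- round(m$ratio, 2)
  m$ratio_sd <- m$ratio * sqrt((m$sd / m$value)^2 + (ref$sd / ref$value)^2)
  m$ratio_sd[m$label == reference_label] <- 0
  if (!is.null(paired_compartment)) {
    p <- as.data.frame(paired_compartment)
    if (any(p$value <= 0)) stopf("paired measurements must be positive")
    m$paired_value <- p$value[match(m$label, p$label)]
    m$cross_ratio <- m$value / m$paired_value
    m$cross_ratio_display <- round(m$cross_ratio, 2)
  }
  class(m) <- c("sfhi_ratio_table", "data.frame")
  m
}

#' Per-organ uptake means and reference-organ factors
#'
#' Summarises a biodistribution study: for each organ, the mean gold mass
#' across injected animals, and the ratio of the reference organ's mean
#' (the liver, by default the largest sink for >5 nm nanoparticles) to each
#' organ's mean. A zero organ mean yields an \code{Inf} factor marker, not
#' an error.
#'
#' @param per_organ_masses named list: organ -> numeric vector of masses
#'   across animals.
#' @param reference_organ name of the numerator organ (default
#'   \code{"liver"}).
#' @return data.frame with columns \code{organ}, \code{mean_mass},
#'   \code{factor} (reference mean / organ mean) and
#'   \code{factor_reported} (nearest integer).
#' @export
biodistribution_summary <- function(per_organ_masses,
                                    reference_organ = "liver") {
  if (length(per_organ_masses) < 2) stopf("need at least two organs")
  if (!reference_organ %in% names(per_organ_masses))
    stopf("reference organ '%s' not found", reference_organ)
  means <- vapply(per_organ_masses, mean, numeric(1))
  fac <- ifelse(means > 0, means[[reference_organ]] / means, Inf)
  data.frame(organ = names(means), mean_mass = unname(means),
             factor = unname(fac),
             factor_reported = unname(ifelse(is.finite(fac), round(fac), Inf)),
             row.names = NULL)
}

# ---- ROI file I/O --------------------------------------------------------

#' Read ROI definitions from a JSON file
#'
#' Format: a JSON list of objects \code{{name, type: "ellipse", center,
#' axes, angle_deg, role}} (mask ROIs are constructed in code, not files).
#'
#' @param path JSON file path.
#' @return list of [roi()] objects.
#' @export
read_rois <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  lapply(raw, function(r) {
    if (!identical(r$type, "ellipse"))
      stopf("unsupported ROI type '%s' (only 'ellipse' in files)", r$type)
    roi(r$name, center = unlist(r$center), axes = unlist(r$axes),
        angle_deg = if (is.null(r$angle_deg)) 0 else r$angle_deg,
        role = r$role)
  })
}

#' Write ROI definitions to a JSON file
#' @param rois list of [roi()] objects (ellipse ROIs only).
#' @param path output path.
#' @export
write_rois <- function(rois, path) {
  out <- lapply(rois, function(r) {
    if (is.null(r$center)) stopf("mask ROI '%s' cannot be serialized", r$name)
    list(name = r$name, type = "ellipse", center = r$center, axes = r$axes,
         angle_deg = r$angle_deg, role = r$role)
  })
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
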