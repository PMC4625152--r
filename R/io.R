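#' Write a raster image with a JSON metadata sidecar
#'
#' Images are stored as 16-bit grayscale TIFF (or PNG by extension). A JSON
#' sidecar (\code{<path>.json}) records how stored 16-bit code values map
#' back to physical values: \code{value = offset + code * scale}.
#'
#' Two scale policies:
#' \describe{
#'   \item{\code{"none"}}{the raster must already be integer counts in
#'     \code{[0, 65535]}; stored exactly, \code{scale = 1, offset = 0}.}
#'   \item{\code{"auto"}}{floating-point rasters are min--max scaled onto
#'     the 16-bit range; the quantization error is at most half a scale
#'     quantum.}
#' }
#'
#' @param raster numeric matrix.
#' @param path output file, extension \code{.tif}/\code{.tiff} or
#'   \code{.png}.
#' @param scale \code{"none"} or \code{"auto"}.
#' @return \code{path}, invisibly.
#' @export
write_image <- function(raster, path, scale = c("auto", "none")) {
  scale <- match.arg(scale)
  ext <- tolower(tools::file_ext(path))
  if (!ext %in% c("tif", "tiff", "png"))
    stopf("unsupported image format '.%s' (use 16-bit TIFF or PNG)", ext)
  bits <- if (ext == "png") 8L else 16L   # writePNG stores 8 bits/channel
  maxcode <- 2^bits - 1
  if (scale == "none") {
    if (any(raster != round(raster)) || any(raster < 0) ||
        any(raster > maxcode))
      stopf("scale='none' requires integer counts in [0, %d] for %d-bit %s",
            maxcode, bits, ext)
    offset <- 0; quantum <- 1
    codes <- raster
  } else {
    offset <- min(raster)
    spread <- max(raster) - offset
    quantum <- if (spread > 0) spread / maxcode else 1
    codes <- round((raster - offset) / quantum)
  }
  if (ext == "png") png::writePNG(codes / maxcode, path)
  else tiff::writeTIFF(codes / maxcode, path, bits.per.sample = 16L)
  jsonlite::write_json(
    list(scale = quantum, offset = offset, scale_policy = scale,
         shape = dim(raster), bits = bits),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a raster image written by [write_image()]
#'
#' @param path image file path; its \code{<path>.json} sidecar must exist
#'   (it carries the code-to-value mapping).
#' @return numeric matrix of physical values, with the sidecar attached as
#'   attribute \code{sidecar}.
#' @export
read_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (!ext %in% c("tif", "tiff", "png"))
    stopf("unsupported image format '.%s' (use 16-bit TIFF or PNG)", ext)
  sidecar_path <- paste0(path, ".json")
  if (!file.exists(sidecar_path))
    stopf("missing sidecar '%s': cannot map stored codes to values", sidecar_path)
  side <- jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
  img01 <- if (ext == "png") png::readPNG(path) else tiff::readTIFF(path)
  if (length(dim(img01)) != 2) stopf("expected a single-channel grayscale image")
  code <- round(img01 * (2^side$bits - 1))
  out <- side$offset + code * side$scale
  attr(out, "sidecar") <- side
  out
}

#' Read a pipeline/phantom configuration from YAML
#'
#' Schema: \code{grid{pitch_px,duty,open_transmission,wire_transmission,
#' orientation_deg}}, \code{geometry{source_detector_m,sample_position_m}},
#' \code{acquisition{fluence,seed,noise}}, \code{shape}, \code{scatter_coupling},
#' \code{regions[{name,center,axes,angle_deg,optical_depth,gold_ugcm3}]}
#' and optionally \code{rois[...]} (same fields plus \code{role}).
#'
#' @param path YAML file.
#' @return validated list with constructed \code{grid}, \code{geometry},
#'   \code{acquisition}, \code{phantom} objects plus raw config fields.
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  for (key in c("grid", "acquisition", "shape"))
    if (is.null(cfg[[key]])) stopf("config is missing required key '%s'", key)
  g <- cfg$grid
  grid <- grid_spec(
    pitch_px = g$pitch_px,
    duty = if (is.null(g$duty)) 0.05 else g$duty,
    open_transmission = if (is.null(g$open_transmission)) 0.98 else g$open_transmission,
    wire_transmission = if (is.null(g$wire_transmission)) 0.10 else g$wire_transmission,
    orientation_deg = if (is.null(g$orientation_deg)) 0 else g$orientation_deg)
  geom <- if (is.null(cfg$geometry)) geometry()
  else geometry(cfg$geometry$source_detector_m, cfg$geometry$sample_position_m)
  a <- cfg$acquisition
  acq <- acquisition_settings(
    fluence = a$fluence,
    rng_seed = if (is.null(a$seed)) 1L else a$seed,
    noise_enabled = if (is.null(a$noise)) TRUE else a$noise)
  shape <- as.integer(unlist(cfg$shape))
  regions <- regions_from_list(if (is.null(cfg$regions)) list() else cfg$regions)
  phantom <- mouse_phantom(shape, regions,
                           scatter_coupling = if (is.null(cfg$scatter_coupling))
                             0.05 else cfg$scatter_coupling)
  rois <- if (is.null(cfg$rois)) list() else lapply(cfg$rois, function(r)
    roi(r$name, center = unlist(r$center), axes = unlist(r$axes),
        angle_deg = if (is.null(r$angle_deg)) 0 else r$angle_deg,
        role = r$role))
  list(grid = grid, geometry = geom, acquisition = acq, phantom = phantom,
       rois = rois, shape = shape, raw = cfg)
}

#' Load one of the packaged published-measurement tables
#'
#' Small CSV tables of published gold-nanoparticle measurements that feed
#' the ratio/factor arithmetic: \code{"cell_uptake"} (mass of gold per cell
#' by surface chemistry), \code{"iod_immunofluorescence"} (integrated
#' optical densities by conjugate and cell line),
#' \code{"organ_biodistribution"} (per-organ gold masses by injected
#' agent), \code{"organ_enhancements"} (per-organ absorbance/scatter signal
#' enhancements), \code{"tumor_gold"} (gold concentration in tumors and
#' their corresponding livers).
#'
#' @param name table name (see above).
#' @return data.frame.
#' @export
sfhi_example_table <- function(name = c("cell_uptake", "iod_immunofluorescence",
                                        "organ_biodistribution",
                                        "organ_enhancements", "tumor_gold")) {
  name <- match.arg(name)
  path <- system.file("extdata", paste0(name, ".csv"), package = "sfhi",
                      mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
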