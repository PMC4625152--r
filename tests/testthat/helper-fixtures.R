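# shared fixtures: everything is generated in code at test time

default_grid <- function(pitch = 8) grid_spec(pitch_px = pitch)

# phantom with a spatially uniform scatter blur width and optical depth
uniform_sigma_phantom <- function(shape, sigma, optical_depth = 0) {
  ph <- mouse_phantom(shape, list(), scatter_coupling = 1)
  ph$gold_map[] <- sigma^2
  ph$optical_depth[] <- optical_depth
  ph
}

# body + gold-labeled tumor phantom used for enhancement/ordering tests;
# body attenuation is uniform so the tumor differs only in scatter, and a
# low background gold level keeps the control ROI's scatter mean nonzero
tumor_phantom <- function(shape = c(160, 160), gold = 26, body_od = 0.3,
                          body_gold = 2, coupling = 0.05) {
  n <- shape[1]
  ph <- mouse_phantom(shape, list(
    phantom_region("tumor_1", center = c(0.7 * n, 0.62 * n),
                   axes = c(10, 10), gold_ugcm3 = gold)
  ), scatter_coupling = coupling)
  ph$optical_depth[] <- body_od
  ph$gold_map <- pmax(ph$gold_map, body_gold)
  ph
}

tumor_rois <- function(shape = c(160, 160)) {
  n <- shape[1]
  list(target = roi("tumor", center = c(0.7 * n, 0.62 * n), axes = c(7, 7)),
       control = roi("control", center = c(0.7 * n, 0.3 * n), axes = c(7, 7),
                     role = "control"))
}

# smooth off-center scatter blob (sigma^2 Gaussian profile); smoothness
# matters for equivariance checks: hard-edged sigma steps ring directionally
smooth_blob_phantom <- function(shape = c(160, 160), peak_sig2 = 1.2,
                                base_sig2 = 0.1, width = 10, body_od = 0.3) {
  n <- shape[1]
  ph <- mouse_phantom(shape, list(), scatter_coupling = 1)
  rr <- outer((seq_len(n) - 0.7 * n)^2, rep(1, shape[2])) +
    outer(rep(1, n), (seq_len(shape[2]) - 0.62 * n)^2)
  ph$gold_map <- base_sig2 + peak_sig2 * exp(-rr / (2 * width^2))
  ph$optical_depth[] <- body_od
  ph
}

# 90-degree counter-clockwise rotation (test-local copy)
rot90ccw <- function(x) t(x)[rev(seq_len(ncol(x))), , drop = FALSE]

noise_free <- function(fluence = 1e4) {
  acquisition_settings(fluence = fluence, rng_seed = 1L, noise_enabled = FALSE)
}
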