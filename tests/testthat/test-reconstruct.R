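test_that("carrier frequency is recovered from the reference to one bin", {
  for (pitch in c(8, 16)) {
    ref <- simulate_reference(default_grid(pitch), c(256, 256), noise_free())
    f <- estimate_grid_frequency(ref)
    expect_equal(unname(f), rep(1 / pitch, 2), tolerance = 1 / 256)
  }
  # with thin wires all harmonic multiples carry near-equal power; noise
  # must not push the estimate onto a higher multiple of the fundamental
  ref_noisy <- simulate_reference(default_grid(8), c(160, 160),
                                  acquisition_settings(2e4, 7L, TRUE))
  expect_equal(unname(estimate_grid_frequency(ref_noisy)), c(1 / 8, 1 / 8),
               tolerance = 1 / 160)
  expect_error(estimate_grid_frequency(matrix(1, 64, 64)), "no grid detected")
})

test_that("harmonic band construction enforces the no-overlap window rule", {
  expect_error(harmonic_band(c(0, 1), 1 / 8, halfwidth = 1 / 8), "overlap")
  expect_error(harmonic_band(c(0, 1), 1 / 8, halfwidth = 0), "overlap")
  b <- harmonic_band(c(0, 1), 1 / 8)
  expect_equal(b$halfwidth, 1 / 16)
  expect_equal(b$center_freq, c(0, 1 / 8))
  # harmonic beyond Nyquist: pitch 4 puts (1,1)-order second harmonic out
  expect_error(harmonic_band(c(2, 0), 1 / 3), "Nyquist")
})

test_that("envelope of a pure cosine at band centre is half its amplitude", {
  n <- 64
  img <- matrix(cos(2 * pi * (col(matrix(0, n, n)) - 1) / 8), n, n)
  env <- extract_harmonic(img, harmonic_band(c(0, 1), 1 / 8))
  expect_equal(max(Mod(env)), 0.5, tolerance = 1e-10)
  expect_lt(stats::sd(Mod(env)), 1e-10)
})

test_that("zero-order band of a constant image returns the constant", {
  img <- matrix(3.7, 32, 32)
  env <- extract_harmonic(img, harmonic_band(c(0, 0), 1 / 8))
  expect_equal(Mod(env), matrix(3.7, 32, 32), tolerance = 1e-12)
})

test_that("a band over empty spectrum returns a ~zero envelope", {
  img <- matrix(5, 64, 64)  # all energy at DC
  env <- extract_harmonic(img, harmonic_band(c(0, 1), 1 / 8))
  expect_lt(max(Mod(env)), 1e-10 * sqrt(mean(img^2)))
})

test_that("reconstructing the reference against itself gives null images", {
  ref <- simulate_reference(default_grid(), c(128, 128), noise_free())
  rec <- reconstruct(ref, ref, pitch_px = 8)
  expect_lt(max(abs(rec$absorption)), 1e-9)
  expect_lt(max(abs(rec$scatter_h)), 1e-9)
  expect_lt(max(abs(rec$scatter_v)), 1e-9)
})

test_that("uniform attenuation is recovered by the zero-order ratio", {
  g <- default_grid()
  ref <- simulate_reference(g, c(128, 128), noise_free())
  ph <- uniform_sigma_phantom(c(128, 128), 0, optical_depth = 0.5)
  rec <- reconstruct(simulate_acquisition(ph, g, noise_free()), ref,
                     pitch_px = 8)
  interior_abs <- interior(rec$absorption, rec$margin)
  expect_equal(mean(interior_abs), 0.5, tolerance = 1e-6)
  expect_lt(max(abs(interior(rec$scatter_h, rec$margin))), 1e-9)
})

test_that("uniform blur yields the closed-form scatter metric", {
  # sigma = 1.2 px at pitch 8: S = 2 pi^2 sigma^2 f0^2 = 0.4441
  g <- default_grid(8)
  ref <- simulate_reference(g, c(128, 128), noise_free())
  sample <- simulate_acquisition(uniform_sigma_phantom(c(128, 128), 1.2),
                                 g, noise_free())
  rec <- reconstruct(sample, ref, pitch_px = 8)
  closed_form <- 2 * pi^2 * 1.2^2 * (1 / 8)^2
  expect_equal(mean(interior(rec$scatter_h, rec$margin)), closed_form,
               tolerance = 0.02)
  expect_equal(mean(interior(rec$scatter_v, rec$margin)), closed_form,
               tolerance = 0.02)
})

test_that("scatter metric is linear in blur variance", {
  g <- default_grid()
  ref <- simulate_reference(g, c(128, 128), noise_free())
  sig <- seq(0.3, 1.5, by = 0.3)
  S <- vapply(sig, function(s) {
    rec <- reconstruct(simulate_acquisition(uniform_sigma_phantom(c(128, 128), s),
                                            g, noise_free()), ref, pitch_px = 8)
    mean(interior(rec$scatter_h, rec$margin))
  }, numeric(1))
  fit <- stats::lm(S ~ I(sig^2))
  expect_gte(summary(fit)$r.squared, 0.999)
})

test_that("degenerate and corrupt inputs are flagged", {
  g0 <- grid_spec(8, duty = 0)
  ref0 <- simulate_reference(g0, c(64, 64), noise_free())
  expect_error(reconstruct(ref0, ref0, pitch_px = 8), "no grid detected")
  ref <- simulate_reference(default_grid(), c(64, 64), noise_free())
  expect_error(reconstruct(ref, matrix(0, 64, 64), pitch_px = 8),
               "flat-field")
  expect_error(reconstruct(ref, ref[1:32, ], pitch_px = 8), "shapes differ")
})

test_that("scatter metric inverts back to the blur width", {
  expect_equal(scatter_to_sigma(0, 1 / 8), 0, ignore_attr = TRUE)
  # algebraic inverse of the closed form: S = 0.4441 at f0 = 1/8 -> 1.2 px
  S <- 2 * pi^2 * 1.2^2 * (1 / 8)^2
  expect_equal(scatter_to_sigma(S, 1 / 8), 1.2, ignore_attr = TRUE)
  expect_warning(out <- scatter_to_sigma(c(-0.01, 0.1), 1 / 8), "clipped")
  expect_equal(out[1], 0)
  expect_equal(attr(out, "n_clipped"), 1L)
})

test_that("simulate -> reconstruct -> invert recovers sigma within 5%", {
  g <- default_grid()
  ref <- simulate_reference(g, c(128, 128), noise_free(1e5))
  for (sigma in c(0.5, 1.0, 1.5)) {
    rec <- reconstruct(
      simulate_acquisition(uniform_sigma_phantom(c(128, 128), sigma),
                           g, noise_free(1e5)), ref, pitch_px = 8)
    est <- scatter_to_sigma(mean(interior(rec$scatter_h, rec$margin)), 1 / 8)
    expect_equal(as.numeric(est), sigma, tolerance = 0.05)
  }
})
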