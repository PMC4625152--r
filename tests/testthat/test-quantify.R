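test_that("ROI statistics match a brute-force loop over mask pixels", {
  set.seed(11)
  img <- matrix(rnorm(64 * 64), 64, 64)
  r <- roi("blob", center = c(30, 40), axes = c(9, 6), angle_deg = 20)
  st <- roi_stats(img, r)
  # naive-summation oracle over the rasterized mask
  mask <- sfhi:::.roi_mask(r, c(64, 64))
  acc <- c(); for (i in 1:64) for (j in 1:64) if (mask[i, j])
    acc <- c(acc, img[i, j])
  expect_equal(st$mean, sum(acc) / length(acc), tolerance = 1e-12)
  expect_equal(st$sd, stats::sd(acc), tolerance = 1e-12)
  expect_equal(st$n, length(acc))
})

test_that("constant and checkerboard images give textbook ROI statistics", {
  img5 <- matrix(5, 32, 32)
  r <- roi("r", center = c(16, 16), axes = c(8, 8))
  st <- roi_stats(img5, r)
  expect_equal(st$mean, 5)
  expect_equal(st$sd, 0)
  checker <- outer(1:32, 1:32, function(i, j) (i + j) %% 2)
  full <- roi("all", mask = matrix(TRUE, 32, 32))
  expect_equal(roi_stats(checker, full)$mean, 0.5)
  expect_error(roi_stats(img5, roi("empty", mask = matrix(FALSE, 32, 32))),
               "zero pixels")
})

test_that("signal enhancement implements the percent-change definition", {
  img <- matrix(1, 64, 64)
  tgt <- roi("t", center = c(20, 20), axes = c(6, 6))
  ctl <- roi("c", center = c(44, 44), axes = c(6, 6), role = "control")
  expect_equal(signal_enhancement(img, tgt, ctl)$enhancement_pct, 0)
  img[sfhi:::.roi_mask(tgt, c(64, 64))] <- 1.129
  enh <- signal_enhancement(img, tgt, ctl)
  expect_equal(enh$enhancement_pct, 12.9, tolerance = 1e-12)
  expect_error(signal_enhancement(matrix(0, 64, 64), tgt, ctl), "undefined")
})

test_that("enhancement is invariant under image rescaling", {
  set.seed(3)
  img <- matrix(runif(64 * 64, 1, 2), 64, 64)
  tgt <- roi("t", center = c(20, 20), axes = c(6, 6))
  ctl <- roi("c", center = c(44, 44), axes = c(6, 6), role = "control")
  e1 <- signal_enhancement(img, tgt, ctl)$enhancement_pct
  e2 <- signal_enhancement(37.5 * img, tgt, ctl)$enhancement_pct
  expect_equal(e1, e2, tolerance = 1e-12)
})

test_that("integrated optical density is background-subtracted summation", {
  expect_equal(iod(matrix(0, 10, 10)), 0)
  img <- matrix(0, 20, 20); img[1, 1:10] <- 101
  expect_equal(iod(img, threshold = 1), 1000)
  # doubling the stained area doubles the IOD
  img2 <- img; img2[2, 1:10] <- 101
  expect_equal(iod(img2, 1), 2 * iod(img, 1))
  # monotone nonincreasing in threshold
  thresholds <- c(0, 1, 50, 100, 101)
  vals <- vapply(thresholds, function(t) iod(img, t), numeric(1))
  expect_true(all(diff(vals) <= 0))
})

test_that("published immunofluorescence IODs reproduce factors 11 and 12", {
  tab <- sfhi_example_table("iod_immunofluorescence")
  f <- sapply(split(tab, tab$diameter_nm), function(d)
    enhancement_factor(d$value[d$role == "target"],
                       d$value[d$role == "control"]))
  expect_equal(unname(f["10"]), 532 / mean(c(38, 61)), tolerance = 1e-12)
  expect_equal(unname(report_factor(f)), c(11, 12))
})

test_that("enhancement factor times the control mean returns the target", {
  expect_equal(enhancement_factor(7.3, c(7.3)), 1)
  a <- 532; ctrl <- c(38, 61)
  expect_equal(enhancement_factor(a, ctrl) * mean(ctrl), a, tolerance = 1e-15)
  expect_error(enhancement_factor(5, numeric(0)), "control")
  expect_error(enhancement_factor(5, c(2, 0)), "positive")
})

test_that("ratio tables reproduce the published uptake ratios", {
  tg <- sfhi_example_table("tumor_gold")
  tumors <- tg[tg$compartment == "tumor", ]
  livers <- tg[tg$compartment == "liver", ]
  rt <- ratio_table(tumors, "Au-PEG-COOH", paired_compartment = livers)
  expect_equal(rt$ratio_display[rt$label == "Au-PEG-COOH"], 1.00)
  expect_equal(rt$ratio_display[rt$label == "Au-PEG-FB50 tumor 2"], 1.33)
  expect_true(all(rt$ratio > 0))
  # the untargeted liver holds ~3x the gold of the targeted one
  bio <- sfhi_example_table("organ_biodistribution")
  liver <- bio[bio$organ == "liver", c("agent", "mass")]
  names(liver) <- c("label", "value")
  lr <- ratio_table(liver, "Au-PEG-FB50")
  expect_equal(round(lr$ratio[lr$label == "Au-PEG-COOH"]), 3)
  expect_error(ratio_table(liver, "nope"), "not found")
})

test_that("ratio tables are invariant under common unit rescaling", {
  m <- data.frame(label = c("a", "b", "c"), value = c(18, 26, 24))
  r1 <- ratio_table(m, "a")$ratio
  m2 <- m; m2$value <- m2$value * 1000  # ug -> ng
  expect_equal(ratio_table(m2, "a")$ratio, r1, tolerance = 1e-15)
  single <- ratio_table(data.frame(label = "only", value = 2.5), "only")
  expect_equal(single$ratio_display, 1.00)
})

test_that("biodistribution summary reproduces the liver-dominance factors", {
  bio <- sfhi_example_table("organ_biodistribution")
  po <- split(bio$mass, bio$organ)
  bs <- biodistribution_summary(po, "liver")
  expect_equal(bs$mean_mass[bs$organ == "liver"], mean(c(115, 38)))
  expect_equal(bs$factor[bs$organ == "spleen"], 76.5 / 21.5, tolerance = 1e-12)
  expect_equal(bs$factor_reported[bs$organ == "spleen"], 4)
  # lungs mean 0.5 -> raw factor 153 (an order-of-magnitude published as ~100)
  expect_equal(bs$factor[bs$organ == "lungs"], 153)
  same <- biodistribution_summary(list(liver = c(2, 4), other = c(2, 4)))
  expect_equal(same$factor, c(1, 1))
  zero <- biodistribution_summary(list(liver = c(1, 1), gone = c(0, 0)))
  expect_equal(zero$factor[zero$organ == "gone"], Inf)
})

test_that("cellular uptake of bare vs PEGylated particles differs by ~2 orders", {
  up <- sfhi_example_table("cell_uptake")
  ratio <- up$value[up$label == "Au-cit"] / up$value[up$label == "Au-PEG-COOH"]
  expect_equal(ratio, 69)
  expect_equal(round(log10(ratio)), 2)
})

test_that("ROI definitions round-trip through the JSON file format", {
  rois <- list(
    roi("tumor", center = c(30, 40), axes = c(6, 7), role = "target"),
    roi("bg", center = c(60, 20), axes = c(5, 5), angle_deg = 15,
        role = "control"))
  path <- withr::local_tempfile(fileext = ".json")
  write_rois(rois, path)
  back <- read_rois(path)
  expect_equal(back, rois)
})
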