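#!/usr/bin/env Rscript
# Dual-modality figure: colour-mapped scatter image alpha-blended over the
# grayscale absorption image, thresholded so that only scatter-bright
# (gold-labeled) tissue is colored.

suppressPackageStartupMessages(library(sfhi))

out <- "results/run"
absorption <- read_image(file.path(out, "absorption.tiff"))
scatter <- read_image(file.path(out, "scatter_h.tiff"))

thr <- as.numeric(quantile(scatter, 0.9))
ov <- overlay(absorption, scatter,
              overlay_spec(alpha = 0.5, threshold = thr))
png::writePNG(ov, file.path(out, "overlay.png"))
cat(sprintf("Overlay: threshold %.3f colors %.1f%% of pixels; wrote %s\n",
            thr, 100 * mean(scatter > thr), file.path(out, "overlay.png")))
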