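#!/usr/bin/env Rscript
# Stage 2: segment the stage-1 scans, landmark every kernel, apply shape
# and color QC, and aggregate to per-plot hue phenotypes. Compares the
# recovered plot hues with the generator's ground truth.

suppressMessages(library(pericolor))
truth <- read.csv("results/scan_truth.csv")

kernel_tables <- list()
for (i in seq_len(nrow(truth))) {
  scan <- readRDS(file.path("scratch", sprintf("scan_%s.rds", truth$plot[i])))
  seg <- segment_scan(scan$image)
  ak <- analyze_kernels(seg$labeled, scan$image, image_id = truth$plot[i])
  q <- shape_qc(ak$kernels)
  cat(sprintf("%s: %d components, %d geometry-removed, %d shape-QC-removed\n",
              truth$plot[i], seg$labeled$n_components, nrow(ak$removed),
              nrow(q$removed)))
  kernel_tables[[i]] <- q$kernels
}
kernels <- do.call(rbind, kernel_tables)
cq <- color_qc(kernels)
cat("color QC removed", nrow(cq$removed), "of", nrow(kernels), "kernels\n")
write.csv(cq$kernels, "results/kernel_table.csv", row.names = FALSE)

meta <- data.frame(image_id = truth$plot, line_id = truth$plot, replicate = 1)
agg <- aggregate_line_hue(cq$kernels, meta)
out <- merge(agg$lines, truth[, c("plot", "target_hue", "truth_hue")],
             by.x = "line_id", by.y = "plot")
out$abs_error <- abs(out$hue - out$truth_hue)
write.csv(out, "results/plot_hue.csv", row.names = FALSE)
cat("plot hue recovery (deg):\n")
print(out[, c("line_id", "truth_hue", "hue", "abs_error", "n_kernels")],
      digits = 4)
cat("max abs error:", round(max(out$abs_error), 3), "deg;",
    "hue is monotone in truth:", !is.unsorted(out$hue[order(out$truth_hue)]),
    "\n")
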