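#!/usr/bin/env Rscript
# Stage 1: generate the synthetic raw data for the downstream stages -- a
# set of kernel-scan images with known per-kernel color and a DH population
# segregating under a two-locus epistatic model.

suppressMessages(library(pericolor))
dir.create("results", showWarnings = FALSE); dir.create("scratch", showWarnings = FALSE)

seed <- 1L

# five plots, one scan each, on a darkness ladder of known line hues
plot_hues <- c(P1 = 27, P2 = 30, P3 = 33, P4 = 36, P5 = 39)
truth_rows <- list()
for (i in seq_along(plot_hues)) {
  spec <- kernel_scan_spec(n_kernels = 50, canvas = c(900, 700),
                           body_hue = plot_hues[i], hue_sd = 2,
                           damaged_frac = 0.1, debris_count = 2)
  scan <- generate_kernel_scan(spec, seed = seed + i)
  saveRDS(scan, file.path("scratch", sprintf("scan_%s.rds", names(plot_hues)[i])))
  truth_rows[[i]] <- data.frame(plot = names(plot_hues)[i],
                                target_hue = plot_hues[i],
                                truth_hue = mean(scan$truth$per_kernel$hue),
                                n_kernels = scan$truth$kernel_count)
}
truth <- do.call(rbind, truth_rows)
write.csv(truth, "results/scan_truth.csv", row.names = FALSE)
cat("wrote", nrow(truth), "scans; truth hues:",
    paste(round(truth$truth_hue, 2), collapse = ", "), "\n")

# DH population: 150 lines, functional-A-and-(B-or-C) pigment model,
# 2-degree main QTL plus a 1-degree modifier
map <- make_marker_map(n_chr = 5, n_markers = 60, chr_length_cM = 120)
m <- genetic_models()
causal <- data.frame(locus = c("A", "B", "C"),
                     marker = c("S1_030", "S2_030", "S3_030"),
                     effect_deg = c(2, 1, 0.5))
pop <- simulate_dh_population(150, map, model = m[m$name == "a_and_b_or_c", ],
                              causal = causal, seed = seed)
write.csv(data.frame(line = rownames(pop$geno), pop$geno,
                     check.names = FALSE),
          "results/population_genotypes.csv", row.names = FALSE)
write.csv(pop$map, "results/population_map.csv", row.names = FALSE)
write.csv(pop$pheno, "results/population_phenotypes.csv", row.names = FALSE)
write.csv(data.frame(line = names(pop$pigment), pigment = pop$pigment),
          "results/population_pigment.csv", row.names = FALSE)
saveRDS(pop, "scratch/population.rds")
cat("simulated", nrow(pop$geno), "DH lines x", ncol(pop$geno), "markers;",
    sum(pop$pigment), "pigmented /", sum(pop$pigment == 0), "clear\n")
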