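#!/usr/bin/env Rscript
# Stage 5: genome scan on the stage-1 population. QC, HMM genotype
# probabilities, Haley-Knott LOD scan, 1,000-permutation threshold, peak
# credible intervals and shrunken allele effects; LD and variance
# explained at the top peak.

suppressMessages(library(pericolor))
pop <- readRDS("scratch/population.rds")

qc <- filter_markers_individuals(pop$geno, pop$map)
cat("QC:", nrow(qc$geno), "individuals x", ncol(qc$geno), "markers kept;",
    nrow(qc$report), "removals\n")

prob <- dh_genotype_probabilities(qc$geno, qc$map)
bl <- fit_line_blues(pop$pheno)
y <- bl$blues[rownames(qc$geno)]

scan <- hk_scan(prob, y)
th <- permutation_threshold(prob, y, n_perm = 1000, seed = 2)
cat(sprintf("LOD threshold (1,000 permutations, alpha 0.05): %.2f\n",
            th$threshold))

scan_df <- data.frame(marker = qc$map$marker, chr = qc$map$chr,
                      pos_cM = qc$map$pos_cM, lod = scan$lod)
write.csv(scan_df, "results/lod_scan.csv", row.names = FALSE)

peaks <- peak_intervals(scan_df, th$threshold)
if (nrow(peaks) > 0) {
  eff <- lapply(peaks$marker, function(mk) blup_allele_effect(prob[, mk], y,
                parents = c("parentA", "parentB")))
  peaks$effect_deg <- round(vapply(eff, `[[`, numeric(1), "effect"), 2)
  peaks$donor <- vapply(eff, `[[`, character(1), "donor")
}
write.csv(peaks, "results/qtl_peaks.csv", row.names = FALSE)
cat("significant peaks (true QTL at S1_030 / S2_030 / S3_030, effects 2 / 1 / 0.5 deg):\n")
print(peaks, digits = 4)

if (nrow(peaks) > 0) {
  top <- peaks$marker[which.max(peaks$lod)]
  dos <- geno_to_dosage(qc$geno)[, top]
  cat(sprintf("\ntop peak %s: variance explained (adj R2) = %.3f\n",
              top, variance_explained(y, dos)))
  near <- qc$map$marker[qc$map$chr == qc$map$chr[qc$map$marker == top]][1:10]
  r2 <- ld_r2(geno_to_dosage(qc$geno)[, near])
  cat("LD r2 of the first 10 markers on the peak chromosome with each other:",
      sprintf("median %.2f", stats::median(r2[upper.tri(r2)])), "\n")
}
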