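#!/usr/bin/env Rscript
# Stage 4: quantitative variation. Fits line BLUEs and the Cullis
# heritability at the trial's design scale, groups populations by Tukey
# letters, and validates hue against simulated visual ratings.

suppressMessages(library(pericolor))
dir.create("results", showWarnings = FALSE)

# design-scale trial: ~1,300 lines, partial second replicate
sim <- simulate_line_records(seed = 4)
bl <- fit_line_blues(sim$records)
h2 <- cullis_h2(bl$sigma_g2, bl$avsed)
summary_row <- data.frame(
  n_lines = length(bl$blues), heritability = round(h2$h2, 3),
  sigma_g2 = round(bl$sigma_g2, 3), avsed = round(bl$avsed, 3),
  mean = round(mean(bl$blues), 2), min = round(min(bl$blues), 2),
  max = round(max(bl$blues), 2))
write.csv(summary_row, "results/phenotypic_summary.csv", row.names = FALSE)
print(summary_row)

# population contrasts on the stage-1 population BLUEs
pop <- readRDS("scratch/population.rds")
pbl <- fit_line_blues(pop$pheno)
grp <- ifelse(pop$pigment[names(pbl$blues)] == 1, "pigmented", "clear")
tg <- tukey_groups(pbl$blues, grp)
cat("\nTukey letters (pigment class):\n"); print(tg$letters)
cat("class means:\n"); print(round(tg$means, 2))

# hue vs simulated 1-5 visual ratings: darker (lower hue) scores higher
set.seed(4)
rank5 <- cut(-pbl$blues, 5, labels = FALSE)
rating <- pmin(5, pmax(1, rank5 + sample(c(-1, 0, 0, 1), length(rank5),
                                         replace = TRUE)))
sv <- spearman_validation(pbl$blues, rating)
cat(sprintf("\nSpearman rho vs ratings: %.2f (p = %.2g)\n", sv$rho, sv$p_value))
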