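# exhaustive hidden-path oracle for the 2-state HMM on a handful of markers
enumerate_posterior <- function(obs, r, error_rate) {
  m <- length(obs)
  emis <- function(o, state) {
    if (is.na(o)) return(1)
    if (o == state) 1 - error_rate else error_rate
  }
  paths <- expand.grid(rep(list(c("A", "B")), m), stringsAsFactors = FALSE)
  w <- apply(paths, 1, function(p) {
    wt <- 0.5 * emis(obs[1], p[1])
    for (k in seq_len(m - 1)) {
      wt <- wt * (if (p[k] == p[k + 1]) 1 - r[k] else r[k]) *
        emis(obs[k + 1], p[k + 1])
    }
    wt
  })
  vapply(seq_len(m), function(k) {
    sum(w[paths[[k]] == "A"]) / sum(w)
  }, numeric(1))
}

test_that("genotype QC drops bad markers then bad individuals", {
  map <- tiny_map(1, 500, 250)
  pop <- simulate_dh_population(60, map, seed = 3,
                                missing_rate = 0, error_rate = 0)
  geno <- pop$truth$geno
  clean <- filter_markers_individuals(geno, map)
  expect_equal(nrow(clean$report), 0)

  # an individual alternating A/B at 500 markers has ~499 crossovers
  geno2 <- geno
  geno2[1, ] <- rep(c("A", "B"), length.out = 500)
  f <- filter_markers_individuals(geno2, map)
  expect_true(rownames(geno)[1] %in% f$report$id[f$report$reason == "crossovers"])
  expect_equal(nrow(f$geno), 59)

  # a marker missing in 80% of individuals goes first
  geno3 <- geno
  geno3[seq_len(48), 10] <- NA
  f3 <- filter_markers_individuals(geno3, map)
  expect_true(map$marker[10] %in% f3$report$id)

  # monomorphic markers are dropped under the MAF rule
  geno4 <- geno
  geno4[, 20] <- "A"
  f4 <- filter_markers_individuals(geno4, map)
  expect_true(map$marker[20] %in% f4$report$id)

  expect_error(filter_markers_individuals(
    matrix("A", 10, 3, dimnames = list(NULL, c("a", "b", "c"))),
    data.frame(marker = c("a", "b", "c"), chr = 1, pos_cM = 1:3)),
    "all markers")
})

test_that("HMM posteriors match exact enumeration and the flank formula", {
  map <- data.frame(marker = c("m1", "m2", "m3"), chr = 1, pos_cM = c(0, 5, 10))

  # missing middle marker between two A-typed flanks, no genotyping error
  g <- matrix(c("A", NA, "A"), 1, 3, dimnames = list("i1", map$marker))
  p <- dh_genotype_probabilities(g, map, error_rate = 0)
  r <- haldane(5)
  expect_equal(p[1, 2], (1 - r)^2 / ((1 - r)^2 + r^2), tolerance = 1e-12)
  expect_gt(p[1, 2], 0.98)
  expect_equal(unname(p[1, c(1, 3)]), c(1, 1))

  # with genotyping error, against the exhaustive hidden-path oracle
  for (obs in list(c("A", "B", "A"), c("B", NA, "A"), c("A", "A", "B"))) {
    g2 <- matrix(obs, 1, 3, dimnames = list("i1", map$marker))
    p2 <- dh_genotype_probabilities(g2, map, error_rate = 0.02)
    expect_equal(unname(p2[1, ]),
                 enumerate_posterior(obs, haldane(c(5, 5)), 0.02),
                 tolerance = 1e-10)
  }

  # probabilities always live in [0, 1]
  pop <- simulate_dh_population(40, tiny_map(), seed = 6)
  pr <- dh_genotype_probabilities(pop$geno, pop$map)
  expect_true(all(pr >= 0 & pr <= 1))
})

test_that("the LOD equals its closed form and caps perfect fits", {
  map <- tiny_map(1, 30, 100)
  pop <- simulate_dh_population(80, map, seed = 10,
                                missing_rate = 0, error_rate = 0)
  prob <- dh_genotype_probabilities(pop$geno, map, error_rate = 0)
  set.seed(2)
  y <- rnorm(80) + 0.8 * prob[, 15]
  names(y) <- rownames(pop$geno)
  sc <- hk_scan(prob, y)
  closed <- vapply(seq_len(ncol(prob)), function(j) {
    r <- cor(y, prob[, j])
    -(80 / 2) * log10(1 - r^2)
  }, numeric(1))
  expect_equal(unname(sc$lod), closed, tolerance = 1e-8)

  # phenotype identical to the 0/1 genotype: capped and flagged
  y2 <- prob[, 15]
  sc2 <- hk_scan(prob, y2)
  expect_equal(unname(sc2$lod[15]), 50)
  expect_true(sc2$capped[15])

  # monomorphic position scores zero
  prob2 <- prob; prob2[, 4] <- 1
  expect_equal(unname(hk_scan(prob2, y)$lod[4]), 0)
})

test_that("permutation thresholds behave at the edges", {
  map <- tiny_map(2, 25, 100)
  pop <- simulate_dh_population(60, map, seed = 12)
  prob <- dh_genotype_probabilities(pop$geno, map)
  const <- rep(1, 60); names(const) <- rownames(pop$geno)
  th0 <- permutation_threshold(prob, const, n_perm = 100, seed = 1)
  expect_equal(th0$threshold, 0)

  set.seed(3)
  y <- rnorm(60); names(y) <- rownames(pop$geno)
  th05 <- permutation_threshold(prob, y, n_perm = 200, alpha = 0.05, seed = 2)
  th20 <- permutation_threshold(prob, y, n_perm = 200, alpha = 0.20, seed = 2)
  expect_gte(th05$threshold, th20$threshold)
  expect_warning(permutation_threshold(prob, y, n_perm = 50, seed = 2),
                 "permutations")
})

test_that("peaks and intervals are reported sanely", {
  scan <- data.frame(marker = sprintf("m%02d", 1:40),
                     chr = rep(1:2, each = 20),
                     pos_cM = rep(seq(0, 95, by = 5), 2),
                     lod = 0.2)
  expect_equal(nrow(peak_intervals(scan, 3)), 0)

  spike <- scan
  spike$lod[10] <- 12
  pk <- peak_intervals(spike, 3)
  expect_equal(nrow(pk), 1)
  expect_equal(pk$marker, "m10")
  expect_lte(pk$interval_hi - pk$interval_lo, 10)
  expect_true(pk$interval_lo <= pk$pos_cM && pk$pos_cM <= pk$interval_hi)

  drop <- peak_intervals(spike, 3, method = "lod_drop")
  expect_equal(drop$marker, "m10")
})

test_that("BLUP effects are shrunken and equivariant to recoding", {
  map <- tiny_map(1, 40, 120)
  pop <- simulate_dh_population(
    150, map, model = genetic_models()[1, ],
    causal = data.frame(locus = "A", marker = "S1_020", effect_deg = 2),
    residual_sd = 1, n_reps = 1, prop_two_rep = 0, seed = 77,
    missing_rate = 0, error_rate = 0)
  prob <- dh_genotype_probabilities(pop$geno, map, error_rate = 0)
  y <- setNames(pop$pheno$hue, pop$pheno$line)[rownames(pop$geno)]
  eff <- blup_allele_effect(prob[, "S1_020"], y, parents = c("P_A", "P_B"))
  expect_lt(abs(eff$effect - (-2)), 0.5)
  expect_equal(eff$donor, "P_A")
  expect_lte(abs(eff$effect), abs(eff$ols_effect) + 1e-8)

  flipped <- blup_allele_effect(1 - prob[, "S1_020"], y, parents = c("P_A", "P_B"))
  expect_equal(flipped$effect, -eff$effect, tolerance = 1e-6)

  # null phenotype: effect shrunk essentially to zero
  set.seed(8)
  ynull <- rnorm(150); names(ynull) <- rownames(pop$geno)
  null_eff <- blup_allele_effect(prob[, "S1_020"], ynull)
  expect_lte(abs(null_eff$effect), abs(null_eff$ols_effect) + 1e-8)
})

test_that("LD r2 is a proper squared correlation matrix", {
  set.seed(14)
  map <- tiny_map(2, 10, 100)
  pop <- simulate_dh_population(10000, map, seed = 15,
                                missing_rate = 0, error_rate = 0)
  d <- geno_to_dosage(pop$truth$geno)
  r2 <- ld_r2(d[, c("S1_001", "S1_002", "S2_001")])
  expect_equal(unname(diag(r2)), rep(1, 3))
  expect_equal(r2, t(r2))
  expect_true(all(r2 >= 0 & r2 <= 1))
  # markers on different chromosomes are unlinked
  expect_lt(r2["S1_001", "S2_001"], 0.01)
  # perfectly co-inherited markers
  dd <- cbind(a = d[, 1], b = d[, 1])
  expect_equal(ld_r2(dd)["a", "b"], 1)
})

test_that("variance explained by a marker is the adjusted R-squared", {
  set.seed(16)
  dos <- rbinom(1000, 1, 0.5)
  expect_gt(variance_explained(2 * dos + rnorm(1000, 0, 1e-6), dos), 0.999)
  expect_lt(abs(variance_explained(rnorm(1000), dos)), 0.01)
  expect_warning(ve <- variance_explained(rnorm(10), rep(1, 10)), "constant")
  expect_true(is.na(ve))

  # a marker built to explain 8% of variance at the panel size of 416
  est <- vapply(seq_len(20), function(i) {
    set.seed(600 + i)
    d <- rbinom(416, 1, 0.21)
    beta <- 1
    sigma2 <- beta^2 * var(d) * (1 - 0.08) / 0.08
    variance_explained(beta * d + rnorm(416, 0, sqrt(sigma2)), d)
  }, numeric(1))
  expect_lt(abs(mean(est) - 0.08), 0.03)
})
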