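#' Marker and individual quality control for a DH genotype matrix
#'
#' Applies the genotype QC rules used before mapping: markers with more than
#' `max_marker_missing` missing data, minor allele frequency below
#' `min_maf`, or no polymorphism are dropped first; then individuals with
#' more than `max_crossovers` apparent crossovers (counted on the ordered
#' map with [count_crossovers()]) or more than `max_ind_missing` missing
#' calls are dropped.
#'
#' @param geno Individuals x markers character matrix of "A"/"B"/NA.
#' @param map Marker map matching the columns of `geno`.
#' @param max_marker_missing,min_maf,max_crossovers,max_ind_missing QC
#'   thresholds (defaults 0.75, 0.05, 200, 0.15).
#' @return List with filtered `geno`, `map` and a `report` data frame
#'   listing every removed marker/individual and the reason.
#' @export
filter_markers_individuals <- function(geno, map,
                                       max_marker_missing = 0.75,
                                       min_maf = 0.05,
                                       max_crossovers = 200,
                                       max_ind_missing = 0.15) {
  stopifnot(ncol(geno) == nrow(map))
  report <- data.frame(id = character(0), type = character(0),
                       reason = character(0), stringsAsFactors = FALSE)

  miss_m <- colMeans(is.na(geno))
  freq_a <- colMeans(geno == "A", na.rm = TRUE)
  maf <- pmin(freq_a, 1 - freq_a)
  maf[is.nan(maf)] <- 0
  drop_miss <- miss_m > max_marker_missing
  drop_maf <- !drop_miss & maf < min_maf
  for (j in which(drop_miss)) {
    report <- rbind(report, data.frame(id = map$marker[j], type = "marker",
                                       reason = "missingness", stringsAsFactors = FALSE))
  }
  for (j in which(drop_maf)) {
    report <- rbind(report, data.frame(id = map$marker[j], type = "marker",
                                       reason = if (maf[j] == 0) "monomorphic" else "maf",
                                       stringsAsFactors = FALSE))
  }
  keep_m <- !(drop_miss | drop_maf)
  if (!any(keep_m)) stop("all markers removed by QC")
  geno <- geno[, keep_m, drop = FALSE]
  map <- map[keep_m, , drop = FALSE]

  xo <- count_crossovers(geno, map)
  miss_i <- rowMeans(is.na(geno))
  drop_xo <- xo > max_crossovers
  drop_mi <- miss_i > max_ind_missing
  ids <- rownames(geno)
  for (i in which(drop_xo)) {
    report <- rbind(report, data.frame(id = ids[i], type = "individual",
                                       reason = "crossovers", stringsAsFactors = FALSE))
  }
  for (i in which(drop_mi & !drop_xo)) {
    report <- rbind(report, data.frame(id = ids[i], type = "individual",
                                       reason = "missingness", stringsAsFactors = FALSE))
  }
  keep_i <- !(drop_xo | drop_mi)
  list(geno = geno[keep_i, , drop = FALSE], map = map, report = report)
}

#' Hidden-Markov genotype probabilities for a DH population
#'
#' Two-state (parental origin A or B) forward-backward smoothing along each
#' chromosome. Transition probabilities between adjacent markers come from
#' the map distance via the Haldane map function; the emission model allows
#' a symmetric genotyping-error rate, and missing calls emit uninformatively.
#'
#' @param geno Individuals x markers character matrix of "A"/"B"/NA.
#' @param map Matching marker map (`chr`, `pos_cM`, strictly increasing
#'   within chromosome).
#' @param error_rate Genotyping error probability per call (default 0.002).
#' @return Matrix of P(origin = A), individuals x markers; P(B) is its
#'   complement, so the two probabilities sum to one at every position.
#' @export
dh_genotype_probabilities <- function(geno, map, error_rate = 0.002) {
  stopifnot(ncol(geno) == nrow(map), error_rate >= 0, error_rate < 0.5)
  n <- nrow(geno)
  pA <- matrix(NA_real_, n, ncol(geno), dimnames = dimnames(geno))

  # emission P(obs | state A) and P(obs | state B) per call
  e_a <- matrix(1, n, ncol(geno))  # P(obs | A)
  e_b <- matrix(1, n, ncol(geno))
  obs_a <- !is.na(geno) & geno == "A"
  obs_b <- !is.na(geno) & geno == "B"
  e_a[obs_a] <- 1 - error_rate; e_b[obs_a] <- error_rate
  e_a[obs_b] <- error_rate;     e_b[obs_b] <- 1 - error_rate

  for (ch in unique(map$chr)) {
    idx <- which(map$chr == ch)
    m <- length(idx)
    r <- if (m > 1) haldane(diff(map$pos_cM[idx])) else numeric(0)

    # scaled forward
    fA <- matrix(0, n, m); fB <- matrix(0, n, m)
    a <- 0.5 * e_a[, idx[1]]; b <- 0.5 * e_b[, idx[1]]
    s <- a + b
    fA[, 1] <- a / s; fB[, 1] <- b / s
    for (k in seq_len(m - 1)) {
      pa <- fA[, k] * (1 - r[k]) + fB[, k] * r[k]
      pb <- fA[, k] * r[k] + fB[, k] * (1 - r[k])
      a <- pa * e_a[, idx[k + 1]]; b <- pb * e_b[, idx[k + 1]]
      s <- a + b
      fA[, k + 1] <- a / s; fB[, k + 1] <- b / s
    }

    # scaled backward
    bA <- matrix(1, n, m); bB <- matrix(1, n, m)
    if (m > 1) {
      for (k in (m - 1):1) {
        ea <- e_a[, idx[k + 1]] * bA[, k + 1]
        eb <- e_b[, idx[k + 1]] * bB[, k + 1]
        a <- (1 - r[k]) * ea + r[k] * eb
        b <- r[k] * ea + (1 - r[k]) * eb
        s <- a + b
        bA[, k] <- a / s; bB[, k] <- b / s
      }
    }

    post_a <- fA * bA
    pA[, idx] <- post_a / (post_a + fB * bB)
  }
  pA
}

#' Haley-Knott single-QTL LOD scan
#'
#' At every marker the phenotype is regressed on the probability of carrying
#' the parent-A allele, and the LOD score is
#' \eqn{(n/2)\log_{10}(RSS_0/RSS_1)} with \eqn{RSS_0} from the
#' intercept-only model. Numerically perfect fits are capped at `lod_cap`
#' and flagged; monomorphic positions score 0.
#'
#' @param prob Individuals x markers matrix of P(A) from
#'   [dh_genotype_probabilities()].
#' @param pheno Numeric phenotype per individual (NAs dropped with their
#'   rows).
#' @param lod_cap Cap for infinite LOD scores (default 50).
#' @return List with `lod` (per-marker vector), `n` (individuals used) and
#'   `capped` (logical per marker).
#' @export
hk_scan <- function(prob, pheno, lod_cap = 50) {
  keep <- !is.na(pheno)
  prob <- prob[keep, , drop = FALSE]
  y <- pheno[keep]
  n <- length(y)
  if (n < 20) stop("phenotype available for fewer than 20 individuals")
  lod <- .hk_lod_matrix(prob, matrix(y, ncol = 1), lod_cap = lod_cap)
  list(lod = lod$lod[, 1], n = n, capped = lod$capped[, 1])
}

# core Haley-Knott computation shared by the scan and the permutation test:
# LOD for every marker (rows) against every phenotype column
.hk_lod_matrix <- function(prob, Y, lod_cap = 50) {
  n <- nrow(prob)
  Xc <- sweep(prob, 2, colMeans(prob))
  Yc <- sweep(Y, 2, colMeans(Y))
  sxx <- colSums(Xc^2)
  syy <- colSums(Yc^2)
  sxy <- crossprod(Xc, Yc)                       # markers x phenotypes
  denom <- outer(sxx, syy)
  r2 <- ifelse(denom > 0, sxy^2 / denom, 0)
  r2 <- pmin(r2, 1)
  lod <- -(n / 2) * log10(1 - r2)
  capped <- !is.finite(lod) | lod > lod_cap
  lod[capped] <- lod_cap
  lod[syy[col(lod)] == 0] <- 0                   # constant phenotype
  dimnames(lod) <- list(colnames(prob), colnames(Y))
  list(lod = lod, capped = capped)
}

#' Genome-wide permutation LOD threshold
#'
#' Permutes the phenotype against the genotype probabilities `n_perm` times
#' and returns the `1 - alpha` quantile of the genome-wide maximum LOD.
#'
#' @param prob,pheno As in [hk_scan()].
#' @param n_perm Number of permutations (default 1000; fewer than 100 draws
#'   a warning about quantile instability).
#' @param alpha Genome-wide error rate (default 0.05).
#' @param seed Integer seed for the permutations.
#' @return List with `threshold`, `max_lod` (the permutation distribution),
#'   `n_perm` and `alpha`.
#' @export
permutation_threshold <- function(prob, pheno, n_perm = 1000, alpha = 0.05,
                                  seed = 1) {
  if (n_perm < 100) warning("fewer than 100 permutations: unstable quantile")
  keep <- !is.na(pheno)
  prob <- prob[keep, , drop = FALSE]
  y <- pheno[keep]
  set.seed(seed)
  Y <- vapply(seq_len(n_perm), function(i) y[sample.int(length(y))],
              numeric(length(y)))
  lod <- .hk_lod_matrix(prob, Y)$lod
  mx <- apply(lod, 2, max)
  list(threshold = unname(stats::quantile(mx, 1 - alpha)),
       max_lod = mx, n_perm = n_perm, alpha = alpha)
}

#' Find significant peaks and their credible intervals
#'
#' Per chromosome, if the maximum LOD reaches the threshold the peak is
#' reported together with an interval: by default the Bayesian credible
#' interval (smallest contiguous region around the peak holding `prob` of
#' the chromosome's normalized \eqn{10^{LOD}} mass), or a LOD-drop support
#' interval.
#'
#' @param scan Data frame with `marker`, `chr`, `pos_cM` and `lod` columns.
#' @param threshold LOD significance threshold.
#' @param method `"bayes"` (default) or `"lod_drop"`.
#' @param prob Credible mass for the Bayes interval (default 0.95).
#' @param lod_drop LOD units for the drop interval (default 1.5).
#' @return Data frame of peaks: `chr`, `pos_cM`, `marker`, `lod`,
#'   `interval_lo`, `interval_hi` (cM). Zero rows when nothing is
#'   significant.
#' @export
peak_intervals <- function(scan, threshold, method = c("bayes", "lod_drop"),
                           prob = 0.95, lod_drop = 1.5) {
  method <- match.arg(method)
  stopifnot(all(c("marker", "chr", "pos_cM", "lod") %in% names(scan)))
  peaks <- list()
  for (ch in unique(scan$chr)) {
    sub <- scan[scan$chr == ch, , drop = FALSE]
    if (max(sub$lod) < threshold) next
    pk <- which.max(sub$lod)
    if (method == "bayes") {
      w <- 10^(sub$lod - max(sub$lod))
      w <- w / sum(w)
      lo <- hi <- pk
      mass <- w[pk]
      while (mass < prob && (lo > 1 || hi < nrow(sub))) {
        w_lo <- if (lo > 1) w[lo - 1] else -Inf
        w_hi <- if (hi < nrow(sub)) w[hi + 1] else -Inf
        if (w_lo >= w_hi) { lo <- lo - 1; mass <- mass + w[lo] }
        else { hi <- hi + 1; mass <- mass + w[hi] }
      }
    } else {
      keepl <- sub$lod >= sub$lod[pk] - lod_drop
      lo <- pk; while (lo > 1 && keepl[lo - 1]) lo <- lo - 1
      hi <- pk; while (hi < nrow(sub) && keepl[hi + 1]) hi <- hi + 1
    }
    peaks[[length(peaks) + 1]] <- data.frame(
      chr = ch, pos_cM = sub$pos_cM[pk], marker = sub$marker[pk],
      lod = sub$lod[pk], interval_lo = sub$pos_cM[lo],
      interval_hi = sub$pos_cM[hi], stringsAsFactors = FALSE)
  }
  if (length(peaks) == 0) {
    return(data.frame(chr = integer(0), pos_cM = numeric(0),
                      marker = character(0), lod = numeric(0),
                      interval_lo = numeric(0), interval_hi = numeric(0)))
  }
  do.call(rbind, peaks)
}

#' Shrunken (BLUP) allele effect at a QTL peak
#'
#' Individuals are classed by their most probable parental origin at the
#' peak and the class effect is treated as random, so the estimated
#' difference is shrunken toward zero relative to the ordinary
#' least-squares class contrast. The reported effect is the effect of
#' carrying the parent-A allele relative to parent B; a negative effect
#' means the A allele lowers hue (darker pericarp), and the donor parent is
#' the one whose allele carries the negative effect.
#'
#' @param prob_peak P(A) per individual at the peak marker.
#' @param pheno Phenotype per individual.
#' @param parents Names of the two parents, in (A, B) order.
#' @return List with `effect` (shrunken A-vs-B difference), `ols_effect`,
#'   `donor` (parent contributing the hue-lowering allele) and `sigma_u`
#'   (the random-effect SD).
#' @export
blup_allele_effect <- function(prob_peak, pheno, parents = c("A", "B")) {
  keep <- !is.na(pheno) & !is.na(prob_peak)
  y <- pheno[keep]
  cls <- factor(ifelse(prob_peak[keep] >= 0.5, "A", "B"), levels = c("A", "B"))
  if (nlevels(droplevels(cls)) < 2) {
    return(list(effect = 0, ols_effect = 0, donor = NA_character_, sigma_u = 0))
  }
  ols <- unname(mean(y[cls == "A"]) - mean(y[cls == "B"]))
  fit <- suppressMessages(suppressWarnings(
    lme4::lmer(y ~ 1 + (1 | cls),
               control = lme4::lmerControl(check.conv.singular = "ignore",
                                           calc.derivs = FALSE))))
  u <- lme4::ranef(fit)$cls
  eff <- if (all(c("A", "B") %in% rownames(u))) u["A", 1] - u["B", 1] else 0
  sigma_u <- attr(lme4::VarCorr(fit)$cls, "stddev")
  donor <- if (eff < 0) parents[1] else parents[2]
  list(effect = unname(eff), ols_effect = ols, donor = donor,
       sigma_u = unname(sigma_u))
}

#' Pairwise linkage disequilibrium r-squared
#'
#' Squared Pearson correlation between allele-dosage vectors, computed on
#' pairwise-complete observations. Monomorphic markers give NA entries.
#'
#' @param dosage Individuals x markers numeric dosage matrix (0/1 for DH).
#' @return Symmetric matrix of r-squared values with unit diagonal for
#'   polymorphic markers.
#' @export
ld_r2 <- function(dosage) {
  stopifnot(ncol(dosage) >= 2)
  r <- suppressWarnings(stats::cor(dosage, use = "pairwise.complete.obs"))
  r^2
}

#' Phenotypic variance explained by a marker
#'
#' Adjusted R-squared from the simple regression of line BLUEs on allele
#' dosage.
#'
#' @param blues Numeric BLUEs per line.
#' @param dosage Matching allele dosage.
#' @return Adjusted R-squared (NA when the dosage is constant).
#' @export
variance_explained <- function(blues, dosage) {
  keep <- !is.na(blues) & !is.na(dosage)
  if (stats::sd(dosage[keep]) == 0) {
    warning("constant dosage: variance explained undefined")
    return(NA_real_)
  }
  summary(stats::lm(blues[keep] ~ dosage[keep]))$adj.r.squared
}

#' Bonferroni-corrected genome-wide significance threshold
#'
#' @param alpha Family-wise error rate (default 0.05).
#' @param n_tests Number of markers tested.
#' @return `alpha / n_tests`.
#' @export
bonferroni_threshold <- function(alpha = 0.05, n_tests) {
  stopifnot(n_tests >= 1, alpha > 0, alpha < 1)
  alpha / n_tests
}

#' Convert A/B genotype calls to numeric allele dosage
#'
#' @param geno Character matrix of "A"/"B"/NA.
#' @param count_allele Allele counted as 1 (default "B").
#' @return Numeric matrix of 0/1 dosages with NAs preserved.
#' @export
geno_to_dosage <- function(geno, count_allele = "B") {
  d <- (geno == count_allele) * 1
  mode(d) <- "numeric"
  d
}
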