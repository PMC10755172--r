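#' Haldane map function
#'
#' Converts a genetic distance in centimorgans to a recombination fraction
#' under no crossover interference: \eqn{r = (1 - e^{-2d/100}) / 2}.
#'
#' @param d_cM Distance in centimorgans (vectorized, non-negative).
#' @return Recombination fraction(s) in [0, 0.5).
#' @export
haldane <- function(d_cM) {
  stopifnot(all(d_cM >= 0))
  (1 - exp(-2 * d_cM / 100)) / 2
}

#' Build a regular marker map
#'
#' @param n_chr Number of chromosomes.
#' @param n_markers Markers per chromosome.
#' @param chr_length_cM Chromosome length in cM; markers are equally spaced
#'   from 0 to `chr_length_cM`.
#' @return Data frame with `marker`, `chr` (integer), `pos_cM`.
#' @export
make_marker_map <- function(n_chr = 10, n_markers = 100, chr_length_cM = 150) {
  stopifnot(n_chr >= 1, n_markers >= 2, chr_length_cM > 0)
  do.call(rbind, lapply(seq_len(n_chr), function(ch) {
    pos <- seq(0, chr_length_cM, length.out = n_markers)
    data.frame(marker = sprintf("S%d_%03d", ch, seq_len(n_markers)),
               chr = ch, pos_cM = pos, stringsAsFactors = FALSE)
  }))
}

#' Simulate a doubled haploid biparental population
#'
#' Each DH line is a mosaic of the two fully inbred parental genomes ("A"
#' and "B"). Along every chromosome the parental origin follows a Markov
#' chain: the first marker allele is drawn with probability 1/2 and the
#' origin switches between adjacent markers with the recombination fraction
#' given by the Haldane map function on the inter-marker distance.
#'
#' The qualitative pigment phenotype is assigned by evaluating the genetic
#' model's locus logic at designated causal markers (the "A" allele is the
#' functional one by default). The quantitative hue phenotype follows the
#' two-way structure of a replicated field trial,
#' hue = baseline - sum(carried QTL effects) + replicate effect + residual,
#' so that carrying a pigmenting allele lowers hue (darker pericarp).
#' Genotyping errors (allele flips) and missing calls are injected into the
#' returned genotype matrix at configurable rates; phenotypes are always
#' computed from the true mosaic.
#'
#' @param n_ind Number of DH lines (> 0).
#' @param map Marker map as from [make_marker_map()]; positions must be
#'   strictly increasing within chromosome.
#' @param model Optional one-row subset of [genetic_models()] (or a list with
#'   `logic` and `loci`) giving the qualitative pigment logic. When `NULL`
#'   no binary phenotype is produced.
#' @param causal Data frame mapping loci to the map: columns `locus`,
#'   `marker` (must exist in `map`) and `effect_deg` (hue decrease in
#'   degrees when the functional "A" allele is carried; may be 0 for loci
#'   that act only qualitatively).
#' @param baseline_hue Mean hue (degrees) of a line carrying no QTL allele.
#' @param replicate_sd SD of the random replicate effect (degrees).
#' @param residual_sd SD of the residual (degrees).
#' @param n_reps Number of field replicates; `prop_two_rep` of the lines are
#'   observed in all replicates, the rest only in replicate 1 (mirrors a
#'   partially harvested second replicate).
#' @param prop_two_rep Proportion of lines observed in every replicate.
#' @param missing_rate,error_rate Per-call rates of missing genotypes and
#'   genotyping errors.
#' @param seed Integer seed; every draw is reproducible given it.
#' @return A list of class `dh_population`: `geno` (n_ind x n_marker
#'   character matrix with "A"/"B"/NA), `map`, `pheno` (long data frame
#'   `line`, `rep`, `hue`), `pigment` (0/1 per line, or NULL), `truth`
#'   (true mosaic matrix, causal table, model, variance parameters, seed).
#' @export
simulate_dh_population <- function(n_ind, map, model = NULL,
                                   causal = NULL,
                                   baseline_hue = 35, replicate_sd = 0.5,
                                   residual_sd = 0.8, n_reps = 2,
                                   prop_two_rep = 0.33,
                                   missing_rate = 0.02, error_rate = 0.002,
                                   seed = 1) {
  stopifnot(n_ind > 0, is.data.frame(map),
            all(c("marker", "chr", "pos_cM") %in% names(map)))
  for (ch in unique(map$chr)) {
    p <- map$pos_cM[map$chr == ch]
    if (any(diff(p) <= 0)) stop("map positions must be strictly increasing within chromosome ", ch)
  }
  if (!is.null(causal)) {
    missing_loci <- setdiff(causal$marker, map$marker)
    if (length(missing_loci) > 0) {
      stop("causal locus not on the map: ", paste(missing_loci, collapse = ", "))
    }
  }
  set.seed(seed)
  n_mrk <- nrow(map)

  # true parental-origin mosaic: TRUE = allele A
  origin <- matrix(NA, n_ind, n_mrk)
  for (ch in unique(map$chr)) {
    idx <- which(map$chr == ch)
    r <- haldane(diff(map$pos_cM[idx]))
    state <- stats::runif(n_ind) < 0.5
    origin[, idx[1]] <- state
    for (k in seq_along(r)) {
      flip <- stats::runif(n_ind) < r[k]
      state <- xor(state, flip)
      origin[, idx[k + 1]] <- state
    }
  }
  truth_geno <- ifelse(origin, "A", "B")
  dimnames(truth_geno) <- list(sprintf("DH%04d", seq_len(n_ind)), map$marker)

  # observed genotypes: inject allele flips then missing calls
  geno <- truth_geno
  if (error_rate > 0) {
    err <- matrix(stats::runif(n_ind * n_mrk) < error_rate, n_ind, n_mrk)
    geno[err] <- ifelse(geno[err] == "A", "B", "A")
  }
  if (missing_rate > 0) {
    geno[matrix(stats::runif(n_ind * n_mrk) < missing_rate, n_ind, n_mrk)] <- NA
  }

  # qualitative pigment phenotype from the true mosaic
  pigment <- NULL
  if (!is.null(model)) {
    if (is.data.frame(model)) model <- as.list(model[1, ])
    loci <- strsplit(model$loci, ",")[[1]]
    if (is.null(causal) || !all(loci %in% causal$locus)) {
      stop("every model locus needs a row in `causal`")
    }
    expr <- str2lang(model$logic)
    carrier <- lapply(loci, function(l) {
      mk <- causal$marker[causal$locus == l]
      truth_geno[, mk] == "A"
    })
    names(carrier) <- loci
    pigment <- as.integer(vapply(seq_len(n_ind), function(i) {
      isTRUE(eval(expr, envir = lapply(carrier, `[`, i)))
    }, logical(1)))
    names(pigment) <- rownames(truth_geno)
  }

  # quantitative hue phenotype: baseline - sum of carried effects + rep + resid
  genetic_value <- rep(baseline_hue, n_ind)
  if (!is.null(causal) && any(causal$effect_deg != 0)) {
    for (i in seq_len(nrow(causal))) {
      carr <- truth_geno[, causal$marker[i]] == "A"
      genetic_value <- genetic_value - causal$effect_deg[i] * carr
    }
  }
  two_rep <- stats::runif(n_ind) < prop_two_rep
  rep_eff <- stats::rnorm(n_reps, 0, replicate_sd)
  pheno <- do.call(rbind, lapply(seq_len(n_reps), function(j) {
    keep <- if (j == 1) rep(TRUE, n_ind) else two_rep
    data.frame(line = rownames(truth_geno)[keep], rep = j,
               hue = genetic_value[keep] + rep_eff[j] +
                 stats::rnorm(sum(keep), 0, residual_sd),
               stringsAsFactors = FALSE)
  }))

  structure(list(geno = geno, map = map, pheno = pheno, pigment = pigment,
                 truth = list(geno = truth_geno, causal = causal,
                              model = model, genetic_value = genetic_value,
                              baseline_hue = baseline_hue,
                              replicate_sd = replicate_sd,
                              residual_sd = residual_sd, seed = seed)),
            class = "dh_population")
}

#' Simulate line x replicate hue records for a replicated trial
#'
#' Draws line, replicate and residual effects from the two-way variance
#' structure hue = baseline + g_i + r_j + e_ij used by the BLUE /
#' heritability analysis, with a configurable fraction of lines harvested
#' in both replicates and the rest only in the first (an unbalanced
#' harvest). Defaults reflect a trial of ~1,300 inbred lines with a hue
#' phenotype: line SD ~2.5 degrees, small replicate effects, sub-degree
#' residual noise.
#'
#' @param n_lines Number of lines.
#' @param sigma_g2,sigma_rep2,sigma_e2 Variance components (degrees^2).
#' @param baseline Overall mean hue (degrees).
#' @param n_reps,prop_two_rep Replicate structure.
#' @param seed Integer seed.
#' @return List with `records` (line, rep, hue) and `truth` (the drawn line
#'   effects and the variance parameters).
#' @export
simulate_line_records <- function(n_lines = 1327, sigma_g2 = 6.5,
                                  sigma_rep2 = 0.3, sigma_e2 = 0.8,
                                  baseline = 35, n_reps = 2,
                                  prop_two_rep = 0.33, seed = 1) {
  stopifnot(n_lines >= 2, sigma_g2 >= 0, sigma_rep2 >= 0, sigma_e2 >= 0)
  set.seed(seed)
  g <- stats::rnorm(n_lines, 0, sqrt(sigma_g2))
  r <- stats::rnorm(n_reps, 0, sqrt(sigma_rep2))
  ids <- sprintf("L%04d", seq_len(n_lines))
  two_rep <- stats::runif(n_lines) < prop_two_rep
  records <- do.call(rbind, lapply(seq_len(n_reps), function(j) {
    keep <- if (j == 1) rep(TRUE, n_lines) else two_rep
    data.frame(line = ids[keep], rep = j,
               hue = baseline + g[keep] + r[j] +
                 stats::rnorm(sum(keep), 0, sqrt(sigma_e2)),
               stringsAsFactors = FALSE)
  }))
  list(records = records,
       truth = list(g = stats::setNames(g, ids), sigma_g2 = sigma_g2,
                    sigma_rep2 = sigma_rep2, sigma_e2 = sigma_e2,
                    baseline = baseline, seed = seed))
}

#' Count apparent crossovers per individual
#'
#' Number of changes of parental origin between consecutive non-missing
#' markers, summed over chromosomes. Used both by the simulator's sanity
#' checks and by the genotype quality-control filter.
#'
#' @param geno Individuals x markers character matrix of "A"/"B"/NA.
#' @param map Matching marker map.
#' @return Integer vector of crossover counts per individual.
#' @export
count_crossovers <- function(geno, map) {
  stopifnot(ncol(geno) == nrow(map))
  n <- nrow(geno)
  out <- integer(n)
  for (ch in unique(map$chr)) {
    idx <- which(map$chr == ch)
    sub <- geno[, idx, drop = FALSE]
    for (i in seq_len(n)) {
      g <- sub[i, ]
      g <- g[!is.na(g)]
      if (length(g) > 1) out[i] <- out[i] + sum(g[-1] != g[-length(g)])
    }
  }
  names(out) <- rownames(geno)
  out
}
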