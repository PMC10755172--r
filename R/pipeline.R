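#' Default configuration for an end-to-end synthetic run
#'
#' All stage parameters in one validated list: population design, genetic
#' model, QTL effects, variance components, QC thresholds and scan
#' settings. Invalid values (negative multipliers, rates outside [0, 1])
#' fail here, before any work is done.
#'
#' @param ... Named overrides of the defaults.
#' @return List of class `pericarp_config`.
#' @export
pericarp_config <- function(...) {
  cfg <- list(
    n_ind = 150, n_chr = 5, n_markers = 60, chr_length_cM = 120,
    model = "a_and_b_or_c",
    qtl_effect = 2, baseline_hue = 35,
    replicate_sd = 0.5, residual_sd = 0.8, n_reps = 2, prop_two_rep = 0.33,
    missing_rate = 0.02, error_rate = 0.002,
    iqr_mult = 1.5, hmm_error_rate = 0.002,
    n_perm = 1000, alpha = 0.05
  )
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad) > 0) stop("unknown config field(s): ", paste(bad, collapse = ", "))
  cfg[names(over)] <- over
  with(cfg, stopifnot(
    n_ind > 0, n_chr >= 1, n_markers >= 2, chr_length_cM > 0,
    qtl_effect >= 0, replicate_sd >= 0, residual_sd >= 0, n_reps >= 1,
    prop_two_rep >= 0, prop_two_rep <= 1,
    missing_rate >= 0, missing_rate < 1, error_rate >= 0, error_rate < 0.5,
    iqr_mult > 0, n_perm >= 1, alpha > 0, alpha < 1))
  if (!cfg$model %in% genetic_models()$name) stop("unknown model: ", cfg$model)
  structure(cfg, class = c("pericarp_config", "list"))
}

#' Run the synthetic analysis pipeline end to end
#'
#' Simulates a DH population under the configured genetic model (stage
#' `simulate`), tests the six segregation models on the simulated pigment
#' counts (`segregate`), fits line BLUEs and the Cullis heritability
#' (`analyze`), and runs the QC + HMM + Haley-Knott scan with a permutation
#' threshold (`scan`). Every random stage derives its seed from the single
#' run seed, so identical config + seed reproduces identical outputs.
#'
#' @param config A [pericarp_config()].
#' @param seed Integer run seed.
#' @return List of class `pericarp_run` with per-stage results and a
#'   `manifest` (seeds, record counts, winner model, threshold, peaks).
#' @export
run_pericarp_pipeline <- function(config = pericarp_config(), seed = 1) {
  stopifnot(inherits(config, "pericarp_config"))
  map <- make_marker_map(config$n_chr, config$n_markers, config$chr_length_cM)
  model <- genetic_models()
  model <- model[model$name == config$model, ]
  loci <- strsplit(model$loci, ",")[[1]]
  # spread the causal loci over distinct chromosomes, mid-chromosome
  causal <- data.frame(
    locus = loci,
    marker = vapply(seq_along(loci), function(k) {
      idx <- which(map$chr == ((k - 1) %% config$n_chr) + 1)
      map$marker[idx[ceiling(length(idx) / 2)]]
    }, character(1)),
    effect_deg = c(config$qtl_effect,
                   rep(config$qtl_effect / 2, length(loci) - 1))[seq_along(loci)])

  pop <- simulate_dh_population(
    config$n_ind, map, model = model, causal = causal,
    baseline_hue = config$baseline_hue, replicate_sd = config$replicate_sd,
    residual_sd = config$residual_sd, n_reps = config$n_reps,
    prop_two_rep = config$prop_two_rep, missing_rate = config$missing_rate,
    error_rate = config$error_rate, seed = seed)

  seg <- select_best_model(sum(pop$pigment), sum(pop$pigment == 0))

  blues <- fit_line_blues(pop$pheno)
  h2 <- cullis_h2(blues$sigma_g2, blues$avsed)

  qc <- filter_markers_individuals(pop$geno, pop$map)
  prob <- dh_genotype_probabilities(qc$geno, qc$map,
                                    error_rate = config$hmm_error_rate)
  y <- blues$blues[rownames(qc$geno)]
  scan <- hk_scan(prob, y)
  thr <- permutation_threshold(prob, y, n_perm = config$n_perm,
                               alpha = config$alpha, seed = seed + 1)
  scan_df <- data.frame(marker = qc$map$marker, chr = qc$map$chr,
                        pos_cM = qc$map$pos_cM, lod = scan$lod)
  peaks <- peak_intervals(scan_df, thr$threshold)
  if (nrow(peaks) > 0) {
    eff <- lapply(peaks$marker, function(mk) {
      blup_allele_effect(prob[, mk], y)
    })
    peaks$effect <- vapply(eff, `[[`, numeric(1), "effect")
    peaks$donor <- vapply(eff, `[[`, character(1), "donor")
  }

  manifest <- list(
    seed = seed, config = unclass(config),
    n_lines = config$n_ind, n_pheno_records = nrow(pop$pheno),
    n_markers_kept = ncol(qc$geno), n_ind_kept = nrow(qc$geno),
    pigmented = sum(pop$pigment), clear = sum(pop$pigment == 0),
    winner_model = seg$winner, h2 = h2$h2, lod_threshold = thr$threshold,
    n_peaks = nrow(peaks))

  structure(list(population = pop, segregation = seg, blues = blues,
                 h2 = h2, scan = scan_df, threshold = thr, peaks = peaks,
                 manifest = manifest),
            class = "pericarp_run")
}

#' Human-readable summary of a pipeline run
#'
#' Formats the segregation tests, the phenotypic summary and the QTL peaks
#' as plain-text tables. Regenerating the report from the same run is
#' idempotent.
#'
#' @param run A `pericarp_run` from [run_pericarp_pipeline()].
#' @return Character vector of report lines (invisibly printable with
#'   `cat(x, sep = "\n")`).
#' @export
make_report <- function(run) {
  stopifnot(inherits(run, "pericarp_run"))
  m <- run$manifest
  seg <- run$segregation$tests
  out <- c(
    "== Segregation analysis ==",
    sprintf("observed pigmented:clear = %d:%d (ratio %.2f)",
            m$pigmented, m$clear,
            pigment_frequency(m$pigmented, m$pigmented + m$clear)),
    sprintf("  %-36s %-5s p=%.2f", seg$label, seg$ratio, seg$p_value),
    sprintf("best-fitting model: %s", paste(run$segregation$winner, collapse = ", ")),
    "",
    "== Phenotypic analysis ==",
    sprintf("lines: %d  records: %d", m$n_lines, m$n_pheno_records),
    sprintf("hue BLUE mean %.2f  min %.2f  max %.2f (degrees)",
            mean(run$blues$blues), min(run$blues$blues), max(run$blues$blues)),
    sprintf("sigma_g2 %.2f  avsed %.3f  Cullis h2 %.3f",
            run$blues$sigma_g2, run$blues$avsed, m$h2),
    "",
    "== QTL scan ==",
    sprintf("markers kept %d  individuals kept %d  LOD threshold %.2f (%d permutations)",
            m$n_markers_kept, m$n_ind_kept, m$lod_threshold,
            run$threshold$n_perm))
  if (nrow(run$peaks) == 0) {
    out <- c(out, "no peaks")
  } else {
    out <- c(out, sprintf(
      "chr %d  pos %.1f cM  LOD %.2f  interval [%.1f, %.1f]  effect %.2f  donor %s",
      run$peaks$chr, run$peaks$pos_cM, run$peaks$lod, run$peaks$interval_lo,
      run$peaks$interval_hi, run$peaks$effect, run$peaks$donor))
  }
  out
}
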