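#' Expected pigmented proportion of a DH population under a locus-logic model
#'
#' In a doubled haploid (DH) biparental population every locus is homozygous
#' and the two parental alleles segregate 1:1, so the \eqn{2^L} multilocus
#' classes over \eqn{L} unlinked loci are equiprobable. The expected
#' proportion of pigmented progeny under a qualitative genetic model is the
#' fraction of those classes whose functional-allele pattern satisfies the
#' model's boolean pigment logic.
#'
#' @param logic A one-line logical expression over the locus labels, given as
#'   a character string (e.g. `"A & (B | C)"`). A locus symbol evaluates to
#'   `TRUE` when the line carries the functional allele at that locus.
#' @param loci Character vector of declared locus labels. Every symbol used
#'   in `logic` must be declared here.
#' @return The exact proportion as a numeric scalar; it is always a multiple
#'   of \eqn{1/2^L}.
#' @examples
#' dh_expected_proportion("A", "A")                      # 1/2
#' dh_expected_proportion("A & B", c("A", "B"))          # 1/4
#' dh_expected_proportion("A | (B & C)", c("A", "B", "C")) # 5/8
#' @export
dh_expected_proportion <- function(logic, loci) {
  stopifnot(is.character(logic), length(logic) == 1, length(loci) >= 1)
  expr <- str2lang(logic)
  used <- all.vars(expr)
  bad <- setdiff(used, loci)
  if (length(bad) > 0) {
    stop("logic references undeclared locus: ", paste(bad, collapse = ", "))
  }
  classes <- expand.grid(rep(list(c(TRUE, FALSE)), length(loci)),
                         KEEP.OUT.ATTRS = FALSE)
  names(classes) <- loci
  pigmented <- vapply(seq_len(nrow(classes)), function(i) {
    isTRUE(eval(expr, envir = as.list(classes[i, , drop = FALSE])))
  }, logical(1))
  sum(pigmented) / nrow(classes)
}

#' The six candidate genetic models for qualitative pericarp pigmentation
#'
#' One- to three-locus models ranging from single-gene Mendelian inheritance
#' to epistatic interactions without linkage, each with its pigment logic and
#' the expected pigmented:clear DH segregation ratio implied by it.
#'
#' @return A data frame with one row per model: `name` (short identifier),
#'   `label` (descriptive name), `loci` (comma-separated locus labels),
#'   `logic` (pigment condition), `ratio` (pigmented:clear label) and
#'   `expected_pigmented` (exact proportion from [dh_expected_proportion()]).
#' @export
genetic_models <- function() {
  m <- data.frame(
    name  = c("single_gene", "two_additive", "two_functional",
              "three_functional", "a_or_bc", "a_and_b_or_c"),
    label = c("Single gene",
              "Two additive genes",
              "2 functional genes",
              "3 functional genes",
              "Functional A or functional B and C",
              "Functional A and functional B or C"),
    loci  = c("A", "A,B", "A,B", "A,B,C", "A,B,C", "A,B,C"),
    logic = c("A", "A | B", "A & B", "A & B & C",
              "A | (B & C)", "A & (B | C)"),
    ratio = c("1:1", "3:1", "1:3", "1:7", "5:3", "3:5"),
    stringsAsFactors = FALSE
  )
  m$expected_pigmented <- vapply(seq_len(nrow(m)), function(i) {
    dh_expected_proportion(m$logic[i], strsplit(m$loci[i], ",")[[1]])
  }, numeric(1))
  m
}

#' Chi-square goodness-of-fit test of an observed pigmented:clear split
#'
#' Pearson chi-square test (1 df, no continuity correction) of the observed
#' pigmented and clear counts against the expected proportion under a
#' genetic model.
#'
#' @param observed_pigmented,observed_clear Non-negative integer counts.
#' @param expected_proportion Expected pigmented proportion in (0, 1).
#' @return A list with `observed`, `expected` (counts), `chi_square`, `df`,
#'   `p_value` and `unreliable` (TRUE when an expected count is below 1).
#' @export
chisq_goodness_of_fit <- function(observed_pigmented, observed_clear,
                                  expected_proportion) {
  stopifnot(observed_pigmented >= 0, observed_clear >= 0,
            observed_pigmented + observed_clear > 0,
            expected_proportion > 0, expected_proportion < 1)
  obs <- c(pigmented = observed_pigmented, clear = observed_clear)
  p <- c(expected_proportion, 1 - expected_proportion)
  expected <- sum(obs) * p
  unreliable <- any(expected < 1)
  if (unreliable) {
    warning("an expected count is below 1; the chi-square test is unreliable")
  }
  ct <- suppressWarnings(stats::chisq.test(obs, p = p, correct = FALSE))
  list(observed = obs, expected = expected,
       chi_square = unname(ct$statistic), df = unname(ct$parameter),
       p_value = unname(ct$p.value), unreliable = unreliable)
}

#' Test all candidate genetic models and pick the best-fitting one
#'
#' Each candidate model is tested by [chisq_goodness_of_fit()]; the winner is
#' the model with the largest p-value. Models whose p-values are within
#' `1e-6` of the maximum are reported as joint winners rather than broken
#' silently.
#'
#' @param observed_pigmented,observed_clear Observed counts.
#' @param models Candidate models, default [genetic_models()].
#' @return A list with `tests` (a data frame of all models ranked by
#'   p-value), `winner` (name(s) of the best model) and `tied` (logical).
#' @export
select_best_model <- function(observed_pigmented, observed_clear,
                              models = genetic_models()) {
  stopifnot(nrow(models) >= 1)
  res <- models
  stats_list <- lapply(models$expected_pigmented, function(p) {
    chisq_goodness_of_fit(observed_pigmented, observed_clear, p)
  })
  res$chi_square <- vapply(stats_list, `[[`, numeric(1), "chi_square")
  res$p_value <- vapply(stats_list, `[[`, numeric(1), "p_value")
  res <- res[order(-res$p_value), ]
  rownames(res) <- NULL
  top <- res$p_value[1]
  winners <- res$name[res$p_value > top - 1e-6]
  list(tests = res, winner = winners, tied = length(winners) > 1)
}

#' Observed pigment frequency
#'
#' @param observed_pigmented Number of pigmented lines.
#' @param total Total population size (> 0).
#' @return `observed_pigmented / total`.
#' @export
pigment_frequency <- function(observed_pigmented, total) {
  stopifnot(total > 0, observed_pigmented >= 0, observed_pigmented <= total)
  observed_pigmented / total
}

#' Observed pigmented/clear counts for the ten DH mapping populations
#'
#' Per-population counts of doubled haploid lines scored pigmented or clear
#' by visual inspection of the kernel scans, together with the genetic model
#' reported to fit each population best. These counts are the input to the
#' qualitative segregation analysis.
#'
#' @return Data frame: `population`, `pigmented`, `clear`, `reported_model`
#'   (the `name` of the matching row of [genetic_models()]).
#' @export
pericarp_segregation_counts <- function() {
  data.frame(
    population = c("3IIH6 x PHK76", "LH185 x PHK76", "LH185 x PHN46",
                   "LH185 x PHP02", "LH82 x PHK76", "LH82 x PHN46",
                   "LH82 x PHP02", "W606S x PHK76", "W606S x PHN46",
                   "W606S x PHP02"),
    pigmented = c(35L, 85L, 39L, 41L, 50L, 37L, 39L, 70L, 38L, 64L),
    clear     = c(120L, 64L, 114L, 86L, 75L, 96L, 80L, 52L, 79L, 63L),
    reported_model = c("two_functional", "a_or_bc", "two_functional",
                       "a_and_b_or_c", "a_and_b_or_c", "two_functional",
                       "a_and_b_or_c", "a_or_bc", "a_and_b_or_c",
                       "single_gene"),
    stringsAsFactors = FALSE
  )
}

#' Doubled haploid counts per biparental mapping population
#'
#' Number of DH lines genotyped per population after quality control, from
#' the factorial cross of four seed parents to three pollen parents (two
#' combinations were fixed for clear pericarp and not used).
#'
#' @return Named integer vector of population sizes.
#' @export
dh_population_sizes <- function() {
  c("3IIH6 x PHK76" = 155L, "LH185 x PHK76" = 149L, "LH185 x PHN46" = 153L,
    "LH185 x PHP02" = 127L, "LH82 x PHK76" = 125L, "LH82 x PHN46" = 133L,
    "LH82 x PHP02" = 119L, "W606S x PHK76" = 122L, "W606S x PHN46" = 117L,
    "W606S x PHP02" = 127L)
}
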