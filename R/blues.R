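#' Line BLUEs from a replicated trial
#'
#' Fits the two-way model hue = line + replicate + residual by REML with the
#' line as a fixed effect and the replicate as a random effect, matching the
#' analysis of a randomized complete block trial with partially harvested
#' second replicates. Returns best linear unbiased estimators (BLUEs) per
#' line, the variance components, and `avsed`, the average standard error of
#' a pairwise difference between line BLUEs (mean over all pairs of
#' \eqn{\sqrt{var(\hat g_i - \hat g_j)}}).
#'
#' The line variance component \eqn{\sigma^2_g} needed for the Cullis
#' heritability is not identified when lines are fixed, so it is estimated
#' from the companion model with the line random (same data, same REML).
#'
#' @param records Data frame with columns `line`, `rep` and `hue` (one row
#'   per line x replicate observation; single-replicate lines allowed).
#' @return A list of class `blue_set`: `blues` (named vector), `se`,
#'   `sigma_g2`, `sigma_rep2`, `sigma_e2`, `avsed` and `degenerate` (TRUE
#'   when all data are in one replicate, in which case plain line means are
#'   returned).
#' @export
fit_line_blues <- function(records) {
  stopifnot(all(c("line", "rep", "hue") %in% names(records)))
  records$line <- factor(records$line)
  records$rep <- factor(records$rep)
  if (nlevels(records$line) < 2) stop("need at least 2 lines")

  if (nlevels(records$rep) < 2) {
    blues <- tapply(records$hue, records$line, mean)
    warning("all observations in one replicate: returning plain line means")
    return(structure(list(blues = blues, se = rep(NA_real_, length(blues)),
                          sigma_g2 = stats::var(blues), sigma_rep2 = 0,
                          sigma_e2 = NA_real_, avsed = NA_real_,
                          degenerate = TRUE), class = "blue_set"))
  }

  fit <- suppressMessages(lme4::lmer(hue ~ 0 + line + (1 | rep),
                                     data = records, REML = TRUE))
  b <- lme4::fixef(fit)
  names(b) <- sub("^line", "", names(b))
  V <- as.matrix(stats::vcov(fit))
  se <- sqrt(diag(V))
  # var(g_i - g_j) = V_ii + V_jj - 2 V_ij over all pairs
  dv <- outer(diag(V), diag(V), "+") - 2 * V
  avsed <- mean(sqrt(dv[upper.tri(dv)]))
  vc <- as.data.frame(lme4::VarCorr(fit))
  sigma_rep2 <- vc$vcov[vc$grp == "rep"]
  sigma_e2 <- vc$vcov[vc$grp == "Residual"]

  rfit <- suppressMessages(suppressWarnings(
    lme4::lmer(hue ~ 1 + (1 | line) + (1 | rep), data = records, REML = TRUE,
               control = lme4::lmerControl(check.conv.singular = "ignore"))))
  rvc <- as.data.frame(lme4::VarCorr(rfit))
  sigma_g2 <- rvc$vcov[rvc$grp == "line"]

  structure(list(blues = b, se = se, sigma_g2 = sigma_g2,
                 sigma_rep2 = sigma_rep2, sigma_e2 = sigma_e2,
                 avsed = avsed, degenerate = FALSE),
            class = "blue_set")
}

#' Cullis generalized heritability
#'
#' \eqn{h^2 = 1 - PEV / (2\sigma^2_g)} with \eqn{PEV = avsed^2}, the squared
#' average standard error of a difference between line estimates. Suited to
#' unbalanced trials where the classical entry-mean heritability is not
#' well defined.
#'
#' @param sigma_g2 Line variance component (> 0).
#' @param avsed Average SE of a pairwise difference (>= 0).
#' @return List with `h2`, `pev` and `sigma_g2`.
#' @export
cullis_h2 <- function(sigma_g2, avsed) {
  if (!is.finite(sigma_g2) || sigma_g2 <= 0) {
    stop("sigma_g2 must be positive: heritability undefined")
  }
  stopifnot(avsed >= 0)
  pev <- avsed^2
  list(h2 = 1 - pev / (2 * sigma_g2), pev = pev, sigma_g2 = sigma_g2)
}

#' Tukey multiple-comparison letter groups
#'
#' All pairwise comparisons of group means with studentized-range
#' family-wise error control, summarized as a compact letter display:
#' groups sharing no letter differ significantly at level `alpha`.
#'
#' @param values Numeric response (e.g. line BLUEs).
#' @param groups Grouping factor (e.g. population); groups of size 1 are
#'   excluded with a warning.
#' @param alpha Experiment-wise error rate (default 0.05).
#' @return List with `letters` (named character vector per group), `means`
#'   (group means) and the underlying `glht` object.
#' @export
tukey_groups <- function(values, groups, alpha = 0.05) {
  groups <- factor(groups)
  sizes <- table(groups)
  if (any(sizes < 2)) {
    warning("excluding groups of size 1: ",
            paste(names(sizes)[sizes < 2], collapse = ", "))
    keep <- groups %in% names(sizes)[sizes >= 2]
    values <- values[keep]
    groups <- droplevels(groups[keep])
  }
  if (nlevels(groups) < 2) stop("need at least 2 groups of size >= 2")
  d <- data.frame(y = values, g = groups)
  fit <- stats::lm(y ~ g, data = d)
  gl <- multcomp::glht(fit, linfct = multcomp::mcp(g = "Tukey"))
  cl <- multcomp::cld(gl, level = alpha)
  list(letters = cl$mcletters$Letters,
       means = tapply(values, groups, mean), glht = gl)
}

#' Spearman validation of hue against visual ratings
#'
#' Rank correlation (midranks for ties) between the quantitative hue
#' phenotype and ordinal 1-5 darkness ratings; expected negative because
#' darker pericarp means both lower hue and higher rating.
#'
#' @param hue Numeric hue values.
#' @param ratings Matching integer ratings 1-5.
#' @return List with `rho` and `p_value`.
#' @export
spearman_validation <- function(hue, ratings) {
  keep <- !is.na(hue) & !is.na(ratings)
  hue <- hue[keep]; ratings <- ratings[keep]
  if (length(hue) < 5) stop("need at least 5 paired observations")
  if (stats::sd(ratings) == 0) stop("constant ratings: correlation undefined")
  ct <- suppressWarnings(stats::cor.test(hue, ratings, method = "spearman"))
  list(rho = unname(ct$estimate), p_value = ct$p.value)
}
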