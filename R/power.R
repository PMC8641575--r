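#' Analytic power for a two-sample MR analysis
#'
#' Two-sided normal-approximation power of the IVW causal test, following
#' the standard summary-data MR power calculator. For a continuous outcome
#' the non-centrality parameter is `sqrt(n * r2) * beta_alt`, with `n` the
#' outcome GWAS sample size, `r2` the proportion of exposure variance
#' explained by the instruments, and `beta_alt` the alternative effect in
#' outcome SD units per exposure SD. For a binary (case-control) outcome
#' the alternative odds ratio is first mapped to an effect on the observed
#' binary scale, `b = K * (OR / (1 + K * (OR - 1)) - 1)` with `K` the case
#' proportion, whose sampling variance is `(K * (1 - K) - b^2) / (n * r2)`;
#' the non-centrality parameter is `b` divided by that standard deviation.
#' Power is `pnorm(-z + NCP) + pnorm(-z - NCP)` with
#' `z = qnorm(1 - alpha/2)`, so a null effect returns exactly `alpha`.
#'
#' @param n Outcome GWAS sample size.
#' @param r2 Proportion of exposure variance explained by the instruments,
#'   in (0, 1).
#' @param alpha Type-I error rate.
#' @param beta_alt Alternative effect for a continuous outcome (SD units);
#'   supply exactly one of `beta_alt` / `or_alt`.
#' @param or_alt Alternative odds ratio for a binary outcome.
#' @param k_cases Proportion of cases, required with `or_alt`.
#' @return Power in `[0, 1]`.
#' @export
#' @examples
#' mr_power(n = 10000, r2 = 0.02, beta_alt = 0.1)
#' mr_power(n = 400000, r2 = 0.023, or_alt = 1.32, k_cases = 0.1)
mr_power <- function(n, r2, alpha = 0.05, beta_alt = NULL, or_alt = NULL,
                     k_cases = NULL) {
  if (!is.finite(n) || n <= 0) stop("n must be positive", call. = FALSE)
  if (!is.finite(r2) || r2 <= 0 || r2 >= 1) {
    stop("r2 must lie strictly in (0, 1)", call. = FALSE)
  }
  if (!is.finite(alpha) || alpha <= 0 || alpha >= 1) {
    stop("alpha must lie strictly in (0, 1)", call. = FALSE)
  }
  if (is.null(beta_alt) == is.null(or_alt)) {
    stop("supply exactly one of beta_alt (continuous) or or_alt (binary)",
         call. = FALSE)
  }
  if (!is.null(beta_alt)) {
    ncp <- sqrt(n * r2) * beta_alt
  } else {
    if (is.null(k_cases) || k_cases <= 0 || k_cases >= 1) {
      stop("binary power needs k_cases in (0, 1)", call. = FALSE)
    }
    if (or_alt <= 0) stop("or_alt must be positive", call. = FALSE)
    b <- k_cases * (or_alt / (1 + k_cases * (or_alt - 1)) - 1)
    v <- (k_cases * (1 - k_cases) - b^2) / (n * r2)
    if (v <= 0) stop("degenerate binary variance; check parameters",
                     call. = FALSE)
    ncp <- b / sqrt(v)
  }
  z <- stats::qnorm(1 - alpha / 2)
  stats::pnorm(-z + ncp) + stats::pnorm(-z - ncp)
}

#' Bonferroni classification of exposure-outcome p-values
#'
#' Partitions every test into `significant` (p strictly below
#' `alpha / (n_exposures * n_outcomes)`), `suggestive` (at or above the
#' corrected threshold but below 0.05), or `null`. The default family of
#' 3 exposures x 13 outcomes gives the exact threshold 0.05/39 ~= 1.282e-3
#' (conventionally rounded to 1.3e-3); the exact value is used for
#' classification and both are returned.
#'
#' @param pvals A data.frame with columns `exposure`, `outcome`, `p` (or any
#'   data.frame with a `p` column).
#' @param n_exposures,n_outcomes Size of the test family.
#' @param alpha Family-wise error rate.
#' @return The input with a `class` factor column appended; the exact and
#'   rounded thresholds are attached as attributes `threshold` and
#'   `threshold_rounded`.
#' @export
bonferroni_classify <- function(pvals, n_exposures = 3L, n_outcomes = 13L,
                                alpha = 0.05) {
  stopifnot("p" %in% names(pvals))
  if (any(pvals$p <= 0 | pvals$p > 1)) {
    stop("p-values must lie in (0, 1]", call. = FALSE)
  }
  threshold <- alpha / (n_exposures * n_outcomes)
  cls <- ifelse(pvals$p < threshold, "significant",
                ifelse(pvals$p < 0.05, "suggestive", "null"))
  pvals$class <- factor(cls, levels = c("significant", "suggestive", "null"))
  attr(pvals, "threshold") <- threshold
  attr(pvals, "threshold_rounded") <- signif(threshold, 2)
  pvals
}
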