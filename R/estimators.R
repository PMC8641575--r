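#' Causal-estimate result objects
#'
#' Every estimator returns an `mr_result`: the causal estimate per 1 SD of
#' exposure (log odds ratio for binary outcomes), its standard error, 95%
#' confidence interval and p-value, the number of SNPs used, and — where
#' applicable — heterogeneity diagnostics (Cochran's Q, its p-value, the
#' I-squared percentage) and the MR-Egger intercept triple.
#'
#' @param method Estimator name.
#' @param estimate,se Point estimate and standard error.
#' @param pval Two-sided p-value.
#' @param n_snp Number of instruments used.
#' @param ci_low,ci_high 95% interval bounds; computed as normal Wald limits
#'   when omitted.
#' @param ... Extra diagnostic fields (`q`, `q_pval`, `i2`,
#'   `egger_intercept`, `intercept_se`, `intercept_pval`, metadata).
#' @return A list of class `mr_result`.
#' @export
mr_result <- function(method, estimate, se, pval, n_snp,
                      ci_low = estimate - stats::qnorm(0.975) * se,
                      ci_high = estimate + stats::qnorm(0.975) * se, ...) {
  structure(list(method = method, estimate = estimate, se = se,
                 ci_low = ci_low, ci_high = ci_high, pval = pval,
                 n_snp = n_snp, ...),
            class = "mr_result")
}

#' @export
print.mr_result <- function(x, ...) {
  cat(sprintf("<mr_result> %s (%d SNPs)\n", x$method, x$n_snp))
  cat(sprintf("  estimate %.4f (se %.4f), 95%% CI [%.4f, %.4f], p = %.3g\n",
              x$estimate, x$se, x$ci_low, x$ci_high, x$pval))
  if (!is.null(x$q) && is.finite(x$q)) {
    cat(sprintf("  Q = %.2f (p = %.3g), I2 = %.1f%%\n", x$q, x$q_pval, x$i2))
  }
  if (!is.null(x$egger_intercept)) {
    cat(sprintf("  intercept %.4f (se %.4f), p = %.3g\n",
                x$egger_intercept, x$intercept_se, x$intercept_pval))
  }
  invisible(x)
}

#' @rdname mr_result
#' @param x An `mr_result` for a binary outcome (log-OR scale).
#' @return `or_scale()`: named vector `or`, `ci_low`, `ci_high` with the
#'   exponentiated estimate and interval.
#' @export
or_scale <- function(x) {
  c(or = exp(x$estimate), ci_low = exp(x$ci_low), ci_high = exp(x$ci_high))
}

#' @export
as.data.frame.mr_result <- function(x, ...) {
  data.frame(method = x$method, estimate = x$estimate, se = x$se,
             ci_low = x$ci_low, ci_high = x$ci_high, pval = x$pval,
             n_snp = x$n_snp,
             q = x$q %||% NA_real_, q_pval = x$q_pval %||% NA_real_,
             i2 = x$i2 %||% NA_real_,
             egger_intercept = x$egger_intercept %||% NA_real_,
             intercept_pval = x$intercept_pval %||% NA_real_,
             stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Per-SNP Wald ratio with delta-method standard error
#'
#' The single-instrument causal estimate `beta_y / beta_x`. The default
#' standard error is the first-order delta approximation `se_y / |beta_x|`;
#' the second-order option adds the `beta_y^2 * se_x^2 / beta_x^4` term that
#' accounts for sampling error in the SNP-exposure effect.
#'
#' @param beta_x,se_x SNP-exposure effect and standard error.
#' @param beta_y,se_y SNP-outcome effect and standard error.
#' @param second_order Include the exposure-error term in the SE.
#' @return A list with `estimate` and `se` (vectorized over SNPs).
#' @export
#' @examples
#' wald_ratio(0.1, 0.01, 0.05, 0.02)  # estimate 0.5, se 0.2
wald_ratio <- function(beta_x, se_x, beta_y, se_y, second_order = FALSE) {
  if (any(beta_x == 0)) {
    stop("wald ratio undefined for beta_x = 0", call. = FALSE)
  }
  est <- beta_y / beta_x
  var1 <- se_y^2 / beta_x^2
  se <- if (second_order) {
    sqrt(var1 + beta_y^2 * se_x^2 / beta_x^4)
  } else {
    sqrt(var1)
  }
  list(estimate = est, se = se)
}

# Ratio estimates and first-order inverse-variance weights for a set.
ratio_weights <- function(set, second_order = FALSE) {
  wr <- wald_ratio(set$beta_x, set$se_x, set$beta_y, set$se_y, second_order)
  list(ratio = wr$estimate, w = 1 / wr$se^2)
}

#' Inverse-variance-weighted causal estimate
#'
#' Meta-analyzes the per-SNP Wald ratios with first-order inverse-variance
#' weights. The default multiplicative random-effects model inflates the
#' fixed-effect standard error by `max(1, sqrt(Q / (J - 1)))`, crediting
#' over-dispersion but never under-dispersion; `effects = "fixed"` skips the
#' inflation. With a single SNP the result reduces exactly to the Wald
#' ratio. Cochran's Q, its p-value, and I-squared are attached whenever
#' J >= 2.
#'
#' @param set A [harmonized_set()].
#' @param effects `"random"` (multiplicative over-dispersion, default) or
#'   `"fixed"`.
#' @param second_order Use second-order Wald SEs for the weights.
#' @return An [mr_result()] with heterogeneity diagnostics.
#' @export
mr_ivw <- function(set, effects = c("random", "fixed"),
                   second_order = FALSE) {
  effects <- match.arg(effects)
  J <- nrow(set)
  if (J < 1L) stop("need at least 1 SNP", call. = FALSE)
  rw <- ratio_weights(set, second_order)
  if (J == 1L) {
    wr <- wald_ratio(set$beta_x, set$se_x, set$beta_y, set$se_y, second_order)
    return(mr_result("ivw", wr$estimate, wr$se,
                     2 * stats::pnorm(-abs(wr$estimate / wr$se)), 1L,
                     q = NA_real_, q_pval = NA_real_, i2 = NA_real_,
                     effects = "fixed"))
  }
  est <- sum(rw$w * rw$ratio) / sum(rw$w)
  se_fixed <- sum(rw$w)^-0.5
  q <- sum(rw$w * (rw$ratio - est)^2)
  se <- if (effects == "random") se_fixed * max(1, sqrt(q / (J - 1)))
        else se_fixed
  mr_result("ivw", est, se, 2 * stats::pnorm(-abs(est / se)), J,
            q = q, q_pval = stats::pchisq(q, J - 1, lower.tail = FALSE),
            i2 = max(0, (q - (J - 1)) / q) * 100, effects = effects)
}

#' Cochran's Q and I-squared heterogeneity of the Wald ratios
#'
#' `Q = sum w_j (ratio_j - ivw)^2` against a chi-squared with J - 1 degrees
#' of freedom, and `I2 = max(0, (Q - (J-1)) / Q) * 100`. The conventional
#' flag combines I2 > 25% with Q p-value < 0.05.
#'
#' @param set A [harmonized_set()] with at least 2 SNPs.
#' @return A list: `q`, `q_pval`, `i2` (percent), `heterogeneous`.
#' @export
cochran_q <- function(set) {
  J <- nrow(set)
  if (J < 2L) stop("heterogeneity needs at least 2 SNPs", call. = FALSE)
  res <- mr_ivw(set, effects = "fixed")
  list(q = res$q, q_pval = res$q_pval, i2 = res$i2,
       heterogeneous = res$i2 > 25 && res$q_pval < 0.05)
}

#' MR-Egger regression
#'
#' Weighted least squares of the SNP-outcome effects on the SNP-exposure
#' effects with a free intercept, weights `se_y^-2`, after orienting all
#' SNP-exposure effects to be non-negative (each pair sign-flipped as
#' needed). The slope estimates the causal effect under InSIDE; the
#' intercept estimates average directional pleiotropy, and its test
#' (p < 0.05) is the usual pleiotropy screen. Standard errors use
#' multiplicative over-dispersion floored at 1 and t p-values with J - 2
#' degrees of freedom.
#'
#' @param set A [harmonized_set()] with at least 3 SNPs.
#' @return An [mr_result()] carrying `egger_intercept`, `intercept_se`,
#'   `intercept_pval` alongside the slope estimate.
#' @export
mr_egger <- function(set) {
  J <- nrow(set)
  if (J < 3L) stop("MR-Egger needs at least 3 SNPs", call. = FALSE)
  s <- ifelse(set$beta_x < 0, -1, 1)
  bx <- s * set$beta_x
  by <- s * set$beta_y
  if (stats::var(bx) == 0) {
    stop("zero variance in beta_x; Egger slope unidentified", call. = FALSE)
  }
  w <- 1 / set$se_y^2
  fit <- stats::lm(by ~ bx, weights = w)
  sm <- summary(fit)
  sigma <- sm$sigma  # sqrt(weighted RSS / (J - 2))
  scale <- max(1, sigma)
  co <- sm$coefficients
  se_slope <- co["bx", "Std. Error"] / sigma * scale
  se_int <- co["(Intercept)", "Std. Error"] / sigma * scale
  slope <- co["bx", "Estimate"]
  int <- co["(Intercept)", "Estimate"]
  tcrit <- stats::qt(0.975, J - 2)
  mr_result("egger", slope, se_slope,
            2 * stats::pt(-abs(slope / se_slope), J - 2), J,
            ci_low = slope - tcrit * se_slope,
            ci_high = slope + tcrit * se_slope,
            egger_intercept = int, intercept_se = se_int,
            intercept_pval = 2 * stats::pt(-abs(int / se_int), J - 2),
            df = J - 2)
}

# Weighted-median point estimate of ordered ratios (Bowden's interpolation).
weighted_median_point <- function(ratio, w) {
  ord <- order(ratio)
  r <- ratio[ord]; w <- w[ord]
  S <- cumsum(w)
  p <- (S - w / 2) / S[length(S)]
  stats::approx(p, r, xout = 0.5, rule = 2, ties = "ordered")$y
}

#' Weighted-median causal estimate
#'
#' Consistent when instruments carrying at least half the total weight are
#' valid. Ratios are ordered and the estimate interpolated at the midpoint
#' of the standardized cumulative inverse-variance weights
#' `p_j = (S_j - w_j/2) / S_J`. The standard error comes from a parametric
#' bootstrap: SNP effects are resampled from their sampling normals, the
#' median recomputed, and the bootstrap standard deviation taken.
#'
#' @param set A [harmonized_set()] with at least 3 SNPs.
#' @param n_boot Bootstrap replicates (default 5000).
#' @param seed Seed for the bootstrap stream; same seed, same result.
#' @return An [mr_result()].
#' @export
mr_weighted_median <- function(set, n_boot = 5000L, seed = 1L) {
  J <- nrow(set)
  if (J < 3L) stop("weighted median needs at least 3 SNPs", call. = FALSE)
  rw <- ratio_weights(set)
  est <- weighted_median_point(rw$ratio, rw$w)
  boots <- with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      bx <- stats::rnorm(J, set$beta_x, set$se_x)
      by <- stats::rnorm(J, set$beta_y, set$se_y)
      bx[bx == 0] <- .Machine$double.eps
      weighted_median_point(by / bx, bx^2 / set$se_y^2)
    }, numeric(1))
  })
  se <- stats::sd(boots)
  mr_result("weighted_median", est, se,
            2 * stats::pnorm(-abs(est / se)), J, n_boot = n_boot)
}

#' Maximum-likelihood causal estimate
#'
#' Maximizes the joint normal likelihood in which each observed
#' SNP-exposure effect is `N(gamma_j, se_xj^2)` and each SNP-outcome effect
#' is `N(theta * gamma_j, se_yj^2)`. The nuisance `gamma_j` are profiled out
#' in closed form and the one-dimensional profile likelihood in `theta` is
#' maximized numerically from the IVW starting value; the standard error is
#' the inverse square root of the observed (profile) information.
#'
#' @param set A [harmonized_set()] with at least 2 SNPs (1 reduces to the
#'   Wald ratio).
#' @return An [mr_result()]; non-convergence raises an error carrying the
#'   optimizer diagnostics.
#' @export
mr_max_likelihood <- function(set) {
  J <- nrow(set)
  if (J < 1L) stop("need at least 1 SNP", call. = FALSE)
  vx <- set$se_x^2; vy <- set$se_y^2
  nll <- function(theta) {
    g <- (set$beta_x / vx + theta * set$beta_y / vy) / (1 / vx + theta^2 / vy)
    0.5 * sum((set$beta_x - g)^2 / vx + (set$beta_y - theta * g)^2 / vy)
  }
  start <- mr_ivw(set, effects = "fixed")$estimate
  opt <- stats::optim(start, nll, method = "BFGS",
                      control = list(reltol = 1e-12))
  if (opt$convergence != 0L) {
    stop("maximum-likelihood optimizer failed to converge (code ",
         opt$convergence, "): ", opt$message %||% "", call. = FALSE)
  }
  h <- stats::optimHess(opt$par, nll)
  se <- 1 / sqrt(drop(h))
  est <- opt$par
  mr_result("max_likelihood", est, se,
            2 * stats::pnorm(-abs(est / se)), J)
}

#' Leave-one-out IVW sensitivity analysis
#'
#' Recomputes the IVW estimate J times, each time excluding one SNP, and
#' flags SNPs whose removal changes the estimate's sign or its significance
#' at 0.05 — the usual screen for single-variant-driven findings.
#'
#' @param set A [harmonized_set()] with at least 3 SNPs.
#' @param effects Passed to [mr_ivw()].
#' @return A data.frame with one row per excluded SNP (`snp`, `estimate`,
#'   `se`, `ci_low`, `ci_high`, `pval`, `sign_change`,
#'   `significance_change`); the full-set result is attached as attribute
#'   `"full"`.
#' @export
leave_one_out <- function(set, effects = "random") {
  J <- nrow(set)
  if (J < 3L) stop("leave-one-out needs at least 3 SNPs", call. = FALSE)
  full <- mr_ivw(set, effects = effects)
  rows <- lapply(seq_len(J), function(j) {
    r <- mr_ivw(set[-j, , drop = FALSE], effects = effects)
    data.frame(snp = set$snp[j], estimate = r$estimate, se = r$se,
               ci_low = r$ci_low, ci_high = r$ci_high, pval = r$pval,
               sign_change = sign(r$estimate) != sign(full$estimate),
               significance_change = (r$pval < 0.05) != (full$pval < 0.05),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "full") <- full
  out
}

#' Run a panel of univariable estimators
#'
#' @param set A [harmonized_set()].
#' @param methods Subset of `c("ivw", "egger", "wmedian", "ml")`.
#' @param n_boot,seed Bootstrap controls for the weighted median.
#' @return Named list of [mr_result()] objects.
#' @export
mr_estimate <- function(set, methods = c("ivw", "egger", "wmedian", "ml"),
                        n_boot = 5000L, seed = 1L) {
  methods <- match.arg(methods, several.ok = TRUE)
  out <- list()
  if ("ivw" %in% methods) out$ivw <- mr_ivw(set)
  if ("egger" %in% methods) out$egger <- mr_egger(set)
  if ("wmedian" %in% methods) {
    out$wmedian <- mr_weighted_median(set, n_boot = n_boot, seed = seed)
  }
  if ("ml" %in% methods) out$ml <- mr_max_likelihood(set)
  out
}
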