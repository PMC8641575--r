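#' Multivariable MR input
#'
#' Per-SNP joint effects on k exposures plus the outcome, for estimating
#' direct effects conditional on the other exposures.
#'
#' @param snp SNP identifiers.
#' @param beta_x,se_x J x k matrices of SNP-exposure effects and standard
#'   errors; column names are the exposure names.
#' @param beta_y,se_y SNP-outcome effect vectors.
#' @param exposure_names Optional override for the matrix column names.
#' @return A list of class `mvmr_input`.
#' @export
mvmr_input <- function(snp, beta_x, se_x, beta_y, se_y,
                       exposure_names = colnames(beta_x)) {
  beta_x <- as.matrix(beta_x); se_x <- as.matrix(se_x)
  k <- ncol(beta_x)
  J <- length(snp)
  if (is.null(exposure_names)) exposure_names <- paste0("exposure_", seq_len(k))
  stopifnot(nrow(beta_x) == J, all(dim(se_x) == dim(beta_x)),
            length(beta_y) == J, length(se_y) == J,
            length(exposure_names) == k)
  if (J < k + 1L) stop("need more SNPs than exposures", call. = FALSE)
  if (any(se_x <= 0) || any(se_y <= 0)) {
    stop("standard errors must be positive", call. = FALSE)
  }
  colnames(beta_x) <- colnames(se_x) <- exposure_names
  structure(list(snp = as.character(snp), beta_x = beta_x, se_x = se_x,
                 beta_y = beta_y, se_y = se_y,
                 exposure_names = exposure_names),
            class = "mvmr_input")
}

#' Multivariable MR direct effects
#'
#' Weighted least squares of the SNP-outcome effects on the k-column matrix
#' of SNP-exposure effects, without intercept, weights `se_y^-2`. Each
#' coefficient is the direct effect of that exposure conditional on the
#' others. Standard errors use multiplicative over-dispersion floored at 1
#' (as in the univariable IVW) and normal p-values. With k = 1 this is
#' identical to the regression form of the univariable IVW.
#'
#' @param input An [mvmr_input()].
#' @return A named list of [mr_result()] objects, one per exposure.
#' @export
mvmr <- function(input) {
  stopifnot(inherits(input, "mvmr_input"))
  X <- input$beta_x
  k <- ncol(X)
  J <- nrow(X)
  if (qr(X)$rank < k) {
    stop("exposure effect matrix is rank deficient (collinear exposures)",
         call. = FALSE)
  }
  w <- 1 / input$se_y^2
  fit <- stats::lm(input$beta_y ~ 0 + X, weights = w)
  sm <- summary(fit)
  sigma <- sm$sigma  # sqrt(weighted RSS / (J - k))
  scale <- max(1, sigma)
  est <- stats::coef(fit)
  se <- sm$coefficients[, "Std. Error"] / sigma * scale
  out <- lapply(seq_len(k), function(i) {
    mr_result("mvmr", unname(est[i]), unname(se[i]),
              unname(2 * stats::pnorm(-abs(est[i] / se[i]))), J,
              exposure = input$exposure_names[i])
  })
  stats::setNames(out, input$exposure_names)
}

#' Difference-method mediation decomposition
#'
#' Decomposes a total causal effect (univariable IVW) into the direct effect
#' (multivariable MR conditional on the mediator) and the indirect effect
#' `total - direct`; the proportion mediated is `indirect / total`. The
#' indirect-effect standard error uses the independence approximation
#' `sqrt(se_total^2 + se_direct^2)`; the proportion-mediated interval comes
#' from the delta method for the ratio, which under the same approximation
#' reduces to `var(PM) = se_direct^2 / total^2 +
#' se_total^2 * direct^2 / total^4`. A proportion outside [0, 1] is
#' reported as computed, with a warning — never clipped.
#'
#' @param total An [mr_result()] for the unadjusted (total) effect.
#' @param direct An [mr_result()] for the mediator-adjusted direct effect,
#'   on the same scale.
#' @param mediator_names Character vector naming the mediator(s) the direct
#'   effect conditions on.
#' @param method `"delta"` (independence approximation, default) or
#'   `"bootstrap"`. The delta interval ignores the positive correlation
#'   between the total and direct estimates (they come from the same data),
#'   so it over-covers; the joint parametric bootstrap, available when the
#'   per-SNP data are supplied, resamples shared SNPs with the *same* draws
#'   in both analyses and is calibrated.
#' @param uni_set The [harmonized_set()] behind `total` (bootstrap only).
#' @param mvmr_in The [mvmr_input()] behind `direct` (bootstrap only); the
#'   primary exposure must be its first column, and SNPs shared with
#'   `uni_set` are matched by identifier.
#' @param n_boot,seed Bootstrap controls.
#' @return A list of class `mediation_result`: `total`, `direct`,
#'   `indirect` (each a list with `estimate`, `se`), `proportion_mediated`,
#'   `pm_ci_low`, `pm_ci_high`, `mediator_names`. The identity
#'   `total = direct + indirect` holds exactly.
#' @export
#' @examples
#' tot <- mr_result("ivw", 0.30, 0.05, 1e-6, 40)
#' dir <- mr_result("mvmr", 0.24, 0.05, 1e-4, 40)
#' mediate(tot, dir, "DBP")$proportion_mediated  # 0.2
mediate <- function(total, direct, mediator_names = "mediator",
                    method = c("delta", "bootstrap"), uni_set = NULL,
                    mvmr_in = NULL, n_boot = 1000L, seed = 1L) {
  method <- match.arg(method)
  t_est <- total$estimate; t_se <- total$se
  d_est <- direct$estimate; d_se <- direct$se
  if (t_est == 0) {
    stop("total effect is zero; proportion mediated undefined", call. = FALSE)
  }
  ind <- t_est - d_est
  pm <- ind / t_est
  z <- stats::qnorm(0.975)
  if (method == "delta") {
    ind_se <- sqrt(t_se^2 + d_se^2)
    pm_var <- d_se^2 / t_est^2 + t_se^2 * d_est^2 / t_est^4
    pm_lo <- pm - z * sqrt(pm_var)
    pm_hi <- pm + z * sqrt(pm_var)
  } else {
    if (is.null(uni_set) || is.null(mvmr_in)) {
      stop("bootstrap mediation needs uni_set and mvmr_in", call. = FALSE)
    }
    bs <- mediation_bootstrap(uni_set, mvmr_in, n_boot, seed)
    ind_se <- stats::sd(bs$indirect)
    qs <- stats::quantile(bs$pm, c(0.025, 0.975), names = FALSE,
                          na.rm = TRUE)
    pm_lo <- qs[1]; pm_hi <- qs[2]
  }
  if (pm < 0 || pm > 1) {
    warning("proportion mediated outside [0, 1]: ", signif(pm, 3),
            " (reported unclipped)", call. = FALSE)
  }
  structure(list(
    total = list(estimate = t_est, se = t_se),
    direct = list(estimate = d_est, se = d_se),
    indirect = list(estimate = ind, se = ind_se),
    proportion_mediated = pm,
    pm_ci_low = pm_lo, pm_ci_high = pm_hi,
    mediator_names = mediator_names, method = method),
    class = "mediation_result")
}

# Joint parametric bootstrap of (total, direct): shared SNPs get identical
# draws in the univariable and multivariable fits, capturing their
# correlation. Returns per-replicate indirect effects and proportions.
mediation_bootstrap <- function(uni_set, mvmr_in, n_boot, seed) {
  J <- length(mvmr_in$snp)
  k <- ncol(mvmr_in$beta_x)
  idx <- match(uni_set$snp, mvmr_in$snp)
  extra <- which(is.na(idx))  # uni SNPs absent from the MVMR union
  w_mv <- 1 / mvmr_in$se_y^2
  w_uni <- 1 / uni_set$se_y^2
  with_seed(seed, {
    indirect <- pm <- numeric(n_boot)
    for (b in seq_len(n_boot)) {
      bx <- matrix(stats::rnorm(J * k, mvmr_in$beta_x, mvmr_in$se_x), J, k)
      by <- stats::rnorm(J, mvmr_in$beta_y, mvmr_in$se_y)
      xw <- bx * w_mv
      direct_b <- solve(crossprod(bx, xw), crossprod(xw, by))[1L]
      ux <- ifelse(is.na(idx), NA_real_, bx[idx, 1L])
      uy <- ifelse(is.na(idx), NA_real_, by[idx])
      if (length(extra)) {
        ux[extra] <- stats::rnorm(length(extra), uni_set$beta_x[extra],
                                  uni_set$se_x[extra])
        uy[extra] <- stats::rnorm(length(extra), uni_set$beta_y[extra],
                                  uni_set$se_y[extra])
      }
      total_b <- sum(w_uni * ux * uy) / sum(w_uni * ux^2)
      indirect[b] <- total_b - direct_b
      pm[b] <- indirect[b] / total_b
    }
    list(indirect = indirect, pm = pm)
  })
}

#' @export
print.mediation_result <- function(x, ...) {
  cat(sprintf("<mediation_result> via %s\n",
              paste(x$mediator_names, collapse = " + ")))
  cat(sprintf("  total %.4f (se %.4f), direct %.4f (se %.4f)\n",
              x$total$estimate, x$total$se, x$direct$estimate, x$direct$se))
  cat(sprintf("  indirect %.4f (se %.4f), PM = %.1f%% [%.1f%%, %.1f%%]\n",
              x$indirect$estimate, x$indirect$se,
              100 * x$proportion_mediated, 100 * x$pm_ci_low,
              100 * x$pm_ci_high))
  invisible(x)
}

#' Assemble an MVMR input from per-exposure GWAS tables
#'
#' Builds the joint effect matrix over an instrument union: each exposure
#' table (and the outcome) is aligned onto the first exposure's effect
#' alleles via [harmonize()], and only SNPs present and reconcilable in
#' every table are retained.
#'
#' @param exposures Named list of [sumstats()] tables (first is the primary
#'   exposure).
#' @param outcome A [sumstats()] table.
#' @param snps Character vector of instrument identifiers (the union of the
#'   per-exposure selections, typically clumped jointly upstream).
#' @param maf_threshold Passed to [harmonize()].
#' @return An [mvmr_input()].
#' @export
build_mvmr_input <- function(exposures, outcome, snps, maf_threshold = 0.42) {
  stopifnot(length(exposures) >= 1L, !is.null(names(exposures)))
  ref <- exposures[[1L]]
  ref <- ref[ref$snp %in% snps, , drop = FALSE]
  class(ref) <- c("sumstats", "data.frame")
  hy <- harmonize(ref, outcome, maf_threshold)
  keep <- hy$snp
  betas <- list(stats::setNames(hy$beta_x, hy$snp))
  ses <- list(stats::setNames(hy$se_x, hy$snp))
  for (k in seq_along(exposures)[-1L]) {
    hk <- harmonize(ref, exposures[[k]], maf_threshold)
    keep <- intersect(keep, hk$snp)
    betas[[k]] <- stats::setNames(hk$beta_y, hk$snp)
    ses[[k]] <- stats::setNames(hk$se_y, hk$snp)
  }
  if (length(keep) < length(exposures) + 1L) {
    stop("too few SNPs shared across all exposures and the outcome",
         call. = FALSE)
  }
  hy <- hy[match(keep, hy$snp), , drop = FALSE]
  bx <- vapply(betas, function(b) unname(b[keep]), numeric(length(keep)))
  sx <- vapply(ses, function(s) unname(s[keep]), numeric(length(keep)))
  colnames(bx) <- colnames(sx) <- names(exposures)
  mvmr_input(keep, bx, sx, hy$beta_y, hy$se_y,
             exposure_names = names(exposures))
}
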