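#' Configuration for the synthetic two-sample GWAS generator
#'
#' Bundles and validates every generating parameter of the simulator. The
#' defaults describe a realistic post-clumping instrument panel for a large
#' biobank exposure GWAS paired with a consortium outcome GWAS: around one
#' hundred independent instruments, an exposure sample of ~400,000, per-SNP
#' effects of ~0.02 SD per allele (comfortably genome-wide significant at
#' that sample size), no causal effect and no pleiotropy unless asked for.
#'
#' @param n_snps Number of instruments J.
#' @param n_exposure,n_outcome GWAS sample sizes for the two non-overlapping
#'   samples.
#' @param theta True causal effect, in outcome units (log-odds for binary
#'   outcomes) per 1 SD of exposure.
#' @param gamma_mean,gamma_sd Normal distribution of true SNP-exposure
#'   effects gamma_j (SD units per effect allele).
#' @param pleiotropy_mean,pleiotropy_sd Normal distribution of direct
#'   SNP-outcome effects alpha_j among invalid instruments; a nonzero mean
#'   gives directional pleiotropy (the Egger intercept's target), a zero
#'   mean balanced pleiotropy.
#' @param invalid_fraction Proportion of instruments with alpha_j != 0.
#' @param maf_range Interval within (0, 0.5] from which minor allele
#'   frequencies are drawn uniformly.
#' @param binary_outcome If `TRUE` the outcome GWAS is a case-control study
#'   reported on the log-odds scale.
#' @param case_fraction K, the proportion of cases when `binary_outcome`.
#' @param seed RNG seed; identical configs give byte-identical output.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_snps = 100L,
                       n_exposure = 408815L,
                       n_outcome = 100000L,
                       theta = 0,
                       gamma_mean = 0.02,
                       gamma_sd = 0.005,
                       pleiotropy_mean = 0,
                       pleiotropy_sd = 0.01,
                       invalid_fraction = 0,
                       maf_range = c(0.05, 0.5),
                       binary_outcome = FALSE,
                       case_fraction = 0.12,
                       seed = 1L) {
  cfg <- list(n_snps = as.integer(n_snps), n_exposure = n_exposure,
              n_outcome = n_outcome, theta = theta,
              gamma_mean = gamma_mean, gamma_sd = gamma_sd,
              pleiotropy_mean = pleiotropy_mean, pleiotropy_sd = pleiotropy_sd,
              invalid_fraction = invalid_fraction, maf_range = maf_range,
              binary_outcome = isTRUE(binary_outcome),
              case_fraction = case_fraction, seed = as.integer(seed))
  nums <- unlist(cfg[c("n_snps", "n_exposure", "n_outcome", "theta",
                       "gamma_mean", "gamma_sd", "pleiotropy_mean",
                       "pleiotropy_sd", "invalid_fraction", "maf_range",
                       "case_fraction")])
  if (any(!is.finite(nums))) stop("non-finite config value", call. = FALSE)
  if (cfg$n_snps < 1L) stop("n_snps must be >= 1", call. = FALSE)
  if (cfg$invalid_fraction < 0 || cfg$invalid_fraction > 1) {
    stop("invalid_fraction must lie in [0, 1]", call. = FALSE)
  }
  if (length(maf_range) != 2L || maf_range[1] <= 0 || maf_range[2] > 0.5 ||
      maf_range[1] > maf_range[2]) {
    stop("maf_range must be an ordered interval within (0, 0.5]", call. = FALSE)
  }
  if (cfg$binary_outcome &&
      (cfg$case_fraction <= 0 || cfg$case_fraction >= 1)) {
    stop("case_fraction must lie in (0, 1) for binary outcomes", call. = FALSE)
  }
  if (cfg$gamma_sd < 0 || cfg$pleiotropy_sd < 0) {
    stop("sd parameters must be >= 0", call. = FALSE)
  }
  class(cfg) <- "sim_config"
  cfg
}

# Run code under a private, seeded RNG stream, restoring the caller's state.
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

two_sided_p <- function(beta, se) {
  pmax(2 * stats::pnorm(-abs(beta / se)), .Machine$double.xmin)
}

# Non-palindromic allele pairs (effect, other); palindromes are introduced
# only by corrupt_alleles so that harmonization fixtures are controllable.
.nonpal_pairs <- rbind(c("A", "G"), c("A", "C"), c("G", "A"), c("C", "A"),
                       c("T", "G"), c("T", "C"), c("G", "T"), c("C", "T"))

#' Simulate a two-sample GWAS summary-statistics pair with known truth
#'
#' Draws per-SNP minor allele frequencies and true instrument effects, then
#' generates independent exposure and outcome association estimates under
#' the standard summary-data MR model: the true SNP-outcome effect is
#' `Gamma_j = theta * gamma_j + alpha_j`, where `alpha_j` is nonzero for the
#' configured fraction of invalid (pleiotropic) instruments. Sampling error
#' follows the standardized-trait approximation
#' `se = 1 / sqrt(2 * maf * (1 - maf) * n)`; binary outcomes are on the
#' log-odds scale with variance inflated by `1 / (K * (1 - K))`. Exposure
#' and outcome noise are independent, matching non-overlapping samples.
#'
#' @param config A [sim_config()].
#' @return A list with elements `exposure` and `outcome` ([sumstats()]
#'   tables) and `truth`, a list recording `theta`, the vectors `gamma` and
#'   `alpha`, `invalid_ids`, and an empty `corruption_log` (filled by
#'   [corrupt_alleles()]).
#' @seealso [corrupt_alleles()] to add allele-encoding corruption,
#'   [harmonize()] to undo it.
#' @export
#' @examples
#' sim <- simulate_two_sample(sim_config(n_snps = 10, seed = 7))
#' head(sim$exposure)
simulate_two_sample <- function(config) {
  if (!inherits(config, "sim_config")) config <- do.call(sim_config, config)
  J <- config$n_snps
  with_seed(config$seed, {
    maf <- stats::runif(J, config$maf_range[1], config$maf_range[2])
    gamma <- stats::rnorm(J, config$gamma_mean, config$gamma_sd)
    n_invalid <- round(config$invalid_fraction * J)
    invalid <- sample.int(J, n_invalid)
    alpha <- numeric(J)
    alpha[invalid] <- stats::rnorm(n_invalid, config$pleiotropy_mean,
                                   config$pleiotropy_sd)
    se_x <- 1 / sqrt(2 * maf * (1 - maf) * config$n_exposure)
    se_y <- 1 / sqrt(2 * maf * (1 - maf) * config$n_outcome)
    if (config$binary_outcome) {
      se_y <- se_y / sqrt(config$case_fraction * (1 - config$case_fraction))
    }
    beta_x <- stats::rnorm(J, gamma, se_x)
    big_gamma <- config$theta * gamma + alpha
    beta_y <- stats::rnorm(J, big_gamma, se_y)
    ids <- sprintf("snp_%03d", seq_len(J))
    chr <- as.character(sample.int(22L, J, replace = TRUE))
    pos <- sample.int(2.4e8, J, replace = TRUE)
    pair <- .nonpal_pairs[sample.int(nrow(.nonpal_pairs), J, replace = TRUE), ,
                          drop = FALSE]
    base <- data.frame(snp = ids, chr = chr, pos = pos,
                       effect_allele = pair[, 1], other_allele = pair[, 2],
                       eaf = maf, stringsAsFactors = FALSE)
    exposure <- sumstats(cbind(base, beta = beta_x, se = se_x,
                               pval = two_sided_p(beta_x, se_x),
                               n = config$n_exposure))
    outcome <- sumstats(cbind(base, beta = beta_y, se = se_y,
                              pval = two_sided_p(beta_y, se_y),
                              n = config$n_outcome))
    truth <- list(theta = config$theta, gamma = gamma, alpha = alpha,
                  invalid_ids = ids[sort(invalid)],
                  corruption_log = data.frame(snp = character(0),
                                              action = character(0),
                                              stringsAsFactors = FALSE))
    list(exposure = exposure, outcome = outcome, truth = truth)
  })
}

#' Corrupt allele encodings to exercise harmonization
#'
#' Applies, to disjoint random subsets of SNPs, the three encoding artefacts
#' a real outcome GWAS can present: effect/other allele swaps (beta negated,
#' EAF reflected — the association itself is unchanged), opposite-strand
#' reporting (A<->T, C<->G complement; statistics untouched), and rewriting
#' the allele pair as palindromic (A/T or C/G), which makes strand
#' resolution depend on allele frequency alone.
#'
#' @param table A [sumstats()] table.
#' @param swap_fraction,strand_fraction,palindromic_fraction Proportions of
#'   SNPs receiving each transform; their sum must not exceed 1 (subsets are
#'   disjoint so each applied transform is individually invertible).
#' @param palindromic_eaf Optional EAF assigned to the palindromic rewrites
#'   (recycled); `NULL` keeps each SNP's existing EAF. Values above 0.42
#'   minor-allele frequency create non-inferable fixtures.
#' @param seed RNG seed.
#' @return A list with the corrupted `table` and a `log` data.frame
#'   (`snp`, `action`) recording each applied transform.
#' @export
corrupt_alleles <- function(table, swap_fraction = 0, strand_fraction = 0,
                            palindromic_fraction = 0, palindromic_eaf = NULL,
                            seed = 1L) {
  stopifnot(inherits(table, "sumstats"))
  fracs <- c(swap_fraction, strand_fraction, palindromic_fraction)
  if (any(fracs < 0) || any(fracs > 1)) {
    stop("fractions must lie in [0, 1]", call. = FALSE)
  }
  if (sum(fracs) > 1 + 1e-12) {
    stop("swap, strand and palindromic fractions must sum to <= 1",
         call. = FALSE)
  }
  J <- nrow(table)
  comp <- c(A = "T", T = "A", C = "G", G = "C")
  with_seed(seed, {
    counts <- round(fracs * J)
    chosen <- sample.int(J, sum(counts))
    idx_swap <- chosen[seq_len(counts[1])]
    idx_strand <- chosen[counts[1] + seq_len(counts[2])]
    idx_pal <- chosen[counts[1] + counts[2] + seq_len(counts[3])]
    log <- data.frame(snp = character(0), action = character(0),
                      stringsAsFactors = FALSE)
    if (length(idx_swap)) {
      ea <- table$effect_allele[idx_swap]
      table$effect_allele[idx_swap] <- table$other_allele[idx_swap]
      table$other_allele[idx_swap] <- ea
      table$beta[idx_swap] <- -table$beta[idx_swap]
      table$eaf[idx_swap] <- 1 - table$eaf[idx_swap]
      log <- rbind(log, data.frame(snp = table$snp[idx_swap],
                                   action = "allele-swap"))
    }
    if (length(idx_strand)) {
      table$effect_allele[idx_strand] <-
        unname(comp[table$effect_allele[idx_strand]])
      table$other_allele[idx_strand] <-
        unname(comp[table$other_allele[idx_strand]])
      log <- rbind(log, data.frame(snp = table$snp[idx_strand],
                                   action = "strand-flip"))
    }
    if (length(idx_pal)) {
      pal <- rbind(c("A", "T"), c("T", "A"), c("C", "G"), c("G", "C"))
      pick <- pal[sample.int(4L, length(idx_pal), replace = TRUE), ,
                  drop = FALSE]
      table$effect_allele[idx_pal] <- pick[, 1]
      table$other_allele[idx_pal] <- pick[, 2]
      if (!is.null(palindromic_eaf)) {
        table$eaf[idx_pal] <- rep_len(palindromic_eaf, length(idx_pal))
      }
      log <- rbind(log, data.frame(snp = table$snp[idx_pal],
                                   action = "made-palindromic"))
    }
    list(table = sumstats(table), log = log)
  })
}

#' Simulate an exposure -> mediator -> outcome system for MVMR/mediation
#'
#' Generates summary statistics for a mediation structure: `J_x` instruments
#' act on the exposure X (each also moves the mediator M through X by the
#' induced path), and `J_m` instruments act on M only. The outcome model is
#' `Y = theta_direct * X + theta_m * M`, so a SNP's total outcome effect is
#' `(theta_direct + q * theta_m) * gamma_xj` for X instruments (with `q` the
#' X -> M path) and `theta_m * gamma_mj` for M instruments. The univariable
#' total effect of X is `theta_direct + q * theta_m`; the indirect effect is
#' `q * theta_m` and the proportion mediated `q * theta_m / total`.
#'
#' @param j_x,j_m Instrument counts for exposure and mediator.
#' @param theta_direct Direct X -> Y effect.
#' @param indirect Mediated effect `q * theta_m`; `theta_m` is solved to
#'   match given the X -> M path `q`.
#' @param q X -> M path coefficient. `q = 0` makes the mediator independent
#'   of the exposure (requires `indirect = 0`; the M -> Y path is then set
#'   to 0.3 so the mediator still moves the outcome).
#' @param n_exposure,n_mediator,n_outcome GWAS sample sizes.
#' @param gamma_mean,gamma_sd Instrument effect distribution (both traits).
#'   The defaults give per-instrument F statistics of several hundred, so
#'   the no-measurement-error assumption behind IVW and MVMR holds and the
#'   decomposition is tested free of weak-instrument attenuation (a
#'   distinct, known phenomenon).
#' @param maf_range Minor-allele-frequency interval.
#' @param seed RNG seed.
#' @return A list: `uni` — a [harmonized_set()] of the X instruments against
#'   the outcome (for the univariable total effect); `mvmr` — an
#'   [mvmr_input()] over exposures `c("X", "M")` on the instrument union;
#'   `truth` — list with `theta_direct`, `theta_m`, `q`, `total`,
#'   `indirect`, `proportion_mediated`.
#' @export
simulate_mediation <- function(j_x = 60L, j_m = 60L, theta_direct = 0.2,
                               indirect = 0.1, n_exposure = 408815,
                               n_mediator = 408815, n_outcome = 200000,
                               gamma_mean = 0.05, gamma_sd = 0.01,
                               maf_range = c(0.05, 0.5), q = 0.3,
                               seed = 1L) {
  if (q == 0) {
    if (indirect != 0) {
      stop("q = 0 forces indirect = 0", call. = FALSE)
    }
    theta_m <- 0.3
  } else {
    theta_m <- indirect / q
  }
  total <- theta_direct + indirect
  with_seed(seed, {
    J <- j_x + j_m
    maf <- stats::runif(J, maf_range[1], maf_range[2])
    is_x <- seq_len(J) <= j_x
    gamma <- stats::rnorm(J, gamma_mean, gamma_sd)
    # true per-SNP effects on X, M, Y
    bx <- ifelse(is_x, gamma, 0)
    bm <- ifelse(is_x, q * gamma, gamma)
    by <- theta_direct * bx + theta_m * bm
    se_x <- 1 / sqrt(2 * maf * (1 - maf) * n_exposure)
    se_m <- 1 / sqrt(2 * maf * (1 - maf) * n_mediator)
    se_y <- 1 / sqrt(2 * maf * (1 - maf) * n_outcome)
    beta_x <- stats::rnorm(J, bx, se_x)
    beta_m <- stats::rnorm(J, bm, se_m)
    beta_y <- stats::rnorm(J, by, se_y)
    ids <- sprintf("snp_%03d", seq_len(J))
    uni <- harmonized_set(data.frame(
      snp = ids[is_x], beta_x = beta_x[is_x], se_x = se_x[is_x],
      beta_y = beta_y[is_x], se_y = se_y[is_x],
      eaf_x = maf[is_x], eaf_y = maf[is_x], stringsAsFactors = FALSE))
    mv <- mvmr_input(snp = ids,
                     beta_x = cbind(X = beta_x, M = beta_m),
                     se_x = cbind(X = se_x, M = se_m),
                     beta_y = beta_y, se_y = se_y)
    list(uni = uni, mvmr = mv,
         truth = list(theta_direct = theta_direct, theta_m = theta_m, q = q,
                      total = total, indirect = indirect,
                      proportion_mediated = indirect / total))
  })
}

#' Write simulation ground truth as a JSON sidecar
#'
#' @param truth The `truth` element of [simulate_two_sample()].
#' @param path Output path.
#' @export
write_sim_truth <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}
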