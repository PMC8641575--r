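#' Harmonized exposure/outcome effect sets
#'
#' The container every estimator consumes: per-SNP aligned effect estimates
#' `(beta_x, se_x, beta_y, se_y)` plus effect-allele frequencies in both
#' datasets, with an audit attribute recording what [harmonize()] did to
#' each input SNP.
#'
#' @param x A data.frame with columns `snp`, `beta_x`, `se_x`, `beta_y`,
#'   `se_y`, `eaf_x`, `eaf_y`.
#' @param audit Optional audit data.frame (`snp`, `action`).
#' @return A data.frame of class `harmonized_set`.
#' @export
harmonized_set <- function(x, audit = NULL) {
  required <- c("snp", "beta_x", "se_x", "beta_y", "se_y", "eaf_x", "eaf_y")
  if (!all(required %in% names(x))) {
    stop("harmonized set needs columns ", paste(required, collapse = ", "),
         call. = FALSE)
  }
  x <- as.data.frame(x)[, required]
  if (anyDuplicated(x$snp)) stop("duplicate snp identifiers", call. = FALSE)
  if (any(x$se_x <= 0) || any(x$se_y <= 0)) {
    stop("standard errors must be strictly positive", call. = FALSE)
  }
  rownames(x) <- NULL
  attr(x, "audit") <- audit
  class(x) <- c("harmonized_set", "data.frame")
  x
}

#' @rdname harmonized_set
#' @param set A `harmonized_set`.
#' @export
harmonize_audit <- function(set) attr(set, "audit")

is_palindromic <- function(a1, a2) {
  (a1 == "A" & a2 == "T") | (a1 == "T" & a2 == "A") |
  (a1 == "C" & a2 == "G") | (a1 == "G" & a2 == "C")
}

#' Align exposure and outcome summary statistics on the same effect allele
#'
#' Matches SNPs by identifier and reconciles allele encodings. Outcome rows
#' whose alleles equal the exposure's are kept as-is; swapped alleles
#' (effect and other interchanged) have `beta_y` sign-flipped and `eaf_y`
#' reflected; opposite-strand encodings are complemented first and then
#' matched the same way. Palindromic SNPs (A/T or C/G) carry no strand
#' information in their alleles, so they are retained only when the minor
#' allele frequency is below `maf_threshold` in both datasets *and* the two
#' effect-allele frequencies fall on the same side of 0.5 after nominal
#' alignment — otherwise they are dropped as non-inferable. SNPs absent
#' from the outcome are audited as `dropped-missing` so a proxy search can
#' be run upstream; allele pairs that cannot be reconciled at all are
#' dropped with reason.
#'
#' @param exposure,outcome [sumstats()] tables keyed by `snp`.
#' @param maf_threshold Palindromic SNPs are inferable only when
#'   `min(eaf, 1 - eaf) < maf_threshold` (strict) in both datasets. The
#'   conventional cutoff 0.42 is the default; a MAF of exactly 0.42 is
#'   dropped.
#' @return A [harmonized_set()] whose audit lists every exposure SNP with
#'   action `kept`, `sign-flipped`, `strand-flipped`,
#'   `strand-flipped+sign-flipped`, `dropped-palindromic`,
#'   `dropped-missing`, or `dropped-irreconcilable`.
#' @export
#' @examples
#' sim <- simulate_two_sample(sim_config(n_snps = 20, seed = 3))
#' h <- harmonize(sim$exposure, sim$outcome)
#' table(harmonize_audit(h)$action)
harmonize <- function(exposure, outcome, maf_threshold = 0.42) {
  stopifnot(inherits(exposure, "sumstats"), inherits(outcome, "sumstats"))
  comp <- c(A = "T", T = "A", C = "G", G = "C")
  o <- as.data.frame(outcome)
  rownames(o) <- o$snp
  n <- nrow(exposure)
  action <- character(n)
  beta_y <- se_y <- eaf_y <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    s <- exposure$snp[i]
    if (!s %in% o$snp) { action[i] <- "dropped-missing"; next }
    ea_x <- exposure$effect_allele[i]; oa_x <- exposure$other_allele[i]
    ea_y <- o[s, "effect_allele"]; oa_y <- o[s, "other_allele"]
    by <- o[s, "beta"]; sy <- o[s, "se"]; fy <- o[s, "eaf"]
    pal_x <- is_palindromic(ea_x, oa_x)
    pal_y <- is_palindromic(ea_y, oa_y)
    if (pal_x || pal_y) {
      # both sides must present the same palindromic pair
      if (!(pal_x && pal_y && (ea_y %in% c(ea_x, oa_x)))) {
        action[i] <- "dropped-irreconcilable"; next
      }
      fx <- exposure$eaf[i]
      if (is.na(fx) || is.na(fy) ||
          min(fx, 1 - fx) >= maf_threshold ||
          min(fy, 1 - fy) >= maf_threshold) {
        action[i] <- "dropped-palindromic"; next
      }
      flip <- ea_y != ea_x  # nominal letter alignment
      if (flip) { by <- -by; fy <- 1 - fy }
      if ((fx < 0.5) != (fy < 0.5)) {  # frequency-implied strands disagree
        action[i] <- "dropped-palindromic"; next
      }
      action[i] <- if (flip) "sign-flipped" else "kept"
    } else {
      strand <- FALSE
      if (!(ea_y %in% c(ea_x, oa_x) && oa_y %in% c(ea_x, oa_x))) {
        ea_y <- unname(comp[ea_y]); oa_y <- unname(comp[oa_y])
        strand <- TRUE
      }
      if (ea_y == ea_x && oa_y == oa_x) {
        action[i] <- if (strand) "strand-flipped" else "kept"
      } else if (ea_y == oa_x && oa_y == ea_x) {
        by <- -by; fy <- 1 - fy
        action[i] <- if (strand) "strand-flipped+sign-flipped"
                     else "sign-flipped"
      } else {
        action[i] <- "dropped-irreconcilable"; next
      }
    }
    beta_y[i] <- by; se_y[i] <- sy; eaf_y[i] <- fy
  }
  kept <- !startsWith(action, "dropped")
  audit <- data.frame(snp = exposure$snp, action = action,
                      stringsAsFactors = FALSE)
  harmonized_set(data.frame(
    snp = exposure$snp[kept],
    beta_x = exposure$beta[kept], se_x = exposure$se[kept],
    beta_y = beta_y[kept], se_y = se_y[kept],
    eaf_x = exposure$eaf[kept], eaf_y = eaf_y[kept],
    stringsAsFactors = FALSE), audit)
}

#' @rdname harmonize
#' @param set A [harmonized_set()] to serialize.
#' @param path Output TSV path.
#' @export
write_harmonized <- function(set, path) {
  utils::write.table(as.data.frame(set), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname harmonize
#' @export
read_harmonized <- function(path) {
  harmonized_set(utils::read.delim(path, stringsAsFactors = FALSE))
}
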