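#' Construct and validate a GWAS summary-statistics table
#'
#' A summary-statistics table holds one row per SNP with the columns every
#' downstream stage consumes: identifier, genomic coordinates, the two
#' alleles, effect-allele frequency, additive effect estimate, its standard
#' error, two-sided p-value, and the GWAS sample size.
#'
#' @param x A data.frame with columns `snp`, `chr`, `pos`, `effect_allele`,
#'   `other_allele`, `eaf`, `beta`, `se`, `pval`, `n`.
#' @return A validated data.frame of class `sumstats`.
#' @details Validation enforces: unique SNP identifiers, `se > 0`,
#'   `eaf` strictly inside (0, 1), `pval` in (0, 1], distinct single-letter
#'   A/C/G/T alleles, and 1-based positive positions.
#' @export
#' @examples
#' tab <- sumstats(data.frame(
#'   snp = "rs1", chr = "1", pos = 1000L, effect_allele = "A",
#'   other_allele = "G", eaf = 0.3, beta = 0.02, se = 0.005,
#'   pval = 6e-5, n = 10000L))
sumstats <- function(x) {
  required <- c("snp", "chr", "pos", "effect_allele", "other_allele",
                "eaf", "beta", "se", "pval", "n")
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols) > 0L) {
    stop("missing summary-statistic columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  x <- as.data.frame(x)[, required]
  x$snp <- as.character(x$snp)
  x$chr <- as.character(x$chr)
  x$effect_allele <- toupper(as.character(x$effect_allele))
  x$other_allele <- toupper(as.character(x$other_allele))
  if (anyDuplicated(x$snp)) stop("duplicate snp identifiers", call. = FALSE)
  if (any(!is.finite(x$se)) || any(x$se <= 0)) {
    stop("all standard errors must be finite and > 0", call. = FALSE)
  }
  if (any(!is.finite(x$eaf)) || any(x$eaf <= 0) || any(x$eaf >= 1)) {
    stop("eaf must lie strictly in (0, 1)", call. = FALSE)
  }
  if (any(!is.finite(x$pval)) || any(x$pval <= 0) || any(x$pval > 1)) {
    stop("pval must lie in (0, 1]", call. = FALSE)
  }
  bad <- !valid_snp_alleles(x$effect_allele, x$other_allele)
  if (any(bad)) {
    stop("invalid or identical alleles for: ",
         paste(utils::head(x$snp[bad], 5L), collapse = ", "), call. = FALSE)
  }
  if (any(!is.finite(x$pos)) || any(x$pos < 1)) {
    stop("pos must be a positive 1-based coordinate", call. = FALSE)
  }
  rownames(x) <- NULL
  class(x) <- c("sumstats", "data.frame")
  x
}

valid_snp_alleles <- function(a1, a2) {
  bases <- c("A", "C", "G", "T")
  a1 %in% bases & a2 %in% bases & a1 != a2
}

#' @rdname sumstats
#' @param path Path of a tab-separated file with the `sumstats` header
#'   columns (`snp chr pos effect_allele other_allele eaf beta se pval n`).
#' @export
read_sumstats <- function(path) {
  sumstats(utils::read.delim(path, stringsAsFactors = FALSE,
                             colClasses = c(chr = "character")))
}

#' @rdname sumstats
#' @param table A `sumstats` table to serialize.
#' @export
write_sumstats <- function(table, path) {
  utils::write.table(as.data.frame(table), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read or write a pairwise LD table
#'
#' LD tables are tab-separated with columns `snp_a`, `snp_b`, `r2`
#' (squared correlation). Symmetry is by convention: a pair listed in either
#' orientation covers both. Pairs absent from the table are treated as
#' independent (r2 = 0) unless strict mode is requested by the caller.
#'
#' @param path File path.
#' @return A data.frame with columns `snp_a`, `snp_b`, `r2`.
#' @export
read_ld_table <- function(path) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE)
  ld_table(x)
}

#' @rdname read_ld_table
#' @param x A data.frame with columns `snp_a`, `snp_b`, `r2`.
#' @export
ld_table <- function(x) {
  required <- c("snp_a", "snp_b", "r2")
  if (!all(required %in% names(x))) {
    stop("LD table needs columns snp_a, snp_b, r2", call. = FALSE)
  }
  x <- as.data.frame(x)[, required]
  x$snp_a <- as.character(x$snp_a)
  x$snp_b <- as.character(x$snp_b)
  if (any(!is.finite(x$r2)) || any(x$r2 < 0) || any(x$r2 > 1)) {
    stop("r2 must lie in [0, 1]", call. = FALSE)
  }
  x
}

#' Look up pairwise r2 values in an LD table
#'
#' @param ld An LD table (see [ld_table()]).
#' @param a,b Equal-length character vectors of SNP identifiers.
#' @param missing Value returned for pairs absent from the table; `NA` makes
#'   absence detectable for strict callers.
#' @return Numeric vector of r2 values; self-pairs return 1.
#' @keywords internal
ld_lookup <- function(ld, a, b, missing = 0) {
  key <- function(x, y) paste(pmin(x, y), pmax(x, y), sep = "\r")
  map <- stats::setNames(ld$r2, key(ld$snp_a, ld$snp_b))
  out <- unname(map[key(a, b)])
  out[a == b] <- 1
  out[is.na(out) & a != b] <- missing
  out
}
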