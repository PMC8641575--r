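#' Instrument sets with exclusion audit
#'
#' An instrument set pairs the retained [sumstats()] rows with an audit
#' trail listing every excluded SNP and the reason (`p-threshold`,
#' `clumped-by:<snp>`, `proxy-substituted:<snp>` ...). Every SNP of the
#' original input appears exactly once in `selected` or in `audit`.
#'
#' @param selected A [sumstats()] table of retained instruments.
#' @param audit A data.frame with columns `snp`, `reason`.
#' @return An object of class `instrument_set`.
#' @export
instrument_set <- function(selected, audit = NULL) {
  if (is.null(audit)) {
    audit <- data.frame(snp = character(0), reason = character(0),
                        stringsAsFactors = FALSE)
  }
  stopifnot(all(c("snp", "reason") %in% names(audit)))
  if (any(audit$snp %in% selected$snp)) {
    stop("a SNP cannot be both selected and audited out", call. = FALSE)
  }
  structure(list(selected = selected, audit = audit),
            class = "instrument_set")
}

#' @export
print.instrument_set <- function(x, ...) {
  cat(sprintf("<instrument_set> %d selected, %d excluded\n",
              nrow(x$selected), nrow(x$audit)))
  if (nrow(x$audit)) {
    tab <- table(sub(":.*$", "", x$audit$reason))
    cat(paste(sprintf("  %s: %d", names(tab), as.integer(tab)),
              collapse = "\n"), "\n")
  }
  invisible(x)
}

#' Retain genome-wide-significant SNPs
#'
#' Keeps rows with `pval` strictly below the threshold (the conventional
#' genome-wide significance level, p < 5e-8, by default) and audits the
#' rest. Idempotent: re-filtering a filtered set changes nothing.
#'
#' @param table A [sumstats()] table or an [instrument_set()] (its audit is
#'   carried forward).
#' @param p_threshold Strict significance threshold.
#' @return An [instrument_set()].
#' @export
filter_significant <- function(table, p_threshold = 5e-8) {
  prior <- NULL
  if (inherits(table, "instrument_set")) {
    prior <- table$audit
    table <- table$selected
  }
  keep <- table$pval < p_threshold
  audit <- data.frame(snp = table$snp[!keep],
                      reason = rep("p-threshold", sum(!keep)),
                      stringsAsFactors = FALSE)
  instrument_set(table[keep, , drop = FALSE], rbind(prior, audit))
}

#' Greedy LD clumping of an instrument set
#'
#' Standard greedy clumping: repeatedly accept the remaining SNP with the
#' smallest p-value, then remove every other remaining SNP on the same
#' chromosome within `window_kb` whose r2 with the accepted SNP is at or
#' above `r2_threshold` (when two SNPs are correlated, the one with the
#' greater p-value is removed). SNPs farther apart than the window are never
#' clumped together, whatever their listed r2. Pairs absent from the LD
#' table count as independent (r2 = 0) unless `strict` is set, in which
#' case a missing within-window pair is an error.
#'
#' Ties in p-value are broken by chromosome then position (then identifier),
#' so output is deterministic.
#'
#' @param set An [instrument_set()] or [sumstats()] table.
#' @param ld An LD table (see [ld_table()]).
#' @param r2_threshold SNP pairs at or above this r2 are clumped.
#' @param window_kb Physical window in kilobases; strictly-greater distances
#'   are exempt from clumping.
#' @param strict Error on within-window pairs missing from `ld` instead of
#'   treating them as independent.
#' @return An [instrument_set()]; removed SNPs are audited as
#'   `clumped-by:<retained snp>`.
#' @export
ld_clump <- function(set, ld, r2_threshold = 0.01, window_kb = 10000,
                     strict = FALSE) {
  prior <- NULL
  if (inherits(set, "instrument_set")) {
    prior <- set$audit
    set <- set$selected
  }
  if (any(is.na(set$chr)) || any(is.na(set$pos))) {
    stop("all SNPs need chr and pos for clumping", call. = FALSE)
  }
  ord <- order(set$pval, set$chr, set$pos, set$snp)
  tab <- set[ord, , drop = FALSE]
  status <- rep(NA_character_, nrow(tab))  # NA = undecided
  keep_idx <- integer(0)
  for (i in seq_len(nrow(tab))) {
    if (!is.na(status[i])) next
    status[i] <- "kept"
    keep_idx <- c(keep_idx, i)
    undecided <- which(is.na(status))
    if (!length(undecided)) break
    near <- undecided[tab$chr[undecided] == tab$chr[i] &
                      abs(tab$pos[undecided] - tab$pos[i]) <=
                        window_kb * 1000]
    if (!length(near)) next
    r2 <- ld_lookup(ld, tab$snp[near], rep(tab$snp[i], length(near)),
                    missing = if (strict) NA else 0)
    if (strict && anyNA(r2)) {
      stop("missing LD entries within window for: ",
           paste(tab$snp[near][is.na(r2)], collapse = ", "), call. = FALSE)
    }
    hit <- near[r2 >= r2_threshold]
    status[hit] <- paste0("clumped-by:", tab$snp[i])
  }
  removed <- status != "kept"
  audit <- data.frame(snp = tab$snp[removed], reason = status[removed],
                      stringsAsFactors = FALSE)
  kept <- tab[!removed, , drop = FALSE]
  kept <- kept[order(match(kept$snp, set$snp)), , drop = FALSE]  # input order
  instrument_set(kept, rbind(prior, audit))
}

#' Choose proxy SNPs for instruments missing from the outcome dataset
#'
#' For each missing SNP, returns the candidate with the highest r2 strictly
#' greater than `r2_min` (the conventional proxy criterion r2 > 0.8), or no
#' proxy when none qualifies. Ties in r2 are broken by candidate identifier
#' order.
#'
#' @param missing Character vector of instrument SNPs absent from the
#'   outcome data.
#' @param proxy_table An LD table linking missing SNPs (either column) to
#'   candidate proxies.
#' @param r2_min Strict lower bound on acceptable proxy r2.
#' @return A data.frame with columns `snp`, `proxy`, `r2`; SNPs with no
#'   qualifying proxy have `proxy = NA`.
#' @export
substitute_proxies <- function(missing, proxy_table, r2_min = 0.8) {
  out <- data.frame(snp = missing,
                    proxy = rep(NA_character_, length(missing)),
                    r2 = rep(NA_real_, length(missing)),
                    stringsAsFactors = FALSE)
  for (i in seq_along(missing)) {
    s <- missing[i]
    hit <- proxy_table[proxy_table$snp_a == s | proxy_table$snp_b == s, ,
                       drop = FALSE]
    if (!nrow(hit)) next
    cand <- ifelse(hit$snp_a == s, hit$snp_b, hit$snp_a)
    ok <- hit$r2 > r2_min & cand != s
    if (!any(ok)) next
    cand <- cand[ok]; r2 <- hit$r2[ok]
    best <- order(-r2, cand)[1L]
    out$proxy[i] <- cand[best]
    out$r2[i] <- r2[best]
  }
  out
}

#' Instrument strength F statistic
#'
#' The standard multi-instrument F statistic
#' `F = (r2 / (1 - r2)) * ((n - k - 1) / k)` for `k` instruments jointly
#' explaining a proportion `r2` of exposure variance in a GWAS of size `n`.
#' F at or below 10 is flagged as weak by the usual rule of thumb.
#'
#' @param r2_total Proportion of exposure variance explained by the
#'   instruments jointly (per-SNP contributions on standardized traits are
#'   `2 * eaf * (1 - eaf) * beta^2`; see [variance_explained()]).
#' @param n Exposure GWAS sample size.
#' @param k Number of instruments.
#' @return A list with `f` and logical `weak` (`f <= 10`).
#' @export
instrument_strength <- function(r2_total, n, k) {
  if (!is.finite(r2_total) || r2_total <= 0 || r2_total >= 1) {
    stop("r2_total must lie strictly in (0, 1)", call. = FALSE)
  }
  if (n <= k + 1) stop("need n > k + 1", call. = FALSE)
  f <- (r2_total / (1 - r2_total)) * ((n - k - 1) / k)
  list(f = f, weak = f <= 10)
}

#' Variance in the exposure explained by instruments
#'
#' Per-SNP `2 * eaf * (1 - eaf) * beta^2` on standardized traits, summed
#' over independent (post-clumping) instruments.
#'
#' @param table A [sumstats()] table of independent instruments.
#' @return Total r2.
#' @export
variance_explained <- function(table) {
  sum(2 * table$eaf * (1 - table$eaf) * table$beta^2)
}
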