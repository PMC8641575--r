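# Small fixture builders shared across test files.

# A minimal valid summary-statistics table with overridable columns.
make_sumstats <- function(n = 5, snp = sprintf("rs%d", seq_len(n)),
                          chr = "1", pos = seq_len(n) * 1000L,
                          effect_allele = "A", other_allele = "G",
                          eaf = 0.3, beta = 0.02, se = 0.005,
                          pval = NULL, nn = 10000L) {
  if (is.null(pval)) pval <- pmax(2 * pnorm(-abs(beta / se)), 1e-300)
  sumstats(data.frame(snp = snp, chr = chr, pos = pos,
                      effect_allele = effect_allele,
                      other_allele = other_allele, eaf = eaf, beta = beta,
                      se = se, pval = pval, n = nn,
                      stringsAsFactors = FALSE))
}

# A harmonized set built directly from effect vectors.
make_hset <- function(beta_x, se_x, beta_y, se_y,
                      eaf = rep(0.3, length(beta_x))) {
  harmonized_set(data.frame(
    snp = sprintf("rs%d", seq_along(beta_x)),
    beta_x = beta_x, se_x = se_x, beta_y = beta_y, se_y = se_y,
    eaf_x = eaf, eaf_y = eaf, stringsAsFactors = FALSE))
}

# Independent greedy-clumping reference: literal transcription of the rule,
# pairwise loops, no shared code with ld_clump().
clump_oracle <- function(tab, ld, r2_threshold, window_kb) {
  key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  r2map <- setNames(ld$r2, key(ld$snp_a, ld$snp_b))
  remaining <- tab[order(tab$pval, tab$chr, tab$pos, tab$snp), ]
  kept <- character(0)
  while (nrow(remaining) > 0) {
    best <- remaining[1, ]
    kept <- c(kept, best$snp)
    drop <- logical(nrow(remaining))
    for (i in seq_len(nrow(remaining))) {
      if (remaining$snp[i] == best$snp) { drop[i] <- TRUE; next }
      if (remaining$chr[i] != best$chr) next
      if (abs(remaining$pos[i] - best$pos) > window_kb * 1000) next
      r2 <- r2map[key(remaining$snp[i], best$snp)]
      if (is.na(r2)) r2 <- 0
      if (r2 >= r2_threshold) drop[i] <- TRUE
    }
    remaining <- remaining[!drop, , drop = FALSE]
  }
  sort(kept)
}
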