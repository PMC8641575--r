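test_that("significance filter is strict, vacuous at 1, idempotent", {
  tab <- make_sumstats(n = 3, pval = c(1e-9, 5e-8, 1e-7))
  set <- filter_significant(tab)
  expect_equal(set$selected$snp, "rs1")  # p == 5e-8 excluded (strict)
  expect_equal(sort(set$audit$snp), c("rs2", "rs3"))
  expect_true(all(set$audit$reason == "p-threshold"))

  all_in <- filter_significant(tab, p_threshold = 1.0 + 1e-9)
  expect_equal(nrow(all_in$selected), 3L)

  twice <- filter_significant(set)
  expect_equal(twice$selected$snp, set$selected$snp)
  expect_equal(nrow(twice$selected) + nrow(twice$audit), nrow(tab))
})

test_that("no null SNPs survive genome-wide significance", {
  withr::local_seed(42)
  tab <- make_sumstats(n = 100, pval = runif(100))
  expect_equal(nrow(filter_significant(tab)$selected), 0L)
})

test_that("clumping keeps the smaller p-value of a correlated pair", {
  tab <- make_sumstats(n = 2, pos = c(1000L, 2000L),
                       pval = c(1e-10, 1e-9))
  ld <- ld_table(data.frame(snp_a = "rs1", snp_b = "rs2", r2 = 0.5))
  out <- ld_clump(tab, ld)
  expect_equal(out$selected$snp, "rs1")
  expect_equal(out$audit$reason, "clumped-by:rs1")

  both <- ld_clump(tab, ld_table(data.frame(snp_a = "rs1", snp_b = "rs2",
                                            r2 = 0.001)))
  expect_equal(sort(both$selected$snp), c("rs1", "rs2"))
})

test_that("distance window and strict mode behave as documented", {
  # same r2 but farther apart than the window: never clumped
  tab <- make_sumstats(n = 2, pos = c(1000L, 1000L + 10000 * 1000 + 1),
                       pval = c(1e-10, 1e-9))
  ld <- ld_table(data.frame(snp_a = "rs1", snp_b = "rs2", r2 = 0.9))
  expect_equal(nrow(ld_clump(tab, ld)$selected), 2L)
  near <- make_sumstats(n = 2, pos = c(1000L, 2000L), pval = c(1e-10, 1e-9))
  expect_equal(nrow(ld_clump(near, ld)$selected), 1L)
  empty_ld <- ld_table(data.frame(snp_a = character(0),
                                  snp_b = character(0), r2 = numeric(0)))
  expect_equal(nrow(ld_clump(near, empty_ld)$selected), 2L)
  expect_error(ld_clump(near, empty_ld, strict = TRUE), "missing LD")
})

test_that("clumping matches the brute-force oracle on a 20-SNP LD block", {
  withr::local_seed(7)
  n <- 20
  tab <- make_sumstats(n = n, chr = rep(c("1", "2"), each = 10),
                       pos = rep(seq(1e5, 1e6, length.out = 10), 2),
                       pval = 10^runif(n, -12, -8))
  # block structure: within each chromosome, adjacent SNPs correlated
  pairs <- expand.grid(i = 1:n, j = 1:n)
  pairs <- pairs[pairs$i < pairs$j, ]
  ld <- ld_table(data.frame(
    snp_a = tab$snp[pairs$i], snp_b = tab$snp[pairs$j],
    r2 = ifelse(tab$chr[pairs$i] == tab$chr[pairs$j] &
                  abs(pairs$i - pairs$j) <= 3,
                runif(nrow(pairs), 0.02, 0.9), 0)))
  got <- sort(ld_clump(tab, ld, r2_threshold = 0.01,
                       window_kb = 10000)$selected$snp)
  expect_equal(got, clump_oracle(tab, ld, 0.01, 10000))
  # property: every removed SNP is correlated with a retained better SNP
  res <- ld_clump(tab, ld)
  for (k in seq_len(nrow(res$audit))) {
    by <- sub("clumped-by:", "", res$audit$reason[k])
    expect_true(by %in% res$selected$snp)
    expect_gte(ld_lookup(ld, res$audit$snp[k], by), 0.01)
    expect_lte(tab$pval[tab$snp == by], tab$pval[tab$snp == res$audit$snp[k]])
  }
})

test_that("proxy substitution picks the best candidate strictly above r2_min", {
  pt <- ld_table(data.frame(snp_a = c("rs1", "rs1", "rs2"),
                            snp_b = c("p1", "p2", "p3"),
                            r2 = c(0.9, 0.85, 0.8)))
  out <- substitute_proxies(c("rs1", "rs2", "rs9"), pt)
  expect_equal(out$proxy[out$snp == "rs1"], "p1")
  expect_true(is.na(out$proxy[out$snp == "rs2"]))  # 0.8 not > 0.8
  expect_true(is.na(out$proxy[out$snp == "rs9"]))
  empty <- substitute_proxies(character(0), pt)
  expect_equal(nrow(empty), 0L)
  # tie on r2 broken by identifier order
  tie <- ld_table(data.frame(snp_a = c("rs1", "rs1"),
                             snp_b = c("pB", "pA"), r2 = c(0.9, 0.9)))
  expect_equal(substitute_proxies("rs1", tie)$proxy, "pA")
})

test_that("F statistic formula, boundary, and monotonicity", {
  expect_equal(instrument_strength(0.5, 12, 5)$f, 1.2)
  expect_true(instrument_strength(0.5, 12, 5)$weak)
  expect_false(instrument_strength(0.9, 1000, 5)$weak)
  expect_error(instrument_strength(1, 100, 5), "r2_total")
  expect_error(instrument_strength(0.5, 6, 5), "n > k")

  # back-solve r2 so F = 10 exactly at n = 1000, k = 10
  c0 <- 10 * 10 / (1000 - 10 - 1)
  r2_star <- c0 / (1 + c0)
  at <- instrument_strength(r2_star, 1000, 10)
  expect_equal(at$f, 10, tolerance = 1e-12)
  expect_true(at$weak)  # boundary counts as weak (F <= 10)
  expect_false(instrument_strength(r2_star + 1e-6, 1000, 10)$weak)

  # strictly increasing in r2 and n, decreasing in k
  f0 <- instrument_strength(0.02, 5e4, 50)$f
  expect_gt(instrument_strength(0.03, 5e4, 50)$f, f0)
  expect_gt(instrument_strength(0.02, 6e4, 50)$f, f0)
  expect_lt(instrument_strength(0.02, 5e4, 60)$f, f0)
})

test_that("variance_explained matches the per-SNP 2p(1-p)beta^2 sum", {
  tab <- make_sumstats(n = 3, beta = c(0.1, -0.2, 0.05),
                       eaf = c(0.2, 0.4, 0.25))
  expect_equal(variance_explained(tab),
               sum(2 * c(0.2, 0.4, 0.25) * c(0.8, 0.6, 0.75) *
                     c(0.1, -0.2, 0.05)^2))
})
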