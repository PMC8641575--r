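test_that("swapped alleles are sign-flipped back", {
  exp <- make_sumstats(n = 1, effect_allele = "A", other_allele = "G",
                       beta = 0.10)
  out <- make_sumstats(n = 1, effect_allele = "G", other_allele = "A",
                       beta = -0.10, eaf = 0.7)
  h <- harmonize(exp, out)
  expect_equal(h$beta_y, 0.10)
  expect_equal(h$eaf_y, 0.3)
  expect_equal(harmonize_audit(h)$action, "sign-flipped")
})

test_that("strand-complementary encodings are recognized", {
  exp <- make_sumstats(n = 1, effect_allele = "A", other_allele = "G",
                       beta = 0.10)
  out_same <- make_sumstats(n = 1, effect_allele = "T", other_allele = "C",
                            beta = 0.05)
  h1 <- harmonize(exp, out_same)
  expect_equal(h1$beta_y, 0.05)
  expect_equal(harmonize_audit(h1)$action, "strand-flipped")
  out_swap <- make_sumstats(n = 1, effect_allele = "C", other_allele = "T",
                            beta = 0.05, eaf = 0.8)
  h2 <- harmonize(exp, out_swap)
  expect_equal(h2$beta_y, -0.05)
  expect_equal(h2$eaf_y, 0.2)
  expect_equal(harmonize_audit(h2)$action, "strand-flipped+sign-flipped")
})

test_that("palindromic SNPs follow the MAF inferability rule", {
  pal <- function(eaf_x, eaf_y, ea_y = "A", oa_y = "T") {
    exp <- make_sumstats(n = 1, effect_allele = "A", other_allele = "T",
                         eaf = eaf_x, beta = 0.1)
    out <- make_sumstats(n = 1, effect_allele = ea_y, other_allele = oa_y,
                         eaf = eaf_y, beta = 0.05)
    harmonize(exp, out)
  }
  # inferable: MAF < 0.42 both sides, concordant orientation
  h <- pal(0.10, 0.12)
  expect_equal(nrow(h), 1L)
  expect_equal(harmonize_audit(h)$action, "kept")
  # non-inferable: exposure MAF at/above 0.42
  expect_equal(harmonize_audit(pal(0.45, 0.12))$action, "dropped-palindromic")
  expect_equal(harmonize_audit(pal(0.42, 0.12))$action, "dropped-palindromic")
  # outcome side also binds
  expect_equal(harmonize_audit(pal(0.10, 0.44))$action, "dropped-palindromic")
  # discordant frequency-implied orientation is dropped, not guessed
  expect_equal(harmonize_audit(pal(0.10, 0.88))$action, "dropped-palindromic")
  # swapped letters with concordant frequency after reflection are kept
  h2 <- pal(0.10, 0.88, ea_y = "T", oa_y = "A")
  expect_equal(h2$beta_y, -0.05)
  expect_equal(harmonize_audit(h2)$action, "sign-flipped")
})

test_that("missing and irreconcilable SNPs are audited, not guessed", {
  exp <- make_sumstats(n = 3, effect_allele = c("A", "A", "A"),
                       other_allele = c("G", "G", "T"))
  out <- make_sumstats(n = 2, snp = c("rs1", "rs2"),
                       effect_allele = c("A", "A"),
                       other_allele = c("C", "G"))
  h <- harmonize(exp, out)
  aud <- harmonize_audit(h)
  expect_equal(aud$action[aud$snp == "rs1"], "dropped-irreconcilable")
  expect_equal(aud$action[aud$snp == "rs2"], "kept")
  expect_equal(aud$action[aud$snp == "rs3"], "dropped-missing")
  expect_equal(nrow(aud), nrow(exp))  # audit covers every exposure SNP
})

test_that("harmonization is idempotent", {
  sim <- simulate_two_sample(sim_config(n_snps = 40, theta = 0.1, seed = 8))
  corr <- corrupt_alleles(sim$outcome, 0.3, 0.3, 0, seed = 2)
  h1 <- harmonize(sim$exposure, corr$table)
  # rebuild an outcome table from the harmonized result (aligned alleles)
  aligned <- sim$exposure
  aligned$beta <- h1$beta_y
  aligned$se <- h1$se_y
  aligned$eaf <- h1$eaf_y
  aligned$pval <- pmax(2 * pnorm(-abs(aligned$beta / aligned$se)), 1e-300)
  h2 <- harmonize(sim$exposure, sumstats(aligned))
  expect_equal(h2$beta_y, h1$beta_y)
  expect_true(all(harmonize_audit(h2)$action == "kept"))
})

test_that("swapping every exposure allele negates beta_x, not the estimate", {
  sim <- simulate_two_sample(sim_config(n_snps = 30, theta = 0.2, seed = 9))
  h1 <- harmonize(sim$exposure, sim$outcome)
  flipped <- as.data.frame(sim$exposure)
  tmp <- flipped$effect_allele
  flipped$effect_allele <- flipped$other_allele
  flipped$other_allele <- tmp
  flipped$beta <- -flipped$beta
  flipped$eaf <- 1 - flipped$eaf
  h2 <- harmonize(sumstats(flipped), sim$outcome)
  expect_equal(h2$beta_x, -h1$beta_x)
  expect_equal(abs(h2$beta_y), abs(h1$beta_y))
  expect_equal(mr_ivw(h2)$estimate, mr_ivw(h1)$estimate)
  expect_equal(mr_ivw(h2)$se, mr_ivw(h1)$se)
})

test_that("corrupt-then-harmonize round-trip restores every effect", {
  sim <- simulate_two_sample(sim_config(n_snps = 50, theta = 0.1, seed = 10))
  corr <- corrupt_alleles(sim$outcome, swap_fraction = 0.4,
                          strand_fraction = 0.4, seed = 5)
  h <- harmonize(sim$exposure, corr$table)
  expect_equal(nrow(h), 50L)
  expect_equal(h$beta_y[match(sim$outcome$snp, h$snp)], sim$outcome$beta)
})
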