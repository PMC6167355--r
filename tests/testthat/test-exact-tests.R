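# replicate-chain agreement: mean of independent short chains vs an exact
# value, within 3 empirical standard errors of the replicate mean
replicate_chain_p <- function(run, n_rep = 16) {
  ps <- vapply(seq_len(n_rep), run, numeric(1))
  list(mean = mean(ps), se = stats::sd(ps) / sqrt(n_rep))
}

test_that("HWE chain agrees with full enumeration on biallelic tables", {
  cases <- list(c(25, 50, 25), c(10, 40, 30), c(30, 10, 20))
  for (cs in cases) {
    cnt <- matrix(c(cs[1], cs[2], 0, cs[3]), 2, 2, byrow = TRUE)
    exact <- oracle_hwe_biallelic(cs[1], cs[2], cs[3])
    rep <- replicate_chain_p(function(i) {
      hwe_exact_test(cnt, cfg = mcmc_config(2e4, 2e3, seed = 100 + i))$p.value
    })
    expect_lt(abs(rep$mean - exact), 3 * max(rep$se, 1e-4))
  }
})

test_that("HWE chain flags extreme heterozygote excess", {
  cnt <- matrix(c(0, 50, 0, 0), 2, 2, byrow = TRUE)
  exact <- oracle_hwe_biallelic(0, 50, 0)
  r <- hwe_exact_test(cnt, cfg = mcmc_config(5e4, 5e3, seed = 1))
  expect_lt(r$p.value, 0.001)
  expect_lt(exact, 0.001)
})

test_that("HWE chain agrees with the i.i.d. shuffling oracle on 3 alleles", {
  set.seed(21)
  a1 <- sample(1:3, 60, TRUE, prob = c(0.5, 0.3, 0.2))
  a2 <- sample(1:3, 60, TRUE, prob = c(0.5, 0.3, 0.2))
  cnt <- matrix(0, 3, 3)
  for (i in seq_along(a1)) {
    cnt[min(a1[i], a2[i]), max(a1[i], a2[i])] <-
      cnt[min(a1[i], a2[i]), max(a1[i], a2[i])] + 1
  }
  oracle <- oracle_hwe_shuffle_p(a1, a2, n_draws = 4000)
  rep <- replicate_chain_p(function(i) {
    hwe_exact_test(cnt, cfg = mcmc_config(2e4, 2e3, seed = 300 + i))$p.value
  })
  se <- sqrt(rep$se^2 + oracle * (1 - oracle) / 4000)
  expect_lt(abs(rep$mean - oracle), 3 * max(se, 1e-3))
})

test_that("monomorphic locus gives the degenerate HWE result", {
  g <- make_genotypes(rep("female", 5), list(L1 = rep("10/10", 5)))
  r <- hwe_exact_test(g, "L1")
  expect_equal(r$p.value, 1)
  expect_equal(r$method, "monomorphic")
})

test_that("chain p-values are bit-reproducible given seed and config", {
  g <- small_cohort(seed = 5)
  cfg <- mcmc_config(1e4, 1e3, seed = 77)
  expect_identical(hwe_exact_test(g, "DXS8378", cfg)$p.value,
                   hwe_exact_test(g, "DXS8378", cfg)$p.value)
  cfg2 <- mcmc_config(1e4, 1e3, seed = 78)
  expect_identical(ld_exact_test_haploid(g, c("DXS8378", "DXS7423"), cfg2)$p.value,
                   ld_exact_test_haploid(g, c("DXS8378", "DXS7423"), cfg2)$p.value)
})

test_that("haploid LD chain matches the Fisher exact oracle", {
  diag10 <- matrix(c(10, 0, 0, 10), 2, 2)
  fisher <- fisher.test(diag10)$p.value  # 2 / choose(20, 10)
  rep <- replicate_chain_p(function(i) {
    ld_exact_test_haploid(diag10, cfg = mcmc_config(4e4, 4e3, seed = 400 + i))$p.value
  })
  se <- sqrt(rep$se^2 + fisher / 4e4)
  expect_lt(abs(rep$mean - fisher), 3 * max(se, 1e-5))

  balanced <- matrix(c(5, 5, 5, 5), 2, 2)
  r <- ld_exact_test_haploid(balanced, cfg = mcmc_config(2e4, 2e3, seed = 9))
  expect_equal(r$p.value, 1)

  set.seed(31)
  tab <- matrix(rpois(12, 6) + 1, 3, 4)
  fisher3 <- fisher.test(tab)$p.value
  rep3 <- replicate_chain_p(function(i) {
    ld_exact_test_haploid(tab, cfg = mcmc_config(3e4, 3e3, seed = 500 + i))$p.value
  })
  expect_lt(abs(rep3$mean - fisher3), 3 * max(rep3$se, 1e-3))
})

test_that("degenerate haploid tables give p = 1", {
  r <- ld_exact_test_haploid(matrix(c(7, 0), 1, 2))
  expect_equal(r$p.value, 1)
  expect_equal(r$method, "degenerate")
})

test_that("bonferroni threshold and pair count", {
  expect_equal(bonferroni_threshold(0.05, 171), 0.0003)
  expect_equal(bonferroni_threshold(0.05, 1), 0.05)
  expect_equal(bonferroni_threshold(0.05, 19 * 18 / 2),
               bonferroni_threshold(0.05, 171))
  expect_equal(bonferroni_threshold(0.05, 171, digits = NULL), 0.05 / 171)
  expect_error(bonferroni_threshold(1.2, 10), "alpha")
})

test_that("HWE test has power against strong inbreeding", {
  rej <- 0
  n_rep <- 60
  for (i in seq_len(n_rep)) {
    spec <- synthetic_spec(265, 0, list(L1 = c(`10` = 0.5, `11` = 0.5)),
                           F_inbreeding = 0.3, seed = 9000 + i)
    g <- simulate_genotypes(spec)
    p <- hwe_exact_test(g, "L1", mcmc_config(5e3, 500, seed = i))$p.value
    if (p <= 0.05) rej <- rej + 1
  }
  expect_gte(rej / n_rep, 0.8)
})

test_that("Fst is 0 for identical strata and 1 for fixed differences", {
  expect_equal(fst_statistic(c(A = 50, B = 50), c(A = 500, B = 500)), 0)
  expect_equal(fst_statistic(c(A = 100), c(B = 100)), 1)
  g <- make_genotypes(c("female", "male"), list(L1 = c("10/10", "10")))
  r <- fst_gender(g, "L1", permutations = 10)
  expect_equal(r$p.value, 1)
  expect_equal(r$method, "monomorphic")
})

test_that("sex-differentiation test is reproducible and detects divergence", {
  g <- small_cohort(seed = 17, n_f = 60, n_m = 60)
  r1 <- fst_gender(g, "DXS8378", permutations = 300, seed = 5)
  r2 <- fst_gender(g, "DXS8378", permutations = 300, seed = 5)
  expect_identical(r1$p.value, r2$p.value)

  # males and females drawn from different allele distributions
  gdiff <- make_genotypes(c(rep("female", 60), rep("male", 60)),
                          list(L1 = c(rep("10/10", 60), rep("11", 60))))
  rd <- fst_gender(gdiff, "L1", permutations = 300, seed = 5)
  expect_lte(rd$p.value, 0.01)
  expect_equal(rd$statistic, 1)
})
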