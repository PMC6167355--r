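test_that("allele frequencies count two female and one male chromosome", {
  g <- make_genotypes(c("female", "male"),
                      list(DXS8378 = c("15/16", "15")))
  fr <- allele_frequencies(g, "pooled")
  expect_equal(fr$N[["DXS8378"]], 3)
  expect_equal(fr$tab$DXS8378$freq, c(2 / 3, 1 / 3))
  expect_equal(fr$tab$DXS8378$allele, c("15", "16"))

  ff <- allele_frequencies(g, "female")
  expect_equal(ff$N[["DXS8378"]], 2)
  fm <- allele_frequencies(g, "male")
  expect_equal(fm$tab$DXS8378$freq, 1)
  expect_equal(fm$N[["DXS8378"]], length(unique(g$sample_id[g$sex == "male"])))
})

test_that("pooled counts conserve female + male counts and sum to one", {
  g <- small_cohort(seed = 3)
  fp <- allele_frequencies(g, "pooled")
  ff <- allele_frequencies(g, "female")
  fm <- allele_frequencies(g, "male")
  for (loc in fp$loci) {
    expect_equal(sum(fp$tab[[loc]]$freq), 1, tolerance = 1e-12)
    cf <- setNames(ff$tab[[loc]]$count, ff$tab[[loc]]$allele)
    cm <- setNames(fm$tab[[loc]]$count, fm$tab[[loc]]$allele)
    merged <- setNames(numeric(nrow(fp$tab[[loc]])), fp$tab[[loc]]$allele)
    merged[names(cf)] <- merged[names(cf)] + cf
    merged[names(cm)] <- merged[names(cm)] + cm
    expect_equal(setNames(fp$tab[[loc]]$count, fp$tab[[loc]]$allele), merged)
    expect_equal(fp$N[[loc]], ff$N[[loc]] + fm$N[[loc]])
  }
})

test_that("missing calls drop the sample from that locus only", {
  g <- make_genotypes(c("female", "female", "male"),
                      list(L1 = c("10/11", NA, "10"),
                           L2 = c("12/12", "12/13", NA)))
  fr <- allele_frequencies(g, "pooled")
  expect_equal(fr$N, c(L1 = 3, L2 = 4))
})

test_that("empty stratum at a locus is flagged absent, not zero-filled", {
  g <- make_genotypes(c("female", "female"),
                      list(L1 = c("10/11", "10/10")))
  expect_message(fm <- try(allele_frequencies(g, "male"), silent = TRUE),
                 "flagged absent")
  expect_s3_class(fm, "try-error")  # male stratum empty everywhere
})

test_that("frequency estimates converge to generating frequencies", {
  p <- c(`12` = 0.55, `13` = 0.3, `14` = 0.15)
  spec <- synthetic_spec(2500, 0, list(L1 = p), seed = 42)
  g <- simulate_genotypes(spec)
  fr <- allele_frequencies(g, "pooled")
  N <- fr$N[["L1"]]
  phat <- setNames(fr$tab$L1$freq, fr$tab$L1$allele)
  for (a in names(p)) {
    expect_lt(abs(phat[[a]] - p[[a]]), 3 * sqrt(p[[a]] * (1 - p[[a]]) / N))
  }
})

test_that("haplotypes are counted from complete males in group locus order", {
  # 248 males, 18 carrying 25-19-10 at the LG2 loci
  n <- 248
  a159 <- c(rep("25", 18), as.character(rep(26:30, length.out = n - 18)))
  a162 <- c(rep("19", 18), as.character(rep(20:24, length.out = n - 18)))
  a164 <- c(rep("10", 18), as.character(rep(11:17, length.out = n - 18)))
  g <- make_genotypes(rep("male", n),
                      list(DXS10159 = a159, DXS10162 = a162, DXS10164 = a164))
  h <- haplotype_frequencies(g, list(LG2 = c("DXS10159", "DXS10162", "DXS10164")))
  tab <- h$groups$LG2$table
  expect_equal(tab$haplotype[1], "25-19-10")
  expect_equal(tab$count[1], 18)
  expect_equal(round_half_up(tab$freq[1], 4), 0.0726)
  expect_equal(sum(tab$count), n)
})

test_that("haplotype degenerate cases: all identical and all unique", {
  g1 <- make_genotypes(rep("male", 5),
                       list(L1 = rep("10", 5), L2 = rep("20", 5)))
  h1 <- haplotype_frequencies(g1, list(G = c("L1", "L2")))
  expect_equal(h1$groups$G$n_distinct, 1L)
  expect_equal(h1$groups$G$table$freq, 1)
  expect_equal(h1$groups$G$n_singletons, 0L)

  g2 <- make_genotypes(rep("male", 5),
                       list(L1 = as.character(10:14), L2 = as.character(20:24)))
  h2 <- haplotype_frequencies(g2, list(G = c("L1", "L2")))
  expect_equal(h2$groups$G$n_distinct, 5L)
  expect_equal(h2$groups$G$n_singletons, 5L)
  expect_equal(singleton_fraction(h2, "G"), 1)
})

test_that("males missing any group locus are dropped; females excluded with note", {
  g <- make_genotypes(c("male", "male", "female"),
                      list(L1 = c("10", NA, "10/11"),
                           L2 = c("20", "21", "20/20")))
  expect_message(h <- haplotype_frequencies(g, list(G = c("L1", "L2"))),
                 "excluded")
  expect_equal(h$groups$G$n_males, 1L)
  expect_equal(sum(h$groups$G$table$count), 1)
})

test_that("singleton fraction matches published worked examples", {
  counts <- c(rep(1, 128), rep(2, 33), rep(3, 18))  # 179 distinct, 248 males
  g <- make_genotypes(rep("male", sum(counts)),
                      list(L1 = rep(as.character(seq_along(counts) + 100), counts)))
  h <- haplotype_frequencies(g, list(G = "L1"))
  expect_equal(h$groups$G$n_distinct, 179L)
  expect_equal(round_half_up(singleton_fraction(h, "G"), 4), 0.7151)
  expect_error(singleton_fraction(h, "nope"), "unknown")
})
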