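# the full-cohort report is expensive (19 HWE chains, within-group LD
# battery), so it is computed once and shared across the tests in this file
.report_cache <- new.env(parent = emptyenv())

cached_report <- function() {
  if (is.null(.report_cache$rep)) {
    g <- gelao_like_fixture(seed = 2)
    .report_cache$g <- g
    .report_cache$rep <- run_full_study(
      g,
      hwe_cfg = mcmc_config(4e3, 400),
      female_ld_cfg = perm_config(25, 2),
      male_ld_cfg = mcmc_config(4e3, 400),
      fst_permutations = 50,
      ld_pairs = "within_groups",
      seed = 1
    )
  }
  .report_cache$rep
}

test_that("the full study report has one row per locus and per group", {
  rep <- cached_report()
  expect_equal(nrow(rep$loci_summary), 19L)
  expect_equal(rep$loci_summary$locus, panel_loci())
  expect_equal(nrow(rep$group_summary), 7L)
  expect_equal(rep$group_summary$group, paste0("LG", 1:7))
  expect_equal(rep$n_ld_pairs, 171)
  expect_true(all(rep$loci_summary$N == 778))
  expect_true(all(rep$loci_summary$p_hwe >= 0 & rep$loci_summary$p_hwe <= 1))
  expect_true(all(rep$fst$p >= 0 & rep$fst$p <= 1))
})

test_that("every report row satisfies the parameter identities", {
  rep <- cached_report()
  L <- rep$loci_summary
  expect_equal(L$PD_m,
               unname(1 - vapply(rep$frequencies$pooled$tab[L$locus],
                                 function(d) sum(d$freq^2), numeric(1))))
  expect_equal(L$MEC_Desmarais, L$PIC, tolerance = 1e-12)
  expect_equal(L$GD, L$N / (L$N - 1) * L$PD_m, tolerance = 1e-12)
  G <- rep$group_summary
  expect_equal(G$PD_m, 1 - G$MP, tolerance = 1e-12)
  expect_equal(G$MEC_Desmarais, G$PIC, tolerance = 1e-12)
  expect_equal(G$HD, G$n_males / (G$n_males - 1) * G$PD_m, tolerance = 1e-12)
  prob_cols <- c("Ho", "He", "GD", "PIC", "PD_m", "PD_f", "MEC_Kruger",
                 "MEC_Kishida", "MEC_Desmarais", "MEC_Desmarais_Duo")
  expect_true(all(as.matrix(L[prob_cols]) >= 0 & as.matrix(L[prob_cols]) <= 1))
})

test_that("a rerun with the same seed is byte-identical on disk", {
  g <- small_cohort(seed = 31, n_f = 40, n_m = 30)
  groups <- list(G1 = c("DXS8378", "DXS7423"), G2 = "HPRTB")
  run <- function() run_full_study(
    g, groups = groups,
    hwe_cfg = mcmc_config(2e3, 200),
    female_ld_cfg = perm_config(30, 2),
    male_ld_cfg = mcmc_config(2e3, 200),
    fst_permutations = 30, ld_pairs = "all", seed = 7
  )
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_report_bundle(run(), d1)
  write_report_bundle(run(), d2)
  for (f in c("loci_summary.tsv", "group_summary.tsv", "ld_pvalues.tsv",
              "fst_gender.tsv", "combined_powers.tsv")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     info = f)
  }
})

test_that("LD matrix fills females upper and males lower triangle", {
  rep <- cached_report()
  lg7 <- c("DXS10134", "DXS7423")
  i <- match(lg7[1], panel_loci())
  j <- match(lg7[2], panel_loci())
  expect_false(is.na(rep$ld_female[min(i, j), max(i, j)]))
  expect_false(is.na(rep$ld_male[max(i, j), min(i, j)]))
  # cross-group pairs untested in this mode
  expect_true(is.na(rep$ld_female[1, 2]))
  expect_equal(rep$ld_bonferroni, 0.05 / 171)
})

test_that("combined powers in the report are consistent with their columns", {
  rep <- cached_report()
  expect_equal(rep$combined$PD_m$complement,
               prod(1 - rep$loci_summary$PD_m), tolerance = 1e-9)
  expect_equal(rep$combined$PD_m_haplotype$complement,
               prod(rep$group_summary$MP), tolerance = 1e-9)
  expect_match(rep$combined$PD_f$text, "^0\\.9{12}")
})

test_that("population comparison bundle is complete and locus-restrictable", {
  set.seed(44)
  loci <- setNames(lapply(panel_loci(), function(l) {
    w <- rgamma(5, 2)
    setNames(w / sum(w), as.character(10:14))
  }), panel_loci())
  spec <- synthetic_spec(0, 0, loci, n_populations = 5,
                         fst_divergence = 0.05, seed = 44)
  pops <- simulate_divergent_populations(spec)
  cmp <- suppressWarnings(compare_populations(pops))
  expect_equal(sort(cmp$tree$tip.label), sort(names(pops)))
  expect_equal(dim(cmp$pca$scores), c(5L, 3L))
  expect_equal(dim(cmp$mds$points), c(5L, 2L))

  cmp11 <- suppressWarnings(compare_populations(pops, loci = argus_overlap_loci()))
  expect_equal(cmp11$distances, t(cmp11$distances), tolerance = 1e-12)
  expect_equal(diag(cmp11$distances), setNames(rep(0, 5), names(pops)))
  expect_false(isTRUE(all.equal(cmp11$distances, cmp$distances)))

  expect_warning(two <- compare_populations(pops[1:2]), "skipped")
  expect_null(two$pca)
  expect_equal(dim(two$distances), c(2L, 2L))

  d <- withr::local_tempdir()
  write_comparison_bundle(cmp, d)
  expect_true(all(file.exists(file.path(d, c("nei_distances.tsv",
                                             "pca_scores.tsv",
                                             "mds_coordinates.tsv",
                                             "nj_tree.nwk")))))
  tr <- read_newick(file.path(d, "nj_tree.nwk"))
  expect_equal(sort(tr$tip.label), sort(names(pops)))
})

test_that("published reference tables load with expected shape", {
  L <- reported_gelao_parameters("loci")
  G <- reported_gelao_parameters("groups")
  expect_equal(nrow(L), 19L)
  expect_equal(nrow(G), 7L)
  expect_setequal(L$locus, panel_loci())
  # internal identity of the published rows: PD_m = 1 - MP at print precision
  expect_equal(G$PD_m, round_half_up(1 - G$MP, 4), tolerance = 1e-12)
})
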