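#' Per-locus forensic parameter summary
#'
#' One row per locus in the classic report layout: number of alleles, female
#' observed/expected heterozygosity, the Hardy-Weinberg exact-test p-value
#' (when supplied), gene diversity, PIC, powers of discrimination and the
#' four mean exclusion chances — all computed from the pooled allele
#' frequencies unless another stratum is requested.
#'
#' @param g an [xstr_genotypes] object.
#' @param hwe optional named list of `xstr_test` results per locus.
#' @param stratum frequency stratum feeding the parameters
#'   (default `"pooled"`).
#' @return `data.frame`, one row per locus.
#' @export
forensic_summary_loci <- function(g, hwe = NULL, stratum = "pooled") {
  fr <- allele_frequencies(g, stratum)
  rows <- lapply(fr$loci, function(loc) {
    p <- fr$tab[[loc]]$freq
    ps <- power_sums(p)
    het <- observed_expected_het(g, loc)
    data.frame(
      locus = loc,
      n_alleles = length(p),
      Ho = het[["Ho"]],
      He = het[["He"]],
      p_hwe = if (!is.null(hwe) && loc %in% names(hwe))
        hwe[[loc]]$p.value else NA_real_,
      GD = diversity(ps, fr$N[[loc]]),
      PIC = pic(ps),
      PD_m = pd_male(ps),
      PD_f = pd_female(ps),
      MEC_Kruger = mec_kruger(p),
      MEC_Kishida = mec_trio_x(p, "kishida"),
      MEC_Desmarais = mec_trio_x(p, "desmarais"),
      MEC_Desmarais_Duo = mec_duo(p),
      N = fr$N[[loc]],
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Per-linkage-group forensic parameter summary
#'
#' One row per group from male haplotype frequencies: number of distinct
#' haplotypes, fraction of unique haplotypes, haplotype diversity, match
#' probability, PIC, powers of discrimination and the four mean exclusion
#' chances (haplotypes treated as alleles of a super-locus).
#'
#' @param h an `xstr_haplotypes` object (see [haplotype_frequencies]).
#' @return `data.frame`, one row per linkage group.
#' @export
forensic_summary_groups <- function(h) {
  stopifnot(inherits(h, "xstr_haplotypes"))
  rows <- lapply(names(h$groups), function(grp) {
    hg <- h$groups[[grp]]
    p <- hg$table$freq
    ps <- power_sums(p)
    data.frame(
      group = grp,
      n_haplotypes = hg$n_distinct,
      unique_fraction = singleton_fraction(h, grp),
      HD = diversity(ps, hg$n_males),
      MP = match_probability(ps),
      PIC = pic(ps),
      PD_m = pd_male(ps),
      PD_f = pd_female(ps),
      MEC_Kruger = mec_kruger(p),
      MEC_Kishida = mec_trio_x(p, "kishida"),
      MEC_Desmarais = mec_trio_x(p, "desmarais"),
      MEC_Desmarais_Duo = mec_duo(p),
      n_males = hg$n_males,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Run the complete single-population study pipeline
#'
#' Deterministic end-to-end analysis of one cohort: stratified allele
#' frequencies, male linkage-group haplotypes, female HWE exact tests,
#' pairwise LD (females, EM permutation; males, haploid exact test),
#' per-locus sex-differentiation Fst, the per-locus and per-group forensic
#' parameter tables, and combined powers. The `seed` drives every stochastic
#' stage through per-stage derived seeds, so reruns are identical.
#'
#' @param g an [xstr_genotypes] object.
#' @param groups linkage-group definitions.
#' @param hwe_cfg [mcmc_config] for the HWE chains.
#' @param female_ld_cfg [perm_config] for the female LD permutation tests.
#' @param male_ld_cfg [mcmc_config] for the male LD chains.
#' @param fst_permutations permutations for the sex-differentiation test
#'   (0 skips the Fst stage).
#' @param ld_pairs which locus pairs to test for LD: `"all"`,
#'   `"within_groups"`, or `"none"`.
#' @param alpha family-wise level for the Bonferroni flags.
#' @param seed master seed.
#' @return list of class `xstr_report`: summaries, test matrices, combined
#'   powers and the configuration echo.
#' @export
run_full_study <- function(g, groups = default_linkage_groups(),
                           hwe_cfg = mcmc_config(),
                           female_ld_cfg = perm_config(),
                           male_ld_cfg = mcmc_config(1e4, 1e3),
                           fst_permutations = 1e4,
                           ld_pairs = c("all", "within_groups", "none"),
                           alpha = 0.05, seed = 1) {
  stopifnot(inherits(g, "xstr_genotypes"))
  ld_pairs <- match.arg(ld_pairs)
  seed <- as.integer(seed)
  loci <- g$loci

  hwe <- list()
  for (i in seq_along(loci)) {
    cfg <- mcmc_config(hwe_cfg$chain_length, hwe_cfg$dememorization,
                       seed = derive_seed(seed, 131, i))
    hwe[[loci[i]]] <- hwe_exact_test(g, loci[i], cfg)
  }

  haps <- suppressMessages(haplotype_frequencies(g, groups))
  loci_summary <- forensic_summary_loci(g, hwe)
  group_summary <- forensic_summary_groups(haps)

  n_pairs <- choose(length(loci), 2)
  threshold <- bonferroni_threshold(alpha, n_pairs, digits = NULL)

  ld_f <- ld_m <- matrix(NA_real_, length(loci), length(loci),
                         dimnames = list(loci, loci))
  if (ld_pairs != "none") {
    pair_list <- combn(length(loci), 2, simplify = FALSE)
    if (ld_pairs == "within_groups") {
      pair_list <- Filter(function(ij) {
        any(vapply(groups, function(gl)
          all(loci[ij] %in% gl), logical(1)))
      }, pair_list)
    }
    for (k in seq_along(pair_list)) {
      ij <- pair_list[[k]]
      fcfg <- perm_config(female_ld_cfg$permutations,
                          female_ld_cfg$em_initial_conditions,
                          seed = derive_seed(seed, 197, k))
      mcfg <- mcmc_config(male_ld_cfg$chain_length, male_ld_cfg$dememorization,
                          seed = derive_seed(seed, 233, k))
      # upper triangle: females; lower triangle: males
      ld_f[ij[1], ij[2]] <- ld_em_permutation_test(g, loci[ij], fcfg)$p.value
      ld_m[ij[2], ij[1]] <- ld_exact_test_haploid(g, loci[ij], mcfg)$p.value
    }
  }

  fst <- NULL
  if (fst_permutations > 0) {
    fst <- do.call(rbind, lapply(seq_along(loci), function(i) {
      r <- fst_gender(g, loci[i], permutations = fst_permutations,
                      seed = derive_seed(seed, 269, i))
      data.frame(locus = loci[i], Fst = r$statistic, p = r$p.value,
                 stringsAsFactors = FALSE)
    }))
  }

  combined <- list(
    PD_m = combined_power(loci_summary$PD_m),
    PD_f = combined_power(loci_summary$PD_f),
    MEC_Kruger = combined_power(loci_summary$MEC_Kruger),
    MEC_Kishida = combined_power(loci_summary$MEC_Kishida),
    MEC_Desmarais = combined_power(loci_summary$MEC_Desmarais),
    MEC_Desmarais_Duo = combined_power(loci_summary$MEC_Desmarais_Duo),
    PD_m_haplotype = combined_power(group_summary$PD_m),
    PD_f_haplotype = combined_power(group_summary$PD_f),
    MEC_Kruger_haplotype = combined_power(group_summary$MEC_Kruger),
    MEC_Kishida_haplotype = combined_power(group_summary$MEC_Kishida),
    MEC_Desmarais_haplotype = combined_power(group_summary$MEC_Desmarais),
    MEC_Desmarais_Duo_haplotype = combined_power(group_summary$MEC_Desmarais_Duo)
  )

  structure(list(
    loci_summary = loci_summary,
    group_summary = group_summary,
    haplotypes = haps,
    frequencies = list(pooled = allele_frequencies(g, "pooled"),
                       female = allele_frequencies(g, "female"),
                       male = allele_frequencies(g, "male")),
    hwe = hwe,
    ld_female = ld_f,
    ld_male = ld_m,
    ld_bonferroni = threshold,
    n_ld_pairs = n_pairs,
    fst = fst,
    combined = combined,
    config = list(hwe_cfg = hwe_cfg, female_ld_cfg = female_ld_cfg,
                  male_ld_cfg = male_ld_cfg,
                  fst_permutations = fst_permutations, ld_pairs = ld_pairs,
                  alpha = alpha, seed = seed)
  ), class = "xstr_report")
}

#' @export
print.xstr_report <- function(x, ...) {
  cat("<xstr_report> ", nrow(x$loci_summary), " loci, ",
      nrow(x$group_summary), " linkage groups\n", sep = "")
  cat("combined PD_m: ", x$combined$PD_m$text, "\n", sep = "")
  cat("combined PD_f: ", x$combined$PD_f$text, "\n", sep = "")
  invisible(x)
}

#' Write a study report bundle to disk
#'
#' Human-readable delimited tables rounded to 4 decimals (report style,
#' half-away-from-zero) next to a machine-readable JSON bundle at full
#' precision, plus a run log echoing the configuration.
#'
#' @param report an `xstr_report` from [run_full_study].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report_bundle <- function(report, dir) {
  stopifnot(inherits(report, "xstr_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  round_df <- function(d) {
    num <- vapply(d, is.numeric, logical(1))
    d[num] <- lapply(d[num], round_half_up, digits = 4)
    d
  }
  write.table(round_df(report$loci_summary), file.path(dir, "loci_summary.tsv"),
              sep = "\t", row.names = FALSE, quote = FALSE)
  write.table(round_df(report$group_summary), file.path(dir, "group_summary.tsv"),
              sep = "\t", row.names = FALSE, quote = FALSE)
  if (!is.null(report$fst)) {
    write.table(round_df(report$fst), file.path(dir, "fst_gender.tsv"),
                sep = "\t", row.names = FALSE, quote = FALSE)
  }
  ld <- report$ld_female
  ld[lower.tri(ld)] <- report$ld_male[lower.tri(ld)]
  write.table(round_half_up(ld, 4), file.path(dir, "ld_pvalues.tsv"),
              sep = "\t", col.names = NA, quote = FALSE)
  for (st in names(report$frequencies)) {
    write_frequency_table(report$frequencies[[st]],
                          file.path(dir, paste0("freq_", st, ".tsv")))
  }
  combined_txt <- vapply(report$combined, function(x) x$text, character(1))
  writeLines(paste(names(combined_txt), combined_txt, sep = "\t"),
             file.path(dir, "combined_powers.tsv"))
  bundle <- list(
    loci_summary = report$loci_summary,
    group_summary = report$group_summary,
    fst = report$fst,
    ld_female = report$ld_female,
    ld_male = report$ld_male,
    ld_bonferroni = report$ld_bonferroni,
    combined = lapply(report$combined, function(x)
      list(value = x$value, complement = x$complement, text = x$text)),
    config = report$config
  )
  jsonlite::write_json(bundle, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, na = "null",
                       pretty = TRUE, force = TRUE)
  writeLines(c(
    paste("generated:", format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
    paste("seed:", report$config$seed),
    paste("hwe chain:", report$config$hwe_cfg$chain_length,
          "burn-in:", report$config$hwe_cfg$dememorization),
    paste("female LD permutations:", report$config$female_ld_cfg$permutations,
          "EM starts:", report$config$female_ld_cfg$em_initial_conditions),
    paste("male LD chain:", report$config$male_ld_cfg$chain_length,
          "burn-in:", report$config$male_ld_cfg$dememorization),
    paste("fst permutations:", report$config$fst_permutations),
    paste("ld pairs:", report$config$ld_pairs),
    paste("alpha:", report$config$alpha,
          "bonferroni threshold:", format(report$ld_bonferroni))
  ), file.path(dir, "run_log.txt"))
  invisible(dir)
}

#' Inter-population comparison bundle
#'
#' Nei distance matrix, covariance PCA of per-allele frequencies, classical
#' MDS of the distance matrix, and the Neighbor-Joining tree, optionally
#' restricted to a named locus subset (e.g. [argus_overlap_loci()]). With
#' fewer than three populations the ordination and tree stages are skipped
#' with a warning and the distances are still returned.
#'
#' @param tables named list of [xstr_freqs] objects (the focal population
#'   plus references).
#' @param loci optional locus subset.
#' @param components PCA components to keep (default `min(n - 1, 3)`).
#' @param dims MDS dimensions (default 2).
#' @return list of class `xstr_comparison`: `distances`, `pca`, `mds`,
#'   `tree`.
#' @export
compare_populations <- function(tables, loci = NULL, components = NULL,
                                dims = 2) {
  if (length(tables) < 2) stop("need at least two populations")
  d <- nei_distance_matrix(tables, loci)
  pca <- mds <- tree <- NULL
  if (length(tables) < 3) {
    warning("fewer than 3 populations: PCA, MDS and NJ skipped")
  } else {
    components <- components %||% min(length(tables) - 1, 3)
    pca <- pca_frequencies(tables, loci, components)
    mds <- mds_from_distances(d, dims = min(dims, length(tables) - 1))
    tree <- nj_tree(d)
  }
  structure(list(distances = d, pca = pca, mds = mds, tree = tree),
            class = "xstr_comparison")
}

#' Write an inter-population comparison bundle to disk
#'
#' @param cmp an `xstr_comparison` from [compare_populations].
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_comparison_bundle <- function(cmp, dir) {
  stopifnot(inherits(cmp, "xstr_comparison"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write.table(cmp$distances, file.path(dir, "nei_distances.tsv"),
              sep = "\t", col.names = NA, quote = FALSE)
  if (!is.null(cmp$pca)) {
    write.table(cmp$pca$scores, file.path(dir, "pca_scores.tsv"),
                sep = "\t", col.names = NA, quote = FALSE)
    writeLines(paste0("PC", seq_along(cmp$pca$pct_variance), "\t",
                      format(cmp$pca$pct_variance)),
               file.path(dir, "pca_pct_variance.tsv"))
  }
  if (!is.null(cmp$mds)) {
    write.table(cmp$mds$points, file.path(dir, "mds_coordinates.tsv"),
                sep = "\t", col.names = NA, quote = FALSE)
  }
  if (!is.null(cmp$tree)) write_newick(cmp$tree, file.path(dir, "nj_tree.nwk"))
  invisible(dir)
}

# stage-specific seed derivation kept inside 32-bit integer range
derive_seed <- function(seed, mult, i) {
  as.integer((as.numeric(seed) * mult + i) %% 2147483647)
}
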