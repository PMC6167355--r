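#' Markov-chain configuration for exact tests
#'
#' @param chain_length total chain steps (must exceed `dememorization`).
#' @param dememorization burn-in steps discarded before counting.
#' @param seed optional integer seed applied before the chain runs.
#' @return list of class `mcmc_config`.
#' @export
mcmc_config <- function(chain_length = 1e6, dememorization = 1e5, seed = NULL) {
  if (dememorization < 0 || chain_length <= dememorization) {
    stop("need chain_length > dememorization >= 0")
  }
  structure(list(chain_length = chain_length, dememorization = dememorization,
                 seed = seed), class = "mcmc_config")
}

#' Permutation-test configuration for the female LD test
#'
#' @param permutations number of permutations (>= 1).
#' @param em_initial_conditions number of EM starts per likelihood
#'   maximization (>= 1; the first start is the independence product, the
#'   rest are random).
#' @param seed optional integer seed.
#' @return list of class `perm_config`.
#' @export
perm_config <- function(permutations = 1e4, em_initial_conditions = 2,
                        seed = NULL) {
  if (permutations < 1 || em_initial_conditions < 1) {
    stop("permutations and em_initial_conditions must be >= 1")
  }
  structure(list(permutations = permutations,
                 em_initial_conditions = em_initial_conditions, seed = seed),
            class = "perm_config")
}

xstr_test <- function(statistic, p, draws, method) {
  structure(list(statistic = statistic, p.value = p,
                 se = if (is.finite(draws) && draws > 0)
                   sqrt(p * (1 - p) / draws) else NA_real_,
                 draws = draws, method = method),
            class = "xstr_test")
}

#' @export
print.xstr_test <- function(x, ...) {
  cat(x$method, ": p = ", format(x$p.value, digits = 4),
      " (MC s.e. ", format(x$se, digits = 3), ", ", x$draws, " draws)\n",
      sep = "")
  invisible(x)
}

#' Hardy-Weinberg exact test in females (Markov-chain)
#'
#' Exact conditional test of Hardy-Weinberg proportions for multi-allelic
#' loci, in the Guo-Thompson tradition: a Markov chain over genotype
#' configurations with fixed allele margins (two-individual allele-swap
#' proposals; the conditional-probability ratio of each proposal is one, so
#' every swap is accepted and the stationary law is the conditional null).
#' The p-value is the fraction of post-burn-in states whose conditional
#' probability does not exceed the observed table's.
#'
#' @param g an [xstr_genotypes] object, or a symmetric genotype count matrix
#'   (females only).
#' @param locus locus name (when `g` is a genotype table).
#' @param cfg an [mcmc_config].
#' @return an `xstr_test` (statistic = observed log conditional probability,
#'   up to an additive constant).
#' @export
hwe_exact_test <- function(g, locus = NULL, cfg = mcmc_config()) {
  stopifnot(inherits(cfg, "mcmc_config"))
  if (inherits(g, "xstr_genotypes")) {
    if (is.null(locus)) stop("locus required with a genotype table")
    m <- g$calls[[locus]][g$sex == "female", , drop = FALSE]
    m <- m[!is.na(m[, 1]), , drop = FALSE]
    if (nrow(m) == 0) stop("no typed females at ", locus)
    alleles <- sort(unique(c(m[, 1], m[, 2])))
    a1 <- match(m[, 1], alleles) - 1L
    a2 <- match(m[, 2], alleles) - 1L
  } else if (is.matrix(g)) {
    if (nrow(g) != ncol(g)) stop("genotype count matrix must be square")
    pairs <- genotype_pairs_from_counts(g)
    a1 <- pairs[, 1]
    a2 <- pairs[, 2]
    alleles <- seq_len(nrow(g))
  } else {
    stop("g must be a genotype table or a genotype count matrix")
  }
  k <- length(alleles)
  if (k < 2) {
    return(xstr_test(0, 1, Inf, "monomorphic"))
  }
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  res <- cpp_hwe_chain(a1, a2, k, cfg$chain_length, cfg$dememorization)
  xstr_test(res$logp_obs, res$p, res$draws, "hwe_mcmc")
}

# expand an upper/full symmetric genotype count matrix into (a1, a2) rows
genotype_pairs_from_counts <- function(cnt) {
  k <- nrow(cnt)
  out <- NULL
  for (a in 1:k) for (b in a:k) {
    n_ab <- if (a == b) cnt[a, b] else {
      if (cnt[a, b] > 0 && cnt[b, a] > 0 && cnt[a, b] != cnt[b, a])
        stop("inconsistent symmetric counts")
      max(cnt[a, b], cnt[b, a])
    }
    if (n_ab > 0) out <- rbind(out, matrix(c(a - 1L, b - 1L), n_ab, 2, byrow = TRUE))
  }
  if (is.null(out)) stop("empty genotype count matrix")
  out
}

#' Haploid exact test of linkage disequilibrium in males
#'
#' Male genotypes are phased haplotypes, so pairwise LD reduces to an exact
#' test of independence on the allele-A x allele-B contingency table: a
#' Markov chain over tables with fixed margins (allele-swap proposals between
#' two males), p = fraction of visited tables with conditional probability
#' \eqn{\le} the observed one.
#'
#' @param g an [xstr_genotypes] object, or a contingency table (matrix of
#'   male haplotype counts, rows = alleles at locus A).
#' @param loci character vector of the two locus names (genotype-table input).
#' @param cfg an [mcmc_config].
#' @return an `xstr_test`.
#' @export
ld_exact_test_haploid <- function(g, loci = NULL, cfg = mcmc_config()) {
  stopifnot(inherits(cfg, "mcmc_config"))
  if (inherits(g, "xstr_genotypes")) {
    if (length(loci) != 2) stop("loci must name two loci")
    male <- g$sex == "male"
    a <- g$calls[[loci[1]]][male, 1]
    b <- g$calls[[loci[2]]][male, 1]
    keep <- !is.na(a) & !is.na(b)
    a <- a[keep]
    b <- b[keep]
  } else if (is.matrix(g)) {
    idx <- which(g > 0, arr.ind = TRUE)
    a <- rep(idx[, 1], g[idx])
    b <- rep(idx[, 2], g[idx])
  } else {
    stop("g must be a genotype table or a contingency table")
  }
  fa <- factor(a)
  fb <- factor(b)
  if (nlevels(fa) < 2 || nlevels(fb) < 2 || length(a) == 0) {
    return(xstr_test(0, 1, Inf, "degenerate"))
  }
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  res <- cpp_haploid_chain(as.integer(fa) - 1L, as.integer(fb) - 1L,
                           nlevels(fa), nlevels(fb),
                           cfg$chain_length, cfg$dememorization)
  xstr_test(res$logp_obs, res$p, res$draws, "ld_haploid_mcmc")
}

#' Bonferroni-corrected per-test threshold
#'
#' @param alpha family-wise level in (0, 1).
#' @param m number of tests (>= 1).
#' @param digits rounding applied for reporting (default 4 decimals; use
#'   `NULL` for the raw threshold).
#' @return per-test significance threshold `alpha / m`.
#' @export
bonferroni_threshold <- function(alpha, m, digits = 4) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  if (m < 1) stop("m must be >= 1")
  th <- alpha / m
  if (is.null(digits)) th else round_half_up(th, digits)
}

#' Allele-frequency Fst between two strata
#'
#' `Fst = (H_T - H_S) / H_T` with `H = 1 - sum(p^2)`; `H_S` is the
#' chromosome-count-weighted mean of the stratum heterozygosities and `H_T`
#' uses the pooled frequencies. Monomorphic pooled data give `Fst = 0`.
#'
#' @param counts_a,counts_b named numeric vectors of allele counts in the two
#'   strata (names = allele labels).
#' @return Fst (can be slightly negative only through the weighting; here
#'   bounded in \[0, 1\] since `H_T >= H_S` for two strata at one locus).
#' @export
fst_statistic <- function(counts_a, counts_b) {
  alleles <- union(names(counts_a), names(counts_b))
  ca <- setNames(numeric(length(alleles)), alleles)
  cb <- ca
  ca[names(counts_a)] <- counts_a
  cb[names(counts_b)] <- counts_b
  na <- sum(ca)
  nb <- sum(cb)
  if (na == 0 || nb == 0) stop("a stratum has no observations")
  ha <- 1 - sum((ca / na)^2)
  hb <- 1 - sum((cb / nb)^2)
  hs <- (na * ha + nb * hb) / (na + nb)
  pbar <- (ca + cb) / (na + nb)
  ht <- 1 - sum(pbar^2)
  if (ht == 0) return(0)
  (ht - hs) / ht
}

#' Male/female differentiation test at one locus
#'
#' Permutation test of sex differentiation: the observed allele-frequency
#' Fst between male and female chromosomes is compared against the Fst
#' distribution under random reassignment of chromosomes to the two strata
#' (stratum chromosome counts preserved). p = fraction of permutations with
#' `Fst >= observed`.
#'
#' @param g an [xstr_genotypes] object.
#' @param locus locus name.
#' @param permutations number of permutations.
#' @param seed optional integer seed.
#' @return an `xstr_test` (statistic = observed Fst).
#' @export
fst_gender <- function(g, locus, permutations = 1e4, seed = NULL) {
  stopifnot(inherits(g, "xstr_genotypes"))
  m <- g$calls[[locus]]
  female <- g$sex == "female"
  chrom_f <- c(m[female, 1], m[female, 2])
  chrom_f <- chrom_f[!is.na(chrom_f)]
  chrom_m <- m[!female, 1]
  chrom_m <- chrom_m[!is.na(chrom_m)]
  if (length(chrom_f) == 0 || length(chrom_m) == 0) {
    stop("both sexes must be typed at ", locus)
  }
  obs <- fst_statistic(table_counts(chrom_m), table_counts(chrom_f))
  pool <- c(chrom_m, chrom_f)
  if (length(unique(pool)) < 2) {
    return(xstr_test(0, 1, Inf, "monomorphic"))
  }
  nm <- length(chrom_m)
  if (!is.null(seed)) set.seed(seed)
  hits <- 0L
  for (i in seq_len(permutations)) {
    idx <- sample.int(length(pool), nm)
    f <- fst_statistic(table_counts(pool[idx]), table_counts(pool[-idx]))
    if (f >= obs - 1e-12) hits <- hits + 1L
  }
  xstr_test(obs, hits / permutations, permutations, "fst_permutation")
}

table_counts <- function(x) {
  tb <- table(x)
  setNames(as.numeric(tb), names(tb))
}
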