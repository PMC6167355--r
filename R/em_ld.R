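#' EM estimate of two-locus haplotype frequencies from unphased diploids
#'
#' Maximum-likelihood haplotype frequencies for a pair of loci from female
#' (diploid, unphased) genotypes under random union of gametes. Only double
#' heterozygotes are phase-ambiguous; the E step splits them between the two
#' resolutions in proportion to the current haplotype frequencies. The best
#' of `n_starts` initializations is returned (the first start is the
#' independence product of allele frequencies, the rest are random).
#'
#' @param ga,gb `n x 2` matrices of allele labels at the two loci (rows =
#'   individuals; no missing values).
#' @param n_starts number of EM initializations.
#' @param tol convergence threshold on the log-likelihood gain.
#' @param max_iter iteration cap per start.
#' @return list: `haplotypes` (matrix of frequencies, rows = alleles at locus
#'   A), `loglik`, `iterations`, `converged`.
#' @export
em_haplotype_frequencies <- function(ga, gb, n_starts = 2, tol = 1e-7,
                                     max_iter = 1000) {
  cls <- genotype_pair_classes(ga, gb)
  ka <- cls$ka
  kb <- cls$kb
  best <- NULL
  for (s in seq_len(n_starts)) {
    h <- if (s == 1) outer(cls$pa, cls$pb) else {
      w <- matrix(rgamma(ka * kb, 1), ka, kb)
      w / sum(w)
    }
    ll_old <- -Inf
    converged <- FALSE
    for (it in seq_len(max_iter)) {
      stepres <- em_step(h, cls)
      h <- stepres$h
      if (stepres$ll - ll_old < tol && it > 1) {
        converged <- TRUE
        break
      }
      ll_old <- stepres$ll
    }
    ll <- class_loglik(h, cls)
    if (is.null(best) || ll > best$loglik) {
      best <- list(haplotypes = h, loglik = ll, iterations = it,
                   converged = converged)
    }
  }
  dimnames(best$haplotypes) <- list(cls$alleles_a, cls$alleles_b)
  best
}

# aggregate individuals into distinct two-locus genotype classes
genotype_pair_classes <- function(ga, gb) {
  stopifnot(nrow(ga) == nrow(gb))
  if (anyNA(ga) || anyNA(gb)) stop("missing calls not allowed here")
  alleles_a <- sort(unique(c(ga)))
  alleles_b <- sort(unique(c(gb)))
  ia <- matrix(match(ga, alleles_a), ncol = 2)
  ib <- matrix(match(gb, alleles_b), ncol = 2)
  ia <- cbind(pmin(ia[, 1], ia[, 2]), pmax(ia[, 1], ia[, 2]))
  ib <- cbind(pmin(ib[, 1], ib[, 2]), pmax(ib[, 1], ib[, 2]))
  key <- paste(ia[, 1], ia[, 2], ib[, 1], ib[, 2])
  tb <- table(key)
  first <- match(names(tb), key)
  ka <- length(alleles_a)
  kb <- length(alleles_b)
  n <- nrow(ia)
  pa <- as.numeric(table(factor(c(ia), levels = 1:ka))) / (2 * n)
  pb <- as.numeric(table(factor(c(ib), levels = 1:kb))) / (2 * n)
  list(a1 = ia[first, 1], a2 = ia[first, 2], b1 = ib[first, 1],
       b2 = ib[first, 2], w = as.numeric(tb), n = n,
       ka = ka, kb = kb, pa = pa, pb = pb,
       alleles_a = alleles_a, alleles_b = alleles_b)
}

# per-class likelihood pieces: cell indices of the two phase resolutions
class_probs <- function(h, cls) {
  # resolution 1: (a1,b1)+(a2,b2); resolution 2: (a1,b2)+(a2,b1)
  h11 <- h[cbind(cls$a1, cls$b1)]
  h22 <- h[cbind(cls$a2, cls$b2)]
  h12 <- h[cbind(cls$a1, cls$b2)]
  h21 <- h[cbind(cls$a2, cls$b1)]
  het_a <- cls$a1 != cls$a2
  het_b <- cls$b1 != cls$b2
  dh <- het_a & het_b
  # unordered genotype probability: 2*h*h' per resolution with distinct
  # haplotypes, h^2 when both haplotypes coincide
  p1 <- ifelse(het_a | het_b, 2 * h11 * h22, h11 * h22)
  p2 <- ifelse(dh, 2 * h12 * h21, 0)
  list(p1 = p1, p2 = p2, dh = dh)
}

class_loglik <- function(h, cls) {
  cp <- class_probs(h, cls)
  sum(cls$w * log(pmax(cp$p1 + cp$p2, 1e-300)))
}

em_step <- function(h, cls) {
  cp <- class_probs(h, cls)
  tot <- pmax(cp$p1 + cp$p2, 1e-300)
  w1 <- cls$w * cp$p1 / tot
  w2 <- cls$w * cp$p2 / tot
  newh <- matrix(0, nrow(h), ncol(h))
  acc <- function(m, i, j, w) {
    for (cell in which(w > 0)) {
      m[i[cell], j[cell]] <- m[i[cell], j[cell]] + w[cell]
    }
    m
  }
  newh <- acc(newh, cls$a1, cls$b1, w1)
  newh <- acc(newh, cls$a2, cls$b2, w1)
  newh <- acc(newh, cls$a1, cls$b2, w2)
  newh <- acc(newh, cls$a2, cls$b1, w2)
  list(h = newh / (2 * cls$n), ll = sum(cls$w * log(tot)))
}

#' EM-based permutation test of linkage disequilibrium in females
#'
#' Likelihood-ratio test of gametic association between two loci from
#' unphased female genotypes. The statistic compares the EM-maximized
#' two-locus haplotype likelihood against the independence model (product of
#' single-locus allele frequencies). The null distribution is generated by
#' permuting one locus's genotype column across individuals (whole
#' single-locus genotypes move together, preserving within-locus structure);
#' p = fraction of permuted statistics `>=` the observed one.
#'
#' @param g an [xstr_genotypes] object (females used), or a list
#'   `list(ga, gb)` of two `n x 2` matrices.
#' @param loci the two locus names (genotype-table input).
#' @param cfg a [perm_config].
#' @return an `xstr_test` (statistic = likelihood-ratio statistic
#'   `2 * (LL_EM - LL_independence)`).
#' @export
ld_em_permutation_test <- function(g, loci = NULL, cfg = perm_config()) {
  stopifnot(inherits(cfg, "perm_config"))
  if (inherits(g, "xstr_genotypes")) {
    if (length(loci) != 2) stop("loci must name two loci")
    female <- g$sex == "female"
    ga <- g$calls[[loci[1]]][female, , drop = FALSE]
    gb <- g$calls[[loci[2]]][female, , drop = FALSE]
    keep <- !is.na(ga[, 1]) & !is.na(gb[, 1])
    ga <- ga[keep, , drop = FALSE]
    gb <- gb[keep, , drop = FALSE]
  } else if (is.list(g) && length(g) == 2) {
    ga <- g[[1]]
    gb <- g[[2]]
  } else {
    stop("g must be a genotype table or list(ga, gb)")
  }
  n <- nrow(ga)
  if (n < 2) stop("need >= 2 females typed at both loci")
  if (length(unique(c(ga))) < 2 || length(unique(c(gb))) < 2) {
    return(xstr_test(0, 1, Inf, "degenerate"))
  }
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  stat <- ld_lrt_statistic(ga, gb, cfg$em_initial_conditions)
  hits <- 0L
  for (i in seq_len(cfg$permutations)) {
    perm <- sample.int(n)
    s <- ld_lrt_statistic(ga, gb[perm, , drop = FALSE],
                          cfg$em_initial_conditions)
    if (s >= stat - 1e-9) hits <- hits + 1L
  }
  xstr_test(stat, hits / cfg$permutations, cfg$permutations, "ld_em_permutation")
}

ld_lrt_statistic <- function(ga, gb, n_starts) {
  cls <- genotype_pair_classes(ga, gb)
  fit <- em_haplotype_frequencies(ga, gb, n_starts = n_starts)
  ll0 <- class_loglik(outer(cls$pa, cls$pb), cls)
  max(0, 2 * (fit$loglik - ll0))
}
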