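# Independent brute-force oracles: every formula-level claim in the package
# is checked against exhaustive enumeration over genotype configurations.
# These deliberately avoid the package's closed forms.

# all frequency vectors with <= kmax alleles on a `step` grid (multisets of
# positive multiples of `step` summing to 1)
grid_frequency_vectors <- function(kmax = 5, step = 0.05) {
  units <- round(1 / step)
  out <- list()
  recurse <- function(prefix, remaining, max_unit) {
    if (length(prefix) == kmax || remaining == 0) {
      if (remaining == 0 && length(prefix) > 0) out[[length(out) + 1]] <<- prefix
      return()
    }
    for (u in seq_len(min(remaining, max_unit))) {
      recurse(c(prefix, u), remaining - u, u)
    }
    if (remaining > 0 && length(prefix) > 0 && remaining <= min(prefix)) {
      # handled by loop above; nothing extra
    }
  }
  recurse(integer(0), units, units)
  lapply(out, function(u) u * step)
}

# trio exclusion with an untyped diploid relative (grandmother-style):
# enumerate mother genotype x paternal allele x segregation; the random
# woman is excluded when neither of her two alleles fits the obligate set
oracle_mec_kruger <- function(p) {
  k <- length(p)
  excl <- 0
  for (m1 in 1:k) for (m2 in 1:k) for (f in 1:k) {
    w <- p[m1] * p[m2] * p[f]  # m1 is the transmitted maternal allele
    s <- p[f]
    if (f != m1 && f == m2) s <- s + p[m1]  # obligate paternal allele ambiguous
    excl <- excl + w * (1 - s)^2
  }
  excl
}

# X trio with a daughter: random alleged father contributes one allele
oracle_mec_trio <- function(p) {
  k <- length(p)
  excl <- 0
  for (m1 in 1:k) for (m2 in 1:k) for (f in 1:k) {
    w <- p[m1] * p[m2] * p[f]
    s <- p[f]
    if (f != m1 && f == m2) s <- s + p[m1]
    excl <- excl + w * (1 - s)
  }
  excl
}

# father/daughter duo: daughter genotype only; any allele she carries fits
oracle_mec_duo <- function(p) {
  k <- length(p)
  excl <- 0
  for (c1 in 1:k) for (c2 in 1:k) {
    s <- if (c1 == c2) p[c1] else p[c1] + p[c2]
    excl <- excl + p[c1] * p[c2] * (1 - s)
  }
  excl
}

# probability two random HWE female genotypes differ: enumerate unordered
# genotypes explicitly
oracle_pd_female <- function(p) {
  k <- length(p)
  match_prob <- 0
  for (a in 1:k) for (b in a:k) {
    gp <- if (a == b) p[a]^2 else 2 * p[a] * p[b]
    match_prob <- match_prob + gp^2
  }
  1 - match_prob
}

# PIC by its defining double sum, not the power-sum polynomial
oracle_pic <- function(p) {
  k <- length(p)
  cross <- 0
  for (i in 1:k) for (j in 1:k) if (i != j) cross <- cross + p[i]^2 * p[j]^2
  1 - sum(p^2) - cross
}

# exact conditional p-value of the biallelic HWE test: enumerate every
# genotype table compatible with the allele margins
oracle_hwe_biallelic <- function(nAA, nAB, nBB) {
  n <- nAA + nAB + nBB
  nA <- 2 * nAA + nAB
  logprob <- function(ab) {
    aa <- (nA - ab) / 2
    bb <- n - aa - ab
    if (ab %% 2 != nA %% 2 || aa < 0 || bb < 0) return(-Inf)
    ab * log(2) - lfactorial(aa) - lfactorial(ab) - lfactorial(bb)
  }
  abs <- seq(nA %% 2, min(nA, 2 * n - nA), by = 2)
  lp <- vapply(abs, logprob, numeric(1))
  keep <- is.finite(lp)
  lp <- lp[keep]
  pr <- exp(lp - max(lp))
  pr <- pr / sum(pr)
  obs <- lp[match(nAB, abs[keep])]
  sum(pr[lp <= obs + 1e-9])
}

# i.i.d. sampler from the conditional HWE null: shuffle the 2n alleles and
# pair consecutive entries; independent of the package's Markov chain
oracle_hwe_shuffle_p <- function(a1, a2, n_draws = 2000) {
  alleles <- c(a1, a2)
  n <- length(a1)
  tab_logprob <- function(x1, x2) {
    key <- paste(pmin(x1, x2), pmax(x1, x2))
    cnt <- table(key)
    het <- sum(cnt[vapply(strsplit(names(cnt), " "),
                          function(z) z[1] != z[2], logical(1))])
    het * log(2) - sum(lfactorial(cnt))
  }
  obs <- tab_logprob(a1, a2)
  hits <- 0
  for (i in seq_len(n_draws)) {
    s <- sample(alleles)
    if (tab_logprob(s[1:n], s[(n + 1):(2 * n)]) <= obs + 1e-9) hits <- hits + 1
  }
  hits / n_draws
}

# Weir-style moment estimator of Fst across population frequency tables
estimate_fst_across_pops <- function(pops) {
  num <- den <- 0
  loci <- pops[[1]]$loci
  for (loc in loci) {
    alleles <- unique(unlist(lapply(pops, function(t) t$tab[[loc]]$allele)))
    pm <- sapply(pops, function(t) {
      v <- setNames(numeric(length(alleles)), alleles)
      v[t$tab[[loc]]$allele] <- t$tab[[loc]]$freq
      v
    })
    pbar <- rowMeans(pm)
    v <- apply(pm, 1, var)
    num <- num + sum(v)
    den <- den + sum(pbar * (1 - pbar))
  }
  num / den
}
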