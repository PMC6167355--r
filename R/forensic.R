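#' Power sums of a frequency vector
#'
#' The three partial power sums `s2 = sum(p^2)`, `s3 = sum(p^3)`,
#' `s4 = sum(p^4)` that every forensic parameter of the suite is built from.
#' Summation is done in descending-frequency order so results are
#' deterministic regardless of input ordering.
#'
#' @param p numeric vector of positive frequencies summing to 1 (within 1e-9).
#' @return object of class `xstr_power_sums`: list with `s2`, `s3`, `s4`, `k`.
#' @export
power_sums <- function(p) {
  if (length(p) == 0) stop("empty frequency vector")
  p <- as.numeric(p)
  if (any(p <= 0)) stop("frequencies must be positive")
  if (abs(sum(p) - 1) > 1e-9) stop("frequencies sum to ", sum(p), ", not 1")
  p <- sort(p, decreasing = TRUE)
  structure(list(s2 = sum(p^2), s3 = sum(p^3), s4 = sum(p^4),
                 k = length(p)),
            class = "xstr_power_sums")
}

as_power_sums <- function(x) {
  if (inherits(x, "xstr_power_sums")) return(x)
  if (is.numeric(x) && length(x) >= 1) return(power_sums(x))
  stop("expected a frequency vector or an xstr_power_sums object")
}

#' Gene or haplotype diversity (bias-corrected)
#'
#' `GD/HD = N/(N-1) * (1 - sum(p^2))`, the sample-size-corrected probability
#' that two randomly drawn chromosomes differ.
#'
#' @param ps an `xstr_power_sums` object, a frequency vector, or a bare match
#'   probability (`sum(p^2)`) as a length-1 numeric.
#' @param N number of chromosomes observed (>= 2).
#' @return diversity in \[0, 1\].
#' @export
diversity <- function(ps, N) {
  if (!is.numeric(N) || length(N) != 1 || is.na(N) || N < 2) {
    stop("N must be a single number >= 2")
  }
  s2 <- if (is.numeric(ps) && length(ps) == 1) ps else as_power_sums(ps)$s2
  N / (N - 1) * (1 - s2)
}

#' Match probability
#'
#' `MP = sum(p^2)`: the probability that two random chromosomes (or male
#' haplotypes) carry the same allele.
#'
#' @inheritParams diversity
#' @return match probability in \[0, 1\].
#' @export
match_probability <- function(ps) as_power_sums(ps)$s2

#' Power of discrimination in males
#'
#' `PD_m = 1 - MP`: males are hemizygous, so discrimination acts on single
#' chromosomes.
#'
#' @inheritParams diversity
#' @return probability in \[0, 1\].
#' @export
pd_male <- function(ps) 1 - as_power_sums(ps)$s2

#' Power of discrimination in females
#'
#' `PD_f = 1 - 2*s2^2 + s4`: the probability that two random diploid
#' genotypes drawn under Hardy-Weinberg proportions differ.
#'
#' @inheritParams diversity
#' @return probability in \[0, 1\].
#' @export
pd_female <- function(ps) {
  ps <- as_power_sums(ps)
  1 - 2 * ps$s2^2 + ps$s4
}

#' Polymorphism information content
#'
#' `PIC = 1 - s2 - s2^2 + s4`.
#'
#' @inheritParams diversity
#' @return probability in \[0, 1\].
#' @export
pic <- function(ps) {
  ps <- as_power_sums(ps)
  1 - ps$s2 - ps$s2^2 + ps$s4
}

#' Mean exclusion chance, Krueger variant
#'
#' Exclusion power for trio-style casework where the tested relative is an
#' untyped diploid woman (classically the paternal grandmother in X-marker
#' deficiency cases; identical in form to the autosomal trio MEC):
#' `sum(p*(1-p)^2) - sum_{i<j} (p_i p_j)^2 * (4 - 3*(p_i + p_j))`.
#'
#' @param p numeric frequency vector (positive, sums to 1).
#' @return exclusion probability in \[0, 1\].
#' @export
mec_kruger <- function(p) {
  ps <- power_sums(p)  # validates
  s1 <- sum(p * (1 - p)^2)
  pp <- outer(p, p)
  sums <- outer(p, p, "+")
  cross <- pp^2 * (4 - 3 * sums)
  s1 - sum(cross[upper.tri(cross)])
}

#' Mean exclusion chance for X-marker trios with a daughter
#'
#' Exclusion power against a random non-father in mother/daughter/alleged
#' father trios typed with X markers.
#' \itemize{
#'   \item `variant = "desmarais"`: the closed form `1 - s2 - s2^2 + s4`,
#'     identical to [pic()].
#'   \item `variant = "kishida"`: the exact exclusion chance obtained by
#'     enumerating every configuration (mother genotype x true-father allele
#'     x maternal segregation x alleged-father allele) and accounting for
#'     ambiguity of the obligate paternal allele. Published values of this
#'     variant differ from the Desmarais closed form by at most a few 1e-4.
#' }
#'
#' @param p numeric frequency vector (positive, sums to 1).
#' @param variant `"desmarais"` or `"kishida"`.
#' @return exclusion probability in \[0, 1\].
#' @export
mec_trio_x <- function(p, variant = c("desmarais", "kishida")) {
  variant <- match.arg(variant)
  if (variant == "desmarais") return(pic(power_sums(p)))
  power_sums(p)  # validation only
  k <- length(p)
  excl <- 0
  # ordered mother (m1, m2); m1 is the transmitted allele (symmetry covers
  # the other segregation). Paternal allele f; obligate-paternal set is {f},
  # plus {m1} when the daughter is het and f also matches the mother.
  for (m1 in seq_len(k)) {
    for (m2 in seq_len(k)) {
      w <- p[m1] * p[m2]
      ambiguous <- p * 0
      ambiguous[m2] <- if (m2 != m1) p[m1] else 0
      excl <- excl + w * sum(p * (1 - p - ambiguous))
    }
  }
  excl
}

#' Mean exclusion chance for duos (Desmarais duo variant)
#'
#' Father/daughter or mother/son duos: `1 - 2*s2 + s3`.
#'
#' @param p numeric frequency vector (positive, sums to 1).
#' @return exclusion probability in \[0, 1\].
#' @export
mec_duo <- function(p) {
  ps <- power_sums(p)
  1 - 2 * ps$s2 + ps$s3
}

#' Observed and expected heterozygosity in females
#'
#' `Ho` is the fraction of heterozygous typed females; `He` is the unbiased
#' expected heterozygosity `(2n/(2n-1)) * (1 - sum(p^2))` computed from
#' female-only allele frequencies (`n` = typed females).
#'
#' @param g an [xstr_genotypes] object.
#' @param locus locus name.
#' @return named numeric vector `c(Ho =, He =)`.
#' @export
observed_expected_het <- function(g, locus) {
  stopifnot(inherits(g, "xstr_genotypes"))
  if (!locus %in% g$loci) stop("unknown locus: ", locus)
  m <- g$calls[[locus]][g$sex == "female", , drop = FALSE]
  m <- m[!is.na(m[, 1]), , drop = FALSE]
  n <- nrow(m)
  if (n < 2) stop("need >= 2 typed females at ", locus)
  ho <- mean(m[, 1] != m[, 2])
  p <- as.numeric(table(c(m[, 1], m[, 2]))) / (2 * n)
  he <- (2 * n / (2 * n - 1)) * (1 - sum(p^2))
  c(Ho = ho, He = he)
}

#' Combine per-unit powers across loci or linkage groups
#'
#' `1 - prod(1 - x)`, accumulated in log space so that combined values
#' indistinguishable from 1 in double precision are still reportable: the
#' result carries the complement `prod(1 - x)` and a decimal text rendering
#' with as many leading nines as the complement's magnitude implies.
#'
#' @param values numeric vector of per-unit probabilities in \[0, 1\].
#' @param digits significant digits of the complement kept in the text
#'   rendering (default 6).
#' @return object of class `xstr_combined_power`: list with `value` (double,
#'   may round to 1), `complement`, `log10_complement` and `text`.
#' @export
combined_power <- function(values, digits = 6) {
  if (length(values) == 0) stop("empty value list")
  if (any(values < 0 | values > 1)) stop("values must lie in [0, 1]")
  if (any(values == 1)) {
    lc <- -Inf
  } else {
    lc <- sum(log10(1 - values))
  }
  comp <- 10^lc
  structure(list(value = 1 - comp, complement = comp, log10_complement = lc,
                 text = nines_text(lc, digits)),
            class = "xstr_combined_power")
}

# decimal rendering of 1 - 10^lc with explicit nines, e.g. lc = log10(2.905e-12)
# -> "0.999999999997095"
nines_text <- function(lc, digits = 6) {
  if (!is.finite(lc)) return("1")
  if (lc >= 0) return("0")
  e <- floor(lc)
  mant <- 10^(lc - e)              # in [1, 10)
  M <- round(mant * 10^(digits - 1))
  if (M >= 10^digits) {            # carry, e.g. 9.9999995 -> 10
    M <- M / 10
    e <- e + 1
  }
  E <- (digits - 1) - e            # complement ~ M * 10^-E, E >= digits
  if (E <= digits) {               # complement >= 10^-digits: plain format
    return(format(1 - M * 10^(-E), digits = 15))
  }
  tail_num <- 10^digits - M
  paste0("0.", strrep("9", E - digits),
         formatC(tail_num, width = digits, flag = "0", format = "d"))
}

#' @export
print.xstr_combined_power <- function(x, ...) {
  cat("combined power:", x$text, "\n")
  invisible(x)
}

#' @export
format.xstr_combined_power <- function(x, ...) x$text
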