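# small in-code fixtures shared across test files

# genotype table from compact strings: list(locus = c("15/16", "15", NA, ...))
make_genotypes <- function(sex, calls) {
  n <- length(sex)
  mats <- lapply(calls, function(x) {
    parts <- strsplit(ifelse(is.na(x), "", x), "/", fixed = TRUE)
    cbind(vapply(parts, function(p) if (length(p) >= 1) p[1] else NA_character_,
                 character(1)),
          vapply(parts, function(p) if (length(p) >= 2) p[2] else NA_character_,
                 character(1)))
  })
  xstr_genotypes(sprintf("S%03d", seq_len(n)), sex, mats, names(calls))
}

# frequency table object from a named list of named numeric vectors
make_freqs <- function(loci, N = NULL) {
  tab <- lapply(loci, function(p) {
    data.frame(allele = names(p), count = NA_real_, freq = as.numeric(p),
               stringsAsFactors = FALSE)
  })
  Nv <- setNames(rep(NA_real_, length(loci)), names(loci))
  if (!is.null(N)) Nv[names(N)] <- N
  xstr_freqs(tab, Nv)
}

# a small random cohort with independent loci, for round-trip properties
small_cohort <- function(seed = 1, n_f = 30, n_m = 20) {
  loci <- list(
    DXS8378 = setNames(c(0.4, 0.3, 0.2, 0.1), c("10", "11", "12", "12.1")),
    DXS7423 = setNames(c(0.5, 0.3, 0.2), c("14", "15", "16")),
    HPRTB   = setNames(c(0.6, 0.25, 0.15), c("12", "13", "14"))
  )
  simulate_genotypes(synthetic_spec(n_f, n_m, loci, seed = seed))
}
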