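#' Specification for synthetic X-STR data
#'
#' Describes a simulated study cohort: numbers of diploid females and
#' hemizygous males, per-locus allele-frequency vectors, optional per-locus
#' inbreeding (females drift toward homozygosity: the second gamete is
#' identical by descent with probability `F`), optional linkage groups with
#' explicit haplotype-frequency tables (male haplotypes and female gametes
#' are then drawn jointly, haplotype-level random union), and optional
#' multi-population Balding-Nichols divergence.
#'
#' @param n_females,n_males sample sizes.
#' @param loci named list of named numeric vectors: per-locus allele
#'   frequencies (names are STR allele labels such as `"15"`, `"24.1"`).
#' @param F_inbreeding per-locus inbreeding coefficient in \[0, 1\]; scalar
#'   recycled over loci.
#' @param linkage_groups optional named list; each element is a list with
#'   `loci` (ordered names) and `haplotypes` (`data.frame` with one column
#'   per locus plus `freq`).
#' @param n_populations,fst_divergence optional multi-population settings for
#'   [simulate_divergent_populations].
#' @param seed integer seed making every draw reproducible.
#' @return list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_females, n_males, loci, F_inbreeding = 0,
                           linkage_groups = NULL, n_populations = NULL,
                           fst_divergence = NULL, seed = 1) {
  if (n_females < 0 || n_males < 0) stop("counts must be >= 0")
  if (is.null(names(loci)) || anyDuplicated(names(loci))) {
    stop("loci must be a uniquely named list")
  }
  for (loc in names(loci)) {
    p <- loci[[loc]]
    if (is.null(names(p)) || any(p <= 0) || abs(sum(p) - 1) > 1e-9) {
      stop("locus ", loc, " needs named positive frequencies summing to 1")
    }
    bad <- !grepl(.allele_pattern, names(p))
    if (any(bad)) stop("bad allele label at ", loc, ": ",
                       paste(names(p)[bad], collapse = ", "))
  }
  Fv <- rep_len(F_inbreeding, length(loci))
  names(Fv) <- names(loci)
  if (any(Fv < 0 | Fv > 1)) stop("F_inbreeding must lie in [0, 1]")
  if (!is.null(linkage_groups)) {
    validate_linkage_groups(lapply(linkage_groups, `[[`, "loci"))
    for (grp in names(linkage_groups)) {
      lg <- linkage_groups[[grp]]
      if (!all(lg$loci %in% names(loci))) {
        stop("group ", grp, " references loci without frequency vectors")
      }
      h <- lg$haplotypes
      if (!is.null(h)) {
        stopifnot(all(c(lg$loci, "freq") %in% names(h)))
        if (abs(sum(h$freq) - 1) > 1e-9 || any(h$freq <= 0)) {
          stop("haplotype frequencies of ", grp, " must be positive and sum to 1")
        }
      }
    }
  }
  structure(list(n_females = n_females, n_males = n_males, loci = loci,
                 F_inbreeding = Fv, linkage_groups = linkage_groups,
                 n_populations = n_populations,
                 fst_divergence = fst_divergence, seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Simulate an X-STR genotype table
#'
#' Females draw two gametes per locus (the second identical by descent with
#' probability `F`, otherwise independent); males draw one. Loci belonging to
#' a linkage group with an explicit haplotype table are drawn jointly from
#' that table: one haplotype per male, two independent haplotypes per female
#' (random union, i.e. Hardy-Weinberg at the haplotype level). The generating
#' parameters are attached as the `truth` attribute.
#'
#' @param spec a [synthetic_spec].
#' @return an [xstr_genotypes] with attribute `truth`.
#' @export
simulate_genotypes <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  nf <- spec$n_females
  nm <- spec$n_males
  n <- nf + nm
  sex <- c(rep("female", nf), rep("male", nm))
  ids <- sprintf("S%04d", seq_len(n))
  calls <- lapply(spec$loci, function(p) matrix(NA_character_, n, 2))
  grouped <- character(0)
  for (grp in names(spec$linkage_groups)) {
    lg <- spec$linkage_groups[[grp]]
    if (is.null(lg$haplotypes)) next
    grouped <- c(grouped, lg$loci)
    h <- lg$haplotypes
    hap1 <- sample.int(nrow(h), n, replace = TRUE, prob = h$freq)
    hap2 <- sample.int(nrow(h), n, replace = TRUE, prob = h$freq)
    for (loc in lg$loci) {
      a <- as.character(h[[loc]])
      calls[[loc]][, 1] <- a[hap1]
      calls[[loc]][sex == "female", 2] <- a[hap2][sex == "female"]
    }
  }
  for (loc in setdiff(names(spec$loci), grouped)) {
    p <- spec$loci[[loc]]
    lab <- names(p)
    a1 <- lab[sample.int(length(p), n, replace = TRUE, prob = p)]
    a2 <- lab[sample.int(length(p), n, replace = TRUE, prob = p)]
    ibd <- runif(n) < spec$F_inbreeding[[loc]]
    a2[ibd] <- a1[ibd]
    calls[[loc]][, 1] <- a1
    calls[[loc]][sex == "female", 2] <- a2[sex == "female"]
  }
  g <- xstr_genotypes(ids, sex, calls, names(spec$loci))
  attr(g, "truth") <- spec
  g
}

#' Simulate allele-frequency tables for diverged populations
#'
#' Balding-Nichols construction: for each population and locus, frequencies
#' are drawn from a Dirichlet distribution centered on the ancestral vector
#' with concentration `(1 - Fst) / Fst`, so that the expected allele-frequency
#' variance is `Fst * p * (1 - p)`. `Fst = 0` returns the ancestral
#' frequencies for every population.
#'
#' @param spec a [synthetic_spec] with `n_populations >= 2` and
#'   `0 <= fst_divergence < 1` set; `loci` holds the ancestral frequencies.
#' @return named list of [xstr_freqs] objects with attribute `truth`.
#' @export
simulate_divergent_populations <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  npop <- spec$n_populations
  fst <- spec$fst_divergence
  if (is.null(npop) || npop < 2) stop("spec error: need n_populations >= 2")
  if (is.null(fst) || fst < 0 || fst >= 1) {
    stop("spec error: fst_divergence must lie in [0, 1)")
  }
  if (fst > 0 && any(vapply(spec$loci, length, integer(1)) < 2)) {
    stop("spec error: degenerate (monomorphic) ancestral locus with Fst > 0")
  }
  set.seed(spec$seed)
  out <- list()
  for (i in seq_len(npop)) {
    tab <- list()
    N <- numeric(0)
    for (loc in names(spec$loci)) {
      p <- spec$loci[[loc]]
      q <- if (fst == 0) as.numeric(p) else {
        conc <- p * (1 - fst) / fst
        draw <- rgamma(length(p), shape = conc, rate = 1)
        while (sum(draw) == 0) draw <- rgamma(length(p), shape = conc, rate = 1)
        draw / sum(draw)
      }
      keep <- q > 0
      tab[[loc]] <- data.frame(allele = names(p)[keep], count = NA_real_,
                               freq = q[keep] / sum(q[keep]),
                               stringsAsFactors = FALSE)
      N[loc] <- NA_real_
    }
    out[[sprintf("pop%02d", i)]] <- xstr_freqs(tab, N)
  }
  attr(out, "truth") <- spec
  out
}

#' A study-sized synthetic X-STR cohort
#'
#' Generates a cohort with the design of a full population survey of the
#' 19-locus panel: 265 diploid females and 248 hemizygous males (513 samples,
#' 778 X chromosomes per fully typed locus), the 19 panel loci with realistic
#' per-locus allele richness (5 alleles at DXS7423 up to 26 at DXS10135,
#' microvariant labels such as `"24.1"` at DXS10148), and the seven canonical
#' linkage groups simulated with explicit haplotype distributions so that
#' within-group association is present.
#'
#' @param seed integer seed.
#' @return an [xstr_genotypes] with attribute `truth` (the generating
#'   [synthetic_spec]).
#' @export
gelao_like_fixture <- function(seed = 1) {
  set.seed(seed)
  n_alleles <- c(DXS8378 = 9, DXS7423 = 5, DXS10148 = 22, DXS10159 = 10,
                 DXS10134 = 21, DXS7424 = 9, DXS10164 = 10, DXS10162 = 13,
                 DXS7132 = 8, DXS10079 = 10, DXS6789 = 12, DXS101 = 14,
                 DXS10103 = 10, DXS10101 = 20, HPRTB = 7, DXS6809 = 10,
                 DXS10075 = 14, DXS10074 = 12, DXS10135 = 26)
  range_start <- c(DXS8378 = 7, DXS7423 = 12, DXS10148 = 13, DXS10159 = 23,
                   DXS10134 = 28, DXS7424 = 9, DXS10164 = 7, DXS10162 = 14,
                   DXS7132 = 10, DXS10079 = 14, DXS6789 = 14, DXS101 = 18,
                   DXS10103 = 13, DXS10101 = 24, HPRTB = 9, DXS6809 = 28,
                   DXS10075 = 10, DXS10074 = 7, DXS10135 = 15)
  micro <- c("DXS10148", "DXS10135")  # loci carrying ".1" microvariants
  loci <- list()
  for (loc in panel_loci()) {
    k <- n_alleles[[loc]]
    lab <- as.character(seq(range_start[[loc]], length.out = k))
    if (loc %in% micro) {
      lab <- if (loc == "DXS10148") paste0(lab, ".1") else {
        # a few partial-repeat variants among integer alleles
        replace(lab, c(3, 7), paste0(lab[c(3, 7)], ".1"))
      }
    }
    # unimodal-ish frequency profile with a uniform floor keeping every
    # configured allele observable in 778 chromosomes
    w <- 0.65 * as.numeric(rgamma(k, shape = 3)) + 0.35 * mean(rgamma(k, 3))
    p <- w / sum(w)
    loci[[loc]] <- setNames(p, lab)
  }
  hap_pool <- c(LG1 = 300, LG2 = 120, LG3 = 300, LG4 = 70, LG5 = 55,
                LG6 = 160, LG7 = 45)
  lgs <- list()
  for (grp in names(default_linkage_groups())) {
    gloci <- default_linkage_groups()[[grp]]
    K <- hap_pool[[grp]]
    cols <- list()
    for (loc in gloci) {
      p <- loci[[loc]]
      lab <- names(p)
      # guarantee every allele occurs in the haplotype pool, fill the rest
      # from the target marginal
      col <- c(sample(lab), lab[sample.int(length(p), K - length(p),
                                           replace = TRUE, prob = p)])
      cols[[loc]] <- sample(col)
    }
    h <- as.data.frame(cols, stringsAsFactors = FALSE, check.names = FALSE)
    w <- as.numeric(rgamma(K, shape = 0.8))
    h$freq <- w / sum(w)
    # aggregate duplicated haplotypes
    key <- do.call(paste, c(h[gloci], sep = "-"))
    agg <- rowsum(h$freq, key)
    first <- match(rownames(agg), key)
    h <- h[first, , drop = FALSE]
    h$freq <- agg[, 1]
    lgs[[grp]] <- list(loci = gloci, haplotypes = h)
  }
  spec <- synthetic_spec(n_females = 265, n_males = 248, loci = loci,
                         linkage_groups = lgs, seed = seed + 1L)
  simulate_genotypes(spec)
}
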