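#' Construct and validate an X-STR genotype table
#'
#' The central container for sample-level X-STR calls. Females carry two
#' allele labels per typed locus, males are hemizygous and carry exactly one.
#' Missing calls are `NA`; a sample missing a locus is excluded from that
#' locus's counts only.
#'
#' @param sample_id character vector of unique sample identifiers.
#' @param sex character vector, `"female"` or `"male"` (also accepts
#'   `"F"`/`"M"`, case-insensitive).
#' @param calls named list, one element per locus, each an `n x 2` character
#'   matrix of allele labels (second column `NA` for males and for missing).
#' @param loci ordered character vector of locus names; defaults to
#'   `names(calls)`.
#' @return an object of class `xstr_genotypes`.
#' @export
xstr_genotypes <- function(sample_id, sex, calls, loci = names(calls)) {
  sample_id <- as.character(sample_id)
  n <- length(sample_id)
  if (anyDuplicated(sample_id)) stop("duplicate sample ids")
  sex <- normalize_sex(sex)
  if (length(sex) != n) stop("sex and sample_id lengths differ")
  if (is.null(names(calls)) || anyDuplicated(names(calls))) {
    stop("calls must be a named list with unique locus names")
  }
  if (!setequal(loci, names(calls)) || anyDuplicated(loci)) {
    stop("loci must match names(calls) and be unique")
  }
  calls <- calls[loci]
  for (loc in loci) {
    m <- calls[[loc]]
    if (!is.matrix(m)) m <- matrix(as.character(m), ncol = 2)
    storage.mode(m) <- "character"
    dimnames(m) <- NULL
    if (nrow(m) != n || ncol(m) != 2) {
      stop("calls for locus ", loc, " must be an n x 2 matrix")
    }
    m[m %in% c("", "NA")] <- NA_character_
    lab <- m[!is.na(m)]
    bad <- !grepl(.allele_pattern, lab)
    if (any(bad)) {
      stop("malformed allele label at locus ", loc, ": ",
           paste(unique(lab[bad]), collapse = ", "))
    }
    female <- sex == "female"
    one_allele <- !is.na(m[, 1]) & is.na(m[, 2])
    if (any(female & one_allele)) {
      stop("ploidy error: female sample(s) with a single allele at ", loc, ": ",
           paste(sample_id[female & one_allele], collapse = ", "))
    }
    # hemizygous males: a duplicated call like 15/15 is a common typing
    # artifact and collapses to one allele; two distinct alleles is an error
    male2 <- !female & !is.na(m[, 2])
    if (any(male2)) {
      distinct <- male2 & m[, 1] != m[, 2]
      if (any(distinct)) {
        stop("ploidy error: male sample(s) with two distinct alleles at ", loc,
             ": ", paste(sample_id[distinct], collapse = ", "))
      }
      warning("male sample(s) with duplicated allele call at ", loc,
              " treated as hemizygous: ",
              paste(sample_id[male2], collapse = ", "))
      m[male2, 2] <- NA_character_
    }
    miss1 <- is.na(m[, 1]) & !is.na(m[, 2])
    if (any(miss1)) {
      m[miss1, 1] <- m[miss1, 2]
      m[miss1, 2] <- NA_character_
    }
    calls[[loc]] <- m
  }
  structure(
    list(sample_id = sample_id, sex = sex, loci = loci, calls = calls),
    class = "xstr_genotypes"
  )
}

normalize_sex <- function(sex) {
  s <- tolower(as.character(sex))
  s[s %in% c("f", "female", "2")] <- "female"
  s[s %in% c("m", "male", "1")] <- "male"
  bad <- !s %in% c("female", "male")
  if (any(bad)) stop("unrecognized sex code(s): ", paste(unique(sex[bad]), collapse = ", "))
  s
}

#' @export
print.xstr_genotypes <- function(x, ...) {
  cat("<xstr_genotypes> ", length(x$sample_id), " samples (",
      sum(x$sex == "female"), " female, ", sum(x$sex == "male"), " male), ",
      length(x$loci), " loci\n", sep = "")
  invisible(x)
}

#' Number of non-missing allele observations per locus
#'
#' Counts X chromosomes: two per typed female, one per typed male.
#'
#' @param g an `xstr_genotypes` object.
#' @return named integer vector over loci.
#' @export
chromosome_counts <- function(g) {
  stopifnot(inherits(g, "xstr_genotypes"))
  vapply(g$loci, function(loc) sum(!is.na(g$calls[[loc]])), integer(1))
}

# logical index of samples typed (non-missing) at a locus
typed_at <- function(g, locus) !is.na(g$calls[[locus]][, 1])

#' Subset samples of a genotype table
#'
#' @param g an `xstr_genotypes` object.
#' @param idx logical or integer sample index.
#' @return an `xstr_genotypes` with the selected samples.
#' @export
subset_samples <- function(g, idx) {
  xstr_genotypes(
    g$sample_id[idx], g$sex[idx],
    lapply(g$calls, function(m) m[idx, , drop = FALSE]), g$loci
  )
}
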