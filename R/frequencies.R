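#' Estimate allele frequencies by sex stratum
#'
#' Direct counting of X chromosomes: each typed female contributes two allele
#' observations per locus, each typed male one; the pooled stratum therefore
#' has `N = 2 * females + males` chromosomes per fully typed locus.
#' Loci with no observations in the stratum are flagged absent (dropped with
#' a message), never zero-filled.
#'
#' @param g an [xstr_genotypes] object.
#' @param stratum `"pooled"`, `"female"` or `"male"`.
#' @return an [xstr_freqs] object.
#' @export
allele_frequencies <- function(g, stratum = c("pooled", "female", "male")) {
  stopifnot(inherits(g, "xstr_genotypes"))
  stratum <- match.arg(stratum)
  keep <- switch(stratum,
                 pooled = rep(TRUE, length(g$sex)),
                 female = g$sex == "female",
                 male   = g$sex == "male")
  tab <- list()
  N <- numeric(0)
  for (loc in g$loci) {
    m <- g$calls[[loc]][keep, , drop = FALSE]
    obs <- m[!is.na(m)]
    if (length(obs) == 0) {
      message("locus ", loc, " has no observations in stratum '", stratum,
              "'; flagged absent")
      next
    }
    cnt <- table(obs)
    d <- data.frame(allele = names(cnt), count = as.numeric(cnt),
                    freq = as.numeric(cnt) / length(obs),
                    stringsAsFactors = FALSE)
    tab[[loc]] <- d
    N[loc] <- length(obs)
  }
  if (!length(tab)) stop("stratum '", stratum, "' is empty at every locus")
  xstr_freqs(tab, N)
}

#' Male linkage-group haplotype frequencies by direct counting
#'
#' Male X-STR genotypes are directly phased haplotypes, so group haplotypes
#' are counted exactly. A male enters a group's count only when typed at every
#' locus of that group; females are excluded (phase unknown) with a note.
#' Haplotype labels join allele labels with `"-"` in the group's declared
#' locus order.
#'
#' @param g an [xstr_genotypes] object.
#' @param groups named list of ordered locus vectors; defaults to
#'   [default_linkage_groups()].
#' @return an object of class `xstr_haplotypes`: per group a
#'   `data.frame(haplotype, count, freq)` (descending count), the number of
#'   typed males, distinct haplotypes and singletons.
#' @export
haplotype_frequencies <- function(g, groups = default_linkage_groups()) {
  stopifnot(inherits(g, "xstr_genotypes"))
  validate_linkage_groups(groups)
  missing_loci <- setdiff(unlist(groups), g$loci)
  if (length(missing_loci)) {
    stop("linkage group locus not in genotype table: ",
         paste(missing_loci, collapse = ", "))
  }
  if (any(g$sex == "female")) {
    message(sum(g$sex == "female"),
            " female sample(s) excluded from haplotype counting (phase unknown)")
  }
  male <- g$sex == "male"
  out <- list()
  for (grp in names(groups)) {
    loci <- groups[[grp]]
    alle <- sapply(loci, function(loc) g$calls[[loc]][male, 1])
    if (!is.matrix(alle)) alle <- matrix(alle, nrow = sum(male))
    complete <- rowSums(is.na(alle)) == 0
    if (!any(complete)) {
      out[[grp]] <- list(table = data.frame(haplotype = character(),
                                            count = numeric(), freq = numeric()),
                         n_males = 0L, n_distinct = 0L, n_singletons = 0L)
      next
    }
    hap <- apply(alle[complete, , drop = FALSE], 1, paste, collapse = "-")
    cnt <- sort(table(hap), decreasing = TRUE)
    d <- data.frame(haplotype = names(cnt), count = as.numeric(cnt),
                    freq = as.numeric(cnt) / sum(cnt), stringsAsFactors = FALSE)
    out[[grp]] <- list(table = d, n_males = sum(complete),
                       n_distinct = nrow(d),
                       n_singletons = sum(d$count == 1))
  }
  structure(list(groups = out, loci_by_group = groups),
            class = "xstr_haplotypes")
}

#' @export
print.xstr_haplotypes <- function(x, ...) {
  for (grp in names(x$groups)) {
    h <- x$groups[[grp]]
    cat(grp, ": ", h$n_males, " males, ", h$n_distinct, " haplotypes (",
        h$n_singletons, " singletons)\n", sep = "")
  }
  invisible(x)
}

#' Fraction of unique haplotypes in a linkage group
#'
#' Singletons (haplotypes carried by exactly one male) divided by the number
#' of distinct haplotypes.
#'
#' @param h an `xstr_haplotypes` object.
#' @param group group name.
#' @return fraction in \[0, 1\].
#' @export
singleton_fraction <- function(h, group) {
  stopifnot(inherits(h, "xstr_haplotypes"))
  if (!group %in% names(h$groups)) stop("unknown linkage group: ", group)
  hg <- h$groups[[group]]
  if (hg$n_distinct < 1) stop("no haplotypes counted in group ", group)
  hg$n_singletons / hg$n_distinct
}
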