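#' Read a sample-level X-STR genotype table
#'
#' Accepts two delimited-text dialects, autodetected from the header:
#' \itemize{
#'   \item wide: columns `sample_id, sex, <locus>_1, <locus>_2`, with
#'     `<locus>_2` empty for males;
#'   \item compact: one column per locus holding `15/16` for females and a
#'     single label for males.
#' }
#' The delimiter is inferred from the file extension (`.csv` comma, otherwise
#' tab) unless `sep` is given. Empty cells and `"NA"` are missing data.
#'
#' @param path file path.
#' @param sep optional field separator overriding autodetection.
#' @return an [xstr_genotypes] object.
#' @export
read_genotypes <- function(path, sep = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- sep %||% infer_sep(path)
  df <- read.table(path, header = TRUE, sep = sep, colClasses = "character",
                   check.names = FALSE, na.strings = c("", "NA"),
                   strip.white = TRUE)
  nm <- names(df)
  id_col <- if ("sample_id" %in% nm) "sample_id" else nm[1]
  sex_col <- if ("sex" %in% nm) "sex" else nm[2]
  rest <- setdiff(nm, c(id_col, sex_col))
  wide <- grepl("_[12]$", rest)
  calls <- list()
  if (all(wide) && length(rest) > 0) {
    loci <- unique(sub("_[12]$", "", rest))
    for (loc in loci) {
      c1 <- paste0(loc, "_1")
      c2 <- paste0(loc, "_2")
      if (!all(c(c1, c2) %in% rest)) {
        stop("locus ", loc, " needs both ", c1, " and ", c2, " columns")
      }
      calls[[loc]] <- cbind(df[[c1]], df[[c2]])
    }
  } else if (!any(wide)) {
    loci <- rest
    for (loc in loci) {
      parts <- strsplit(ifelse(is.na(df[[loc]]), "", df[[loc]]), "/", fixed = TRUE)
      a1 <- vapply(parts, function(p) if (length(p) >= 1) p[1] else NA_character_,
                   character(1))
      a2 <- vapply(parts, function(p) if (length(p) >= 2) p[2] else NA_character_,
                   character(1))
      toomany <- lengths(parts) > 2
      if (any(toomany)) {
        stop("parse error at locus ", loc, ", row(s) ",
             paste(which(toomany), collapse = ", "), ": more than two alleles")
      }
      calls[[loc]] <- cbind(a1, a2)
    }
  } else {
    stop("mixed genotype column dialects: found both <locus>_1/_2 and single columns")
  }
  xstr_genotypes(df[[id_col]], df[[sex_col]], calls, names(calls))
}

#' Write a genotype table as delimited text
#'
#' @param g an [xstr_genotypes] object.
#' @param path output path (`.csv` comma, otherwise tab).
#' @param dialect `"wide"` (two columns per locus) or `"compact"`
#'   (slash-separated).
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(g, path, dialect = c("wide", "compact")) {
  stopifnot(inherits(g, "xstr_genotypes"))
  dialect <- match.arg(dialect)
  out <- data.frame(sample_id = g$sample_id, sex = g$sex,
                    check.names = FALSE, stringsAsFactors = FALSE)
  for (loc in g$loci) {
    m <- g$calls[[loc]]
    if (dialect == "wide") {
      out[[paste0(loc, "_1")]] <- m[, 1]
      out[[paste0(loc, "_2")]] <- m[, 2]
    } else {
      out[[loc]] <- ifelse(is.na(m[, 1]), NA_character_,
                           ifelse(is.na(m[, 2]), m[, 1],
                                  paste0(m[, 1], "/", m[, 2])))
    }
  }
  write.table(out, path, sep = infer_sep(path), row.names = FALSE,
              quote = FALSE, na = "")
  invisible(path)
}

infer_sep <- function(path) if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"

#' Construct an allele-frequency table
#'
#' Per-locus relative allele frequencies with the number of X chromosomes
#' observed (`N`). Frequencies must be positive and sum to one per locus.
#'
#' @param tab named list, one `data.frame(allele, count, freq)` per locus
#'   (`count` may be `NA` when only frequencies are known).
#' @param N named numeric vector of chromosome counts per locus (`NA` allowed).
#' @return an object of class `xstr_freqs`.
#' @export
xstr_freqs <- function(tab, N) {
  loci <- names(tab)
  if (is.null(loci) || anyDuplicated(loci)) stop("tab must be named by unique loci")
  if (!all(loci %in% names(N))) stop("N must cover every locus")
  for (loc in loci) {
    d <- tab[[loc]]
    stopifnot(all(c("allele", "freq") %in% names(d)))
    if (is.null(d$count)) d$count <- NA_real_
    d$allele <- as.character(d$allele)
    bad <- !grepl(.allele_pattern, d$allele)
    if (any(bad)) stop("malformed allele label at ", loc, ": ",
                       paste(d$allele[bad], collapse = ", "))
    if (any(d$freq <= 0)) stop("non-positive frequency at locus ", loc)
    if (abs(sum(d$freq) - 1) > 1e-9) {
      stop("frequencies at locus ", loc, " sum to ", sum(d$freq), ", not 1")
    }
    if (!is.na(N[[loc]]) && N[[loc]] < 1) stop("N < 1 at locus ", loc)
    tab[[loc]] <- d[allele_order(d$allele), c("allele", "count", "freq")]
    rownames(tab[[loc]]) <- NULL
  }
  structure(list(loci = loci, tab = tab, N = N[loci]), class = "xstr_freqs")
}

#' @export
print.xstr_freqs <- function(x, ...) {
  cat("<xstr_freqs> ", length(x$loci), " loci; alleles per locus: ",
      paste(range(vapply(x$tab, nrow, integer(1))), collapse = "-"), "\n", sep = "")
  invisible(x)
}

#' Read a locus-by-allele frequency table
#'
#' Matrix layout: rows are allele labels (first column `allele`), remaining
#' columns are loci, cells hold relative frequencies (blank = allele absent at
#' that locus). An optional row labelled `N` carries the number of observed
#' chromosomes per locus. Columns whose frequencies sum within 0.01 of 1 are
#' renormalized to sum exactly 1; anything further off is a consistency error.
#'
#' @param path file path (`.csv` comma, otherwise tab).
#' @return an [xstr_freqs] object.
#' @export
read_frequency_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.table(path, header = TRUE, sep = infer_sep(path),
                   check.names = FALSE, colClasses = "character",
                   na.strings = c("", "NA"), strip.white = TRUE)
  lab <- df[[1]]
  n_row <- which(lab == "N")
  loci <- names(df)[-1]
  Nv <- rep(NA_real_, length(loci))
  names(Nv) <- loci
  if (length(n_row)) {
    Nv[] <- suppressWarnings(as.numeric(df[n_row[1], -1]))
    df <- df[-n_row, , drop = FALSE]
    lab <- df[[1]]
  }
  tab <- list()
  for (loc in loci) {
    fr <- suppressWarnings(as.numeric(df[[loc]]))
    keep <- !is.na(fr)
    if (!any(keep)) next
    fr <- fr[keep]
    al <- lab[keep]
    if (any(fr < 0)) stop("negative frequency at locus ", loc)
    s <- sum(fr)
    if (s < 0.99 || s > 1.01) {
      stop("consistency error at locus ", loc, ": frequencies sum to ",
           format(s), " (outside [0.99, 1.01])")
    }
    fr <- fr / s
    cnt <- if (is.na(Nv[[loc]])) rep(NA_real_, length(fr)) else fr * Nv[[loc]]
    tab[[loc]] <- data.frame(allele = al, count = cnt, freq = fr,
                             stringsAsFactors = FALSE)
  }
  xstr_freqs(tab, Nv[names(tab)])
}

#' Write an allele-frequency table as delimited text
#'
#' Inverse of [read_frequency_table]: union of allele labels as rows (sorted
#' numerically), loci as columns, plus an `N` row. Frequencies are written at
#' full precision unless `digits` is given.
#'
#' @param f an [xstr_freqs] object.
#' @param path output path.
#' @param digits optional rounding (e.g. 4 for report-style tables).
#' @return `path`, invisibly.
#' @export
write_frequency_table <- function(f, path, digits = NULL) {
  stopifnot(inherits(f, "xstr_freqs"))
  alleles <- unique(unlist(lapply(f$tab, function(d) d$allele)))
  alleles <- alleles[allele_order(alleles)]
  m <- matrix(NA_real_, length(alleles), length(f$loci),
              dimnames = list(alleles, f$loci))
  for (loc in f$loci) m[f$tab[[loc]]$allele, loc] <- f$tab[[loc]]$freq
  if (!is.null(digits)) m <- round_half_up(m, digits)
  out <- data.frame(allele = c(alleles, "N"), rbind(m, f$N[f$loci]),
                    check.names = FALSE, stringsAsFactors = FALSE)
  write.table(format(out, digits = 15, trim = TRUE, scientific = FALSE),
              path, sep = infer_sep(path), row.names = FALSE, quote = FALSE,
              na = "")
  invisible(path)
}

#' Read or write linkage-group definitions
#'
#' Definitions are a named list mapping group names to ordered locus vectors,
#' serialized as YAML or JSON (by extension).
#'
#' @param path file path ending in `.yaml`/`.yml` or `.json`.
#' @return named list of character vectors.
#' @export
read_linkage_groups <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lgs <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  }
  lgs <- lapply(lgs, as.character)
  validate_linkage_groups(lgs)
  lgs
}

#' @rdname read_linkage_groups
#' @param lgs named list of ordered locus vectors.
#' @export
write_linkage_groups <- function(lgs, path) {
  validate_linkage_groups(lgs)
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::write_yaml(lgs, path)
  } else {
    jsonlite::write_json(lgs, path, auto_unbox = FALSE, pretty = TRUE)
  }
  invisible(path)
}

validate_linkage_groups <- function(lgs) {
  if (is.null(names(lgs)) || anyDuplicated(names(lgs))) {
    stop("linkage groups must be a uniquely named list")
  }
  all_loci <- unlist(lgs, use.names = FALSE)
  if (anyDuplicated(all_loci)) {
    stop("locus assigned to more than one linkage group: ",
         paste(unique(all_loci[duplicated(all_loci)]), collapse = ", "))
  }
  invisible(lgs)
}

#' Serialize a phylogenetic tree to Newick text
#'
#' Standard Newick with branch lengths, terminated by `";"`.
#'
#' @param tree an `ape::phylo` object with unique leaf names.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  if (!inherits(tree, "phylo")) stop("serialization error: not a phylo tree")
  if (is.null(tree$tip.label) || length(tree$tip.label) == 0) {
    stop("serialization error: empty tree")
  }
  if (anyDuplicated(tree$tip.label)) {
    stop("serialization error: duplicate leaf names")
  }
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' @rdname write_newick
#' @export
read_newick <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  ape::read.tree(path)
}
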