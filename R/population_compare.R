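#' Nei's (1972) standard genetic distance between two populations
#'
#' `D = -ln(I)` with normalized identity `I = J_AB / sqrt(J_A * J_B)`, where
#' the `J` quantities are arithmetic means across shared loci of
#' `sum(p_A * p_B)`, `sum(p_A^2)` and `sum(p_B^2)` over the per-locus union
#' allele set (absent alleles count as frequency zero).
#'
#' @param popA,popB [xstr_freqs] objects.
#' @param loci optional locus subset; defaults to all shared loci.
#' @return non-negative distance (`Inf` with a warning when the populations
#'   share no alleles anywhere).
#' @export
nei_distance <- function(popA, popB, loci = NULL) {
  stopifnot(inherits(popA, "xstr_freqs"), inherits(popB, "xstr_freqs"))
  shared <- intersect(popA$loci, popB$loci)
  if (!is.null(loci)) shared <- intersect(shared, loci)
  if (length(shared) == 0) stop("no shared loci between the two populations")
  jab <- ja <- jb <- numeric(length(shared))
  for (i in seq_along(shared)) {
    da <- popA$tab[[shared[i]]]
    db <- popB$tab[[shared[i]]]
    alleles <- union(da$allele, db$allele)
    pa <- setNames(numeric(length(alleles)), alleles)
    pb <- pa
    pa[da$allele] <- da$freq
    pb[db$allele] <- db$freq
    jab[i] <- sum(pa * pb)
    ja[i] <- sum(pa^2)
    jb[i] <- sum(pb^2)
  }
  I <- mean(jab) / sqrt(mean(ja) * mean(jb))
  if (I == 0) {
    warning("no shared alleles at any locus: distance is infinite")
    return(Inf)
  }
  max(0, -log(I))
}

#' Pairwise Nei distance matrix over a set of populations
#'
#' @param tables named list of [xstr_freqs] objects.
#' @param loci optional locus subset applied to every pair.
#' @return symmetric matrix with zero diagonal.
#' @export
nei_distance_matrix <- function(tables, loci = NULL) {
  npop <- length(tables)
  if (npop < 2) stop("need at least two populations")
  nm <- names(tables) %||% paste0("pop", seq_len(npop))
  d <- matrix(0, npop, npop, dimnames = list(nm, nm))
  for (i in seq_len(npop - 1)) for (j in (i + 1):npop) {
    d[i, j] <- d[j, i] <- nei_distance(tables[[i]], tables[[j]], loci)
  }
  d
}

as_distance_matrix <- function(d) {
  if (!is.matrix(d) || nrow(d) != ncol(d)) stop("distance matrix must be square")
  if (max(abs(d - t(d))) > 1e-12) stop("distance matrix must be symmetric")
  if (any(diag(d) != 0)) stop("distance matrix must have zero diagonal")
  if (any(d < 0)) stop("distances must be non-negative")
  d
}

# populations x features matrix of per-allele frequencies over the union
# allele set (absent alleles zero-filled); feature names "<locus>:<allele>"
freq_feature_matrix <- function(tables, loci = NULL) {
  nm <- names(tables) %||% paste0("pop", seq_along(tables))
  loci <- loci %||% Reduce(intersect, lapply(tables, function(t) t$loci))
  if (length(loci) == 0) stop("no shared loci across populations")
  feats <- list()
  for (loc in loci) {
    alleles <- unique(unlist(lapply(tables, function(t)
      if (loc %in% t$loci) t$tab[[loc]]$allele else character(0))))
    alleles <- alleles[allele_order(alleles)]
    m <- matrix(0, length(tables), length(alleles),
                dimnames = list(nm, paste0(loc, ":", alleles)))
    for (i in seq_along(tables)) {
      t <- tables[[i]]
      if (loc %in% t$loci) m[i, paste0(loc, ":", t$tab[[loc]]$allele)] <- t$tab[[loc]]$freq
    }
    feats[[loc]] <- m
  }
  do.call(cbind, feats)
}

#' Principal component analysis on population allele frequencies
#'
#' Column-centered covariance PCA of the populations x per-allele-frequency
#' matrix ([freq_feature_matrix]). Components use a deterministic sign
#' convention: the loading of largest magnitude on each component is
#' positive.
#'
#' @param tables named list of [xstr_freqs] objects (>= 3 populations).
#' @param loci optional locus subset.
#' @param components number of components to keep (default: all).
#' @return list: `scores` (populations x components), `loadings`,
#'   `pct_variance` (eigenvalue shares, percent of total over all
#'   components).
#' @export
pca_frequencies <- function(tables, loci = NULL, components = NULL) {
  if (length(tables) < 3) stop("need >= 3 populations for PCA")
  X <- freq_feature_matrix(tables, loci)
  fit <- prcomp(X, center = TRUE, scale. = FALSE)
  ncomp_all <- length(fit$sdev)
  total_var <- sum(fit$sdev^2)
  pct <- if (total_var == 0) rep(0, ncomp_all) else 100 * fit$sdev^2 / total_var
  components <- components %||% ncomp_all
  if (components > min(length(tables) - 1, ncol(X))) {
    stop("components exceeds min(populations - 1, features)")
  }
  rot <- fit$rotation
  sco <- fit$x
  for (j in seq_len(ncol(rot))) {
    if (rot[which.max(abs(rot[, j])), j] < 0) {
      rot[, j] <- -rot[, j]
      sco[, j] <- -sco[, j]
    }
  }
  list(scores = sco[, seq_len(components), drop = FALSE],
       loadings = rot[, seq_len(components), drop = FALSE],
       pct_variance = pct[seq_len(components)],
       pct_variance_all = pct)
}

#' Classical (Torgerson) metric multidimensional scaling
#'
#' Double-centering and eigendecomposition of the squared-distance matrix,
#' with Kruskal's stress-1 reported against the input distances and the same
#' deterministic sign convention as [pca_frequencies].
#'
#' @param d symmetric distance matrix with zero diagonal.
#' @param dims embedding dimension (`1 <= dims <= n - 1`).
#' @return list: `points` (n x dims coordinates), `stress` (stress-1),
#'   `eig` (eigenvalues).
#' @export
mds_from_distances <- function(d, dims = 2) {
  d <- as_distance_matrix(d)
  n <- nrow(d)
  if (dims < 1 || dims > n - 1) stop("dims must lie in [1, populations - 1]")
  fit <- cmdscale(d, k = dims, eig = TRUE)
  pts <- fit$points
  if (ncol(pts) < dims) {  # degenerate geometry: pad zero coordinates
    pts <- cbind(pts, matrix(0, n, dims - ncol(pts)))
  }
  for (j in seq_len(ncol(pts))) {
    if (max(pts[, j]) < -min(pts[, j])) pts[, j] <- -pts[, j]
  }
  rownames(pts) <- rownames(d)
  dd <- as.matrix(dist(pts))
  num <- sum((d[upper.tri(d)] - dd[upper.tri(dd)])^2)
  den <- sum(d[upper.tri(d)]^2)
  stress <- if (den == 0) 0 else sqrt(num / den)
  list(points = pts, stress = stress, eig = fit$eig)
}

#' Neighbor-Joining tree from a distance matrix
#'
#' Saitou-Nei agglomeration (Q-criterion, standard branch-length formulas)
#' via `ape::nj`. Exact on additive (tree-metric) inputs. Negative branch
#' lengths, which NJ can produce on non-additive matrices, are clamped to
#' zero with a warning unless `clamp_negative = FALSE`.
#'
#' @param d symmetric distance matrix with zero diagonal (>= 3 populations).
#' @param clamp_negative clamp negative branch lengths to zero?
#' @return an `ape::phylo` tree whose leaves are the population names.
#' @export
nj_tree <- function(d, clamp_negative = TRUE) {
  d <- as_distance_matrix(d)
  if (nrow(d) < 3) stop("need >= 3 populations for a NJ tree")
  tree <- ape::nj(d)
  if (clamp_negative && any(tree$edge.length < 0)) {
    warning("negative NJ branch length(s) clamped to zero")
    tree$edge.length[tree$edge.length < 0] <- 0
  }
  tree
}
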