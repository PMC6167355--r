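test_that("Nei distance: identity, hand example, symmetry, disjoint alleles", {
  fa <- make_freqs(list(L1 = c(`10` = 0.6, `11` = 0.4)))
  fb <- make_freqs(list(L1 = c(`10` = 0.5, `11` = 0.5)))
  expect_equal(nei_distance(fa, fa), 0)
  # J_A = 0.52, J_B = 0.5, J_AB = 0.5 -> I = 0.98058, D = 0.01961
  expect_equal(round(nei_distance(fa, fb), 5), 0.01961)
  expect_equal(nei_distance(fa, fb), nei_distance(fb, fa), tolerance = 1e-12)

  fc <- make_freqs(list(L1 = c(`20` = 0.5, `21` = 0.5)))
  expect_warning(d <- nei_distance(fa, fc), "infinite")
  expect_equal(d, Inf)
  fd <- make_freqs(list(L9 = c(`10` = 1)))
  expect_error(nei_distance(fa, fd), "shared loci")
})

test_that("Nei distance matrix is symmetric with zero diagonal", {
  set.seed(12)
  spec <- synthetic_spec(0, 0,
                         loci = setNames(lapply(1:6, function(i) {
                           p <- rgamma(4, 2)
                           setNames(p / sum(p), as.character(10:13))
                         }), paste0("L", 1:6)),
                         n_populations = 5, fst_divergence = 0.08, seed = 12)
  pops <- simulate_divergent_populations(spec)
  d <- nei_distance_matrix(pops)
  expect_equal(d, t(d), tolerance = 1e-12)
  expect_equal(diag(d), setNames(rep(0, 5), names(pops)))
  expect_true(all(d >= 0))
})

test_that("PCA on frequencies: degenerate, collinear and conservation cases", {
  f <- make_freqs(list(L1 = c(`10` = 0.5, `11` = 0.5)))
  same <- list(a = f, b = f, c = f)
  p0 <- pca_frequencies(same, components = 2)
  expect_true(all(p0$pct_variance_all == 0))
  expect_equal(max(abs(p0$scores)), 0, tolerance = 1e-12)

  # three populations on a line in frequency space -> PC1 carries 100%
  mk <- function(x) make_freqs(list(L1 = c(`10` = x, `11` = 1 - x)))
  line <- list(a = mk(0.3), b = mk(0.4), c = mk(0.5))
  p1 <- pca_frequencies(line, components = 2)
  expect_equal(p1$pct_variance[1], 100, tolerance = 1e-9)
  expect_equal(sum(p1$pct_variance_all), 100, tolerance = 1e-9)

  expect_error(pca_frequencies(line, components = 3), "components")
  expect_error(pca_frequencies(same[1:2]), ">= 3")
})

test_that("PCA sign convention is deterministic", {
  set.seed(5)
  spec <- synthetic_spec(0, 0,
                         loci = list(L1 = setNames(rep(0.25, 4), 10:13),
                                     L2 = setNames(rep(0.25, 4), 10:13)),
                         n_populations = 4, fst_divergence = 0.1, seed = 5)
  pops <- simulate_divergent_populations(spec)
  p <- pca_frequencies(pops, components = 2)
  for (j in 1:2) {
    expect_gt(p$loadings[which.max(abs(p$loadings[, j])), j], 0)
  }
})

test_that("classical MDS recovers Euclidean configurations", {
  set.seed(10)
  pts <- matrix(rnorm(12), 6, 2)
  d <- as.matrix(dist(pts))
  fit <- mds_from_distances(d, dims = 2)
  expect_equal(as.matrix(dist(fit$points)), d, tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_lt(fit$stress, 1e-9)

  # equilateral triangle from all-equal distances
  d3 <- matrix(1, 3, 3) - diag(3)
  dimnames(d3) <- list(letters[1:3], letters[1:3])
  f3 <- mds_from_distances(d3, dims = 2)
  dd <- as.matrix(dist(f3$points))
  expect_equal(dd[upper.tri(dd)], rep(1, 3), tolerance = 1e-9)

  # two populations: one axis, distance preserved exactly
  d2 <- matrix(c(0, 0.4, 0.4, 0), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  f2 <- mds_from_distances(d2, dims = 1)
  expect_equal(abs(diff(unname(f2$points[, 1]))), 0.4, tolerance = 1e-12)
  expect_error(mds_from_distances(d2, dims = 2), "dims")
  expect_error(mds_from_distances(matrix(c(0, 1, 2, 0), 2, 2)), "symmetric")
})

test_that("NJ recovers additive trees exactly", {
  # 3 taxa: unique star with three-point branch lengths
  d <- matrix(0, 3, 3, dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  d["A", "B"] <- d["B", "A"] <- 5
  d["A", "C"] <- d["C", "A"] <- 7
  d["B", "C"] <- d["C", "B"] <- 8
  tr <- nj_tree(d)
  bl <- setNames(tr$edge.length[match(1:3, tr$edge[, 2])], tr$tip.label)
  expect_equal(bl[["A"]], 2)  # (5 + 7 - 8) / 2
  expect_equal(bl[["B"]], 3)
  expect_equal(bl[["C"]], 5)

  # random additive matrices from known trees, up to 8 leaves
  set.seed(77)
  for (i in 1:10) {
    n <- sample(4:8, 1)
    true <- ape::rtree(n)
    true$edge.length <- true$edge.length + 0.1  # keep edges clearly positive
    dm <- ape::cophenetic.phylo(true)
    dm <- dm[sort(rownames(dm)), sort(colnames(dm))]
    est <- nj_tree(dm)
    expect_equal(ape::dist.topo(ape::unroot(true), est), 0,
                 ignore_attr = TRUE)
    expect_equal(ape::cophenetic.phylo(est)[rownames(dm), colnames(dm)], dm,
                 tolerance = 1e-9)
  }
})

test_that("NJ clamps negative branch lengths and validates input", {
  # a strongly non-additive matrix drives one NJ branch negative
  d <- matrix(c(0, 2, 2, 2,
                2, 0, 2, 0.1,
                2, 2, 0, 2,
                2, 0.1, 2, 0), 4, 4,
              dimnames = list(letters[1:4], letters[1:4]))
  raw <- ape::nj(d)
  if (any(raw$edge.length < 0)) {
    expect_warning(tr <- nj_tree(d), "clamped")
  } else {
    tr <- nj_tree(d)
  }
  expect_true(all(tr$edge.length >= 0))
  expect_error(nj_tree(d[1:2, 1:2]), ">= 3")
})
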