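test_that("genetic distances match counting oracles", {
  gm <- genotype_matrix(
    a1 = matrix(c("A", "A"), 2, 1), a2 = matrix(c("A", "B"), 2, 1),
    individuals = c("x", "y"))
  # AA vs AB shares one allele: shared_allele d = 1 - 1/2
  d <- genetic_distance(gm, "shared_allele")
  expect_equal(d["x", "y"], 0.5)
  expect_equal(diag(d), c(x = 0, y = 0))

  # identical homozygotes: both measures zero
  gm0 <- genotype_matrix(matrix("A", 2, 3), matrix("A", 2, 3),
                         individuals = c("x", "y"))
  expect_equal(genetic_distance(gm0, "shared_allele")["x", "y"], 0)
  expect_equal(genetic_distance(gm0, "nei1972")["x", "y"], 0)

  # no shared alleles anywhere: shared_allele d = 1
  gm1 <- genotype_matrix(matrix(c("A", "C"), 2, 2), matrix(c("B", "D"), 2, 2),
                         individuals = c("x", "y"))
  expect_equal(genetic_distance(gm1, "shared_allele")["x", "y"], 1)

  # symmetry and missing-pair handling
  a1 <- matrix(c("A", NA, "A", "B", NA, "B"), 3, 2)
  gm2 <- genotype_matrix(a1, a1)
  d2 <- genetic_distance(gm2, "shared_allele")
  expect_true(isSymmetric(unname(d2)))
  expect_true(is.na(d2[1, 2]))  # no co-genotyped locus
})

test_that("nj recovers small additive trees exactly", {
  # 4-taxon tree ((A:1,B:2):1,(C:3,D:1)) as additive distances
  d <- matrix(c(0, 3, 5, 3,
                3, 0, 6, 4,
                5, 6, 0, 4,
                3, 4, 4, 0), 4, 4,
              dimnames = list(c("A", "B", "C", "D"), c("A", "B", "C", "D")))
  tr <- nj_tree(d)
  expect_equal(max(abs(as.matrix(ape::cophenetic.phylo(tr))[rownames(d),
                                                            rownames(d)] - d)),
               0)
  # topology: A,B form a cherry
  expect_equal(as.numeric(ape::dist.topo(ape::unroot(tr),
    ape::read.tree(text = "((A:1,B:2):1,C:3,D:1);"))), 0)

  # 3 taxa: closed-form star lengths
  d3 <- matrix(c(0, 2, 3, 2, 0, 4, 3, 4, 0), 3, 3,
               dimnames = list(letters[1:3], letters[1:3]))
  t3 <- nj_tree(d3)
  cp <- as.matrix(ape::cophenetic.phylo(t3))[letters[1:3], letters[1:3]]
  expect_equal(max(abs(cp - d3)), 0)

  # property: random additive trees up to 10 tips are reproduced exactly
  set.seed(19)
  for (i in 1:20) {
    n <- sample(4:10, 1)
    tr0 <- ape::rtree(n, br = function(k) runif(k, 0.2, 2))
    tr0 <- ape::unroot(tr0)
    d0 <- as.matrix(ape::cophenetic.phylo(tr0))
    tr1 <- nj_tree(d0)
    d1 <- as.matrix(ape::cophenetic.phylo(tr1))[rownames(d0), colnames(d0)]
    expect_lt(max(abs(d1 - d0)), 1e-8)
    expect_equal(as.numeric(ape::dist.topo(tr1, tr0)), 0)
  }
})

test_that("pcoa embeds planted configurations and conserves variance", {
  set.seed(41)
  # points on a line: axis 1 explains 100%
  x <- matrix(c(0, 1, 2, 5), ncol = 1)
  pc <- pcoa_analysis(as.matrix(dist(x)))
  expect_equal(pc$percent_variance[1], 100)

  # planted 2-D configuration reconstructed to 1e-9
  pts <- cbind(rnorm(12), rnorm(12))
  dd <- as.matrix(dist(pts))
  pc <- pcoa_analysis(dd)
  expect_lt(max(abs(as.matrix(dist(pc$coordinates[, 1:2])) - dd)), 1e-9)
  # sum of positive eigenvalues equals total squared centred coordinates
  cc <- scale(pts, scale = FALSE)
  expect_equal(sum(pc$eigenvalues[pc$eigenvalues > 1e-10]),
               sum(cc^2), tolerance = 1e-8)
  # axis sign convention: largest-magnitude loading is positive
  for (k in seq_len(ncol(pc$coordinates))) {
    v <- pc$coordinates[, k]
    expect_gte(v[which.max(abs(v))], 0)
  }
})

test_that("mantel_test handles exact, inverse and null relations", {
  set.seed(43)
  pts <- cbind(rnorm(10), rnorm(10))
  d1 <- as.matrix(dist(pts))
  # d2 = d1: r = 1, p = 1/(n_perm+1)
  mt <- mantel_test(d1, d1, n_perm = 99, seed = 5)
  expect_equal(mt$r, 1)
  expect_equal(mt$p, 1 / 100)
  # perfect negative linear transform: r = -1
  mt <- mantel_test(d1, max(d1) + 1 - d1 - diag(max(d1) + 1, nrow(d1)),
                    n_perm = 99, seed = 5)
  expect_equal(mt$r, -1)
  expect_error(mantel_test(d1, matrix(1, 10, 10) - diag(1, 10) * 0 + 0 * d1,
                           n_perm = 99, seed = 1), "constant")
  # determinism under the same seed
  d2 <- as.matrix(dist(cbind(rnorm(10), rnorm(10))))
  expect_identical(mantel_test(d1, d2, 199, seed = 7),
                   mantel_test(d1, d2, 199, seed = 7))
  # cross-check r against vegan on a random pair
  if (requireNamespace("vegan", quietly = TRUE)) {
    vm <- vegan::mantel(as.dist(d1), as.dist(d2), permutations = 99)
    expect_equal(mantel_test(d1, d2, 99, seed = 1)$r, unname(vm$statistic),
                 tolerance = 1e-12)
  }
})

test_that("haversine distances are metric-sane", {
  lat <- c(13.7, 18.8, 7.9); lon <- c(100.5, 98.9, 98.3)
  d <- haversine_matrix(lat, lon)
  expect_true(isSymmetric(d))
  expect_equal(diag(d), rep(0, 3))
  # Bangkok to Chiang Mai is roughly 580-600 km
  expect_gt(d[1, 2], 500); expect_lt(d[1, 2], 700)
})
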