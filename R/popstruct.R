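# Distance matrices, neighbor-joining, principal coordinates and the Mantel
# test over codominant genotype data.

#' Pairwise genetic distances between individuals
#'
#' Two codominant measures are provided. `nei1972`: Nei's standard distance
#' `D = -ln( Jxy / sqrt(Jx Jy) )`, where `Jxy` is the mean over co-genotyped
#' loci of `sum_i p_xi p_yi` with per-individual allele "frequencies" 0, 0.5
#' or 1. `shared_allele`: allele-sharing dissimilarity
#' `d = 1 - (1/L) sum_l s_l / 2`, with `s_l` the number of shared alleles
#' (multiset intersection, 0..2) at locus `l`. Loci missing in either
#' individual are dropped pairwise.
#'
#' @param gm a [genotype_matrix()].
#' @param measure `"shared_allele"` (default) or `"nei1972"`.
#' @return symmetric matrix with zero diagonal and attribute `measure`;
#'   entries are `NA` when a pair shares no co-genotyped locus.
#' @export
genetic_distance <- function(gm, measure = c("shared_allele", "nei1972")) {
  measure <- match.arg(measure)
  n <- length(gm$individuals)
  stopifnot(n >= 2)
  d <- matrix(0, n, n, dimnames = list(gm$individuals, gm$individuals))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      ok <- !is.na(gm$a1[i, ]) & !is.na(gm$a1[j, ])
      if (!any(ok)) { d[i, j] <- d[j, i] <- NA; next }
      if (measure == "shared_allele") {
        s <- vapply(which(ok), function(l) {
          x <- c(gm$a1[i, l], gm$a2[i, l]); y <- c(gm$a1[j, l], gm$a2[j, l])
          shared <- 0L
          for (a in x) {
            hit <- match(a, y)
            if (!is.na(hit)) { shared <- shared + 1L; y <- y[-hit] }
          }
          shared
        }, integer(1))
        d[i, j] <- d[j, i] <- 1 - mean(s) / 2
      } else {
        jxy <- jx <- jy <- numeric(sum(ok))
        for (t in seq_along(which(ok))) {
          l <- which(ok)[t]
          px <- ind_freqs(gm$a1[i, l], gm$a2[i, l])
          py <- ind_freqs(gm$a1[j, l], gm$a2[j, l])
          alle <- union(names(px), names(py))
          px <- px[alle]; py <- py[alle]
          px[is.na(px)] <- 0; py[is.na(py)] <- 0
          jxy[t] <- sum(px * py); jx[t] <- sum(px^2); jy[t] <- sum(py^2)
        }
        ratio <- mean(jxy) / sqrt(mean(jx) * mean(jy))
        d[i, j] <- d[j, i] <- if (ratio <= 0) Inf else -log(ratio)
      }
    }
  }
  attr(d, "measure") <- measure
  d
}

# Per-individual allele "frequency" vector: 1 for a homozygote's allele,
# 0.5 each for a heterozygote's two alleles.
ind_freqs <- function(a1, a2) {
  if (a1 == a2) stats::setNames(1, a1)
  else stats::setNames(c(0.5, 0.5), c(a1, a2))
}

#' Neighbor-joining tree
#'
#' Saitou-Nei agglomeration on a distance matrix: at each step the pair
#' minimising `Q(i,j) = (n-2) d(i,j) - R_i - R_j` (row sums `R`) is joined;
#' ties break toward the smallest row/column index pair in the current
#' matrix. Branch lengths follow the standard NJ formulas and the final
#' three nodes are joined by the closed-form star lengths.
#'
#' @param d symmetric distance matrix with labelled rows (n >= 3).
#' @return an unrooted `ape::phylo` tree with branch lengths.
#' @export
nj_tree <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  stopifnot(n >= 3, isSymmetric(unname(d)))
  labels <- rownames(d)
  if (is.null(labels)) labels <- paste0("t", seq_len(n))
  node <- labels  # newick fragment per active node
  while (n > 3) {
    R <- rowSums(d)
    q <- (n - 2) * d - outer(R, R, `+`)
    diag(q) <- Inf
    # ties break toward the lexicographically smallest (i, j)
    best <- Inf; bi <- bj <- 0L
    for (ii in 1:(n - 1)) for (jj in (ii + 1):n) {
      if (q[ii, jj] < best - 1e-12) { best <- q[ii, jj]; bi <- ii; bj <- jj }
    }
    li <- d[bi, bj] / 2 + (R[bi] - R[bj]) / (2 * (n - 2))
    lj <- d[bi, bj] - li
    dk <- (d[bi, ] + d[bj, ] - d[bi, bj]) / 2
    merged <- sprintf("(%s:%.10g,%s:%.10g)", node[bi], li, node[bj], lj)
    keep <- setdiff(seq_len(n), c(bi, bj))
    d_new <- rbind(cbind(d[keep, keep, drop = FALSE], dk[keep]),
                   c(dk[keep], 0))
    node <- c(node[keep], merged)
    rownames(d_new) <- colnames(d_new) <- seq_len(n - 1)
    d <- d_new
    n <- n - 1L
  }
  l1 <- (d[1, 2] + d[1, 3] - d[2, 3]) / 2
  l2 <- (d[1, 2] + d[2, 3] - d[1, 3]) / 2
  l3 <- (d[1, 3] + d[2, 3] - d[1, 2]) / 2
  nwk <- sprintf("(%s:%.10g,%s:%.10g,%s:%.10g);",
                 node[1], l1, node[2], l2, node[3], l3)
  ape::read.tree(text = nwk)
}

#' Principal coordinates analysis
#'
#' Classic metric multidimensional scaling: Gower double-centering of
#' `-d^2/2` followed by eigendecomposition. Negative eigenvalues are kept in
#' the report but excluded from the percent-variance denominator. Axis signs
#' are fixed by making each axis's largest-magnitude coordinate positive.
#'
#' @param d symmetric distance matrix, zero diagonal.
#' @return list with `coordinates` (individuals x axes, positive-eigenvalue
#'   axes only), `eigenvalues` (all, descending) and `percent_variance`.
#' @export
pcoa_analysis <- function(d) {
  d <- as.matrix(d)
  stopifnot(isSymmetric(unname(d)), all(abs(diag(d)) < 1e-12))
  n <- nrow(d)
  a <- -0.5 * d^2
  j <- diag(n) - matrix(1 / n, n, n)
  b <- j %*% a %*% j
  b <- (b + t(b)) / 2
  e <- eigen(b, symmetric = TRUE)
  pos <- e$values > max(e$values) * 1e-10
  coords <- e$vectors[, pos, drop = FALSE] %*%
    diag(sqrt(e$values[pos]), nrow = sum(pos))
  for (k in seq_len(ncol(coords))) {
    m <- which.max(abs(coords[, k]))
    if (coords[m, k] < 0) coords[, k] <- -coords[, k]
  }
  rownames(coords) <- rownames(d)
  colnames(coords) <- paste0("Axis", seq_len(ncol(coords)))
  pct <- 100 * e$values[pos] / sum(e$values[pos])
  list(coordinates = coords, eigenvalues = e$values,
       percent_variance = pct)
}

#' Mantel test between two distance matrices
#'
#' Pearson correlation of upper-triangle entries, with significance from
#' joint row/column permutations of the second matrix under a seeded
#' generator: `p = (#{perm r >= observed r} + 1) / (n_perm + 1)` (one-sided,
#' positive association).
#'
#' @param d1,d2 symmetric distance matrices over the same individuals in the
#'   same order.
#' @param n_perm number of permutations (>= 99; default 999).
#' @param seed integer seed for the permutation stream.
#' @return list with `r`, `p` and `n_permutations`.
#' @export
mantel_test <- function(d1, d2, n_perm = 999L, seed = 1L) {
  d1 <- as.matrix(d1); d2 <- as.matrix(d2)
  stopifnot(all(dim(d1) == dim(d2)), n_perm >= 99L)
  ut <- upper.tri(d1)
  x <- d1[ut]; y <- d2[ut]
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("Mantel correlation undefined for a constant matrix")
  r_obs <- stats::cor(x, y)
  n <- nrow(d1)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  perm_r <- vapply(seq_len(n_perm), function(i) {
    p <- sample.int(n)
    stats::cor(x, d2[p, p][ut])
  }, 0)
  list(r = r_obs,
       p = (sum(perm_r >= r_obs) + 1) / (n_perm + 1),
       n_permutations = n_perm)
}

#' Great-circle distance matrix from coordinates
#'
#' Haversine distances in kilometres between decimal-degree coordinates,
#' for use as the geographic matrix of a Mantel test.
#'
#' @param lat,lon numeric vectors of decimal degrees.
#' @return symmetric matrix of distances in km.
#' @export
haversine_matrix <- function(lat, lon) {
  stopifnot(length(lat) == length(lon))
  rad <- pi / 180
  n <- length(lat)
  d <- matrix(0, n, n)
  for (i in seq_len(n)) {
    dlat <- (lat - lat[i]) * rad / 2
    dlon <- (lon - lon[i]) * rad / 2
    h <- sin(dlat)^2 + cos(lat[i] * rad) * cos(lat * rad) * sin(dlon)^2
    d[i, ] <- 2 * 6371 * asin(pmin(1, sqrt(h)))
  }
  (d + t(d)) / 2
}
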