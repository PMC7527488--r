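# Build a record set directly (flanks + tract), bypassing read simulation.
# Separator bases break the repeat period at both tract boundaries so the
# detected count always equals the planted count.
flank_record <- function(left, motif, count, right, acc = "acc1", depth = 5L) {
  sep_l <- setdiff(c("A", "C", "G", "T"),
                   substr(motif, nchar(motif), nchar(motif)))[1]
  sep_r <- setdiff(c("A", "C", "G", "T"), substr(motif, 1, 1))[1]
  seq <- paste0(left, sep_l, strrep(motif, count), sep_r, right)
  h <- find_perfect_ssrs(seq)
  stopifnot(nrow(h) == 1L, h$repeat_count == count)
  data.frame(accession = acc, sequence = seq, depth = depth,
             masked = mask_ssr(seq, h$start, h$end),
             motif = h$motif, canonical_class = h$canonical_class,
             repeat_count = h$repeat_count,
             ssr_start = h$start, ssr_end = h$end, stringsAsFactors = FALSE)
}

test_that("mask_ssr replaces the tract and preserves flanks", {
  seq <- paste0("GG", strrep("TC", 11), "AA")
  expect_equal(mask_ssr(seq, 2, 24), "GG*AA")
  # allele-length invariance of the mask
  s8 <- paste0("GG", strrep("TC", 8), "AA")
  expect_equal(mask_ssr(s8, 2, 18), mask_ssr(seq, 2, 24))
  # empty left flank allowed
  expect_equal(mask_ssr(paste0(strrep("TC", 6), "AA"), 0, 12), "*AA")
})

test_that("cluster_ssr_loci groups same-locus alleles and splits loci", {
  set.seed(3)
  lf <- random_test_sequence(30); rf <- random_test_sequence(30)
  recs <- rbind(flank_record(lf, "TC", 8, rf, "a"),
                flank_record(lf, "TC", 11, rf, "b"))
  cl <- cluster_ssr_loci(recs, 0.90)
  expect_length(cl, 1L)
  expect_equal(sort(cl[[1]]$members$repeat_count), c(8L, 11L))

  # unrelated flanks: two clusters
  lf2 <- random_test_sequence(30); rf2 <- random_test_sequence(30)
  recs2 <- rbind(recs, flank_record(lf2, "CT", 9, rf2, "c"))
  expect_length(cluster_ssr_loci(recs2, 0.90), 2L)

  # different canonical class never merges even with identical flanks
  recs3 <- rbind(flank_record(lf, "TC", 8, rf, "a"),
                 flank_record(lf, "CAG", 6, rf, "b"))
  expect_length(cluster_ssr_loci(recs3, 0.90), 2L)

  # every record lands in exactly one cluster; order invariance
  set.seed(9)
  many <- do.call(rbind, lapply(1:12, function(i) {
    l <- random_test_sequence(30); r <- random_test_sequence(30)
    rbind(flank_record(l, "AG", 7 + i %% 3, r, "a"),
          flank_record(l, "AG", 9, r, "b"))
  }))
  c1 <- cluster_ssr_loci(many, 0.9)
  c2 <- cluster_ssr_loci(many[sample(nrow(many)), ], 0.9)
  expect_equal(sum(vapply(c1, function(x) nrow(x$members), 1L)), nrow(many))
  expect_equal(vapply(c1, function(x) x$centroid$masked, ""),
               vapply(c2, function(x) x$centroid$masked, ""))
})

test_that("greedy first-fit clusters by centroid identity, not completeness", {
  # b matches a (0.95) and c matches a (0.92), but c-b only 0.87: all three
  # still join the first centroid a (first-fit against centroids only)
  set.seed(21)
  base <- random_test_sequence(100)
  lf_a <- paste0("AA", substr(base, 3, 50))
  # force the to-be-mutated sites to A in a, mutate to T in b/c, so a sorts
  # first and remains the founding centroid
  sites_b <- c(3, 10, 20, 30); sites_c <- c(4, 11, 21, 31, 41, 45)
  v <- strsplit(lf_a, "")[[1]]; v[c(sites_b, sites_c)] <- "A"
  lf_a <- paste(v, collapse = "")
  mut <- function(s, at) {
    v <- strsplit(s, "")[[1]]; v[at] <- "T"; paste(v, collapse = "")
  }
  rf <- substr(base, 51, 80)
  a <- flank_record(lf_a, "TC", 8, rf, "x")
  b <- flank_record(mut(lf_a, sites_b), "TC", 8, rf, "y")
  c_ <- flank_record(mut(lf_a, sites_c), "TC", 8, rf, "z")
  id_ab <- ssrmine:::masked_identity(a$masked, b$masked)
  id_ac <- ssrmine:::masked_identity(a$masked, c_$masked)
  id_bc <- ssrmine:::masked_identity(b$masked, c_$masked)
  expect_true(id_ab >= 0.9 && id_ac >= 0.9 && id_bc < 0.9)
  cl <- cluster_ssr_loci(rbind(a, b, c_), 0.9)
  expect_length(cl, 1L)
  expect_equal(cl[[1]]$centroid$masked, a$masked)  # a sorts first (A prefix)
})

test_that("raising the identity threshold never decreases cluster count", {
  set.seed(13)
  recs <- do.call(rbind, lapply(1:8, function(i) {
    l <- random_test_sequence(30); r <- random_test_sequence(30)
    flank_record(l, "AG", 6 + i %% 4, r, paste0("acc", i))
  }))
  n_prev <- 0
  for (thr in c(0.5, 0.7, 0.9, 0.99)) {
    n <- length(cluster_ssr_loci(recs, thr))
    expect_gte(n, n_prev)
    n_prev <- n
  }
})

test_that("call_polymorphic requires two supported alleles", {
  mk <- function(members) list(cluster_id = 1L, members = members)
  mono <- mk(data.frame(accession = c("a", "b", "c"),
                        repeat_count = c(9L, 9L, 9L), depth = 5L))
  expect_false(call_polymorphic(mono)$polymorphic)

  two <- mk(data.frame(accession = c("a", "b"),
                       repeat_count = c(9L, 11L), depth = 5L))
  cp <- call_polymorphic(two)
  expect_true(cp$polymorphic)
  expect_equal(cp$alleles, c(9L, 11L))

  # heterozygous accession contributes both alleles
  het <- mk(data.frame(accession = c("a", "a", "b"),
                       repeat_count = c(9L, 11L, 9L), depth = 5L))
  cp <- call_polymorphic(het)
  expect_true(cp$polymorphic)
  expect_equal(cp$alleles, c(9L, 11L))

  # min_allele_obs raises the support requirement
  expect_false(call_polymorphic(het, min_allele_obs = 2L)$polymorphic)
  expect_equal(call_polymorphic(mk(data.frame(accession = character(),
                                              repeat_count = integer(),
                                              depth = integer())))$polymorphic,
               FALSE)
})

test_that("allele_table reports support and per-accession allele sets", {
  set.seed(31)
  lf <- random_test_sequence(30); rf <- random_test_sequence(30)
  recs <- rbind(flank_record(lf, "TC", 8, rf, "a"),
                flank_record(lf, "TC", 11, rf, "a"),
                flank_record(lf, "TC", 11, rf, "b"))
  cl <- cluster_ssr_loci(recs, 0.9)
  at <- allele_table(cl, accessions = c("a", "b", "c"))
  expect_equal(at$a, "8,11")
  expect_equal(at$b, "11")
  expect_equal(at$c, "")
  expect_equal(at$support, 2L)
  expect_equal(at$n_alleles, 2L)
})

test_that("select_marker_candidates applies support and product filters", {
  set.seed(17)
  mk_cluster <- function(id, accs, counts) {
    lf <- random_test_sequence(30); rf <- random_test_sequence(30)
    recs <- do.call(rbind, Map(function(a, ct)
      flank_record(lf, "TC", ct, rf, a), accs, counts))
    cl <- cluster_ssr_loci(recs, 0.9)
    cl[[1]]$cluster_id <- id
    cl[[1]]
  }
  fake_pair <- function(prod) structure(list(product_size = prod),
                                        class = "primer_pair")
  accs38 <- sprintf("a%02d", 1:38)
  clusters <- list(
    mk_cluster(1L, sprintf("a%02d", 1:19), rep(c(9, 11), length.out = 19)),
    mk_cluster(2L, accs38, rep(c(9, 11), length.out = 38)),
    mk_cluster(3L, accs38, rep(c(9, 11), length.out = 38)),
    mk_cluster(4L, accs38, rep(9, 38)),
    mk_cluster(5L, accs38, rep(c(9, 11), length.out = 38)))
  pairs <- list(fake_pair(90L), fake_pair(101L), fake_pair(90L),
                fake_pair(90L), structure(list(), class = "primer_failure"))
  sel <- select_marker_candidates(clusters, pairs)
  expect_equal(sel$selected, c(FALSE, FALSE, TRUE, FALSE, FALSE))
  expect_equal(sel$reason, c("support", "size", "", "monomorphic", "no_primer"))
  expect_equal(sel$supporting_accessions[1], 19L)
})
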