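test_that("melting temperature behaves like a nearest-neighbor model", {
  # printed panel anchor: CnSSR1 forward, Tm column 55, tolerance +/-3
  expect_lt(abs(melting_temperature("GCATGCACGAATAAGGATA") - 55), 3)
  # reverse complement symmetry of the duplex
  p <- "GCATGCACGAATAAGGATA"
  expect_equal(melting_temperature(p), melting_temperature(ssrmine:::revcomp(p)))
  # AT-only melts below GC-only at equal length
  expect_lt(melting_temperature(strrep("AT", 9)),
            melting_temperature(strrep("GC", 9)))
  # deterministic and vectorised
  expect_equal(melting_temperature(c(p, p)), rep(melting_temperature(p), 2))
  expect_error(melting_temperature("ACGTNACGT"), "A/C/G/T")
  expect_error(melting_temperature("ACGT"), "short")
})

test_that("printed primer panel validates against the design constraints", {
  m <- read.delim(system.file("extdata", "cnssr_markers.tsv",
                              package = "ssrmine"))
  primers <- c(m$forward, m$reverse)
  lens <- nchar(primers)
  gcs <- gc_content(primers)
  expect_true(all(lens >= 18 & lens <= 23))
  expect_true(all(gcs >= 30 & gcs <= 67))
  # full validator with the +/-3 C Tm slack: >= 95% of pairs pass GC+length,
  # and recomputed Tm agrees with the printed column within tolerance for
  # the overwhelming majority
  ok_tm <- abs(melting_temperature(primers) - rep(m$tm, 2)) <= 3
  expect_gte(mean(ok_tm), 0.85)
})

test_that("design_pair returns a valid pair on a feasible synthetic locus", {
  set.seed(2)
  # balanced 40-nt flanks around a (TC)11 tract
  repeat {
    lf <- random_test_sequence(40); rf <- random_test_sequence(40)
    if (max(ssrmine:::max_homopolymer_run(c(lf, rf))) <= 4 &&
        gc_content(lf) > 40 && gc_content(lf) < 60 &&
        gc_content(rf) > 40 && gc_content(rf) < 60) break
  }
  tmpl <- paste0(lf, strrep("TC", 11), rf)
  pp <- design_primer_pair(tmpl, 40L, 62L, 2L, 11L, alleles = c(9L, 11L))
  expect_s3_class(pp, "primer_pair")
  expect_true(all(validate_primer_pair(pp$forward, pp$reverse)))
  expect_true(pp$product_size >= 50 && pp$product_size <= 100)
  expect_true(pp$tm_f >= 52 && pp$tm_f <= 60)
  expect_true(pp$tm_r >= 52 && pp$tm_r <= 60)
  # determinism
  pp2 <- design_primer_pair(tmpl, 40L, 62L, 2L, 11L, alleles = c(9L, 11L))
  expect_identical(pp, pp2)
  # the reverse primer is the reverse complement of a window right of the SSR
  expect_true(grepl(ssrmine:::revcomp(pp$reverse), substr(tmpl, 63, nchar(tmpl)),
                    fixed = TRUE))
  # exhaustive-enumeration oracle: no window pair with a smaller penalty
  cons <- primer_constraints()
  fwd <- ssrmine:::candidate_windows(tmpl, 0L, 40L, cons, "forward")
  rv <- ssrmine:::candidate_windows(tmpl, 62L, nchar(tmpl), cons, "reverse")
  best <- Inf
  for (i in seq_len(nrow(fwd))) for (j in seq_len(nrow(rv))) {
    prod <- rv$end[j] - fwd$start[i]   # alleles max == centroid here
    if (prod < 50 || prod > 100) next
    if (ssrmine:::three_prime_complementarity(fwd$primer[i], rv$primer[j]) > 3 ||
        ssrmine:::three_prime_complementarity(rv$primer[j], fwd$primer[i]) > 3)
      next
    pen <- abs(fwd$tm[i] - 55) + abs(rv$tm[j] - 55) +
      abs(fwd$tm[i] - rv$tm[j]) + 0.1 * abs(prod - 75)
    best <- min(best, pen)
  }
  expect_lte(pp$penalty, best + 1e-9)
})

test_that("infeasible designs report their failing constraints", {
  tmpl <- paste0(strrep("A", 30), strrep("TC", 11), strrep("A", 30))
  pp <- design_primer_pair(tmpl, 30L, 52L, 2L, 11L)
  expect_s3_class(pp, "primer_failure")
  expect_true(any(attr(pp, "failures")))
})

test_that("expected product sizes shift by repeat-count difference", {
  pair <- structure(list(product_on_centroid = 84L, centroid_count = 11L,
                         motif_len = 2L), class = "primer_pair")
  expect_equal(expected_products(pair, c(9L, 11L)), c(80L, 84L))
  expect_equal(expected_products(pair, 11L), 84L)
  pair3 <- structure(list(product_on_centroid = 80L, centroid_count = 5L,
                          motif_len = 3L), class = "primer_pair")
  expect_equal(expected_products(pair3, c(5L, 9L)), c(80L, 92L))
})

test_that("3'-anchored complementarity counts consecutive pairs", {
  # last 4 bases of a (TCGA read 3'->5' as AGCT) pair with TCGA in b
  expect_gte(ssrmine:::three_prime_complementarity("AAAATCGA", "TTTCGATT"), 4L)
  expect_equal(ssrmine:::three_prime_complementarity("AAAAAAAA", "CCCCCCCC"), 0L)
})
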