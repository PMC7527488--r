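test_that("demultiplexing assigns, trims and rescues barcodes", {
  bcs <- barcode_map(c(ACGT = "acc1", TTGG = "acc2"))
  tail <- "CAGCAAATTCCGGAATT"

  r <- demultiplex_reads(make_read(paste0("ACGT", tail)), bcs, 0L)
  expect_equal(r$reads$accession, "acc1")
  expect_equal(r$reads$sequence, tail)
  expect_equal(nchar(r$reads$quality), nchar(tail))

  # unknown barcode at mm = 0
  r <- demultiplex_reads(make_read(paste0("ACGA", tail)), bcs, 0L)
  expect_equal(nrow(r$reads), 0L)
  expect_equal(r$discarded$reason, "unknown_barcode")

  # unique 1-mismatch rescue: ACGA is Hamming 1 from ACGT, 4 from TTGG
  r <- demultiplex_reads(make_read(paste0("ACGA", tail)), bcs, 1L)
  expect_equal(r$reads$accession, "acc1")

  # ambiguous within tolerance -> discarded with its own reason
  bcs2 <- barcode_map(c(ACGT = "acc1", ACGG = "acc2"))
  r <- demultiplex_reads(make_read(paste0("ACGC", tail)), bcs2, 1L)
  expect_equal(nrow(r$reads), 0L)
  expect_equal(r$discarded$reason, "ambiguous_barcode")

  # order independence
  reads <- rbind(make_read(paste0("ACGT", tail), id = "a"),
                 make_read(paste0("TTGG", tail), id = "b"),
                 make_read(paste0("GGGG", tail), id = "c"))
  fwd <- demultiplex_reads(reads, bcs, 1L)
  rev <- demultiplex_reads(reads[3:1, ], bcs, 1L)
  expect_equal(fwd$reads[order(fwd$reads$read_id), ],
               rev$reads[order(rev$reads$read_id), ],
               ignore_attr = TRUE)
})

test_that("barcode maps reject prefixes and duplicates", {
  expect_error(barcode_map(c(ACG = "a", ACGT = "b")), "prefix")
  expect_error(barcode_map(c(ACG = "a", ACG = "b")), "duplicated")
  expect_error(barcode_map(c(ACG = "a", TTG = "a")), "accession")
})

test_that("restriction remnant check matches CWGC at position 0 only", {
  expect_true(has_restriction_remnant("CAGCTTTT"))
  expect_true(has_restriction_remnant("CTGCAAAA"))
  expect_false(has_restriction_remnant("CCGCAAAA"))
  expect_false(has_restriction_remnant("AACAGCTT"))  # remnant not at 0
  expect_false(has_restriction_remnant("CAG"))       # shorter than pattern
  expect_equal(has_restriction_remnant(c("CAGCAA", "CCGCAA")),
               c(TRUE, FALSE))
})

test_that("quality filter applies sliding-window mean and N rule", {
  expect_true(passes_quality_filter(make_read(strrep("A", 100), q = 40)))
  # one bad window of Q2
  qual <- paste0(qstring(40, 50), qstring(2, 20), qstring(40, 30))
  bad <- gbs_reads("r", strrep("A", 100), qual)
  expect_false(passes_quality_filter(bad))
  # boundary: mean exactly at the threshold is retained (strict < discards)
  expect_true(passes_quality_filter(make_read(strrep("A", 100), q = 10)))
  expect_false(passes_quality_filter(make_read(strrep("A", 100), q = 9)))
  # uncalled base
  expect_false(passes_quality_filter(make_read(paste0("AANAA", strrep("A", 95)),
                                               q = 40)))
})

test_that("truncation enforces a uniform length and drops short reads", {
  reads <- rbind(make_read(strrep("A", 96), id = "long"),
                 make_read(strrep("C", 85), id = "short"),
                 make_read(strrep("G", 90), id = "exact"))
  tr <- truncate_reads(reads, 90L)
  expect_equal(tr$n_dropped, 1L)
  expect_equal(sort(tr$reads$read_id), c("exact", "long"))
  expect_true(all(nchar(tr$reads$sequence) == 90L))
  expect_true(all(nchar(tr$reads$quality) == 90L))
})

test_that("preprocess accounting sums to the raw read count", {
  bcs <- c(ACGT = "acc1", TTGG = "acc2")
  good <- paste0("CAGC", strrep("AT", 45))  # 94 bases, remnant ok
  reads <- rbind(
    make_read(paste0("ACGT", good), id = "keep1"),
    make_read(paste0("TTGG", good), id = "keep2"),
    make_read(paste0("GGCC", good), id = "badbc"),
    make_read(paste0("ACGT", "GGGG", strrep("AT", 45)), id = "badsite"),
    gbs_reads("badq", paste0("ACGT", good), qstring(2, 98)),
    make_read(paste0("ACGT", "CAGCAT"), id = "short"))
  pp <- preprocess_reads(reads, bcs, target_length = 90L)
  expect_equal(sum(pp$report$raw), 6L)
  expect_equal(sum(pp$report$retained), 2L)
  expect_equal(sum(pp$report$discarded_barcode), 1L)
  expect_equal(sum(pp$report$discarded_site), 1L)
  expect_equal(sum(pp$report$discarded_quality), 1L)
  expect_equal(sum(pp$report$discarded_length), 1L)
  with(pp$report, expect_equal(raw, retained + discarded_barcode +
                                 discarded_site + discarded_quality +
                                 discarded_length))
})

test_that("FASTQ round trip preserves sequences and qualities byte-identically", {
  reads <- gbs_reads(c("x", "y"),
                     c("CAGCATTGGC", "CTGCAAGGTT"),
                     c(paste0(qstring(30, 5), qstring(15, 5)), qstring(40, 10)))
  f <- tempfile(fileext = ".fastq")
  write_fastq(reads, f)
  back <- read_fastq(f)
  expect_equal(back$read_id, reads$read_id)
  expect_equal(back$sequence, reads$sequence)
  expect_equal(back$quality, reads$quality)
  # gzip round trip too
  fz <- tempfile(fileext = ".fastq.gz")
  write_fastq(reads, fz)
  expect_equal(read_fastq(fz)$sequence, reads$sequence)
})
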