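# Demultiplexing, restriction-site verification and quality filtering:
# the process_radtags-equivalent stage of the pipeline.

IUPAC_REGEX <- c(A = "A", C = "C", G = "G", T = "T",
                 R = "[AG]", Y = "[CT]", S = "[CG]", W = "[AT]",
                 K = "[GT]", M = "[AC]", B = "[CGT]", D = "[AGT]",
                 H = "[ACT]", V = "[ACG]", N = "[ACGT]")

iupac_to_regex <- function(pattern) {
  chars <- strsplit(toupper(pattern), "")[[1]]
  bad <- setdiff(chars, names(IUPAC_REGEX))
  if (length(bad)) stop("not an IUPAC pattern: ", pattern)
  paste0(IUPAC_REGEX[chars], collapse = "")
}

# Hamming distances between the length-L prefixes of `seqs` and barcode `bc`.
prefix_mismatches <- function(seqs, bc) {
  L <- nchar(bc)
  pref <- substr(seqs, 1L, L)
  short <- nchar(seqs) < L
  m <- matrix(unlist(strsplit(pref, ""), use.names = FALSE), nrow = L)
  d <- colSums(m != strsplit(bc, "")[[1]])
  d[short] <- L  # too short to carry this barcode
  d
}

#' Demultiplex reads by inline barcode
#'
#' Assigns each read to an accession by matching the read prefix against the
#' barcode map, trimming the barcode on success. A read with no exact match
#' may be rescued by a unique barcode within `max_mismatch` substitutions;
#' if two or more barcodes lie within tolerance the read is discarded as
#' ambiguous rather than guessed.
#'
#' @param reads a [gbs_reads()] table.
#' @param barcodes a validated [barcode_map()].
#' @param max_mismatch 0 or 1 allowed barcode mismatches (default 1).
#' @return a list with `reads` (assigned, barcode-trimmed reads) and
#'   `discarded`, a data.frame of read ids with reason `unknown_barcode` or
#'   `ambiguous_barcode`.
#' @export
demultiplex_reads <- function(reads, barcodes, max_mismatch = 1L) {
  barcodes <- barcode_map(barcodes)
  stopifnot(max_mismatch %in% c(0L, 1L))
  if (!nrow(reads)) {
    return(list(reads = reads,
                discarded = data.frame(read_id = character(), reason = character())))
  }
  bcs <- names(barcodes)
  d <- vapply(bcs, function(b) prefix_mismatches(reads$sequence, b),
              numeric(nrow(reads)))
  d <- matrix(d, nrow = nrow(reads))
  best <- apply(d, 1L, min)
  n_at_best <- rowSums(d == best)
  exact <- best == 0L                       # exact prefix match (unique: prefix-free map)
  rescued <- !exact & best <= max_mismatch & n_at_best == 1L
  ambiguous <- !exact & best <= max_mismatch & n_at_best > 1L
  keep <- exact | rescued
  which_bc <- apply(d[keep, , drop = FALSE], 1L, which.min)
  bc <- bcs[which_bc]
  kept <- reads[keep, , drop = FALSE]
  kept$accession <- unname(barcodes[bc])
  kept$sequence <- substring(kept$sequence, nchar(bc) + 1L)
  kept$quality  <- substring(kept$quality,  nchar(bc) + 1L)
  reason <- ifelse(ambiguous[!keep], "ambiguous_barcode", "unknown_barcode")
  list(reads = kept,
       discarded = data.frame(read_id = reads$read_id[!keep], reason = reason,
                              stringsAsFactors = FALSE))
}

#' Check the restriction-site remnant
#'
#' After barcode trimming, a genuine GBS read begins with the remnant of the
#' restriction site (for ApeKI, G^CWGC leaves `CWGC` at position 0).
#' Reads whose first bases do not match the IUPAC remnant pattern are
#' sequencing artifacts and are discarded upstream.
#'
#' @param sequences character vector of barcode-trimmed sequences.
#' @param remnant IUPAC pattern expected at position 0 (default `"CWGC"`).
#' @return logical vector; `FALSE` for reads shorter than the pattern.
#' @export
has_restriction_remnant <- function(sequences, remnant = "CWGC") {
  rx <- paste0("^", iupac_to_regex(remnant))
  nchar(sequences) >= nchar(remnant) & grepl(rx, sequences)
}

#' Sliding-window quality filter
#'
#' A read is discarded when any sliding window of `ceiling(window_fraction *
#' length)` bases has mean Phred quality strictly below `min_mean_q`, or when
#' it contains an uncalled base (N). Defaults mirror the common raw-read
#' filter of RAD/GBS demultiplexers: 15% window, mean Q10.
#'
#' @param reads a [gbs_reads()] table.
#' @param window_fraction window size as a fraction of read length, in (0, 1].
#' @param min_mean_q discard threshold on the window mean Phred score.
#' @return logical vector, `TRUE` for reads to keep.
#' @export
passes_quality_filter <- function(reads, window_fraction = 0.15, min_mean_q = 10) {
  stopifnot(window_fraction > 0, window_fraction <= 1)
  has_n <- grepl("N", reads$sequence, fixed = TRUE)
  ok <- vapply(seq_len(nrow(reads)), function(i) {
    q <- utf8ToInt(reads$quality[i]) - 33L
    w <- as.integer(ceiling(window_fraction * length(q)))
    if (w >= length(q)) return(mean(q) >= min_mean_q)
    cs <- cumsum(c(0L, q))
    means <- (cs[(w + 1L):length(cs)] - cs[1L:(length(cs) - w)]) / w
    all(means >= min_mean_q)
  }, logical(1))
  ok & !has_n
}

#' Truncate reads to a uniform length
#'
#' Exact-sequence stacking requires all reads to share one length; reads are
#' cut down to `target_length` and shorter reads are dropped.
#'
#' @param reads a [gbs_reads()] table.
#' @param target_length final read length in bases.
#' @return a list with `reads` (truncated) and `n_dropped`.
#' @export
truncate_reads <- function(reads, target_length) {
  keep <- nchar(reads$sequence) >= target_length
  out <- reads[keep, , drop = FALSE]
  out$sequence <- substr(out$sequence, 1L, target_length)
  out$quality  <- substr(out$quality,  1L, target_length)
  list(reads = out, n_dropped = sum(!keep))
}

#' Preprocess raw GBS reads
#'
#' Runs the full read-cleaning stage: demultiplexing with barcode trimming,
#' restriction-remnant verification, sliding-window quality filtering, and
#' truncation to a uniform length. Returns the retained reads together with a
#' per-accession accounting report whose categories sum exactly to the raw
#' read count.
#'
#' @param reads a [gbs_reads()] table of raw reads (barcodes still attached).
#' @param barcodes a [barcode_map()].
#' @param remnant IUPAC remnant pattern at position 0 (default `"CWGC"`).
#' @param max_mismatch allowed barcode mismatches (0 or 1).
#' @param window_fraction,min_mean_q see [passes_quality_filter()].
#' @param target_length uniform post-trim length; `NULL` keeps reads untrimmed.
#' @return list with `reads` (clean reads) and `report` (a data.frame with a
#'   row per accession plus an `unassigned` row).
#' @export
preprocess_reads <- function(reads, barcodes, remnant = "CWGC",
                             max_mismatch = 1L,
                             window_fraction = 0.15, min_mean_q = 10,
                             target_length = 90L) {
  n_raw <- nrow(reads)
  dm <- demultiplex_reads(reads, barcodes, max_mismatch)
  x <- dm$reads
  site_ok <- has_restriction_remnant(x$sequence, remnant)
  x_site <- x[site_ok, , drop = FALSE]
  qual_ok <- passes_quality_filter(x_site, window_fraction, min_mean_q)
  x_qual <- x_site[qual_ok, , drop = FALSE]
  if (!is.null(target_length)) {
    tr <- truncate_reads(x_qual, target_length)
    clean <- tr$reads
    short_acc <- x_qual$accession[nchar(x_qual$sequence) < target_length]
  } else {
    clean <- x_qual
    short_acc <- character()
  }

  accs <- sort(unique(unname(barcodes)))
  tab <- function(a) {
    t <- table(factor(a, levels = accs))
    as.integer(t)
  }
  report <- data.frame(
    accession = c(accs, "unassigned"),
    raw = NA_integer_,
    retained = c(tab(clean$accession), 0L),
    discarded_barcode = c(rep(0L, length(accs)), nrow(dm$discarded)),
    discarded_site = c(tab(x$accession[!site_ok]), 0L),
    discarded_quality = c(tab(x_site$accession[!qual_ok]), 0L),
    discarded_length = c(tab(short_acc), 0L),
    stringsAsFactors = FALSE
  )
  report$raw <- report$retained + report$discarded_barcode +
    report$discarded_site + report$discarded_quality + report$discarded_length
  report$nucleotides <- c(vapply(accs, function(a)
    sum(nchar(clean$sequence[clean$accession == a])), numeric(1)), 0)
  stopifnot(sum(report$raw) == n_raw)
  list(reads = clean, report = report)
}
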