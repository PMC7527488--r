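# MISA-equivalent detection of perfect microsatellites (SSRs) and canonical
# motif-class normalisation.

#' Default minimum repeat counts per motif length
#'
#' Perfect SSR tracts are reported when the number of complete motif
#' iterations reaches the class threshold: 6 for dinucleotides and 5 for
#' tri- to hexanucleotides. Mononucleotide runs are never reported.
#'
#' @param di,tri,tetra,penta,hexa minimum complete repeats per motif length.
#' @return named integer vector indexed by motif length "2".."6".
#' @export
ssr_thresholds <- function(di = 6L, tri = 5L, tetra = 5L, penta = 5L, hexa = 5L) {
  th <- c(`2` = di, `3` = tri, `4` = tetra, `5` = penta, `6` = hexa)
  if (any(th < 2L)) stop("thresholds must be >= 2")
  th
}

# TRUE if motif is not a repetition of a shorter motif.
is_primitive_motif <- function(motif) {
  k <- nchar(motif)
  for (p in seq_len(k - 1L)) {
    if (k %% p == 0L &&
        motif == strrep(substr(motif, 1L, p), k / p)) return(FALSE)
  }
  TRUE
}

#' Find all maximal perfect SSR tracts in a sequence
#'
#' Scans for maximal tandem repeats of primitive motifs of length 2-6.
#' A tract is reported from the leftmost base of its maximal period-k
#' region; only complete motif iterations count toward `repeat_count`
#' (partial trailing motifs are ignored), so `end - start ==
#' repeat_count * nchar(motif)`. Regions whose motif is itself a repetition
#' of a shorter motif (e.g. `ATAT`) are left to the shorter, primitive
#' motif. Uncalled bases (N) break tracts. Coordinates are 0-based,
#' half-open.
#'
#' @param sequence a single DNA string (A/C/G/T/N).
#' @param thresholds minimum repeat counts, see [ssr_thresholds()].
#' @param source_id identifier copied into the result (default "seq").
#' @return data.frame with columns `source_id`, `motif`, `canonical_class`,
#'   `repeat_count`, `start`, `end`, `tract`, sorted by `start` then motif
#'   length.
#' @export
find_perfect_ssrs <- function(sequence, thresholds = ssr_thresholds(),
                              source_id = "seq") {
  stopifnot(length(sequence) == 1L)
  sequence <- toupper(sequence)
  s <- strsplit(sequence, "")[[1]]
  n <- length(s)
  hits <- list()
  for (k in as.integer(names(thresholds))) {
    thr <- thresholds[[as.character(k)]]
    if (n < k * thr) next
    idx <- seq_len(n - k)
    b <- s[idx] == s[idx + k] & s[idx] != "N" & s[idx + k] != "N"
    r <- rle(b)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    runs <- which(r$values)
    for (j in runs) {
      region_start <- starts[j]            # 1-based position of first base
      region_len <- r$lengths[j] + k       # bases covered by the period-k region
      count <- region_len %/% k
      if (count < thr) next
      motif <- substr(sequence, region_start, region_start + k - 1L)
      if (!is_primitive_motif(motif)) next
      hits[[length(hits) + 1L]] <- data.frame(
        source_id = source_id, motif = motif,
        canonical_class = canonical_class(motif),
        repeat_count = count,
        start = region_start - 1L,
        end = region_start - 1L + count * k,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(hits)) {
    return(data.frame(source_id = character(), motif = character(),
                      canonical_class = character(), repeat_count = integer(),
                      start = integer(), end = integer(), tract = character(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, hits)
  out <- out[order(out$start, nchar(out$motif)), , drop = FALSE]
  out$tract <- substring(sequence, out$start + 1L, out$end)
  rownames(out) <- NULL
  out
}

#' Find SSRs across many sequences
#'
#' @param sequences named character vector of DNA sequences.
#' @param thresholds see [ssr_thresholds()].
#' @return row-bound [find_perfect_ssrs()] results.
#' @export
find_ssrs_in_set <- function(sequences, thresholds = ssr_thresholds()) {
  ids <- names(sequences)
  if (is.null(ids)) ids <- as.character(seq_along(sequences))
  do.call(rbind, lapply(seq_along(sequences), function(i)
    find_perfect_ssrs(sequences[[i]], thresholds, source_id = ids[i])))
}

revcomp <- function(x) {
  chartr("ACGT", "TGCA",
         vapply(x, function(s) paste(rev(strsplit(s, "")[[1]]), collapse = ""),
                "", USE.NAMES = FALSE))
}

rotations <- function(m) {
  k <- nchar(m)
  vapply(seq_len(k), function(i)
    paste0(substr(m, i, k), substr(m, 1L, i - 1L)), "")
}

#' Canonical motif class
#'
#' Motifs that are cyclic rotations or reverse complements of one another
#' describe the same repeat (e.g. GA, AG, TC and CT all read as the AG/CT
#' class). The class representative is the lexicographically smallest string
#' among all rotations of the motif and of its reverse complement; the label
#' joins it with its reverse complement, e.g. `"AG/CT"` (`"AT/AT"` for
#' self-complementary motifs).
#'
#' @param motif primitive motif of length 2-6.
#' @return the class label string.
#' @export
canonical_class <- function(motif) {
  if (length(motif) > 1L)
    return(vapply(motif, canonical_class, "", USE.NAMES = FALSE))
  motif <- toupper(motif)
  stopifnot(nchar(motif) >= 2L, nchar(motif) <= 6L, grepl("^[ACGT]+$", motif))
  if (!is_primitive_motif(motif)) stop("motif is not primitive: ", motif)
  rep_ <- min(c(rotations(motif), rotations(revcomp(motif))))
  paste0(rep_, "/", revcomp(rep_))
}

#' Summarise SSR hits by motif-length class and repeat-count bin
#'
#' Reproduces the standard mining summary: counts per class (di- through
#' hexanucleotide) across repeat-count bins 5, 6, 7, 8, 9, 10 and >10, class
#' totals, and class frequency percentages (100 x class total / grand total,
#' two decimals).
#'
#' @param hits a data.frame of hits (needs `motif`, `repeat_count`).
#' @return list with `counts` (class x bin matrix), `totals`, `frequency`.
#' @export
summarize_ssrs <- function(hits) {
  classes <- c(`2` = "Dinucleotide", `3` = "Trinucleotide",
               `4` = "Tetranucleotide", `5` = "Pentanucleotide",
               `6` = "Hexanucleotide")
  bins <- c("5", "6", "7", "8", "9", "10", ">10")
  counts <- matrix(0L, nrow = length(classes), ncol = length(bins),
                   dimnames = list(unname(classes), bins))
  if (nrow(hits)) {
    k <- as.character(nchar(hits$motif))
    bin <- ifelse(hits$repeat_count > 10L, ">10",
                  as.character(pmax(hits$repeat_count, 5L)))
    t <- table(factor(classes[k], levels = classes),
               factor(bin, levels = bins))
    counts <- counts + unclass(t)
  }
  totals <- rowSums(counts)
  grand <- sum(totals)
  freq <- if (grand > 0) round(100 * totals / grand, 2) else totals * 0
  list(counts = counts, totals = totals, frequency = freq, grand_total = grand)
}

#' Write SSR hits as a MISA-style table
#'
#' Columns mirror the classic MISA output: ID, SSR nr., type (p2..p6), the
#' SSR written as `(MOTIF)count`, size, start and end. File coordinates are
#' 1-based inclusive for MISA compatibility; in-memory coordinates stay
#' 0-based half-open.
#'
#' @param hits [find_perfect_ssrs()] output.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_misa <- function(hits, path) {
  nr <- stats::ave(seq_len(nrow(hits)), hits$source_id, FUN = seq_along)
  df <- data.frame(
    ID = hits$source_id,
    `SSR nr.` = nr,
    type = paste0("p", nchar(hits$motif)),
    SSR = sprintf("(%s)%d", hits$motif, hits$repeat_count),
    size = hits$end - hits$start,
    start = hits$start + 1L,
    end = hits$end,
    check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
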