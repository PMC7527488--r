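#' Read a FASTQ file into a read table
#'
#' Reads single-end GBS reads (optionally gzipped) into a plain data frame
#' with one row per read. Sequences are uppercased; qualities are kept as
#' Phred+33 encoded strings of the same length as the sequence.
#'
#' @param path path to a FASTQ or FASTQ.gz file.
#' @return a data.frame with columns `read_id`, `sequence`, `quality` and
#'   `accession` (initially `NA`; filled in by [demultiplex_reads()]).
#' @export
read_fastq <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path, format = "fastq", with.qualities = TRUE)
  quals <- as.character(S4Vectors::mcols(seqs)$qualities)
  gbs_reads(
    read_id  = names(seqs),
    sequence = toupper(as.character(seqs)),
    quality  = quals
  )
}

#' Write a read table to FASTQ
#'
#' @param reads a read table as returned by [read_fastq()].
#' @param path output path; a `.gz` suffix triggers gzip compression.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  x <- Biostrings::DNAStringSet(reads$sequence)
  names(x) <- reads$read_id
  q <- Biostrings::BStringSet(reads$quality)
  Biostrings::writeXStringSet(x, path, format = "fastq", qualities = q,
                              compress = grepl("\\.gz$", path))
  invisible(path)
}

#' Construct a read table
#'
#' A read table is the unit of preprocessing: a data frame with one row per
#' single-end read, carrying the DNA sequence, the per-base Phred+33 quality
#' string, and (after demultiplexing) the accession the read belongs to.
#'
#' @param read_id character vector of read identifiers.
#' @param sequence character vector of DNA sequences (A/C/G/T/N).
#' @param quality character vector of Phred+33 quality strings, same lengths
#'   as `sequence`.
#' @param accession accession identifiers, or `NA` before demultiplexing.
#' @return a `data.frame` of class `gbs_reads`.
#' @export
gbs_reads <- function(read_id, sequence, quality, accession = NA_character_) {
  stopifnot(length(read_id) == length(sequence),
            length(sequence) == length(quality))
  if (length(sequence) && any(nchar(sequence) != nchar(quality)))
    stop("sequence and quality lengths differ")
  out <- data.frame(read_id = as.character(read_id),
                    sequence = as.character(sequence),
                    quality = as.character(quality),
                    accession = rep_len(as.character(accession), length(read_id)),
                    stringsAsFactors = FALSE)
  class(out) <- c("gbs_reads", "data.frame")
  out
}

#' Read a barcode map
#'
#' The barcode map assigns an inline barcode (which may vary in length) to
#' each accession. Barcodes must be prefix-free: no barcode may be a prefix
#' of another, or demultiplexing would be ambiguous by construction.
#'
#' @param path TSV with columns `barcode` and `accession`.
#' @return a named character vector, `barcode -> accession`.
#' @export
read_barcode_map <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, colClasses = "character")
  stopifnot(all(c("barcode", "accession") %in% names(df)))
  barcode_map(stats::setNames(df$accession, toupper(df$barcode)))
}

#' Validate a barcode map
#'
#' @param map named character vector, names are barcodes, values accessions.
#' @return the validated map.
#' @export
barcode_map <- function(map) {
  bcs <- names(map)
  if (is.null(bcs) || !length(map)) stop("barcode map is empty")
  if (anyDuplicated(bcs)) stop("duplicated barcodes")
  if (anyDuplicated(map)) stop("duplicated accession identifiers")
  if (!all(grepl("^[ACGT]+$", bcs))) stop("barcodes must be A/C/G/T")
  # prefix-freeness
  for (i in seq_along(bcs)) {
    pref <- startsWith(bcs[-i], bcs[i])
    if (any(pref)) stop("barcode ", bcs[i], " is a prefix of ", bcs[-i][pref][1])
  }
  map
}
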