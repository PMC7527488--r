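# Reference-free read stacking and cross-accession locus cataloguing:
# the ustacks/cstacks-equivalent stage.

# Hamming distance between equal-length strings a (vector) and b (scalar).
hamming_to <- function(seqs, b) {
  if (!length(seqs)) return(integer())
  L <- nchar(b)
  stopifnot(all(nchar(seqs) == L))
  m <- matrix(unlist(strsplit(seqs, ""), use.names = FALSE), nrow = L)
  as.integer(colSums(m != strsplit(b, "")[[1]]))
}

#' Collapse one accession's reads into unique-read stacks
#'
#' Exact-duplicate reads collapse into a stack whose depth is the number of
#' supporting reads. Stacks below `min_depth` are either absorbed into a
#' deep stack (depth added, the deep stack's sequence kept) when exactly one
#' deep stack lies within `merge_distance` substitutions, or dropped. The
#' result is sorted by depth (descending) then sequence, which makes every
#' downstream greedy step order-independent.
#'
#' @param reads a [gbs_reads()] table, single accession, uniform read length.
#' @param min_depth minimum reads supporting a retained stack (default 2).
#' @param merge_distance absorption radius in substitutions, 0..2 (default 1).
#' @return data.frame with columns `sequence`, `depth`, `accession`.
#' @export
build_stacks <- function(reads, min_depth = 2L, merge_distance = 1L) {
  stopifnot(min_depth >= 1L, merge_distance %in% 0:2)
  acc <- unique(reads$accession)
  if (length(acc) > 1L) stop("build_stacks expects reads from one accession")
  if (length(unique(nchar(reads$sequence))) > 1L)
    stop("build_stacks expects uniform read length")
  if (!nrow(reads)) {
    return(data.frame(sequence = character(), depth = integer(),
                      accession = character()))
  }
  tab <- table(reads$sequence)
  stacks <- data.frame(sequence = names(tab), depth = as.integer(tab),
                       stringsAsFactors = FALSE)
  deep <- stacks[stacks$depth >= min_depth, , drop = FALSE]
  sub <- stacks[stacks$depth < min_depth, , drop = FALSE]
  if (nrow(sub) && nrow(deep) && merge_distance > 0L) {
    for (i in seq_len(nrow(sub))) {
      d <- hamming_to(deep$sequence, sub$sequence[i])
      hit <- which(d <= merge_distance)
      if (length(hit) == 1L) deep$depth[hit] <- deep$depth[hit] + sub$depth[i]
    }
  }
  deep <- deep[order(-deep$depth, deep$sequence), , drop = FALSE]
  rownames(deep) <- NULL
  deep$accession <- if (length(acc)) acc else NA_character_
  deep
}

# Depth-weighted per-position majority consensus; ties broken A < C < G < T.
consensus_sequence <- function(sequences, depths) {
  L <- nchar(sequences[1])
  m <- matrix(unlist(strsplit(sequences, ""), use.names = FALSE), nrow = L)
  bases <- c("A", "C", "G", "T")
  counts <- vapply(bases, function(b) {
    rowSums(sweep(m == b, 2, depths, `*`))
  }, numeric(L))
  counts <- matrix(counts, nrow = L)
  paste0(bases[max.col(counts, ties.method = "first")], collapse = "")
}

#' Merge per-accession stacks into a consensus locus catalog
#'
#' Greedy catalog construction over all accessions' stacks, processed in the
#' deterministic order (depth descending, sequence ascending, accession
#' ascending): a stack joins the first existing locus whose consensus lies
#' within `catalog_mismatch` substitutions, otherwise it founds a new locus.
#' The consensus is the depth-weighted per-position majority over member
#' sequences (ties broken by base order A < C < G < T) and is refreshed as
#' members join. Locus ids are assigned in founding order.
#'
#' @param stacks_by_accession a list of [build_stacks()] outputs, or one
#'   combined data.frame with an `accession` column.
#' @param catalog_mismatch merge radius in substitutions, 0..2 (default 0).
#' @return a `ssr_catalog`: list of loci, each with `locus_id`, `consensus`
#'   and `members` (data.frame `accession`, `sequence`, `depth`, `mismatches`).
#' @export
build_catalog <- function(stacks_by_accession, catalog_mismatch = 0L) {
  stopifnot(catalog_mismatch %in% 0:2)
  stacks <- if (is.data.frame(stacks_by_accession)) stacks_by_accession
            else do.call(rbind, stacks_by_accession)
  if (!nrow(stacks)) return(structure(list(), class = "ssr_catalog"))
  if (length(unique(nchar(stacks$sequence))) > 1L)
    stop("catalog requires uniform sequence length")
  stacks <- stacks[order(-stacks$depth, stacks$sequence, stacks$accession), ,
                   drop = FALSE]
  loci <- list()
  consensi <- character()
  for (i in seq_len(nrow(stacks))) {
    s <- stacks[i, ]
    joined <- FALSE
    if (length(consensi)) {
      d <- hamming_to(consensi, s$sequence)
      hit <- which(d <= catalog_mismatch)
      if (length(hit)) {
        j <- hit[1L]
        loci[[j]]$members <- rbind(loci[[j]]$members,
          data.frame(accession = s$accession, sequence = s$sequence,
                     depth = s$depth, mismatches = d[j],
                     stringsAsFactors = FALSE))
        consensi[j] <- consensus_sequence(loci[[j]]$members$sequence,
                                          loci[[j]]$members$depth)
        loci[[j]]$consensus <- consensi[j]
        joined <- TRUE
      }
    }
    if (!joined) {
      loci[[length(loci) + 1L]] <- list(
        locus_id = length(loci) + 1L,
        consensus = s$sequence,
        members = data.frame(accession = s$accession, sequence = s$sequence,
                             depth = s$depth, mismatches = 0L,
                             stringsAsFactors = FALSE))
      consensi <- c(consensi, s$sequence)
    }
  }
  # final mismatch bookkeeping against the settled consensus
  for (j in seq_along(loci)) {
    loci[[j]]$members$mismatches <-
      hamming_to(loci[[j]]$members$sequence, loci[[j]]$consensus)
  }
  structure(loci, class = "ssr_catalog")
}

#' @export
print.ssr_catalog <- function(x, ...) {
  cat("ssr_catalog:", length(x), "consensus loci\n")
  invisible(x)
}

#' Write catalog consensus sequences as FASTA plus a membership table
#'
#' @param catalog an `ssr_catalog`.
#' @param fasta_path output FASTA of consensus sequences (`locus_<id>` headers).
#' @param members_path output TSV of locus membership.
#' @return `fasta_path`, invisibly.
#' @export
write_catalog <- function(catalog, fasta_path, members_path) {
  seqs <- Biostrings::DNAStringSet(vapply(catalog, `[[`, "", "consensus"))
  names(seqs) <- paste0("locus_", vapply(catalog, `[[`, 1L, "locus_id"))
  Biostrings::writeXStringSet(seqs, fasta_path)
  mem <- do.call(rbind, lapply(catalog, function(l)
    cbind(locus_id = l$locus_id, l$members)))
  utils::write.table(mem, members_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(fasta_path)
}
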