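# Flank-based clustering of SSR-bearing sequences across accessions
# (VSEARCH-equivalent), allele tables and marker-selection filters.

#' Mask an SSR tract with a single placeholder
#'
#' Replacing the variable-length repeat tract with one `*` makes sequences
#' carrying different allele lengths at the same locus identical over their
#' flanks, so identity clustering groups them.
#'
#' @param sequence DNA string.
#' @param start,end 0-based half-open tract coordinates.
#' @return the masked string.
#' @export
mask_ssr <- function(sequence, start, end) {
  stopifnot(start >= 0, end <= nchar(sequence), start < end)
  paste0(substr(sequence, 1L, start), "*",
         substr(sequence, end + 1L, nchar(sequence)))
}

#' Build SSR locus records from stacks and their SSR hits
#'
#' One record per (stack, hit): the masked sequence, the motif class and the
#' observed repeat count, tagged with the accession and the stack depth.
#'
#' @param stacks data.frame with `sequence`, `depth`, `accession`.
#' @param thresholds see [ssr_thresholds()].
#' @return data.frame of records suitable for [cluster_ssr_loci()].
#' @export
ssr_records <- function(stacks, thresholds = ssr_thresholds()) {
  recs <- lapply(seq_len(nrow(stacks)), function(i) {
    h <- find_perfect_ssrs(stacks$sequence[i], thresholds,
                           source_id = as.character(i))
    if (!nrow(h)) return(NULL)
    data.frame(accession = stacks$accession[i],
               sequence = stacks$sequence[i],
               depth = stacks$depth[i],
               masked = vapply(seq_len(nrow(h)), function(j)
                 mask_ssr(stacks$sequence[i], h$start[j], h$end[j]), ""),
               motif = h$motif,
               canonical_class = h$canonical_class,
               repeat_count = h$repeat_count,
               ssr_start = h$start, ssr_end = h$end,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, recs)
  if (is.null(out))
    out <- data.frame(accession = character(), sequence = character(),
                      depth = integer(), masked = character(),
                      motif = character(), canonical_class = character(),
                      repeat_count = integer(), ssr_start = integer(),
                      ssr_end = integer(), stringsAsFactors = FALSE)
  out
}

# Global end-gap-free identity between two masked strings: matched columns
# of the best end-gap-free alignment divided by the shorter sequence length
# (so a clean truncation of the same flank scores 1, while an incidental
# short overlap between unrelated flanks scores near 0).
#
# Fast paths: identical strings; ungapped comparison over the common prefix,
# which is itself a valid end-gap-free alignment and therefore a lower
# bound. The gapped alignment is only consulted in the uncertainty band
# below `threshold` (an ungapped identity under 0.35 is treated as a
# rejection: flanks differing by that much are different loci under the
# substitution-dominated error model this clustering targets).
masked_identity <- function(a, b, threshold = 1) {
  if (a == b) return(1)
  n <- min(nchar(a), nchar(b))
  av <- strsplit(substr(a, 1L, n), "")[[1]]
  bv <- strsplit(substr(b, 1L, n), "")[[1]]
  ungapped <- sum(av == bv) / n
  if (ungapped >= threshold) return(ungapped)
  if (ungapped < 0.35) return(ungapped)
  letters5 <- c("A", "C", "G", "T", "*")
  mat <- matrix(-1, 5, 5, dimnames = list(letters5, letters5))
  diag(mat) <- 1
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::BString(a), Biostrings::BString(b), type = "overlap",
    substitutionMatrix = mat, gapOpening = 0, gapExtension = 2)
  max(ungapped, Biostrings::nmatch(aln) / n)
}

#' Cluster masked SSR records into loci
#'
#' Greedy centroid clustering in the spirit of VSEARCH: records are processed
#' in a fixed order (masked length descending, then masked sequence, then
#' accession); each record joins the first centroid sharing its canonical
#' motif class whose global end-gap-free identity over the masked strings is
#' at least `identity_threshold`, otherwise it founds a new centroid.
#'
#' @param records data.frame from [ssr_records()].
#' @param identity_threshold minimum flank identity in (0, 1] (default 0.90).
#' @return an `ssr_clusters` list; each element has `cluster_id`, `centroid`
#'   (the founding record as a one-row data.frame) and `members` (data.frame
#'   of accession, repeat_count, depth, identity).
#' @export
cluster_ssr_loci <- function(records, identity_threshold = 0.90) {
  stopifnot(identity_threshold > 0, identity_threshold <= 1)
  if (!nrow(records)) return(structure(list(), class = "ssr_clusters"))
  ord <- order(-nchar(records$masked), records$masked, records$accession,
               records$repeat_count)
  records <- records[ord, , drop = FALSE]
  clusters <- list()
  cent_masked <- character(); cent_class <- character()
  for (i in seq_len(nrow(records))) {
    r <- records[i, , drop = FALSE]
    assigned <- FALSE
    for (j in seq_along(clusters)) {
      if (cent_class[j] != r$canonical_class) next
      if (masked_identity(r$masked, cent_masked[j],
                          identity_threshold) >= identity_threshold) {
        clusters[[j]]$members <- rbind(clusters[[j]]$members,
          data.frame(accession = r$accession, repeat_count = r$repeat_count,
                     depth = r$depth, stringsAsFactors = FALSE))
        assigned <- TRUE
        break
      }
    }
    if (!assigned) {
      clusters[[length(clusters) + 1L]] <- list(
        cluster_id = length(clusters) + 1L,
        centroid = r,
        members = data.frame(accession = r$accession,
                             repeat_count = r$repeat_count,
                             depth = r$depth, stringsAsFactors = FALSE))
      cent_masked <- c(cent_masked, r$masked)
      cent_class <- c(cent_class, r$canonical_class)
    }
  }
  structure(clusters, class = "ssr_clusters")
}

#' @export
print.ssr_clusters <- function(x, ...) {
  cat("ssr_clusters:", length(x), "SSR locus clusters\n")
  invisible(x)
}

#' Call a cluster polymorphic
#'
#' A locus is polymorphic when at least two distinct repeat-count alleles are
#' each observed in at least `min_allele_obs` accessions. Heterozygous
#' accessions may contribute two repeat counts.
#'
#' @param cluster one element of an `ssr_clusters` list.
#' @param min_allele_obs minimum accessions supporting an allele (default 1).
#' @return list with `polymorphic` (logical) and `alleles` (ascending counts
#'   meeting the support requirement; all observed counts in `observed`).
#' @export
call_polymorphic <- function(cluster, min_allele_obs = 1L) {
  m <- cluster$members
  if (is.null(m) || !nrow(m))
    return(list(polymorphic = FALSE, alleles = integer(), observed = integer()))
  per_allele <- tapply(m$accession, m$repeat_count,
                       function(a) length(unique(a)))
  counts <- as.integer(names(per_allele))
  supported <- sort(counts[per_allele >= min_allele_obs])
  list(polymorphic = length(supported) >= 2L,
       alleles = supported,
       observed = sort(unique(counts)))
}

#' Cross-accession allele table
#'
#' Rows are clusters, columns accessions; a cell holds the set of repeat
#' counts observed for that accession (comma-joined; empty string when the
#' accession has no SSR-spanning sequence at the locus). The `support`
#' attribute counts accessions with data per cluster.
#'
#' @param clusters an `ssr_clusters` list.
#' @param accessions column order; defaults to accessions seen in members.
#' @return data.frame `cluster_id`, `motif`, `canonical_class`, one column
#'   per accession, plus columns `support` and `n_alleles`.
#' @export
allele_table <- function(clusters, accessions = NULL) {
  if (is.null(accessions))
    accessions <- sort(unique(unlist(lapply(clusters,
      function(cl) cl$members$accession))))
  rows <- lapply(clusters, function(cl) {
    cells <- vapply(accessions, function(a) {
      cnt <- sort(unique(cl$members$repeat_count[cl$members$accession == a]))
      paste(cnt, collapse = ",")
    }, "")
    alle <- sort(unique(cl$members$repeat_count))
    c(cluster_id = cl$cluster_id, motif = cl$centroid$motif,
      canonical_class = cl$centroid$canonical_class, cells,
      support = sum(cells != ""), n_alleles = length(alle))
  })
  df <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
  df$cluster_id <- as.integer(df$cluster_id)
  df$support <- as.integer(df$support)
  df$n_alleles <- as.integer(df$n_alleles)
  df
}

#' Apply the marker-selection filters
#'
#' A cluster becomes a marker candidate when it is polymorphic, its designed
#' primer pair yields an expected PCR product (for the longest observed
#' allele) within `product_range`, and it is supported by SSR-spanning
#' sequences from at least `min_support` accessions. Every filter outcome is
#' recorded per cluster; clusters without a feasible primer pair are excluded
#' with reason `no_primer`.
#'
#' @param clusters an `ssr_clusters` list.
#' @param primer_pairs list parallel to `clusters`: [design_primer_pair()]
#'   results (or `NULL` where design failed).
#' @param min_support minimum supporting accessions (default 20).
#' @param product_range closed product-size interval in bp (default c(80, 100)).
#' @param min_allele_obs passed to [call_polymorphic()].
#' @return data.frame with per-cluster support, allele count, product size,
#'   individual filter flags, overall `selected`, and a `reason` string.
#' @export
select_marker_candidates <- function(clusters, primer_pairs,
                                     min_support = 20L,
                                     product_range = c(80L, 100L),
                                     min_allele_obs = 1L) {
  rows <- lapply(seq_along(clusters), function(i) {
    cl <- clusters[[i]]
    call <- call_polymorphic(cl, min_allele_obs)
    support <- length(unique(cl$members$accession))
    pp <- primer_pairs[[i]]
    pass_primer <- inherits(pp, "primer_pair")
    product <- if (pass_primer) pp$product_size else NA_integer_
    pass_poly <- call$polymorphic
    pass_support <- support >= min_support
    pass_product <- pass_primer && product >= product_range[1] &&
      product <= product_range[2]
    reason <- if (!pass_primer) "no_primer"
      else if (!pass_poly) "monomorphic"
      else if (!pass_support) "support"
      else if (!pass_product) "size"
      else ""
    data.frame(cluster_id = cl$cluster_id,
               motif = cl$centroid$motif,
               supporting_accessions = support,
               allele_count = length(call$alleles),
               alleles = paste(call$alleles, collapse = ","),
               product_size = product,
               pass_polymorphic = pass_poly,
               pass_support = pass_support,
               pass_product = pass_product,
               selected = pass_primer && pass_poly && pass_support && pass_product,
               reason = reason,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Write an allele table to TSV
#' @param table [allele_table()] output.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_allele_table <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
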