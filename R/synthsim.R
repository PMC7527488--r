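# Ground-truthed simulation of ApeKI GBS libraries over genomes with planted
# SSR loci: genome construction, diploid population sampling, in-silico
# digestion and error-bearing read generation.

APEKI_SITE <- "GC[AT]GC"

#' Simulation configuration
#'
#' The default configuration describes the validation world used throughout
#' the package: 20 accessions split into an outcrossing "tall" group
#' (inbreeding F = 0.1) and a predominantly selfing "dwarf" group (F = 0.9),
#' 50 planted SSR loci of which 30 are polymorphic, motif classes mixed
#' toward dinucleotides as observed in GBS mining, 100-bp reads at 15x depth
#' per locus and accession, and a 0.1% substitution error rate.
#'
#' @param n_accessions number of accessions (split evenly into tall/dwarf).
#' @param n_loci number of planted SSR loci.
#' @param n_polymorphic how many planted loci carry >= 2 alleles.
#' @param class_counts named integer vector of loci per motif length
#'   ("2".."6"); must sum to `n_loci`. By default the loci are apportioned
#'   by largest remainder across the class frequencies observed in GBS SSR
#'   mining (about 67% di-, 29% tri-, 3% tetra-, 0.5% penta-, 1%
#'   hexanucleotide), which gives 33/14/2/0/1 at the default 50 loci.
#' @param depth reads per locus per accession.
#' @param error_rate per-base substitution error probability.
#' @param read_length raw read length including the inline barcode.
#' @param barcode_length inline barcode length.
#' @param gc GC fraction of background sequence.
#' @param f_tall,f_dwarf inbreeding coefficients per group.
#' @param left_flank,fragment_length geometry of each planted locus fragment.
#' @param seed mandatory integer seed.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_accessions = 20L, n_loci = 50L, n_polymorphic = 30L,
                       class_counts = NULL,
                       depth = 15L, error_rate = 0.001,
                       read_length = 100L, barcode_length = 6L,
                       gc = 0.45, f_tall = 0.1, f_dwarf = 0.9,
                       left_flank = 25L, fragment_length = 200L,
                       seed) {
  if (missing(seed)) stop("sim_config requires an explicit seed")
  if (is.null(class_counts)) {
    frac <- c(`2` = 0.6667, `3` = 0.2888, `4` = 0.0290, `5` = 0.0051,
              `6` = 0.0105)
    base <- floor(frac * n_loci)
    rem <- n_loci - sum(base)
    # largest-remainder apportionment, ties toward shorter motifs
    extra <- order(frac * n_loci - base, -as.integer(names(frac)),
                   decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1L
    class_counts <- stats::setNames(as.integer(base), names(frac))
  }
  stopifnot(sum(class_counts) == n_loci, n_polymorphic <= n_loci,
            f_tall >= 0, f_tall <= 1, f_dwarf >= 0, f_dwarf <= 1,
            error_rate >= 0, error_rate < 1)
  half <- n_accessions %/% 2L
  accs <- sprintf("acc%02d", seq_len(n_accessions))
  groups <- data.frame(
    accession = accs,
    group = c(rep("tall", half), rep("dwarf", n_accessions - half)),
    f = c(rep(f_tall, half), rep(f_dwarf, n_accessions - half)),
    stringsAsFactors = FALSE)
  structure(list(n_accessions = n_accessions, n_loci = n_loci,
                 n_polymorphic = n_polymorphic, class_counts = class_counts,
                 depth = depth, error_rate = error_rate,
                 read_length = read_length, barcode_length = barcode_length,
                 gc = gc, groups = groups, left_flank = left_flank,
                 fragment_length = fragment_length, seed = as.integer(seed)),
            class = "sim_config")
}

random_dna <- function(n, gc = 0.45) {
  paste0(sample(c("A", "C", "G", "T"), n, replace = TRUE,
                prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
         collapse = "")
}

# Background sequence free of restriction sites and of SSRs above thresholds.
# A terminal filler may precede the "G" opening the next cassette, where a
# GC[AT] suffix would complete an unplanned GCWGC site; such tails are
# rejected too.
clean_filler <- function(n, gc, thresholds = ssr_thresholds()) {
  repeat {
    s <- random_dna(n, gc)
    if (!grepl(APEKI_SITE, s) && !grepl("GC[AT]$", s) &&
        nrow(find_perfect_ssrs(s, thresholds)) == 0L)
      return(s)
  }
}

# A primitive motif of length k whose repetitions contain no ApeKI site.
random_motif <- function(k) {
  repeat {
    m <- random_dna(k, gc = 0.5)
    if (!is_primitive_motif(m)) next
    if (grepl(APEKI_SITE, strrep(m, max(3L, 12L %/% k + 2L)))) next
    return(m)
  }
}

#' Build a genome with planted SSR loci
#'
#' Constructs a linear genome as a series of locus cassettes, each carrying
#' an ApeKI site whose downstream fragment exposes the planted SSR tract
#' within read range: remnant, a fixed left flank, the tract, and a right
#' filler sized so the reverse-end read of the fragment never reaches the
#' tract. Background sequence is rejection-sampled to contain no unplanned
#' restriction site and no unplanned SSR; the construction is verified by
#' running the detector over the finished genome.
#'
#' @param config a [sim_config()].
#' @return a `sim_genome` list: `sequence`, `loci` (truth records with
#'   0-based tract coordinates, allele sets and frequencies) and internal
#'   segment structure used to realise per-haplotype genomes.
#' @export
make_genome <- function(config) {
  set.seed(config$seed)
  th <- ssr_thresholds()
  ks <- rep(as.integer(names(config$class_counts)), config$class_counts)
  n <- config$n_loci
  poly <- sort(sample.int(n, config$n_polymorphic))
  loci <- vector("list", n)
  segments <- vector("list", n)
  lead <- clean_filler(30L, config$gc)
  pos <- nchar(lead)
  genome_parts <- lead
  for (i in seq_len(n)) {
    k <- ks[i]
    motif <- random_motif(k)
    ref <- if (k == 2L) sample(9:11, 1L) else sample(5:7, 1L)
    if (i %in% poly) {
      n_all <- sample(2:4, 1L, prob = c(0.5, 0.35, 0.15))
      cand <- setdiff(seq(th[[as.character(k)]], ref + 3L), ref)
      alle <- sort(c(ref, sample(cand, min(n_all - 1L, length(cand)))))
      w <- stats::rgamma(length(alle), shape = 2)
      freqs <- w / sum(w)
    } else {
      alle <- ref
      freqs <- 1
    }
    remnant <- paste0("C", sample(c("A", "T"), 1L), "GC")
    seg <- NULL
    for (attempt in 1:50) {
      motif <- random_motif(k)
      tract <- strrep(motif, ref)
      lf <- clean_filler(config$left_flank, config$gc)
      used <- 1L + nchar(remnant) + nchar(lf) + nchar(tract)
      rf <- clean_filler(config$fragment_length - used, config$gc)
      cand <- paste0("G", remnant, lf, tract, rf)
      # junction screening: the cassette must carry exactly the planted SSR
      # and no restriction site beyond its own leading GCWGC
      body <- paste0(remnant, lf, tract, rf)
      extra_site <- grepl(APEKI_SITE, body)
      hits <- find_perfect_ssrs(cand, th)
      if (!extra_site && nrow(hits) == 1L &&
          hits$start == 1L + nchar(remnant) + nchar(lf) &&
          hits$repeat_count == ref && hits$motif == motif) {
        seg <- cand
        break
      }
    }
    if (is.null(seg)) stop("could not place locus ", i)
    tract_start <- pos + 1L + nchar(remnant) + nchar(lf)
    loci[[i]] <- data.frame(
      locus_id = i, motif = motif, canonical_class = canonical_class(motif),
      ref_count = ref, polymorphic = i %in% poly,
      tract_start = tract_start, tract_end = tract_start + nchar(tract),
      left_flank = lf, remnant = remnant,
      alleles = I(list(alle)), freqs = I(list(freqs)),
      stringsAsFactors = FALSE)
    segments[[i]] <- list(prefix = paste0("G", remnant, lf), motif = motif,
                          suffix = rf)
    genome_parts <- c(genome_parts, seg)
    pos <- pos + nchar(seg)
  }
  genome <- paste0(genome_parts, collapse = "")
  truth <- do.call(rbind, loci)
  found <- find_perfect_ssrs(genome, th)
  stopifnot(nrow(found) == n,
            all(found$start == truth$tract_start),
            all(found$motif == truth$motif))
  structure(list(sequence = genome, loci = truth, segments = segments,
                 lead = lead, config = config), class = "sim_genome")
}

#' Sample a diploid population over the planted loci
#'
#' Genotypes are drawn per accession and locus from the allele frequencies
#' under the group's inbreeding coefficient F:
#' `P(hom i) = p_i^2 + F p_i (1 - p_i)` and `P(het ij) = 2 p_i p_j (1 - F)`.
#'
#' @param genome a `sim_genome` (for its allele configurations), or a list
#'   of allele frequency vectors.
#' @param config a [sim_config()] supplying groups and the seed.
#' @return data.frame: `accession`, `group`, `locus_id`, `allele1`,
#'   `allele2` (repeat counts, allele1 <= allele2).
#' @export
sample_population <- function(genome, config = genome$config) {
  set.seed(config$seed + 1L)
  loci <- genome$loci
  rows <- list()
  for (a in seq_len(nrow(config$groups))) {
    f <- config$groups$f[a]
    for (i in seq_len(nrow(loci))) {
      alle <- loci$alleles[[i]]
      p <- loci$freqs[[i]]
      g <- draw_genotype(alle, p, f)
      rows[[length(rows) + 1L]] <- data.frame(
        accession = config$groups$accession[a],
        group = config$groups$group[a],
        locus_id = loci$locus_id[i],
        allele1 = g[1], allele2 = g[2], stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

# One diploid genotype under inbreeding coefficient f.
draw_genotype <- function(alleles, p, f) {
  k <- length(alleles)
  if (k == 1L) return(c(alleles, alleles))
  gts <- list(); probs <- numeric()
  for (i in seq_len(k)) {
    gts[[length(gts) + 1L]] <- c(alleles[i], alleles[i])
    probs <- c(probs, p[i]^2 + f * p[i] * (1 - p[i]))
  }
  for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
    gts[[length(gts) + 1L]] <- c(alleles[i], alleles[j])
    probs <- c(probs, 2 * p[i] * p[j] * (1 - f))
  }
  gts[[sample.int(length(gts), 1L, prob = probs)]]
}

#' In-silico ApeKI digestion
#'
#' Finds every GCWGC site and cuts G^CWGC, returning the double-stranded
#' fragments (including the 3-base 5' overhangs), so that the template read
#' from either fragment end begins with the CWGC remnant.
#'
#' @param sequence genome string.
#' @return data.frame `start`, `end` (0-based half-open, overhang included)
#'   and `n_sites`; terminal fragments without a remnant are flagged.
#' @export
apeki_digest <- function(sequence) {
  sites <- gregexpr(APEKI_SITE, sequence)[[1]]
  if (sites[1] == -1L)
    return(data.frame(start = 0L, end = nchar(sequence),
                      has_left_remnant = FALSE, has_right_remnant = FALSE))
  cuts <- as.integer(sites)           # 1-based site start; cut after the G
  starts <- c(0L, cuts)               # 0-based fragment starts (cut pos)
  ends <- c(cuts + 4L, nchar(sequence))  # include WGC overhang at right end
  data.frame(start = starts, end = ends,
             has_left_remnant = c(FALSE, rep(TRUE, length(cuts))),
             has_right_remnant = c(rep(TRUE, length(cuts)), FALSE))
}

haplotype_genome <- function(genome, counts) {
  parts <- genome$lead
  for (i in seq_along(genome$segments)) {
    s <- genome$segments[[i]]
    parts <- c(parts, paste0(s$prefix, strrep(s$motif, counts[i]), s$suffix))
  }
  paste0(parts, collapse = "")
}

add_errors <- function(seq, rate) {
  n <- nchar(seq)
  k <- stats::rbinom(1L, n, rate)
  if (k == 0L) return(list(seq = seq, pos = integer()))
  pos <- sample.int(n, k)
  s <- strsplit(seq, "")[[1]]
  for (p in pos) s[p] <- sample(setdiff(c("A", "C", "G", "T"), s[p]), 1L)
  list(seq = paste0(s, collapse = ""), pos = pos)
}

#' Generate error-bearing GBS reads with a truth manifest
#'
#' For every accession, realises the two haplotype genomes from the sampled
#' genotypes, digests them, and emits `depth` reads per locus: the barcoded
#' remnant-anchored read from the SSR-exposing fragment end (haplotype chosen
#' uniformly per read) plus `depth` background reads from the opposite
#' fragment end. Substitution errors are injected at the configured rate;
#' qualities are Q30, errored bases Q15.
#'
#' @param genome a `sim_genome`.
#' @param genotypes [sample_population()] output.
#' @param config a [sim_config()].
#' @return list with `reads` (a [gbs_reads()] table, barcodes attached),
#'   `barcodes` (named map), `genotypes`, and `read_truth` (data.frame
#'   read_id, accession, locus_id, allele, orientation).
#' @export
digest_and_read <- function(genome, genotypes, config = genome$config) {
  set.seed(config$seed + 2L)
  accs <- config$groups$accession
  barcodes <- character(0)
  while (length(unique(barcodes)) < length(accs)) {
    barcodes <- unique(c(barcodes, random_dna(config$barcode_length, 0.5)))
  }
  barcodes <- stats::setNames(accs, barcodes[seq_along(accs)])
  bc_of <- stats::setNames(names(barcodes), accs)
  q30 <- rawToChar(as.raw(33L + 30L)); q15 <- rawToChar(as.raw(33L + 15L))
  n_loci <- nrow(genome$loci)
  depth <- config$depth
  total <- length(accs) * n_loci * 2L * depth
  out_id <- character(total); out_seq <- character(total)
  out_q <- character(total)
  t_acc <- character(total); t_loc <- integer(total)
  t_all <- integer(total); t_or <- character(total)
  pos <- 0L
  for (a in accs) {
    g <- genotypes[genotypes$accession == a, ]
    g <- g[order(g$locus_id), ]
    counts <- cbind(g$allele1, g$allele2)
    bc <- bc_of[[a]]
    tmpl_len <- config$read_length - nchar(bc)
    bq <- strrep(q30, nchar(bc))
    for (i in seq_len(n_loci)) {
      frag_of <- vapply(1:2, function(h)
        locus_fragment(genome, i, counts[i, h]), "")
      for (orient in c("fwd", "rev")) {
        hap_pick <- sample.int(2L, depth, replace = TRUE)
        for (r in seq_len(depth)) {
          h <- hap_pick[r]
          template <- if (orient == "fwd") frag_of[h] else revcomp(frag_of[h])
          template <- substr(template, 1L, tmpl_len)
          err <- add_errors(template, config$error_rate)
          qual <- strrep(q30, nchar(template))
          for (p in err$pos) substr(qual, p, p) <- q15
          pos <- pos + 1L
          out_id[pos] <- sprintf("%s_L%03d_%s_%d", a, i, orient, r)
          out_seq[pos] <- paste0(bc, err$seq)
          out_q[pos] <- paste0(bq, qual)
          t_acc[pos] <- a; t_loc[pos] <- i
          t_all[pos] <- if (orient == "fwd") counts[i, h] else NA_integer_
          t_or[pos] <- orient
        }
      }
    }
  }
  list(reads = gbs_reads(out_id, out_seq, out_q),
       barcodes = barcodes,
       genotypes = genotypes,
       read_truth = data.frame(read_id = out_id, accession = t_acc,
                               locus_id = t_loc, allele = t_all,
                               orientation = t_or, stringsAsFactors = FALSE))
}

# Remnant-anchored double-stranded fragment of locus i carrying `count`
# motif repeats: the cassette body after the G^CWGC cut, plus the GCWG
# overhang contributed by the next cassette's site (absent for the last
# cassette, whose fragment runs to the genome end).
locus_fragment <- function(genome, i, count) {
  s <- genome$segments[[i]]
  body <- paste0(substr(s$prefix, 2L, nchar(s$prefix)),  # drop the cut G
                 strrep(s$motif, count), s$suffix)
  if (i < length(genome$segments)) {
    nxt <- genome$segments[[i + 1L]]
    body <- paste0(body, substr(nxt$prefix, 1L, 4L))
  }
  body
}

#' Run the full simulation
#'
#' Convenience wrapper: genome, population, reads.
#'
#' @param config a [sim_config()].
#' @return list with `genome`, `genotypes`, `reads`, `barcodes`,
#'   `read_truth`.
#' @export
simulate_gbs <- function(config) {
  genome <- make_genome(config)
  genotypes <- sample_population(genome, config)
  rd <- digest_and_read(genome, genotypes, config)
  list(genome = genome, genotypes = genotypes, reads = rd$reads,
       barcodes = rd$barcodes, read_truth = rd$read_truth, config = config)
}
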