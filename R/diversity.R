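# Codominant-marker diversity statistics: allele numbers, MAF, expected and
# observed heterozygosity, PIC, and individual heterozygosity.

#' Construct a codominant genotype matrix
#'
#' Individuals x loci with two allele labels per cell (allele sizes in bp or
#' repeat counts; unordered) and optional group tags and geographic
#' coordinates. Missing genotypes are `NA` in both allele matrices and are
#' excluded from every denominator.
#'
#' @param a1,a2 character or numeric matrices (individuals x loci) holding
#'   the two allele labels per genotype; `NA` for missing.
#' @param individuals,loci row and column names.
#' @param group optional per-individual group tag (e.g. tall/dwarf).
#' @param coords optional data.frame with `lat`, `lon` per individual
#'   (decimal degrees).
#' @return an object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(a1, a2, individuals = rownames(a1),
                            loci = colnames(a1), group = NULL, coords = NULL) {
  a1 <- as.matrix(a1); a2 <- as.matrix(a2)
  stopifnot(all(dim(a1) == dim(a2)))
  if (is.null(individuals)) individuals <- paste0("ind", seq_len(nrow(a1)))
  if (is.null(loci)) loci <- paste0("locus", seq_len(ncol(a1)))
  miss <- is.na(a1) != is.na(a2)
  if (any(miss)) stop("half-missing genotypes not allowed")
  dimnames(a1) <- dimnames(a2) <- list(individuals, loci)
  if (!is.null(group)) stopifnot(length(group) == nrow(a1))
  if (!is.null(coords)) stopifnot(nrow(coords) == nrow(a1),
                                  all(c("lat", "lon") %in% names(coords)))
  structure(list(a1 = a1, a2 = a2, individuals = individuals, loci = loci,
                 group = group, coords = coords), class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", length(x$individuals), "individuals x",
      length(x$loci), "loci\n")
  invisible(x)
}

#' Read a genotype table from TSV
#'
#' Expected layout: columns `individual`, `group`, then two columns per locus
#' named `<locus>_1` and `<locus>_2`; `.` or empty marks missing alleles.
#'
#' @param path input TSV.
#' @return a [genotype_matrix()].
#' @export
read_genotypes <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, colClasses = "character",
                          check.names = FALSE)
  stopifnot("individual" %in% names(df))
  acols <- grep("_[12]$", names(df), value = TRUE)
  loci <- unique(sub("_[12]$", "", acols))
  take <- function(suffix) {
    m <- as.matrix(df[, paste0(loci, suffix), drop = FALSE])
    m[m %in% c(".", "")] <- NA
    m
  }
  genotype_matrix(take("_1"), take("_2"), individuals = df$individual,
                  loci = loci,
                  group = if ("group" %in% names(df)) df$group else NULL)
}

#' Write a genotype matrix to TSV
#' @param gm a [genotype_matrix()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(gm, path) {
  fmt <- function(m) { m[is.na(m)] <- "."; m }
  a1 <- fmt(gm$a1); a2 <- fmt(gm$a2)
  out <- data.frame(individual = gm$individuals,
                    group = if (is.null(gm$group)) "" else gm$group,
                    stringsAsFactors = FALSE, check.names = FALSE)
  for (l in gm$loci) {
    out[[paste0(l, "_1")]] <- a1[, l]
    out[[paste0(l, "_2")]] <- a2[, l]
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Allele frequencies at one locus
#'
#' Gene-counting frequencies: each genotyped individual contributes two
#' allele copies; missing genotypes are excluded.
#'
#' @param gm a [genotype_matrix()].
#' @param locus locus name or index.
#' @param subset optional individual names/indices to restrict to.
#' @return named numeric vector of frequencies summing to 1.
#' @export
allele_freqs <- function(gm, locus, subset = NULL) {
  i <- if (is.null(subset)) seq_along(gm$individuals) else subset
  g <- c(gm$a1[i, locus], gm$a2[i, locus])
  g <- g[!is.na(g)]
  if (!length(g)) stop("no genotyped individuals at locus ", locus)
  tab <- table(g)
  p <- as.numeric(tab) / sum(tab)
  names(p) <- names(tab)
  p
}

#' Expected heterozygosity from allele frequencies
#'
#' Gene diversity `He = 1 - sum(p_i^2)`, with no small-sample correction.
#'
#' @param p numeric vector of allele frequencies (must sum to 1).
#' @return He in [0, 1).
#' @export
he_from_freqs <- function(p) {
  stopifnot(abs(sum(p) - 1) < 1e-8, all(p >= 0))
  1 - sum(p^2)
}

#' Polymorphism information content from allele frequencies
#'
#' Botstein's PIC: `1 - sum(p_i^2) - sum_{i<j} 2 p_i^2 p_j^2`.
#'
#' @param p numeric vector of allele frequencies (must sum to 1).
#' @return PIC, never exceeding He.
#' @export
pic_from_freqs <- function(p) {
  stopifnot(abs(sum(p) - 1) < 1e-8, all(p >= 0))
  sq <- p^2
  # sum_{i<j} 2 p_i^2 p_j^2 == (sum sq)^2 - sum(sq^2)
  1 - sum(sq) - (sum(sq)^2 - sum(sq^2))
}

#' Per-locus diversity statistics
#'
#' Computes allele count (Na), major allele frequency (MAF), gene diversity
#' (He), observed heterozygosity (Ho) and PIC at one locus, optionally within
#' a subset of individuals.
#'
#' @param gm a [genotype_matrix()].
#' @param locus locus name or index.
#' @param subset optional individuals.
#' @return one-row data.frame `locus`, `n`, `na`, `maf`, `he`, `ho`, `pic`.
#' @export
locus_stats <- function(gm, locus, subset = NULL) {
  i <- if (is.null(subset)) seq_along(gm$individuals) else subset
  a1 <- gm$a1[i, locus]; a2 <- gm$a2[i, locus]
  ok <- !is.na(a1)
  if (!any(ok)) stop("no genotyped individuals at locus ", locus)
  p <- allele_freqs(gm, locus, subset)
  lname <- if (is.character(locus)) locus else gm$loci[locus]
  data.frame(locus = lname,
             n = sum(ok),
             na = sum(p > 0),
             maf = max(p),
             he = he_from_freqs(p),
             ho = mean(a1[ok] != a2[ok]),
             pic = pic_from_freqs(p),
             stringsAsFactors = FALSE)
}

#' Diversity statistics for every locus, overall and per group
#'
#' @param gm a [genotype_matrix()].
#' @param by_group also compute per-group statistics when group tags exist.
#' @return data.frame of [locus_stats()] rows; with `by_group`, extra rows
#'   tagged by a `group` column (`"all"` for the overall rows).
#' @export
panel_stats <- function(gm, by_group = !is.null(gm$group)) {
  all_rows <- do.call(rbind, lapply(gm$loci, function(l) locus_stats(gm, l)))
  all_rows$group <- "all"
  if (!by_group || is.null(gm$group)) return(all_rows)
  per <- lapply(unique(gm$group), function(g) {
    idx <- which(gm$group == g)
    rows <- do.call(rbind, lapply(gm$loci, function(l) {
      ok <- !is.na(gm$a1[idx, l])
      if (!any(ok)) return(NULL)
      locus_stats(gm, l, subset = idx)
    }))
    rows$group <- g
    rows
  })
  rbind(all_rows, do.call(rbind, per))
}

#' Individual heterozygosity in percent
#'
#' @param gm a [genotype_matrix()].
#' @param individual individual name or index; all when `NULL`.
#' @return named numeric vector, 100 x heterozygous loci / genotyped loci.
#' @export
individual_heterozygosity <- function(gm, individual = NULL) {
  idx <- if (is.null(individual)) seq_along(gm$individuals)
         else if (is.numeric(individual)) as.integer(individual)
         else match(individual, gm$individuals)
  out <- vapply(idx, function(i) {
    a1 <- gm$a1[i, ]; a2 <- gm$a2[i, ]
    ok <- !is.na(a1)
    if (!any(ok)) return(NA_real_)
    100 * sum(a1[ok] != a2[ok]) / sum(ok)
  }, 0)
  stats::setNames(out, gm$individuals[idx])
}

#' Summarise a marker panel table
#'
#' Given a per-locus marker table with allele counts and diversity columns
#' (overall and per ecotype group), recompute the panel totals and averages:
#' total alleles and the mean Na, He, Ho, PIC per column, rounded to two
#' decimals (allele means: printed convention of the source tables).
#'
#' @param markers data.frame with columns `na_all`, `na_tall`, `na_dwarf`,
#'   `maf`, `he_all`, `ho_all`, `pic_all` (extra columns are summarised too).
#' @return named list of totals and means.
#' @export
summarize_marker_panel <- function(markers) {
  num <- markers[vapply(markers, is.numeric, TRUE)]
  means <- round(colMeans(num), 2)
  list(n_markers = nrow(markers),
       total_alleles = sum(markers$na_all),
       means = means)
}

#' Export genotypes in STRUCTURE two-row format
#'
#' Writes one header row of locus names and two rows per individual (one
#' allele per row), with missing data coded `-9`. Allele labels are mapped
#' to integers per locus.
#'
#' @param gm a [genotype_matrix()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(gm, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(gm$loci, collapse = "\t"), con)
  code <- lapply(gm$loci, function(l)
    sort(unique(c(gm$a1[, l], gm$a2[, l]))))
  names(code) <- gm$loci
  enc <- function(m, i) {
    vapply(gm$loci, function(l) {
      v <- m[i, l]
      if (is.na(v)) -9L else match(v, code[[l]])
    }, integer(1))
  }
  for (i in seq_along(gm$individuals)) {
    for (m in list(gm$a1, gm$a2)) {
      writeLines(paste(c(gm$individuals[i], enc(m, i)), collapse = "\t"), con)
    }
  }
  invisible(path)
}
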