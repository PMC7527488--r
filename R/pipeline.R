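# End-to-end orchestration: demux -> stacks -> catalog -> ssr -> cluster ->
# call -> primers, with per-stage artifacts, machine-readable reports and
# checksum-based resumability.

RUN_CONFIG_KEYS <- c(
  "fastq", "barcodes", "remnant", "max_barcode_mismatch",
  "window_fraction", "min_mean_q", "read_length",
  "min_depth", "merge_distance", "catalog_mismatch",
  "identity_threshold", "min_allele_obs", "min_support",
  "product_min", "product_max", "seed")

#' Build a validated pipeline run configuration
#'
#' Unknown keys are rejected; paths must exist before any stage runs.
#'
#' @param fastq input FASTQ (raw, barcoded reads).
#' @param barcodes barcode map TSV.
#' @param ... overrides for the remaining parameters (see
#'   `ssrmine:::RUN_CONFIG_KEYS`).
#' @return a `run_config` list.
#' @export
run_config <- function(fastq, barcodes, ...) {
  cfg <- list(fastq = fastq, barcodes = barcodes,
              remnant = "CWGC", max_barcode_mismatch = 1L,
              window_fraction = 0.15, min_mean_q = 10,
              read_length = 90L,
              min_depth = 2L, merge_distance = 1L, catalog_mismatch = 0L,
              identity_threshold = 0.90, min_allele_obs = 1L,
              min_support = 20L, product_min = 80L, product_max = 100L,
              seed = 1L)
  dots <- list(...)
  bad <- setdiff(names(dots), RUN_CONFIG_KEYS)
  if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "))
  cfg[names(dots)] <- dots
  if (!file.exists(cfg$fastq)) stop("missing input: ", cfg$fastq)
  if (!file.exists(cfg$barcodes)) stop("missing input: ", cfg$barcodes)
  structure(cfg, class = "run_config")
}

#' Read a pipeline configuration from a key = value file
#'
#' @param path plain text file of `key = value` lines; `#` comments allowed.
#' @return a `run_config` list.
#' @export
read_run_config <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines[nzchar(trimws(lines))])
  kv <- strsplit(lines, "\\s*=\\s*")
  keys <- vapply(kv, `[[`, "", 1L)
  vals <- vapply(kv, function(x) paste(x[-1], collapse = "="), "")
  bad <- setdiff(keys, RUN_CONFIG_KEYS)
  if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "))
  args <- stats::setNames(as.list(vals), keys)
  num <- setdiff(RUN_CONFIG_KEYS, c("fastq", "barcodes", "remnant"))
  for (k in intersect(names(args), num)) args[[k]] <- as.numeric(args[[k]])
  do.call(run_config, args)
}

stage_report_path <- function(dir, stage) file.path(dir, paste0(stage, ".report.json"))

write_stage_report <- function(dir, stage, counts, artifacts) {
  rep <- list(stage = stage, counts = counts,
              artifacts = as.list(tools::md5sum(artifacts)))
  jsonlite::write_json(rep, stage_report_path(dir, stage), auto_unbox = TRUE)
}

stage_done <- function(dir, stage) {
  p <- stage_report_path(dir, stage)
  if (!file.exists(p)) return(FALSE)
  rep <- jsonlite::read_json(p)
  arts <- names(rep$artifacts)
  if (!all(file.exists(arts))) return(FALSE)
  sums <- tools::md5sum(arts)
  if (!all(sums == unlist(rep$artifacts)))
    stop("corrupted artifact detected at stage '", stage,
         "': checksum mismatch; rerun with force = TRUE")
  TRUE
}

#' Run the SSR mining pipeline
#'
#' Executes demux, stacks, catalog, ssr, cluster, call and primers in order,
#' writing each stage's artifact plus a JSON stage report (with read/locus
#' tallies and artifact checksums) into `out_dir`. A rerun skips stages
#' whose report and artifacts are intact unless `force = TRUE`; an artifact
#' that no longer matches its recorded checksum halts the run at that stage.
#'
#' @param config a [run_config()] (or path to a key = value file).
#' @param out_dir run directory, created if needed.
#' @param force recompute all stages.
#' @return `out_dir`, invisibly; artifacts and reports live inside.
#' @export
run_pipeline <- function(config, out_dir, force = FALSE) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  # -- demux ------------------------------------------------------------
  demux_dir <- file.path(out_dir, "demux")
  report_tsv <- file.path(out_dir, "filter_report.tsv")
  if (force || !stage_done(out_dir, "demux")) {
    raw <- read_fastq(config$fastq)
    barcodes <- read_barcode_map(config$barcodes)
    pp <- preprocess_reads(raw, barcodes, remnant = config$remnant,
                           max_mismatch = config$max_barcode_mismatch,
                           window_fraction = config$window_fraction,
                           min_mean_q = config$min_mean_q,
                           target_length = config$read_length)
    dir.create(demux_dir, showWarnings = FALSE)
    files <- character()
    for (a in sort(unique(pp$reads$accession))) {
      f <- file.path(demux_dir, paste0(a, ".fastq"))
      write_fastq(pp$reads[pp$reads$accession == a, ], f)
      files <- c(files, f)
    }
    utils::write.table(pp$report, report_tsv, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    write_stage_report(out_dir, "demux",
                       list(raw = sum(pp$report$raw),
                            clean = sum(pp$report$retained)),
                       c(files, report_tsv))
  }

  # -- stacks -----------------------------------------------------------
  stacks_tsv <- file.path(out_dir, "stacks.tsv")
  if (force || !stage_done(out_dir, "stacks")) {
    files <- list.files(demux_dir, pattern = "\\.fastq$", full.names = TRUE)
    stacks <- do.call(rbind, lapply(files, function(f) {
      reads <- read_fastq(f)
      reads$accession <- sub("\\.fastq$", "", basename(f))
      build_stacks(reads, min_depth = config$min_depth,
                   merge_distance = config$merge_distance)
    }))
    utils::write.table(stacks, stacks_tsv, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    write_stage_report(out_dir, "stacks",
                       list(unique_reads = nrow(stacks),
                            total_depth = sum(stacks$depth)),
                       stacks_tsv)
  }
  stacks <- utils::read.table(stacks_tsv, header = TRUE, sep = "\t",
                              stringsAsFactors = FALSE)

  # -- catalog ----------------------------------------------------------
  catalog_fa <- file.path(out_dir, "catalog.fasta")
  members_tsv <- file.path(out_dir, "catalog_members.tsv")
  if (force || !stage_done(out_dir, "catalog")) {
    catalog <- build_catalog(stacks, catalog_mismatch = config$catalog_mismatch)
    write_catalog(catalog, catalog_fa, members_tsv)
    write_stage_report(out_dir, "catalog", list(loci = length(catalog)),
                       c(catalog_fa, members_tsv))
  }

  # -- ssr --------------------------------------------------------------
  misa_tsv <- file.path(out_dir, "ssr.tsv")
  if (force || !stage_done(out_dir, "ssr")) {
    cons <- Biostrings::readDNAStringSet(catalog_fa)
    hits <- find_ssrs_in_set(stats::setNames(as.character(cons), names(cons)))
    write_misa(hits, misa_tsv)
    s <- summarize_ssrs(hits)
    write_stage_report(out_dir, "ssr",
                       list(ssr_loci = nrow(hits),
                            by_class = as.list(s$totals)),
                       misa_tsv)
  }

  # -- cluster ----------------------------------------------------------
  alleles_tsv <- file.path(out_dir, "allele_table.tsv")
  centroids_fa <- file.path(out_dir, "cluster_centroids.fasta")
  need_cluster <- force || !stage_done(out_dir, "cluster")
  need_call <- force || !stage_done(out_dir, "call")
  need_primers <- force || !stage_done(out_dir, "primers")
  records <- clusters <- NULL
  if (need_cluster || need_call || need_primers) {
    records <- ssr_records(stacks)
    clusters <- cluster_ssr_loci(records, config$identity_threshold)
  }
  if (need_cluster) {
    at <- allele_table(clusters)
    write_allele_table(at, alleles_tsv)
    cent <- Biostrings::DNAStringSet(vapply(clusters, function(cl)
      cl$centroid$sequence, ""))
    names(cent) <- vapply(clusters, function(cl)
      sprintf("cluster_%d motif=%s ssr=%d-%d", cl$cluster_id,
              cl$centroid$motif, cl$centroid$ssr_start, cl$centroid$ssr_end),
      "")
    Biostrings::writeXStringSet(cent, centroids_fa)
    write_stage_report(out_dir, "cluster",
                       list(ssr_records = nrow(records),
                            clusters = length(clusters)),
                       c(alleles_tsv, centroids_fa))
  }

  # -- call -------------------------------------------------------------
  poly_tsv <- file.path(out_dir, "polymorphic.tsv")
  if (need_call) {
    calls <- do.call(rbind, lapply(clusters, function(cl) {
      cc <- call_polymorphic(cl, config$min_allele_obs)
      data.frame(cluster_id = cl$cluster_id,
                 polymorphic = cc$polymorphic,
                 alleles = paste(cc$alleles, collapse = ","),
                 support = length(unique(cl$members$accession)),
                 stringsAsFactors = FALSE)
    }))
    utils::write.table(calls, poly_tsv, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    write_stage_report(out_dir, "call",
                       list(polymorphic = sum(calls$polymorphic)), poly_tsv)
  }

  # -- primers ----------------------------------------------------------
  primers_tsv <- file.path(out_dir, "primers.tsv")
  candidates_tsv <- file.path(out_dir, "candidates.tsv")
  if (need_primers) {
    pairs <- lapply(clusters, function(cl) {
      cc <- call_polymorphic(cl, config$min_allele_obs)
      alle <- if (length(cc$observed)) cc$observed else cl$centroid$repeat_count
      design_primer_pair(cl$centroid$sequence, cl$centroid$ssr_start,
                         cl$centroid$ssr_end, nchar(cl$centroid$motif),
                         cl$centroid$repeat_count, alleles = alle)
    })
    cand <- select_marker_candidates(
      clusters, pairs, min_support = config$min_support,
      product_range = c(config$product_min, config$product_max),
      min_allele_obs = config$min_allele_obs)
    prim <- do.call(rbind, lapply(seq_along(pairs), function(i) {
      p <- pairs[[i]]
      if (!inherits(p, "primer_pair")) return(NULL)
      data.frame(cluster_id = clusters[[i]]$cluster_id,
                 forward = p$forward, reverse = p$reverse,
                 motif = clusters[[i]]$centroid$motif,
                 tm_f = p$tm_f, tm_r = p$tm_r,
                 product_size = p$product_size, stringsAsFactors = FALSE)
    }))
    if (is.null(prim)) prim <- data.frame()
    utils::write.table(prim, primers_tsv, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    utils::write.table(cand, candidates_tsv, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    write_stage_report(out_dir, "primers",
                       list(designed = nrow(prim),
                            selected = sum(cand$selected)),
                       c(primers_tsv, candidates_tsv))
  }
  invisible(out_dir)
}
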