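# Independent brute-force oracle for perfect SSR detection: tests every
# (start, motif length) pair by direct substring comparison, with its own
# primitivity and leftmost-maximality logic.
brute_force_ssrs <- function(seq, thresholds = ssr_thresholds()) {
  s <- strsplit(seq, "")[[1]]
  n <- length(s)
  rows <- list()
  for (k in as.integer(names(thresholds))) {
    thr <- thresholds[[as.character(k)]]
    if (n < k * thr) next
    for (i in 0:(n - k * thr)) {          # 0-based candidate start
      motif <- substr(seq, i + 1, i + k)
      if (grepl("N", motif, fixed = TRUE)) next
      primitive <- TRUE
      for (p in seq_len(k - 1)) {
        if (k %% p == 0 &&
            motif == paste(rep(substr(motif, 1, p), k / p), collapse = ""))
          primitive <- FALSE
      }
      if (!primitive) next
      r <- 1
      while (i + (r + 1) * k <= n &&
             substr(seq, i + r * k + 1, i + (r + 1) * k) == motif) r <- r + 1
      if (r < thr) next
      # leftmost: the period-k region must not extend one base left
      if (i > 0 && s[i] != "N" && s[i] == s[i + k]) next
      rows[[length(rows) + 1]] <- data.frame(
        motif = motif, repeat_count = r, start = i, end = i + r * k,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(motif = character(), repeat_count = integer(),
                      start = integer(), end = integer()))
  out <- do.call(rbind, rows)
  out <- out[order(out$start, nchar(out$motif)), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Random test sequence generator: uniform background, optionally with planted
# repeat tracts and sprinkled Ns, to exercise the detector.
random_test_sequence <- function(len, plant = FALSE, n_rate = 0) {
  s <- sample(c("A", "C", "G", "T"), len, replace = TRUE)
  if (plant) {
    k <- sample(2:6, 1)
    motif <- paste(sample(c("A", "C", "G", "T"), k, replace = TRUE),
                   collapse = "")
    reps <- sample(4:9, 1)
    tract <- strsplit(strrep(motif, reps), "")[[1]]
    at <- sample.int(len - length(tract), 1)
    s[at:(at + length(tract) - 1)] <- tract
  }
  if (n_rate > 0) {
    nn <- rbinom(1, len, n_rate)
    if (nn > 0) s[sample.int(len, nn)] <- "N"
  }
  paste(s, collapse = "")
}

# Phred+33 helpers for building reads in tests.
qchar <- function(q) rawToChar(as.raw(33L + q))
qstring <- function(q, n) strrep(qchar(q), n)

make_read <- function(seq, q = 30, id = "r1") {
  gbs_reads(id, seq, qstring(q, nchar(seq)))
}
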