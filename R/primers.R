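# Flanking-primer enumeration and ranking under marker-design constraints,
# with a nearest-neighbor melting temperature.

# SantaLucia (1998) unified nearest-neighbor parameters.
# dH in kcal/mol, dS in cal/(mol K).
NN_DH <- c(AA = -7.9, TT = -7.9, AT = -7.2, TA = -7.2,
           CA = -8.5, TG = -8.5, GT = -8.4, AC = -8.4,
           CT = -7.8, AG = -7.8, GA = -8.2, TC = -8.2,
           CG = -10.6, GC = -9.8, GG = -8.0, CC = -8.0)
NN_DS <- c(AA = -22.2, TT = -22.2, AT = -20.4, TA = -21.3,
           CA = -22.7, TG = -22.7, GT = -22.4, AC = -22.4,
           CT = -21.0, AG = -21.0, GA = -22.2, TC = -22.2,
           CG = -27.2, GC = -24.4, GG = -19.9, CC = -19.9)

#' Nearest-neighbor melting temperature
#'
#' Duplex melting temperature of a primer against its perfect complement,
#' using the SantaLucia (1998) unified nearest-neighbor parameters with
#' terminal initiation terms. Salt enters through the entropic correction
#' `0.368 (n-1) ln[Mon+]` on an effective monovalent concentration
#' `[Mon+] = [Na+] + 120 sqrt([Mg2+] - [dNTP])` (von Ahsen 2001), and the
#' duplex concentration term uses CT/4 for non-self-complementary primers.
#' Defaults mirror the PCR conditions assumed by Primer3-family design
#' tools: 50 mM monovalent salt, 1.5 mM Mg2+, 0.6 mM dNTP, 50 nM primer;
#' these reproduce the melting temperatures printed for validated GBS-SSR
#' primer panels to within about +/-3 degrees C. Deterministic to 0.01.
#'
#' @param primer one or more DNA strings (A/C/G/T), length >= 8.
#' @param Na monovalent cation concentration, mol/L (default 0.05).
#' @param Mg divalent cation concentration, mol/L (default 0.0015).
#' @param dNTP dNTP concentration, mol/L (default 6e-4).
#' @param primer_conc primer concentration, mol/L (default 5e-8).
#' @return melting temperature(s) in degrees C.
#' @export
melting_temperature <- function(primer, Na = 0.05, Mg = 0.0015,
                                dNTP = 6e-4, primer_conc = 5e-8) {
  if (length(primer) > 1L)
    return(vapply(primer, melting_temperature, 0, Na = Na, Mg = Mg,
                  dNTP = dNTP, primer_conc = primer_conc, USE.NAMES = FALSE))
  primer <- toupper(primer)
  if (!grepl("^[ACGT]+$", primer)) stop("primer must be A/C/G/T only")
  n <- nchar(primer)
  if (n < 8L) stop("primer too short for nearest-neighbor Tm")
  steps <- substring(primer, 1:(n - 1), 2:n)
  dH <- sum(NN_DH[steps])
  dS <- sum(NN_DS[steps])
  ends <- c(substr(primer, 1, 1), substr(primer, n, n))
  for (e in ends) {
    if (e %in% c("G", "C")) { dH <- dH + 0.1;  dS <- dS - 2.8 }
    else                    { dH <- dH + 2.3;  dS <- dS + 4.1 }
  }
  selfcomp <- primer == revcomp(primer)
  if (selfcomp) dS <- dS - 1.4   # symmetry correction
  # von Ahsen effective monovalent: concentrations in mM inside the sqrt
  mon <- Na + if (Mg > dNTP) 0.12 * sqrt((Mg - dNTP) * 1000) else 0
  dS <- dS + 0.368 * (n - 1) * log(mon)
  x <- if (selfcomp) 1 else 4
  tm <- dH * 1000 / (dS + 1.987 * log(primer_conc / x)) - 273.15
  round(tm, 2)
}

#' GC content in percent
#' @param x DNA string(s).
#' @return percentage of G+C bases.
#' @export
gc_content <- function(x) {
  100 * (nchar(gsub("[^GCgc]", "", x)) / nchar(x))
}

max_homopolymer_run <- function(x) {
  vapply(x, function(s) {
    r <- rle(strsplit(s, "")[[1]])
    max(r$lengths)
  }, integer(1), USE.NAMES = FALSE)
}

# Longest run of consecutive complementary pairs anchored at the 3' end of
# `a`, pairing antiparallel against any position of `b`.
three_prime_complementarity <- function(a, b) {
  av <- rev(strsplit(a, "")[[1]])                 # a read 3' -> 5'
  bv <- strsplit(b, "")[[1]]                      # b read 5' -> 3'
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  best <- 0L
  for (start in seq_along(bv)) {
    k <- 0L
    while (k < length(av) && start + k <= length(bv) &&
           comp[[av[k + 1L]]] == bv[start + k]) k <- k + 1L
    best <- max(best, k)
  }
  best
}

#' Primer design constraints
#'
#' The hard constraints a primer pair must satisfy: primer length 18-23 nt,
#' PCR product 50-100 bp (a later marker-selection layer narrows this to
#' 80-100 bp), melting temperature 52-60 degrees C with optimum 55, GC
#' content 30-67%, mononucleotide runs of at most 4, and at most 3
#' consecutive complementary bases anchored at a 3' end (self or pair).
#'
#' @param length_range,product_range,tm_range,gc_range closed intervals.
#' @param tm_opt optimum melting temperature.
#' @param max_run maximum mononucleotide run.
#' @param max_3p_comp maximum 3'-anchored complementarity.
#' @return a named list of constraints.
#' @export
primer_constraints <- function(length_range = c(18L, 23L),
                               product_range = c(50L, 100L),
                               tm_range = c(52, 60), tm_opt = 55,
                               gc_range = c(30, 67),
                               max_run = 4L, max_3p_comp = 3L) {
  stopifnot(length_range[1] <= length_range[2],
            product_range[1] <= product_range[2],
            tm_range[1] < tm_range[2], gc_range[1] < gc_range[2])
  list(length_range = length_range, product_range = product_range,
       tm_range = tm_range, tm_opt = tm_opt, gc_range = gc_range,
       max_run = max_run, max_3p_comp = max_3p_comp)
}

# All candidate windows in [lo, hi) (0-based template coords) with lengths
# from the constraint range that satisfy the single-primer hard constraints.
candidate_windows <- function(template, lo, hi, constraints, sense) {
  out <- list()
  for (len in seq(constraints$length_range[1], constraints$length_range[2])) {
    if (hi - len < lo) next
    starts <- seq.int(lo, hi - len)
    if (!length(starts)) next
    win <- substring(template, starts + 1L, starts + len)
    primer <- if (sense == "forward") win else revcomp(win)
    keep <- grepl("^[ACGT]+$", primer)
    gc <- rep(NA_real_, length(primer)); tm <- rep(NA_real_, length(primer))
    gc[keep] <- gc_content(primer[keep])
    keep <- keep & gc >= constraints$gc_range[1] & gc <= constraints$gc_range[2]
    if (any(keep)) keep[keep] <- max_homopolymer_run(primer[keep]) <= constraints$max_run
    if (any(keep)) {
      tm[keep] <- melting_temperature(primer[keep])
      keep <- keep & tm >= constraints$tm_range[1] & tm <= constraints$tm_range[2]
    }
    if (any(keep)) {
      self_ok <- vapply(primer[keep], function(p)
        three_prime_complementarity(p, p) <= constraints$max_3p_comp, TRUE)
      kidx <- which(keep); keep[kidx[!self_ok]] <- FALSE
    }
    if (!any(keep)) next
    out[[length(out) + 1L]] <- data.frame(
      start = starts[keep], end = starts[keep] + len,
      primer = primer[keep], tm = tm[keep], gc = gc[keep],
      stringsAsFactors = FALSE)
  }
  if (!length(out)) return(NULL)
  do.call(rbind, out)
}

#' Design the best-scoring primer pair for an SSR locus
#'
#' Enumerates every forward window in the left flank and reverse window in
#' the right flank that passes the single-primer constraints, pairs them,
#' keeps pairs whose expected product for the longest observed allele lies in
#' the product range and whose cross-primer 3' complementarity is within
#' bounds, and returns the pair minimising
#' `|Tm_f - opt| + |Tm_r - opt| + |Tm_f - Tm_r| + 0.1 |product - mid(range)|`.
#' Ties break toward the smaller product, then the lexicographically smaller
#' forward primer. The product is computed for the longest allele so every
#' allele stays within the resolvable range.
#'
#' @param template the locus sequence (e.g. cluster centroid).
#' @param ssr_start,ssr_end 0-based half-open tract coordinates on `template`.
#' @param motif_len motif length in bp.
#' @param centroid_count repeat count present in `template`.
#' @param alleles integer repeat counts observed at the locus.
#' @param constraints see [primer_constraints()].
#' @return a `primer_pair` list (forward, reverse, tm_f, tm_r, gc_f, gc_r,
#'   product_size for the longest allele, product_on_centroid, penalty,
#'   positions); when infeasible, an empty `primer_failure` object whose
#'   `failures` attribute counts the violated constraints.
#' @export
design_primer_pair <- function(template, ssr_start, ssr_end, motif_len,
                               centroid_count, alleles = centroid_count,
                               constraints = primer_constraints()) {
  fwd <- candidate_windows(template, 0L, ssr_start, constraints, "forward")
  rev_ <- candidate_windows(template, ssr_end, nchar(template), constraints,
                            "reverse")
  fail <- c(no_forward_window = is.null(fwd), no_reverse_window = is.null(rev_))
  if (is.null(fwd) || is.null(rev_))
    return(structure(list(), class = "primer_failure", failures = fail))
  shift <- (max(alleles) - centroid_count) * motif_len
  grid <- expand.grid(f = seq_len(nrow(fwd)), r = seq_len(nrow(rev_)))
  prod_centroid <- rev_$end[grid$r] - fwd$start[grid$f]
  product <- prod_centroid + shift
  ok <- product >= constraints$product_range[1] &
        product <= constraints$product_range[2]
  if (!any(ok))
    return(structure(list(), class = "primer_failure",
                     failures = c(fail, no_product_in_range = TRUE)))
  grid <- grid[ok, , drop = FALSE]
  product <- product[ok]; prod_centroid <- prod_centroid[ok]
  pair_ok <- vapply(seq_len(nrow(grid)), function(i) {
    f <- fwd$primer[grid$f[i]]; r <- rev_$primer[grid$r[i]]
    three_prime_complementarity(f, r) <= constraints$max_3p_comp &&
      three_prime_complementarity(r, f) <= constraints$max_3p_comp
  }, TRUE)
  if (!any(pair_ok))
    return(structure(list(), class = "primer_failure",
                     failures = c(fail, pair_complementarity = TRUE)))
  grid <- grid[pair_ok, , drop = FALSE]
  product <- product[pair_ok]; prod_centroid <- prod_centroid[pair_ok]
  mid <- mean(constraints$product_range)
  tm_f <- fwd$tm[grid$f]; tm_r <- rev_$tm[grid$r]
  penalty <- abs(tm_f - constraints$tm_opt) + abs(tm_r - constraints$tm_opt) +
    abs(tm_f - tm_r) + 0.1 * abs(product - mid)
  ord <- order(penalty, product, fwd$primer[grid$f])
  i <- ord[1L]
  structure(list(
    forward = fwd$primer[grid$f[i]], reverse = rev_$primer[grid$r[i]],
    tm_f = tm_f[i], tm_r = tm_r[i],
    gc_f = fwd$gc[grid$f[i]], gc_r = rev_$gc[grid$r[i]],
    forward_start = fwd$start[grid$f[i]], reverse_end = rev_$end[grid$r[i]],
    product_on_centroid = prod_centroid[i],
    product_size = product[i],
    centroid_count = centroid_count, motif_len = motif_len,
    penalty = penalty[i]), class = "primer_pair")
}

#' Expected product sizes per allele
#'
#' Fragment size of each allele: the product on the centroid shifted by the
#' repeat-count difference times the motif length.
#'
#' @param pair a `primer_pair` (or a centroid product size).
#' @param alleles integer repeat counts.
#' @param motif_len motif length; taken from `pair` when omitted.
#' @return integer product sizes, one per allele.
#' @export
expected_products <- function(pair, alleles, motif_len = NULL) {
  stopifnot(inherits(pair, "primer_pair"))
  if (is.null(motif_len)) motif_len <- pair$motif_len
  as.integer(pair$product_on_centroid +
             (alleles - pair$centroid_count) * motif_len)
}

#' Independently validate a primer pair against constraints
#'
#' Re-checks every hard constraint from the primer sequences alone (length,
#' GC, Tm, runs, 3' complementarity) without reusing any value cached on the
#' pair.
#'
#' @param forward,reverse primer sequences 5'->3'.
#' @param constraints see [primer_constraints()].
#' @param tm_tolerance slack in degrees C added to the Tm range (default 0).
#' @return named logical vector of per-constraint outcomes.
#' @export
validate_primer_pair <- function(forward, reverse,
                                 constraints = primer_constraints(),
                                 tm_tolerance = 0) {
  chk <- function(p) {
    n <- nchar(p)
    tm <- melting_temperature(p)
    c(length = n >= constraints$length_range[1] & n <= constraints$length_range[2],
      gc = gc_content(p) >= constraints$gc_range[1] &
           gc_content(p) <= constraints$gc_range[2],
      tm = tm >= constraints$tm_range[1] - tm_tolerance &
           tm <= constraints$tm_range[2] + tm_tolerance,
      run = max_homopolymer_run(p) <= constraints$max_run,
      self = three_prime_complementarity(p, p) <= constraints$max_3p_comp)
  }
  f <- chk(forward); r <- chk(reverse)
  c(stats::setNames(f, paste0("forward_", names(f))),
    stats::setNames(r, paste0("reverse_", names(r))),
    pair_3p = three_prime_complementarity(forward, reverse) <= constraints$max_3p_comp &&
              three_prime_complementarity(reverse, forward) <= constraints$max_3p_comp)
}
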