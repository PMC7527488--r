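---
title: "Methods: reference-free GBS SSR mining and marker statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: reference-free GBS SSR mining and marker statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the models and procedures it
implements, the parameters that matter, and the choices made where the
design was genuinely open. It states no empirical result that the test
suite or `scripts/acceptance.R` does not itself compute.

## The problem

Genotyping-by-sequencing (GBS) reduces a large genome to fragments anchored
at restriction sites — here ApeKI, recognition `GCWGC`, cut `G^CWGC`, so
every genuine read begins with the remnant `CWGC`. Without a reference
genome, reads cannot be mapped; instead identical reads are stacked within
each accession and stacks are merged across accessions into consensus loci.
Perfect microsatellites (SSRs) found in these sequences become candidate
codominant markers: the repeat count varies between individuals while the
flanking sequence stays put, so a single primer pair amplifies
length-distinguishable alleles.

## Preprocessing

* **Demultiplexing.** Inline barcodes are matched as read prefixes. An
  exact match always wins (the barcode map is required to be prefix-free);
  otherwise a read is rescued if exactly one barcode lies within
  `max_mismatch` (default 1) substitutions. Two barcodes within tolerance
  make the read *ambiguous* and it is discarded with its own counter —
  guessing would assign reads to the wrong accession silently.
* **Restriction-site check.** The remnant pattern (IUPAC, default `CWGC`)
  is required at position 0 only. GBS library geometry puts the cut site
  immediately after the barcode; a read carrying `CWGC` elsewhere but not
  at the start is an artifact.
* **Quality filter.** A read is discarded when any sliding window of
  `ceiling(0.15 × length)` bases has mean Phred below 10, mirroring the
  documented defaults of the standard RAD demultiplexer, or when it
  contains an uncalled base. The boundary is strict (`< 10` discards), so
  an all-Q10 read is retained; a test pins this convention.
* **Truncation.** Exact-sequence stacking requires one uniform length;
  after barcode removal reads are cut to `target_length` (default 90 for
  100-bp reads with 4–8 bp barcodes) and shorter reads dropped. Every
  discard category is counted per accession and the counts must sum to the
  raw read count — an invariant asserted in code.

## Stacking and the catalog

Stacks are exact-duplicate collapses. Sub-threshold stacks (depth <
`min_depth`) are absorbed into a deep stack when *exactly one* deep stack
lies within `merge_distance` substitutions — this soaks up sequencing-error
singletons without inventing chimeras — and are dropped otherwise. The
default `min_depth = 2` is deliberately below the classic Stacks default of
3: the simulator and typical validation runs work at 15× per locus and
accession, where depth-2 evidence is already reliable; the value is
configurable.

Catalog construction is greedy: stacks sorted by (depth desc, sequence asc,
accession asc) either join the first locus whose consensus is within
`catalog_mismatch` (default 0) or found a new locus. The consensus is the
depth-weighted per-position majority with ties broken `A < C < G < T`, and
is refreshed as members join. The fixed sort key makes the whole procedure
independent of input order; with `catalog_mismatch = 0` it degenerates to
exact grouping, which a test checks against hash grouping.

## Perfect SSR detection

For each motif length *k* in 2–6 the detector computes the boolean profile
`b[i] = (s[i] == s[i+k])` and reads maximal runs of `TRUE` as maximal
period-*k* regions. A region starting at its leftmost base with
`floor(len/k) ≥ threshold` complete motifs becomes a hit; partial trailing
motifs never count, so `end − start = repeat_count × k` exactly. Motifs
that are themselves repetitions (e.g. `ATAT`) are discarded — the primitive
motif's hit covers the region; by the Fine–Wilf periodicity argument no
threshold-passing non-primitive region survives inside a primitive tract.
`N` breaks tracts. Thresholds default to 6 iterations for dinucleotides and
5 for tri- through hexanucleotides; mononucleotides are out of scope.

The printed summaries this workflow tabulates include a repeat-count bin
"5" for dinucleotides even though the stated minimum is 6 — the two
conventions cannot both be defaults. The threshold set is therefore a
plain argument (`ssr_thresholds()`), and the package default follows the
stated minimums (6/5/5/5/5).

The detector is validated against a brute-force oracle that tests every
(start, motif-length) pair by direct substring comparison on 1000 random
300-bp sequences, including planted tracts and N-bearing sequences.

**Canonical classes.** A motif class is the equivalence class under cyclic
rotation and reverse complement; the representative is the
lexicographically smallest of all rotations of the motif and of its reverse
complement, labelled e.g. `AG/CT` (self-complementary classes collapse to
`AT/AT`). Invariance under rotation and reverse complement is
property-tested.

## Locus clustering and allele calling

Each SSR tract is masked with a single `*` so that allele-length variation
cannot break flank identity. Clustering is greedy centroid clustering in
the VSEARCH spirit: records sorted by (masked length desc, sequence asc)
join the first centroid of the *same canonical class* with identity ≥
`identity_threshold` (default 0.90; the tool this emulates publishes no
threshold, and class restriction prevents chimeric loci).

**Identity definition (a deliberate numerical choice).** Identity is the
number of matched columns in the best end-gap-free alignment divided by the
*shorter* sequence length. Two masked strings from the same locus differ
mainly by how much right flank survives read truncation — one is nearly a
prefix of the other — and score ≈ 1 under this definition, while an
incidental short overlap between unrelated flanks scores near 0. Dividing
by the aligned-region length instead (the naive reading) lets unrelated
sequences reach high identity through a clipped 5-base overlap and merges
distinct loci; dividing by the longer length splits genuine loci whose
allele span is large. The implementation short-circuits: equal strings;
then an ungapped comparison over the common prefix (a valid end-gap-free
alignment, hence a lower bound) accepts directly; the gapped alignment
(Biostrings, match +1 / mismatch −1 / linear gap −2 over the `ACGT*`
alphabet) is consulted only in the band between 0.35 and the threshold.
Below 0.35 the pair is rejected without alignment: under the
substitution-only error model this pipeline targets (indel-bearing reads do
not survive exact stacking), no same-locus pair can fall that low. This is
a known limitation for data with real flank indels.

A cluster is **polymorphic** when ≥2 distinct repeat counts are each
observed in ≥ `min_allele_obs` accessions (default 1); heterozygous
accessions contribute two stacks and hence two counts. Alleles are keyed by
repeat count, not fragment length, which keeps them robust to flank
variation; fragment length is derived when needed. Marker selection keeps
polymorphic clusters with ≥20 supporting accessions and expected product
80–100 bp. "Support" counts accessions with an SSR-spanning sequence at
the locus (not merely any read): an accession whose reads do not cross the
tract cannot be genotyped at it, so it lends no validation value. The
80–100 bp selection window is applied *on top of* the 50–100 bp design
window rather than replacing it; both are configurable layers.

## Primer design

All windows of length 18–23 in the left flank (forward) and right flank
(reverse complement) are enumerated and filtered by GC 30–67%, Tm 52–60 °C,
homopolymer run ≤ 4 and 3'-anchored self-complementarity ≤ 3. Pairs must
satisfy mutual 3' complementarity ≤ 3 and produce an expected product
inside the range *for the longest observed allele* — that choice keeps
every allele resolvable below 100 bp on a gel. The returned pair minimises

```
|Tm_f − 55| + |Tm_r − 55| + |Tm_f − Tm_r| + 0.1 × |product − midpoint|
```

with ties broken toward the smaller product and then the lexicographically
smaller forward primer, making the design a pure function of its inputs.
Dimer checks are 3'-anchored complementarity counts, not thermodynamic
duplex ΔG — full Primer3 emulation is a non-goal.

**Melting temperature.** SantaLucia (1998) unified nearest-neighbor
thermodynamics with terminal initiation terms and the symmetry correction.
The stated reference conditions of this model alone (50 mM monovalent salt)
systematically underestimate the temperatures printed for validated GBS-SSR
panels by ~4–6 °C; those panels were designed under PCR buffer conditions.
The defaults therefore add the Primer3-style divalent correction — an
effective monovalent concentration `[Na⁺] + 120·√([Mg²⁺] − [dNTP])` in mM
(von Ahsen 2001) with Mg²⁺ 1.5 mM and dNTP 0.6 mM — and use the CT/4
duplex-concentration convention at 50 nM primer. Under these defaults the
recomputed Tm of the bundled 148-primer panel agrees with the printed
column within ±3 °C for the large majority, which is the tolerance the
validation test asserts. All conditions are arguments, so the bare-salt
convention is one call away.

## Diversity statistics

For a locus with allele frequencies `p` obtained by gene counting (two
copies per genotyped individual; missing genotypes excluded from every
denominator):

* `He = 1 − Σ pᵢ²` — **without** small-sample correction. The uncorrected
  form reproduces the printed biallelic entries of the bundled marker panel
  from their MAF column (0.86 → He 0.24, PIC 0.21 at two decimals), so it
  is taken as that panel's convention.
* `PIC = 1 − Σ pᵢ² − Σ_{i<j} 2 pᵢ² pⱼ²` (Botstein), computed via
  `(Σ p²)² − Σ p⁴` for the cross term. `PIC ≤ He` is an algebraic identity
  asserted over 1000 random genotype tables.
* `Ho` = heterozygous / genotyped individuals; `MAF = max pᵢ`;
  `Na` = alleles with `pᵢ > 0`. Individual heterozygosity is
  100 × heterozygous loci / genotyped loci.

**Distances.** Two codominant measures, labelled explicitly in output
rather than claiming equivalence to any particular "Nei's distance"
citation: `nei1972`, the standard distance
`D = −ln(J_xy / √(J_x J_y))` over per-individual allele frequencies (0, ½,
1); and `shared_allele`, `d = 1 − mean(shared)/2` with multiset allele
sharing per locus. The tree/PCoA default is `shared_allele`, the family of
dissimilarities codominant-marker packages use for individual-level data.
Missing data: pairwise deletion in distances, per-locus deletion in
statistics; a pair with no co-genotyped locus yields `NA` and is reported,
not imputed.

**NJ** is the Saitou–Nei agglomeration on
`Q(i,j) = (n−2)d(i,j) − Rᵢ − Rⱼ` with ties broken toward the
lexicographically smallest current index pair, standard branch-length
formulas, closed-form final three-taxon lengths, and Newick output
(negative branch lengths are reported as computed, as `ape::nj` does).
Property tests require exact recovery of random additive trees up to 10
tips — topology and path lengths.

**PCoA**: Gower double-centering of `−d²/2`, symmetric eigendecomposition;
negative eigenvalues are retained in the report but excluded from the
percent-variance denominator; axis signs are fixed by making each axis's
largest-magnitude coordinate positive. Reconstruction of planted 2-D
configurations to 1e-9 is part of the acceptance suite.

**Mantel**: Pearson correlation of upper-triangle entries; significance
from joint row/column permutations of the second matrix under an explicit
seed, `p = (#{r* ≥ r} + 1)/(n_perm + 1)` (one-sided for positive
association, the direction of interest for isolation-by-distance).
Constant matrices are an error, not `r = 0`. Under the null the p-values
are uniform within Monte-Carlo error (KS-tested over 200 replicates).
Geographic input uses great-circle (haversine) distances from decimal
degrees, in km.

## What the simulator emulates — and what it does not

`sim_config()` describes the validation world: 20 accessions split into an
outcrossing "tall" group (F = 0.1) and a predominantly selfing "dwarf"
group (F = 0.9), mirroring the two ecotypes of the motivating crop; 50
planted loci of which 30 are polymorphic (2–4 alleles, Dirichlet-like
frequencies); motif classes apportioned ≈67/29/3/0.5/1% as mining studies
observe; 100-bp reads at 15× per locus and accession; substitution errors
at 0.1% with Q15 at errored bases, Q30 elsewhere. Background GC is 0.45,
a round value in the plant-typical AT-rich range. Reference repeat counts
are 9–11 for dinucleotides and 5–7 for longer motifs, placing planted
tracts and their ±3-repeat alleles comfortably inside a 90-bp read with
flanks long enough for primer windows.

Each locus is a cassette: an ApeKI site, the `CWGC` remnant, a 25-bp left
flank, the tract, and right filler sized so that the fragment's reverse-end
read never reaches the tract (those reads become realistic non-SSR
background). Fillers are rejection-sampled to contain no unplanned
restriction site (including junction-spanning ones) and no unplanned SSR,
and the finished genome is verified by running the detector over it —
failure to verify is an error, not a warning.

Not emulated: PCR/amplification bias (fragments are sampled uniformly at
the configured depth), indel sequencing errors (substitutions dominate GBS
error profiles and indel handling in exact stacking is a non-goal),
methylation sensitivity of the enzyme, paralogy, and the repeat content of
a real multi-gigabase genome. A green end-to-end test therefore
establishes that the pipeline's logic recovers what it claims under a
clean, known world — not that it would achieve the same rates on real
libraries, whose raw-data tallies additionally depend on archived
sequencing data and wet-lab genotyping outside desk scale.

## Pipeline and determinism

`run_pipeline()` executes demux → stacks → catalog → ssr → cluster → call →
primers, writing per-stage artifacts plus JSON reports with the stage
tallies and artifact MD5 checksums. Reruns skip intact stages; a checksum
mismatch halts at the corrupted stage by name; `force = TRUE` rebuilds.
Every stage is a pure function of its inputs and configuration, so reruns
are bit-identical — the test suite asserts this on checksums. Simulation
randomness flows from a single mandatory seed (genome, population and read
generation use fixed offsets of it), and the Mantel permutation stream has
its own seed argument, isolated from the caller's RNG state.

## Known limitations

* Clustering identity rejects pairs below 0.35 ungapped identity without a
  gapped alignment; flank-indel-rich data would need that band widened.
* Greedy first-fit clustering and cataloguing are order-deterministic, not
  globally optimal; the fixed sort keys make them reproducible but a
  borderline record joins the first acceptable centroid, not the best one.
* `nei1972` distances are infinite for pairs sharing no alleles at any
  co-genotyped locus (the log of zero similarity); the allele-sharing
  measure is the robust default for individual-level trees.
* The primer dimer model counts 3'-anchored complementary bases only; no
  ΔG, hairpins, or multiplexing constraints.
* STRUCTURE/DAPC analyses are exporters only, by design.
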