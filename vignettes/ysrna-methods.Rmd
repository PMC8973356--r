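---
title: "Mutant-pool profiling of Y RNA cleavage: models, conventions and design choices"
author: "ysrna"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mutant-pool profiling of Y RNA cleavage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ysrna)
```

## The experiment this package models

Y RNAs are ~84–112 nt Pol III transcripts folded into a conserved stem–loop
rod. During stress and apoptosis they are cleaved into 3′ and 5′ fragments
(ysRNAs). A saturation-mutagenesis pool experiment probes the determinants of
that cleavage: a 5-nt window of the reference is replaced by fully random
nucleotides (4⁵ = 1,024 variants), the pool is expressed in cells, apoptosis
is induced, and the resulting small RNAs are sequenced with high-definition
(HD) adapters. Which variants still produce fragments, and where the fragment
boundaries fall, identifies the cleavage rules.

`ysrna` implements everything in that workflow that happens at a desk:
enumeration, simulation, trimming, demultiplexing, and inference. The
simulator plays the role of the wet lab — it embeds the cleavage rules as
explicit, configurable parameters, so every inference the pipeline makes can
be validated as parameter recovery against a known ground truth.

## Coordinate and naming conventions

* All positions are 1-based and inclusive.
* A cleavage site is named **cut after position i**: the scission lies
  between *i* and *i* + 1. A 3′ fragment with cut after *i* spans
  *i* + 1 … L; a 5′ fragment spans 1 … *i*. Hence the exact identities
  `cut_after + frag3 length = L` and `frag5 length = cut_after`, which are
  asserted throughout.
* The **offset** of a cut above a stem is the number of nucleotides strictly
  between the cut and the first paired base of the stem's 5′ strand
  (`stem_start − 1 − cut_after`); a cut "between the 2nd and 3rd nt above
  the stem" has offset 2.
* Variant motifs are ordered lexicographically with A < C < G < U; the
  ordinal of a motif is its base-4 value (A=0 … U=3). This makes every
  ranking and every tie-break deterministic.

## The packaged synthetic reference

The true Y RNA sequence is deliberately not bundled; instead
`ysrna_reference()` returns a purpose-built 81-nt sequence whose geometry
realizes every landmark the analysis needs, all simultaneously verifiable:

```{r}
ysrna_reference()
```

* positions 22–26 read **UGGGU** inside loop L2b (the 5′ rule motif);
* position 8 (C) pairs with 68 (G), with an unpaired **cytidine bulge at 9**
  — the RO60 binding site. The C:G orientation (rather than G:C) was chosen
  so that the last position of the L3 window (68) must be G for the site to
  survive, reproducing the observed selection for G at the 5th L3 position;
* the 3′ cut region 49–51 reads **U‑C‑C**, so cuts fall between U49/C50 and
  C50/C51;
* **stem S3** spans 52–57 (5′-strand motif CCACA, 6 bp, 4/6 G:C) pairing
  61–66, with a 9-nt internal loop **L2a** (43–51) above it — 9 nt so that
  the full Δ1–Δ9 loop-deletion series is representable;
* the length is 81 so that a cut 2 nt above S3 (after 49) releases the modal
  **32-nt** 3′ fragment, and the 5′ cut after 32 releases a 32-nt 5′
  fragment.

The curated wild-type structure ships as a dot-bracket annotation
(`ysrna_wt_structure()`), not as a prediction. Six windows L1–L6 mirror the
mutagenesis pools: L1 over the S3 5′ strand, L2 inside loop L2a, L3 over the
RO60-pairing region, L4 over UGGGU, L5/L6 flanking the 5′ cut. Users can
substitute any reference via FASTA plus a landmark list.

## Folding: a weighted base-pair maximizer, by design

`fold()` is a Nussinov-style dynamic program maximizing total pair weight
(G:C = 3, A:U = 2, G:U = 1, hairpin loops ≥ 3 nt), with a fully
deterministic traceback (prefer "leave *i* unpaired", then the smallest
partner). The weights order pairs by stability so GC-rich helices win, and —
unlike a thermodynamic model — the optimum is exhaustively checkable: the
test suite verifies `fold()` against a brute-force enumeration of **all**
nested structures for hundreds of random sequences up to 14 nt.

A base-pair maximizer will not reproduce curated structures of an 81-nt RNA
(it finds many small scattered helices), and the package never pretends it
does: all structure-consuming functions accept any `secondary_structure`,
and curated or externally predicted structures can be imported from
plain-text Vienna-layout dot-bracket files (`read_dotbracket()`). Pair
legality checking can be disabled (`check_pairs = FALSE`) for hypothetical
geometries that stand for a family of mutants, such as the shifted-stem
annotation below. Pseudoknots are rejected.

`parse_elements()` decomposes a structure into maximal stacked helices
(1-bp helices count as stems — such elements do occur beside loop L2b) and
loops classified as hairpin / bulge / internal / multibranch; the test suite
asserts the decomposition partitions every position exactly once.

## The simulator and its defaults

`cleavage_rules()` encodes the ground truth a simulation embeds:

* **rule3** (structural): stem S3 located as the first stem strictly
  downstream of the cut-region start; required stem length ≥ 5 bp
  (reflecting the characteristic 5–6 bp stem); an internal loop of
  ≥ 1 unpaired nt immediately above the stem; an intact RO60 site
  (pair + bases + unpaired C bulge) unless `require_ro60 = FALSE`; cut
  offsets drawn from `{2: 0.6, 3: 0.4}`. Both offsets are reported
  experimentally with the shorter (32 nt) fragment as the dominant size
  class, so offset 2 must be modal; the exact split is not published and
  0.6/0.4 was fixed once as a realistic choice.
* **rule5** (sequence): UGGGU required at position 22, exact by default
  (one mismatch tolerated if `exact_match_required = FALSE`); the 5′ cut is
  drawn over the cut-region positions 32/33 with probabilities 0.7/0.3 —
  again the boundary split is unpublished; 0.7 makes cut-after-32 modal,
  matching the dominant 5′ size class.
* **efficiency** = 0.5: the per-molecule probability that a
  cleavage-competent variant is actually cleaved. Relative cleavage
  efficiencies among competent variants are described only qualitatively in
  the literature, so this is a free scale; 0.5 gives fragment and
  full-length signal comparable weight, as on the blots.

`simulate_pool()` wraps each insert in the HD read layout — 4 random nt,
insert, 4 random nt, the 8-nt adapter prefix TGGAATTC (UGGAAUUC in RNA),
then 4 random tail bases — applies per-base substitution errors (default
0.1%), and adds 5% random decoy reads standing in for the genome-derived
background fraction; decoys must be *rejected by assignment*, not modelled
further. Quality strings are constant because the trimming protocol never
uses them. No indels, PCR duplicates or quality-dependent errors are
simulated. 3′ fragments always extend to the transcript 3′ end and 5′
fragments always start at position 1, which is how cut positions are read
off fragment boundaries in the first place. All randomness flows through a
single seed; outputs are byte-identical per seed.

What passing simulation-based tests shows, and what it does not: recovery of
offsets, motifs, loop thresholds and size classes demonstrates the
*pipeline's* correctness under the modelled noise, not the biological truth
of the rules on real cells — real libraries add ligation bias, PCR
artefacts, indels and mapping ambiguity that this generator intentionally
omits.

## Trimming and assignment

Trimming follows the HD protocol exactly: reject reads containing `N`,
locate the **leftmost** perfect occurrence of the 8-nt adapter prefix
(leftmost maximizes adapter removal and is standard practice; the protocol
itself does not disambiguate multiple hits), discard it and everything
after, then strip 4 HD bases positionally from each end. The minimum insert
is 15 nt — no threshold is published; ysRNAs of interest are ≥ 22 nt, so 15
is safely below while still excluding junk. Whether HD bases are removed
before or after the adapter search does not affect exact-match results; the
adapter is searched first here.

Assignment is exact-substring matching against all 4^k variant sequences,
implemented as reference matching with mismatches confined to the window. A
read covering the window identifies exactly one variant (every k-mer exists
in the library); matching reads that do not cover the window are tallied
**pool-level** rather than fractionally distributed — fractional assignment
would fabricate per-variant signal the data cannot support. Reads are
classified by boundary (full-length / 3′ fragment / 5′ fragment / internal),
with the prefix-and-suffix degenerate case classified 5′-first and counted.
Read-count conservation (`unassigned + pool_level + per-variant = accepted`)
is exact and asserted.

One instructive artefact: a variant whose window content recreates the
adapter sequence across its flanks (in the L3 window, motif GAAUU completes
UGGAAUUC at positions 62–69) is internally trimmed and can never be observed
full length by a perfect-match pipeline. The full-length completeness
analysis therefore uses the L2 window, which was checked exhaustively to be
collision-free at every alignment offset (as are L1 and L4).

## Inference and statistics

* `recover_offset()` converts each 3′ fragment boundary into an offset above
  the located stem and reports the pooled histogram and mode (ties toward
  the smaller offset).
* `loop_length_response()` computes the fragment yield
  `frag / (frag + full_length)` across a loop-size series and reports the
  minimal permissive loop size. The yield denominator mirrors comparing
  fragment against full-length signal on a blot; it is undefined (flagged)
  when no reads exist.
* `localize_motif()` contrasts competent against incompetent variants by
  per-position information content (pseudocount 0.5 per base — unpublished,
  Laplace-style; logo heights are IC × frequency, the standard convention)
  and reports the consensus and the first position whose IC difference
  exceeds half the maximum. "Competent" means yield above 10% of the
  wild-type variant's yield — the published description ("barely produce"
  fragments) carries no number, so the threshold is an explicit parameter.
* `structure_vs_sequence_report()` contrasts Spearman rank correlations of
  per-variant yield with structural similarity (negated base-pair distance
  to wild type) and with sequence similarity (negated window Hamming
  distance). Spearman rather than Pearson because yields are bounded,
  non-normal, and the claim being tested is ordinal. Constant yields are
  flagged and the correlation reported as 0.
* Pool coverage: presence probability 1 − (1 − 1/V)ⁿ and its inverse
  `min_pool_size()`. The published 5,000-colony statement is interpreted as
  a **per-variant** 99% presence target: `min_pool_size(1024, 0.99)` = 4,714
  ≤ 5,000, whereas requiring all 1,024 variants jointly at 99% needs ~9,400
  colonies and contradicts the printed figure.

```{r}
min_pool_size(1024, 0.99)
presence_probability(1024, 5000)
```

## Degenerate inputs and numerical choices

Empty read sets yield empty (flagged) tables, not errors; absent cleavage
signals raise classed conditions (`ysrna_no_cleavage`, `ysrna_no_stem`) that
callers can catch; malformed FASTQ, unbalanced dot-brackets, illegal pairs
and out-of-range landmarks are hard errors. The closed-form
`min_pool_size()` is safeguarded by a local scan so floating point can never
produce an off-by-one result. All modal statistics break ties toward the
smaller value.

## Problem sizes used in validation

The shipped checks run at desk scale, chosen to keep every statistic far
from its noise floor: full-length completeness at depth 20,000 (per-variant
missing probability ≈ 3 × 10⁻⁹ under uniform abundance), offset/size-class/
motif recovery at depth 10,000, the loop series at depth 1,000 per mutant,
and folding verified against exhaustive enumeration for sequences ≤ 14 nt.

## Known limitations

Exact matching means one sequencing error anywhere in the insert unassigns
the read: the unassigned fraction grows with error rate and the pipeline
measures rather than corrects it. The simulator's decoys are uniform random
sequences, far easier to reject than real genomic reads. The 5′ rule is a
single-motif gate; the adjacent UUAU/loop-L2b selection observed in 5′
pools can be probed with the same motif-localization machinery by
configuring a second window, but the package deliberately does not merge
the two calls. Mismatch-tolerant mapping, thermodynamic folding and
structure drawing are out of scope.
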