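# Packaged synthetic Y RNA reference and annotated structures.
#
# The true RNY5 sequence is not bundled; this is a purpose-built 81-nt
# Y RNA-like sequence whose geometry reproduces the coordinates the analysis
# is expressed against: a UGGGU motif at 22-26 inside loop L2b, a C8:G68
# closing pair with an unpaired cytidine bulge at 9 (the RO60 site), a 9-nt
# internal loop L2a (43-51) ending in U49/C50/C51, and a 6-bp GC-rich stem S3
# at 52-57 (5' strand motif CCACA) so that a cut 2 nt above the stem (after
# position 49) releases a 32-nt 3' fragment and a 5' cut after position 32
# releases a 32-nt 5' fragment.

YSRNA_REF_SEQ <- "GGAGACGCCUAAGUCGAUUAAUGGGUUAUCAUACAACACGACAACAUAUCCCCACAGGAACUGUGGAGCGUCACUUGCAUC"

YSRNA_REF_DB <- paste0(
  "...",        #  1-3   exterior
  "(((((",      #  4-8   lower stem P1 (8 pairs 68)
  ".",          #  9     cytidine bulge (RO60)
  "(",          # 10     P2
  "..",         # 11-12
  "((((",       # 13-16  P3
  "..........", # 17-26  loop L2b 5' side (motif 22-26)
  "((", "...", "))",  # 27-33 upper hairpin
  ".....",      # 34-38  loop L2b 3' side
  "))))",       # 39-42  P3'
  ".........",  # 43-51  internal loop L2a
  "((((((",     # 52-57  stem S3
  "...",        # 58-60  S3 hairpin
  "))))))",     # 61-66  stem S3'
  ")",          # 67     P2'
  ")))))",      # 68-72  P1'
  ".........")  # 73-81  3' tail

YSRNA_LANDMARKS <- list(
  ro60_pair      = c(8L, 68L),
  ro60_bulge_pos = 9L,
  cut3_region    = c(49L, 51L),
  cut5_region    = c(32L, 33L),
  motif5_window  = c(22L, 26L),
  loop_L2a_span  = c(43L, 51L),
  loop_L2b_span  = c(23L, 26L),
  stem_S3_span   = c(52L, 57L))

#' Packaged synthetic Y RNA reference
#'
#' An 81-nt synthetic Y RNA-like sequence with full landmark annotation (see
#' the package vignette for how each landmark was placed). Cleaving it after
#' position 49 — 2 nt above stem S3 — yields the modal 32-nt 3' fragment;
#' cleaving after position 32 yields the 32-nt 5' fragment.
#'
#' @return A `reference_rna`.
#' @export
#' @examples
#' ysrna_reference()
ysrna_reference <- function() {
  reference_rna(YSRNA_REF_SEQ, id = "yrna_synthetic_81",
                landmarks = YSRNA_LANDMARKS)
}

#' Annotated wild-type structure of the packaged reference
#'
#' The curated dot-bracket annotation the fixture was designed around (stem
#' S3 at 52-57/61-66, internal loop L2a 43-51, RO60 bulge at 9). This is an
#' annotation, not a prediction: [fold()] maximizes weighted base pairs and
#' need not reproduce it.
#'
#' @return A `secondary_structure`.
#' @export
ysrna_wt_structure <- function() {
  secondary_structure(YSRNA_REF_SEQ, YSRNA_REF_DB)
}

#' Shifted-stem structure emulating L1-like mutants
#'
#' In L1-like mutants the internal loop L2a shortens and the S3 helix starts
#' two positions earlier (position 50 instead of 52), so the cut 2-3 nt above
#' the stem moves upstream and the 3' fragments lengthen to 34/35 nt. The
#' stem positions are mutated in such variants, so base-pair legality against
#' the wild-type sequence is not enforced (`check_pairs = FALSE`).
#'
#' @return A `secondary_structure`.
#' @export
ysrna_shifted_structure <- function() {
  db <- paste0(substr(YSRNA_REF_DB, 1L, 42L),
               ".......",   # 43-49  shortened loop L2a
               "((((((",    # 50-55  shifted stem S3
               ".....",     # 56-60  hairpin
               substr(YSRNA_REF_DB, 61L, 81L))
  secondary_structure(YSRNA_REF_SEQ, db, check_pairs = FALSE)
}

#' Default randomized windows of the packaged reference
#'
#' Six 5-nt windows mirroring the mutagenesis pools: `L1` over the stem S3
#' 5' strand (52-56, wild-type motif CCACA), `L2` inside loop L2a (44-48),
#' `L3` over the RO60-pairing region (64-68), `L4` over the UGGGU motif
#' (22-26), `L5` over the upper hairpin 5' side (27-31, wild-type motif
#' starting UAU) and `L6` at 33-37.
#'
#' @param names Optional character vector to subset (e.g. `"L3"`).
#' @return Named list of `randomized_window` objects.
#' @export
ysrna_windows <- function(names = NULL) {
  w <- list(
    L1 = randomized_window("L1", 52L, 5L),
    L2 = randomized_window("L2", 44L, 5L),
    L3 = randomized_window("L3", 64L, 5L),
    L4 = randomized_window("L4", 22L, 5L),
    L5 = randomized_window("L5", 27L, 5L),
    L6 = randomized_window("L6", 33L, 5L))
  if (!is.null(names)) w <- w[names]
  w
}

#' Loop L2a deletion series
#'
#' Emulates the loop-deletion mutants: from the wild-type 9-nt internal loop
#' L2a, `9 - size` nucleotides are deleted from its 5' end, leaving an
#' upstream loop of `size` unpaired nt above stem S3 (size 0 removes the
#' loop entirely). Sequences shorten accordingly and all landmarks
#' downstream of the deletion shift with it.
#'
#' @param sizes Integer vector of remaining loop sizes (default `0:9`).
#' @return A named list (one element per size, names `"loop0"` ...) of lists
#'   with elements `reference` (a `reference_rna` with adjusted landmarks),
#'   `structure` (a `secondary_structure`) and `loop_size`.
#' @export
ysrna_loop_series <- function(sizes = 0:9) {
  wt_loop <- 9L
  if (any(sizes < 0L | sizes > wt_loop))
    stop("loop sizes must be in 0..", wt_loop)
  out <- lapply(as.integer(sizes), function(s) {
    d <- wt_loop - s
    keep <- setdiff(seq_len(81L), if (d > 0L) 43L:(42L + d) else integer(0))
    seq <- paste0(strsplit(YSRNA_REF_SEQ, "")[[1]][keep], collapse = "")
    db  <- paste0(strsplit(YSRNA_REF_DB,  "")[[1]][keep], collapse = "")
    lm <- YSRNA_LANDMARKS
    shift <- function(v) ifelse(v > 42L, v - d, v)
    lm <- lapply(lm, shift)
    lm$loop_L2a_span <- if (s > 0L) c(43L, 42L + s) else NULL
    lm <- lm[!vapply(lm, is.null, logical(1))]
    list(reference = reference_rna(seq, id = paste0("yrna_loop", s), landmarks = lm),
         structure = secondary_structure(seq, db),
         loop_size = s)
  })
  names(out) <- paste0("loop", sizes)
  out
}
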