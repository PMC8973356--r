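#' Configure the simulator's cleavage rules
#'
#' Encodes the two biogenesis rules the mutant-pool experiments support: a
#' structural 3' rule (cleavage 2-3 nt above a sufficiently long stem S3,
#' requiring an upstream internal loop and, optionally, an intact RO60 site)
#' and a sequence 5' rule (a motif, UGGGU by default, required at a fixed
#' reference position). The rule set is the ground truth a simulation embeds
#' and the quantity the inference module is asked to recover.
#'
#' @param rule3 Named list overriding any of: `enabled` (default `TRUE`),
#'   `offsets` (probabilities over cut offsets above stem S3; default
#'   `c("2" = 0.6, "3" = 0.4)`, making the 2-nt offset — hence the 32-nt
#'   fragment — modal), `require_loop_min` (minimum unpaired nt immediately
#'   above the stem, default 1), `require_ro60` (default `TRUE`),
#'   `stem_min_len` (minimum S3 length in bp, default 5).
#' @param rule5 Named list overriding any of: `enabled` (default `TRUE`),
#'   `motif` (default `"UGGGU"`), `motif_start` (1-based reference position,
#'   default 22), `exact_match_required` (default `TRUE`; if `FALSE` one
#'   mismatch is tolerated), `cut_probs` (probabilities over the positions
#'   of the `cut5_region` landmark, default `c(0.7, 0.3)`).
#' @param efficiency Per-molecule probability that a cleavage-competent
#'   variant is actually cleaved, in `[0, 1]` (default 0.5).
#' @return An object of class `cleavage_rules`.
#' @export
#' @examples
#' cleavage_rules(rule3 = list(offsets = c("4" = 1)))  # inject a 4-nt offset
cleavage_rules <- function(rule3 = list(), rule5 = list(), efficiency = 0.5) {
  r3 <- utils::modifyList(list(
    enabled = TRUE,
    offsets = c("2" = 0.6, "3" = 0.4),
    require_loop_min = 1L,
    require_ro60 = TRUE,
    stem_min_len = 5L), rule3)
  r5 <- utils::modifyList(list(
    enabled = TRUE,
    motif = "UGGGU",
    motif_start = 22L,
    exact_match_required = TRUE,
    cut_probs = c(0.7, 0.3)), rule5)
  if (r3$enabled) {
    if (is.null(names(r3$offsets)) || any(is.na(as.integer(names(r3$offsets)))))
      stop("rule3$offsets must be named by integer offsets")
    if (abs(sum(r3$offsets) - 1) > 1e-8)
      stop("rule3$offsets probabilities must sum to 1")
    if (any(as.integer(names(r3$offsets)) < 0L))
      stop("rule3 offsets must be >= 0")
  }
  if (r5$enabled) {
    r5$motif <- normalize_rna(r5$motif)
    if (nchar(r5$motif) < 1L) stop("rule5$motif must be non-empty")
    if (r5$motif_start < 1L) stop("rule5$motif_start must be >= 1")
  }
  if (efficiency < 0 || efficiency > 1) stop("efficiency must be in [0, 1]")
  structure(list(rule3 = r3, rule5 = r5, efficiency = efficiency),
            class = "cleavage_rules")
}

#' @export
print.cleavage_rules <- function(x, ...) {
  cat("Cleavage rules (efficiency ", x$efficiency, ")\n", sep = "")
  if (x$rule3$enabled)
    cat("  3' structural rule: offsets {",
        paste0(names(x$rule3$offsets), ":", x$rule3$offsets, collapse = ", "),
        "} above stem S3 (>= ", x$rule3$stem_min_len, " bp); loop >= ",
        x$rule3$require_loop_min, " nt",
        if (x$rule3$require_ro60) "; RO60 site required", "\n", sep = "")
  else cat("  3' rule disabled\n")
  if (x$rule5$enabled)
    cat("  5' sequence rule: motif ", x$rule5$motif, " at position ",
        x$rule5$motif_start,
        if (x$rule5$exact_match_required) " (exact)" else " (<=1 mismatch)",
        "\n", sep = "")
  else cat("  5' rule disabled\n")
  invisible(x)
}

# Evaluate both rules for one variant; returns pass/fail plus the stem start
# needed to place 3' cuts. Landmarks come from the reference the variant
# belongs to.
evaluate_rules <- function(sequence, structure, rules, landmarks) {
  if (inherits(landmarks, "reference_rna")) landmarks <- landmarks$landmarks
  frag3 <- FALSE; stem_start <- NA_integer_
  if (rules$rule3$enabled) {
    cut3 <- landmarks$cut3_region
    if (is.null(cut3)) stop("landmarks must define 'cut3_region' for the 3' rule")
    stem <- tryCatch(locate_stem_S3(structure, cut3[1]), ysrna_no_stem = function(e) NULL)
    if (!is.null(stem) &&
        stem$length >= rules$rule3$stem_min_len &&
        loop_above_stem(structure, stem) >= rules$rule3$require_loop_min &&
        (!rules$rule3$require_ro60 ||
           ro60_site_intact(sequence, structure, landmarks))) {
      frag3 <- TRUE
      stem_start <- stem$five_prime_span[1]
    }
  }
  frag5 <- FALSE
  if (rules$rule5$enabled) {
    m <- rules$rule5$motif
    at <- substr(sequence, rules$rule5$motif_start,
                 rules$rule5$motif_start + nchar(m) - 1L)
    mm <- sum(strsplit(at, "")[[1]] != strsplit(m, "")[[1]])
    frag5 <- if (rules$rule5$exact_match_required) mm == 0L else mm <= 1L
  }
  list(frag3 = frag3, frag5 = frag5, stem_start = stem_start)
}
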