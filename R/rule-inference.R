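#' Recover the 3' cleavage offset above stem S3
#'
#' For every 3' fragment read, converts the inferred cut position into an
#' offset above the S3 stem of the corresponding variant's structure
#' (see [cut_offset()]) and pools the counts. Recovering a modal offset of
#' 2 reproduces the signature of cleavage between the 2nd and 3rd nt above
#' the stem.
#'
#' @param table An `assignment_table`.
#' @param structures A single `secondary_structure` shared by all variants,
#'   or a list of one per variant in ordinal order. Window-blind (pool
#'   level) fragment reads are usable only with a shared structure.
#' @param reference A `reference_rna` supplying the `cut3_region` landmark
#'   (defaults to the library reference recorded in `structures`' pairing
#'   context; pass explicitly when in doubt).
#' @return A list of class `offset_recovery` with `histogram` (data frame
#'   `offset`, `count`), `modal_offset` (ties broken toward the smaller
#'   offset) and `n_reads`. Signals `ysrna_no_cleavage` if no usable 3'
#'   fragment reads exist, `ysrna_no_stem` if no variant with fragments has
#'   a located stem.
#' @export
recover_offset <- function(table, structures, reference) {
  cut3 <- landmark(reference, "cut3_region")[1]
  one <- inherits(structures, "secondary_structure")
  d <- fragment_detail(table, "frag3", include_pool = one)
  if (!nrow(d) || sum(d$count) == 0L)
    stop(errorCondition("no 3' fragment reads: no cleavage signal",
                        class = c("ysrna_no_cleavage", "ysrnaError")))
  stem_start_for <- function(ord) {
    st <- if (one) structures else structures[[ord + 1L]]
    s <- tryCatch(locate_stem_S3(st, cut3), ysrna_no_stem = function(e) NULL)
    if (is.null(s)) NA_integer_ else s$five_prime_span[1]
  }
  if (one) {
    starts <- rep(stem_start_for(0L), nrow(d))
  } else {
    starts <- vapply(d$ordinal, function(o)
      if (is.na(o)) NA_integer_ else stem_start_for(o), integer(1))
  }
  usable <- !is.na(starts) & d$cut_after < starts
  if (!any(usable))
    stop(no_stem_error(cut3))
  off <- starts[usable] - 1L - d$cut_after[usable]
  agg <- tapply(d$count[usable], off, sum)
  hist <- data.frame(offset = as.integer(names(agg)), count = as.integer(agg))
  hist <- hist[order(hist$offset), , drop = FALSE]
  rownames(hist) <- NULL
  structure(list(histogram = hist,
                 modal_offset = hist$offset[hist$count == max(hist$count)][1],
                 n_reads = sum(hist$count)),
            class = "offset_recovery")
}

#' @export
print.offset_recovery <- function(x, ...) {
  cat("3' cut offset above stem S3: modal offset ", x$modal_offset,
      " (", x$n_reads, " reads)\n", sep = "")
  print(x$histogram, row.names = FALSE)
  invisible(x)
}

#' Fragment yield across a loop-size series
#'
#' Given assignment tables for a series of loop-deletion mutants (loop L2a
#' progressively removed), computes the 3' fragment yield at every loop size
#' and the minimal permissive loop size — the smallest loop that still
#' supports cleavage. Recovering 1 reproduces the "bulge of at least 1 nt is
#' critical and sufficient" rule.
#'
#' @param tables List of `assignment_table` objects, one per loop size.
#' @param loop_sizes Integer vector of the loop sizes, parallel to `tables`.
#' @param type Fragment type for the yield (default `"frag3"`).
#' @return A list of class `loop_response` with `response` (data frame
#'   `loop_size`, `yield`) and `min_permissive_size` (`NA`, with a warning
#'   attribute, if every yield is zero). Errors if fewer than two distinct
#'   loop sizes are supplied.
#' @export
loop_length_response <- function(tables, loop_sizes, type = "frag3") {
  if (length(tables) != length(loop_sizes))
    stop("tables and loop_sizes lengths differ")
  if (length(unique(loop_sizes)) < 2L)
    stop("need at least two distinct loop sizes")
  yield <- vapply(tables, fragment_yield, numeric(1), type = type)
  yield[is.na(yield)] <- 0
  o <- order(loop_sizes)
  resp <- data.frame(loop_size = as.integer(loop_sizes[o]), yield = yield[o])
  pos <- resp$loop_size[resp$yield > 0]
  out <- list(response = resp,
              min_permissive_size = if (length(pos)) min(pos) else NA_integer_)
  if (!length(pos)) attr(out, "flag") <- "all yields zero"
  structure(out, class = "loop_response")
}

#' @export
print.loop_response <- function(x, ...) {
  cat("Loop-size response (minimal permissive loop: ",
      x$min_permissive_size, " nt)\n", sep = "")
  print(x$response, row.names = FALSE)
  invisible(x)
}

#' Localize a selected sequence motif
#'
#' Contrasts the window motifs of cleavage-competent variants against the
#' incompetent ones by per-position information content and reports where
#' and what is selected: the consensus of the competent set, and the first
#' reference position whose IC difference exceeds half of the maximum
#' difference.
#'
#' @param competent,incompetent Character vectors of equal-length window
#'   motifs.
#' @param window_start 1-based reference coordinate of the window's first
#'   position (default 1, i.e. window-local coordinates).
#' @param pseudocount Passed to [pwm_logo()].
#' @return A list of class `motif_call` with `ic_diff` (per-position,
#'   competent minus incompetent), `consensus`, `start` (reference
#'   coordinate of the first strongly selected position, `NA` when no
#'   position is selected) and `called` (logical).
#' @export
localize_motif <- function(competent, incompetent, window_start = 1L,
                           pseudocount = 0.5) {
  if (!length(competent) || !length(incompetent)) stop("empty motif set")
  pc <- pwm_logo(competent, pseudocount)
  pi <- pwm_logo(incompetent, pseudocount)
  if (ncol(pc$freq) != ncol(pi$freq)) stop("motif lengths differ between sets")
  diff <- pc$ic - pi$ic
  mx <- max(diff)
  called <- mx > 0.1  # below 0.1 bit there is no meaningful selection
  first <- if (called) which(diff > mx / 2)[1] else NA_integer_
  structure(list(ic_diff = diff, consensus = pc$consensus,
                 start = if (called) window_start + first - 1L else NA_integer_,
                 called = called),
            class = "motif_call")
}

#' @export
print.motif_call <- function(x, ...) {
  if (x$called)
    cat("Motif call: consensus ", x$consensus, " starting at position ",
        x$start, "\n", sep = "")
  else cat("No motif selection detected (max IC difference ",
           round(max(x$ic_diff), 3), " bits)\n", sep = "")
  cat("IC difference per position:", round(x$ic_diff, 3), "\n")
  invisible(x)
}

# per-variant frag yield: frag / (frag + full), NA when denominator 0
variant_yields <- function(table, type = "frag3") {
  pv <- table$per_variant
  frag <- pv[[type]]
  den <- frag + pv$full_length
  ifelse(den > 0, frag / den, NA_real_)
}

#' Contrast structural and sequence determinants of 3' cleavage
#'
#' Computes, per variant, the 3' fragment yield and two similarity scores to
#' wild type — structural (negated base-pair distance of the variant's
#' structure to the wild-type structure) and sequence (negated Hamming
#' distance of the window motif to the wild-type motif) — and reports the
#' Spearman rank correlation of yield with each. A structure association
#' exceeding the sequence association is the signature that the fold, not
#' the sequence, licenses 3' cleavage.
#'
#' @param table An `assignment_table`.
#' @param structures List of `secondary_structure` objects, one per variant
#'   in ordinal order.
#' @param wt_structure The wild-type `secondary_structure`.
#' @param library The `variant_library` the table was computed from.
#' @param competent_frac Threshold defining competent variants: yield above
#'   this fraction of the wild-type variant's yield (default 0.1).
#' @param min_variants Minimum number of variants with defined yield
#'   (default 10).
#' @return An object of class `rule_report` with `structure_assoc`,
#'   `sequence_assoc` (Spearman correlations), `yields`, `competent`
#'   (ordinals), `modal_offset` and `offset_histogram` (from
#'   [recover_offset()]), and `n_variants`.
#' @export
structure_vs_sequence_report <- function(table, structures, wt_structure,
                                         library, competent_frac = 0.1,
                                         min_variants = 10L) {
  yields <- variant_yields(table, "frag3")
  def <- which(!is.na(yields))
  if (length(def) < min_variants)
    stop("fewer than ", min_variants, " variants with defined yield")
  sd_ <- vapply(def, function(i) structure_distance(structures[[i]], wt_structure),
                numeric(1))
  wt_motif <- library$motifs[library$wildtype_ordinal + 1L]
  hd_ <- vapply(def, function(i)
    sum(strsplit(library$motifs[i], "")[[1]] != strsplit(wt_motif, "")[[1]]),
    numeric(1))
  y <- yields[def]
  assoc <- function(v) {
    if (stats::sd(y) == 0 || stats::sd(v) == 0) return(0)
    stats::cor(y, -v, method = "spearman")
  }
  structure_assoc <- assoc(sd_)
  sequence_assoc <- assoc(hd_)
  flagged <- stats::sd(y) == 0
  wt_yield <- yields[library$wildtype_ordinal + 1L]
  competent <- if (!is.na(wt_yield) && wt_yield > 0)
    table$per_variant$ordinal[!is.na(yields) & yields > competent_frac * wt_yield]
  else integer(0)
  off <- tryCatch(recover_offset(table, structures, library$reference),
                  ysrnaError = function(e) NULL)
  structure(list(structure_assoc = structure_assoc,
                 sequence_assoc = sequence_assoc,
                 yields = yields, competent = competent,
                 modal_offset = if (is.null(off)) NA_integer_ else off$modal_offset,
                 offset_histogram = if (is.null(off)) NULL else off$histogram,
                 n_variants = length(def), constant_yield = flagged),
            class = "rule_report")
}

#' @export
print.rule_report <- function(x, ...) {
  cat("Cleavage rule report (", x$n_variants, " variants)\n", sep = "")
  cat(sprintf("  structure association (Spearman): %.3f\n", x$structure_assoc))
  cat(sprintf("  sequence association  (Spearman): %.3f\n", x$sequence_assoc))
  if (!is.na(x$modal_offset))
    cat("  modal 3' cut offset above stem S3:", x$modal_offset, "\n")
  cat("  competent variants:", length(x$competent), "\n")
  if (isTRUE(x$constant_yield)) cat("  [flag] yields constant; associations undefined (0)\n")
  invisible(x)
}

#' @export
summary.rule_report <- function(object, ...) {
  cat("Structure vs sequence contrast for 3' cleavage\n")
  print(object)
  if (!is.null(object$offset_histogram)) {
    cat("  offset histogram:\n")
    print(object$offset_histogram, row.names = FALSE)
  }
  invisible(object)
}
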