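LEGAL_PAIRS <- c("AU", "UA", "GC", "CG", "GU", "UG")

#' Construct a secondary structure from a dot-bracket string
#'
#' Builds the pair table from a nested (pseudoknot-free) dot-bracket string
#' and validates it against the sequence. Only `(`, `)` and `.` are allowed;
#' other bracket types (pseudoknot notation) are rejected.
#'
#' @param sequence RNA sequence (T accepted and normalized to U).
#' @param dotbracket Dot-bracket string of the same length.
#' @param check_pairs If `TRUE` (default) every base pair must be one of
#'   AU/UA/GC/CG/GU/UG. Set to `FALSE` for hypothetical geometries (e.g. a
#'   stem annotation standing in for a family of mutants whose window
#'   content varies).
#' @return An object of class `secondary_structure` with elements
#'   `sequence`, `dotbracket` and `pair_table` (integer vector; 0 means
#'   unpaired, otherwise the 1-based partner position).
#' @export
#' @examples
#' ss <- secondary_structure("GGGAAACCC", "(((...)))")
#' ss$pair_table
secondary_structure <- function(sequence, dotbracket, check_pairs = TRUE) {
  sequence <- normalize_rna(sequence)
  if (nchar(sequence) != nchar(dotbracket))
    stop("sequence and dot-bracket lengths differ (",
         nchar(sequence), " vs ", nchar(dotbracket), ")")
  pt <- dotbracket_to_pairtable(dotbracket)
  if (check_pairs) {
    b <- strsplit(sequence, "")[[1]]
    up <- which(pt > seq_along(pt))
    bad <- up[!(paste0(b[up], b[pt[up]]) %in% LEGAL_PAIRS)]
    if (length(bad))
      stop("illegal base pair(s) at position(s) ",
           paste(bad, collapse = ", "), " (", paste0(b[bad], ":", b[pt[bad]],
           collapse = ", "), ")")
  }
  structure(list(sequence = sequence, dotbracket = dotbracket, pair_table = pt),
            class = "secondary_structure")
}

dotbracket_to_pairtable <- function(dotbracket) {
  d <- strsplit(dotbracket, "")[[1]]
  if (any(!d %in% c("(", ")", ".")))
    stop("dot-bracket may contain only '(', ')' and '.' (pseudoknots unsupported)")
  pt <- integer(length(d))
  stack <- integer(0)
  for (i in seq_along(d)) {
    if (d[i] == "(") stack[length(stack) + 1L] <- i
    else if (d[i] == ")") {
      if (!length(stack)) stop("unbalanced dot-bracket: unmatched ')' at ", i)
      j <- stack[length(stack)]; stack <- stack[-length(stack)]
      pt[i] <- j; pt[j] <- i
    }
  }
  if (length(stack)) stop("unbalanced dot-bracket: unmatched '(' at ",
                          paste(stack, collapse = ", "))
  pt
}

pairtable_to_dotbracket <- function(pt) {
  d <- rep(".", length(pt))
  d[pt > seq_along(pt)] <- "("
  d[pt != 0 & pt < seq_along(pt)] <- ")"
  paste0(d, collapse = "")
}

#' @export
print.secondary_structure <- function(x, ...) {
  cat("Secondary structure (", nchar(x$sequence), " nt, ",
      sum(x$pair_table > 0) / 2, " pairs)\n", sep = "")
  cat(" ", x$sequence, "\n ", x$dotbracket, "\n", sep = "")
  invisible(x)
}

pair_weight_matrix <- function(weights = c(GC = 3, AU = 2, GU = 1)) {
  w <- matrix(0, 4, 4, dimnames = list(RNA_BASES, RNA_BASES))
  w["G", "C"] <- w["C", "G"] <- weights[["GC"]]
  w["A", "U"] <- w["U", "A"] <- weights[["AU"]]
  w["G", "U"] <- w["U", "G"] <- weights[["GU"]]
  w
}

#' Fold an RNA by weighted base-pair maximization
#'
#' Predicts a nested secondary structure maximizing the total pair weight
#' (Nussinov-style dynamic programming) subject to a minimum hairpin-loop
#' size. Weighting pairs GC > AU > GU pushes the optimum toward GC-rich
#' helices, a crude stand-in for thermodynamic stability that is exhaustively
#' testable; curated or thermodynamic structures can be supplied instead as
#' dot-bracket files and all downstream feature extraction is agnostic to
#' where a structure came from.
#'
#' The traceback is deterministic: at each decomposition step position i is
#' left unpaired if that achieves the optimum, otherwise i is paired with
#' the smallest admissible partner.
#'
#' @param sequence RNA sequence (T normalized to U).
#' @param min_hairpin Minimum number of unpaired bases in a hairpin loop
#'   (default 3).
#' @param pair_weights Named numeric vector with elements `GC`, `AU`, `GU`.
#' @return A `secondary_structure` with an additional `score` element, the
#'   total pair weight of the returned structure.
#' @export
#' @examples
#' fold("GGGAAACCC")$dotbracket  # "(((...)))", score 9
fold <- function(sequence, min_hairpin = 3, pair_weights = c(GC = 3, AU = 2, GU = 1)) {
  sequence <- normalize_rna(sequence)
  b <- strsplit(sequence, "")[[1]]
  n <- length(b)
  wm <- pair_weight_matrix(pair_weights)
  pw <- wm[b, b, drop = FALSE]        # n x n pairwise weights
  W <- matrix(0, n + 1L, n + 1L)      # padded; entries with i > j stay 0
  minh <- as.integer(min_hairpin)
  if (n >= minh + 2L) {
    for (span in (minh + 1L):(n - 1L)) {
      for (i in seq_len(n - span)) {
        j <- i + span
        ks <- (i + minh + 1L):j
        wk <- pw[i, ks]
        ok <- wk > 0
        best <- W[i + 1L, j]
        if (any(ok)) {
          kk <- ks[ok]
          best <- max(best, wk[ok] + W[i + 1L, kk - 1L] + W[cbind(kk + 1L, j)])
        }
        W[i, j] <- best
      }
    }
  }
  # deterministic traceback: prefer "i unpaired", then smallest partner
  pt <- integer(n)
  stack <- list(c(1L, n))
  while (length(stack)) {
    ij <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
    i <- ij[1]; j <- ij[2]
    while (i < j) {
      if (W[i, j] == W[i + 1L, j]) { i <- i + 1L; next }
      ks <- (i + minh + 1L):j
      wk <- pw[i, ks]
      cand <- wk + W[i + 1L, ks - 1L] + W[cbind(ks + 1L, j)]
      k <- ks[which(wk > 0 & abs(cand - W[i, j]) < 1e-9)[1]]
      pt[i] <- k; pt[k] <- i
      if (k + 1L <= j) stack[[length(stack) + 1L]] <- c(k + 1L, j)
      j <- k - 1L; i <- i + 1L
    }
  }
  out <- secondary_structure(sequence, pairtable_to_dotbracket(pt))
  out$score <- structure_weight(out, pair_weights)
  out
}

#' Total pair weight of a structure
#'
#' @param structure A `secondary_structure`.
#' @param pair_weights Named numeric vector with elements `GC`, `AU`, `GU`.
#' @return Numeric scalar.
#' @export
structure_weight <- function(structure, pair_weights = c(GC = 3, AU = 2, GU = 1)) {
  wm <- pair_weight_matrix(pair_weights)
  b <- strsplit(structure$sequence, "")[[1]]
  pt <- structure$pair_table
  up <- which(pt > seq_along(pt))
  sum(wm[cbind(b[up], b[pt[up]])])
}

#' Decompose a structure into stems and loops
#'
#' A stem is a maximal helix of stacked pairs with no interior unpaired
#' nucleotide (a 1-bp helix counts). Loops are the unpaired regions closed by
#' a pair: hairpin (no inner helix), bulge (one inner helix, unpaired run on
#' one side only), internal (one inner helix, runs on both sides) or multi
#' (two or more inner helices). Positions outside any pair form the exterior.
#'
#' @param structure A `secondary_structure`.
#' @return A list of class `structure_elements` with components `stems`
#'   (list; each has `five_prime_span`, `three_prime_span`, `length`,
#'   `gc_fraction`), `loops` (list; each has `kind`, `spans` (list of
#'   `c(start, end)` unpaired runs), `size`) and `exterior` (integer vector
#'   of unpaired exterior positions).
#' @export
#' @examples
#' parse_elements(secondary_structure("GGGAAACCC", "(((...)))"))
parse_elements <- function(structure) {
  pt <- structure$pair_table
  b <- strsplit(structure$sequence, "")[[1]]
  n <- length(pt)

  # stems: maximal runs of stacked pairs
  stems <- list()
  opens <- which(pt > seq_along(pt))
  used <- rep(FALSE, n)
  for (i in opens) {
    if (used[i]) next
    i0 <- i; j0 <- pt[i]
    i1 <- i0; j1 <- j0
    while (i1 + 1L <= n && pt[i1 + 1L] == j1 - 1L && j1 - 1L > i1 + 1L) {
      i1 <- i1 + 1L; j1 <- j1 - 1L
    }
    used[i0:i1] <- TRUE
    pairs <- paste0(b[i0:i1], b[pt[i0:i1]])
    stems[[length(stems) + 1L]] <- list(
      five_prime_span = c(i0, i1), three_prime_span = c(j1, j0),
      length = i1 - i0 + 1L,
      gc_fraction = mean(pairs %in% c("GC", "CG")))
  }

  # loops: regions closed by a pair that is not a stack continuation
  loops <- list()
  for (i in opens) {
    j <- pt[i]
    if (pt[i + 1L] == j - 1L && j - 1L > i + 1L) next  # stacked: no loop here
    spans <- list(); children <- 0L
    k <- i + 1L; run_start <- NA_integer_
    while (k < j) {
      if (pt[k] == 0L) {
        if (is.na(run_start)) run_start <- k
        k <- k + 1L
      } else {
        if (!is.na(run_start)) { spans[[length(spans) + 1L]] <- c(run_start, k - 1L); run_start <- NA_integer_ }
        children <- children + 1L
        k <- pt[k] + 1L
      }
    }
    if (!is.na(run_start)) spans[[length(spans) + 1L]] <- c(run_start, j - 1L)
    size <- sum(vapply(spans, function(s) s[2] - s[1] + 1L, integer(1)))
    kind <- if (children == 0L) "hairpin"
            else if (children == 1L && length(spans) == 1L) "bulge"
            else if (children == 1L) "internal"
            else "multi"
    loops[[length(loops) + 1L]] <- list(kind = kind, spans = spans,
                                        size = size, closing_pair = c(i, j))
  }

  # exterior: unpaired positions not enclosed by any pair
  exterior <- integer(0)
  k <- 1L
  while (k <= n) {
    if (pt[k] == 0L) { exterior <- c(exterior, k); k <- k + 1L }
    else k <- max(pt[k], k) + 1L
  }
  structure(list(stems = stems, loops = loops, exterior = exterior),
            class = "structure_elements")
}

#' @export
print.structure_elements <- function(x, ...) {
  cat("Structure elements: ", length(x$stems), " stem(s), ",
      length(x$loops), " loop(s), ", length(x$exterior),
      " exterior nt\n", sep = "")
  for (s in x$stems)
    cat(sprintf("  stem %d-%d / %d-%d (%d bp, GC %.2f)\n",
                s$five_prime_span[1], s$five_prime_span[2],
                s$three_prime_span[1], s$three_prime_span[2],
                s$length, s$gc_fraction))
  for (l in x$loops)
    cat(sprintf("  %s loop, %d nt [%s]\n", l$kind, l$size,
                paste(vapply(l$spans, function(s) paste(s, collapse = "-"),
                             character(1)), collapse = ", ")))
  invisible(x)
}

#' Locate stem S3 downstream of the 3' cut region
#'
#' Stem S3 is identified as the stem whose 5'-strand start is the smallest
#' coordinate strictly greater than the start of the 3' cut region — the
#' conserved GC-rich helix that the 3' cleavage site sits 2-3 nt above.
#'
#' @param structure A `secondary_structure`, or a pre-parsed
#'   `structure_elements`.
#' @param cut3_start 1-based start of the 3' cut region (e.g. 49).
#' @return The stem element (see [parse_elements()]).
#' @export
locate_stem_S3 <- function(structure, cut3_start) {
  el <- if (inherits(structure, "structure_elements")) structure
        else parse_elements(structure)
  starts <- vapply(el$stems, function(s) s$five_prime_span[1], integer(1))
  ok <- which(starts > cut3_start)
  if (!length(ok))
    stop(no_stem_error(cut3_start))
  el$stems[[ok[which.min(starts[ok])]]]
}

no_stem_error <- function(cut3_start) {
  errorCondition(
    paste0("no stem downstream of the cut region (start ", cut3_start,
           "): structure incompatible with the 3' rule"),
    class = c("ysrna_no_stem", "ysrnaError"))
}

#' Number of unpaired nucleotides immediately above a stem
#'
#' Counts the maximal run of unpaired positions immediately 5' of the stem's
#' 5'-strand start — the internal-loop segment in which 3' cleavage occurs.
#'
#' @param structure A `secondary_structure`.
#' @param stem A stem element (see [locate_stem_S3()]).
#' @return Integer loop size (>= 0).
#' @export
loop_above_stem <- function(structure, stem) {
  pt <- structure$pair_table
  i <- stem$five_prime_span[1] - 1L
  size <- 0L
  while (i >= 1L && pt[i] == 0L) { size <- size + 1L; i <- i - 1L }
  size
}

#' Offset of a cleavage site above a stem
#'
#' The offset is the number of nucleotides strictly between the cut and the
#' first paired base of the stem's 5' strand: `stem_start - 1 - cut_after`.
#' A cut between the 2nd and 3rd nt above the stem has offset 2.
#'
#' @param cut_after Cut position (scission between `cut_after` and
#'   `cut_after + 1`).
#' @param stem A stem element, or an integer stem 5'-strand start.
#' @return Integer offset (>= 0).
#' @export
#' @examples
#' cut_offset(49, 52)  # 2
cut_offset <- function(cut_after, stem) {
  stem_start <- if (is.numeric(stem)) as.integer(stem) else stem$five_prime_span[1]
  if (any(cut_after >= stem_start))
    stop("cut_after must lie strictly 5' of the stem start (", stem_start, ")")
  as.integer(stem_start - 1L - cut_after)
}

#' Is the RO60 binding site intact?
#'
#' RO60 binds a cytidine bulge adjacent to a G:C pair in the lower stem. The
#' site is called intact when the two landmark positions are paired with each
#' other, the pair is G:C or C:G, and the bulge landmark position carries an
#' unpaired C.
#'
#' @param sequence Variant sequence.
#' @param structure A `secondary_structure` for that sequence (lengths must
#'   match).
#' @param landmarks Landmark list with `ro60_pair` (two positions) and
#'   `ro60_bulge_pos`, or a `reference_rna` to take them from.
#' @return Logical scalar.
#' @export
ro60_site_intact <- function(sequence, structure, landmarks) {
  if (inherits(landmarks, "reference_rna")) landmarks <- landmarks$landmarks
  pr <- landmarks$ro60_pair
  bp <- landmarks$ro60_bulge_pos
  if (is.null(pr) || is.null(bp))
    stop("landmarks must define 'ro60_pair' and 'ro60_bulge_pos'")
  sequence <- normalize_rna(sequence)
  n <- nchar(sequence)
  if (max(pr, bp) > n) stop("RO60 landmarks beyond sequence length")
  b <- strsplit(sequence, "")[[1]]
  pt <- structure$pair_table
  pt[pr[1]] == pr[2] &&
    paste0(b[pr[1]], b[pr[2]]) %in% c("GC", "CG") &&
    b[bp] == "C" && pt[bp] == 0L
}

#' Base-pair distance between two structures
#'
#' Size of the symmetric difference of the two base-pair sets; 0 means
#' identical pairing.
#'
#' @param s1,s2 `secondary_structure` objects of equal length.
#' @return Integer distance.
#' @export
structure_distance <- function(s1, s2) {
  if (length(s1$pair_table) != length(s2$pair_table))
    stop("structures have different lengths")
  p1 <- pair_set(s1$pair_table)
  p2 <- pair_set(s2$pair_table)
  length(setdiff(p1, p2)) + length(setdiff(p2, p1))
}

pair_set <- function(pt) {
  i <- which(pt > seq_along(pt))
  if (!length(i)) return(character(0))
  paste0(i, ":", pt[i])
}

#' Read and write dot-bracket structure files
#'
#' Plain-text records in the de-facto Vienna layout: a `>` header line, the
#' sequence line, then the dot-bracket line.
#'
#' @param path File path.
#' @param check_pairs Passed to [secondary_structure()].
#' @return `read_dotbracket()`: a named list of `secondary_structure`
#'   objects. `write_dotbracket()`: `path`, invisibly.
#' @export
read_dotbracket <- function(path, check_pairs = TRUE) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  hdr <- grep("^>", lines)
  if (!length(hdr)) stop("no dot-bracket records in ", path)
  if (any(hdr + 2L > length(lines)))
    stop("truncated dot-bracket record in ", path)
  out <- lapply(hdr, function(h)
    secondary_structure(lines[h + 1L], lines[h + 2L], check_pairs = check_pairs))
  names(out) <- sub("^>\\s*", "", lines[hdr])
  out
}

#' @param structures Named list of `secondary_structure` objects (or one).
#' @rdname read_dotbracket
#' @export
write_dotbracket <- function(structures, path) {
  if (inherits(structures, "secondary_structure"))
    structures <- list(structure_1 = structures)
  if (is.null(names(structures)))
    names(structures) <- paste0("structure_", seq_along(structures))
  lines <- unlist(lapply(names(structures), function(nm)
    c(paste0(">", nm), structures[[nm]]$sequence, structures[[nm]]$dotbracket)))
  writeLines(lines, path)
  invisible(path)
}
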