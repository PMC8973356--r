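RNA_BASES <- c("A", "C", "G", "U")

#' Define a randomized window
#'
#' A randomized window is a contiguous k-nt region of the reference in which
#' every position is substituted by all four bases, giving a pool of 4^k
#' variants (the mutagenesis libraries L1-L6 use k = 5, i.e. 1,024 variants).
#'
#' @param name Window name (e.g. `"L1"`).
#' @param start 1-based start position in the reference.
#' @param length Window length k (1 <= k <= 8; the enumeration bound is 4^8).
#' @param reference Optional `reference_rna`; if supplied the window is
#'   checked to lie fully inside it.
#' @return An object of class `randomized_window`.
#' @export
randomized_window <- function(name, start, length, reference = NULL) {
  start <- as.integer(start); length <- as.integer(length)
  if (is.na(start) || start < 1L) stop("window start must be >= 1")
  if (is.na(length) || length < 1L) stop("window length must be >= 1")
  if (length > 8L) stop("window length ", length, " exceeds enumeration bound (k <= 8)")
  if (!is.null(reference) && start + length - 1L > nchar(reference$sequence))
    stop("window '", name, "' extends beyond the reference")
  structure(list(name = as.character(name), start = start, length = length),
            class = "randomized_window")
}

#' @export
print.randomized_window <- function(x, ...) {
  cat("Randomized window '", x$name, "': positions ", x$start, "-",
      x$start + x$length - 1L, " (4^", x$length, " = ", 4L^x$length,
      " variants)\n", sep = "")
  invisible(x)
}

#' Enumerate the full variant library of a randomized window
#'
#' Produces all 4^k sequences obtained by substituting every possible k-mer
#' into the window. Motifs are ordered lexicographically with A < C < G < U,
#' so the motif of ordinal o (0-based) is the base-4 expansion of o; the
#' wild-type window content appears exactly once.
#'
#' @param reference A `reference_rna`.
#' @param window A `randomized_window` inside the reference.
#' @return An object of class `variant_library` with elements `reference`,
#'   `window`, `motifs` (character vector of length 4^k in ordinal order),
#'   `sequences` (full-length variant sequences, same order), and
#'   `wildtype_ordinal` (0-based ordinal of the wild-type motif).
#' @export
#' @examples
#' lib <- enumerate_variants(ysrna_reference(), randomized_window("L1", 52, 5))
#' length(lib$motifs)   # 1024
enumerate_variants <- function(reference, window) {
  stopifnot(inherits(reference, "reference_rna"), inherits(window, "randomized_window"))
  n <- nchar(reference$sequence)
  if (window$start + window$length - 1L > n)
    stop("window extends beyond the reference")
  k <- window$length
  motifs <- all_kmers(k)
  pre  <- substr(reference$sequence, 1L, window$start - 1L)
  post <- substr(reference$sequence, window$start + k, n)
  sequences <- paste0(pre, motifs, post)
  wt <- substr(reference$sequence, window$start, window$start + k - 1L)
  structure(list(reference = reference, window = window, motifs = motifs,
                 sequences = sequences, wildtype_ordinal = variant_ordinal(wt)),
            class = "variant_library")
}

# all k-mers over ACGU in ordinal (lexicographic) order
all_kmers <- function(k) {
  grids <- rep(list(RNA_BASES), k)
  m <- as.matrix(rev(expand.grid(rev(grids), stringsAsFactors = FALSE)))
  apply(m, 1L, paste0, collapse = "")
}

#' @export
print.variant_library <- function(x, ...) {
  cat("Variant library: window '", x$window$name, "' (positions ",
      x$window$start, "-", x$window$start + x$window$length - 1L, ") of '",
      x$reference$id, "'\n  ", length(x$motifs), " variants; wild-type motif ",
      x$motifs[x$wildtype_ordinal + 1L], " (ordinal ", x$wildtype_ordinal,
      ")\n", sep = "")
  invisible(x)
}

#' Variant ordinals
#'
#' `variant_ordinal()` maps a window motif to its 0-based ordinal, the base-4
#' value of the motif with A=0, C=1, G=2, U=3 (most significant digit first);
#' `ordinal_to_motif()` is the inverse.
#'
#' @param motif Character vector of motifs over A/C/G/U.
#' @return Integer vector of ordinals in `0 .. 4^k - 1`.
#' @export
#' @examples
#' variant_ordinal("AAAAA")  # 0
#' variant_ordinal("UUUUU")  # 1023
variant_ordinal <- function(motif) {
  vapply(motif, function(m) {
    b <- strsplit(normalize_rna(m), "")[[1]]
    d <- match(b, RNA_BASES) - 1L
    as.integer(sum(d * 4^(rev(seq_along(d)) - 1L)))
  }, integer(1), USE.NAMES = FALSE)
}

#' @param ordinal Integer vector of 0-based ordinals.
#' @param k Motif length.
#' @rdname variant_ordinal
#' @export
ordinal_to_motif <- function(ordinal, k) {
  vapply(as.integer(ordinal), function(o) {
    if (o < 0L || o >= 4L^k) stop("ordinal ", o, " out of range for k = ", k)
    d <- integer(k)
    for (i in k:1) { d[i] <- o %% 4L; o <- o %/% 4L }
    paste0(RNA_BASES[d + 1L], collapse = "")
  }, character(1))
}

#' Read the window content of a variant sequence
#'
#' @param sequence Full-length variant sequence(s).
#' @param window A `randomized_window`.
#' @return Character vector of window motifs.
#' @export
window_motif <- function(sequence, window) {
  substr(sequence, window$start, window$start + window$length - 1L)
}

#' Export a variant library as FASTA
#'
#' Headers are `<pool name>_<motif>` so that each record is self-describing.
#'
#' @param library A `variant_library`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_library_fasta <- function(library, path) {
  ids <- paste0(library$window$name, "_", library$motifs)
  writeLines(paste0(">", ids, "\n", library$sequences), path)
  invisible(path)
}
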