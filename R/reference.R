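#' Construct a reference Y RNA
#'
#' A `reference_rna` bundles the wild-type sequence with the 1-based landmark
#' coordinates that every downstream operation (cleavage-site naming, motif
#' windows, structural rules) is expressed against. Coordinates are 1-based
#' and inclusive; a cleavage site is always named "cut after position i",
#' meaning the scission falls between positions i and i+1.
#'
#' @param sequence Character scalar. RNA (or DNA; `T` is converted to `U`)
#'   sequence over `A`, `C`, `G`, `U`/`T`. Case-insensitive.
#' @param id Character scalar identifier.
#' @param landmarks Named list of landmark coordinates. Positions are single
#'   integers (e.g. `ro60_bulge_pos`); spans and pairs are length-2 integer
#'   vectors (e.g. `cut3_region = c(49, 51)`, `ro60_pair = c(8, 68)`).
#'   All coordinates must lie within the sequence.
#' @return An object of class `reference_rna` with elements `id`, `sequence`
#'   and `landmarks`.
#' @seealso [load_reference()] to read from FASTA, [ysrna_reference()] for
#'   the packaged synthetic reference.
#' @export
#' @examples
#' ref <- reference_rna("ACGT")          # T is normalized to U
#' ref$sequence                          # "ACGU"
reference_rna <- function(sequence, id = "reference", landmarks = list()) {
  if (!is.character(sequence) || length(sequence) != 1L || !nzchar(sequence))
    stop("`sequence` must be a non-empty character scalar")
  seq <- normalize_rna(sequence)
  n <- nchar(seq)
  landmarks <- validate_landmarks(landmarks, n)
  structure(list(id = as.character(id), sequence = seq, landmarks = landmarks),
            class = "reference_rna")
}

# T -> U, upper-case; any residual non-ACGU character is an error
normalize_rna <- function(x) {
  x <- chartr("t", "u", toupper(x))
  x <- chartr("T", "U", x)
  bad <- gsub("[ACGU]", "", x)
  if (any(nzchar(bad)))
    stop("non-ACGU/T character(s) in sequence: ",
         paste(unique(strsplit(paste(bad, collapse = ""), "")[[1]]), collapse = " "))
  x
}

validate_landmarks <- function(landmarks, seq_len) {
  if (length(landmarks) == 0L) return(list())
  if (is.null(names(landmarks)) || any(!nzchar(names(landmarks))))
    stop("landmarks must be a named list")
  for (nm in names(landmarks)) {
    v <- landmarks[[nm]]
    if (!is.numeric(v) || length(v) < 1L || length(v) > 2L || any(v != as.integer(v)))
      stop("landmark '", nm, "' must be one or two integer coordinates")
    v <- as.integer(v)
    if (any(v < 1L) || any(v > seq_len))
      stop("landmark '", nm, "' (", paste(v, collapse = ","),
           ") outside sequence of length ", seq_len)
    if (length(v) == 2L && grepl("span$|region$|window$", nm) && v[1] > v[2])
      stop("landmark '", nm, "' has start > end")
    landmarks[[nm]] <- v
  }
  landmarks
}

#' Load a reference Y RNA from FASTA
#'
#' Reads the first record of a FASTA file and attaches landmark coordinates.
#' `T` is converted to `U` and case is folded; any other character is an
#' error, mirroring the exclusion of reads with unassigned nucleotides.
#'
#' @param fasta_path Path to a FASTA file; the first record is used.
#' @param landmarks Named list of landmark coordinates (see
#'   [reference_rna()]).
#' @return A `reference_rna`.
#' @export
load_reference <- function(fasta_path, landmarks = list()) {
  set <- Biostrings::readBStringSet(fasta_path, format = "fasta")
  if (length(set) == 0L) stop("no FASTA record in ", fasta_path)
  reference_rna(as.character(set[[1]]),
                id = sub("\\s.*$", "", names(set)[1]),
                landmarks = landmarks)
}

#' @export
print.reference_rna <- function(x, ...) {
  cat("Reference Y RNA '", x$id, "' (", nchar(x$sequence), " nt)\n", sep = "")
  cat(" ", x$sequence, "\n", sep = "")
  if (length(x$landmarks)) {
    cat("  landmarks:\n")
    for (nm in names(x$landmarks))
      cat("    ", nm, ": ", paste(x$landmarks[[nm]], collapse = "-"), "\n", sep = "")
  }
  invisible(x)
}

ref_char <- function(reference) strsplit(reference$sequence, "")[[1]]

landmark <- function(reference, name, required = TRUE) {
  v <- reference$landmarks[[name]]
  if (is.null(v) && required)
    stop("reference has no '", name, "' landmark")
  v
}
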