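#' Read raw sequencing records (FASTQ or FASTA)
#'
#' Format is auto-detected from the first character (`@` = FASTQ, `>` =
#' FASTA). Sequences are upper-cased and converted to the RNA alphabet
#' (T to U). Reads containing any other character — including the
#' unassigned-nucleotide code `N` — are counted and excluded.
#'
#' @param path Input file.
#' @return A list with `seqs` (named character vector of retained reads, RNA
#'   alphabet), `n_total` and `n_rejected_N`.
#' @export
read_seq_records <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (file.size(path) == 0L)
    return(list(seqs = character(0), n_total = 0L, n_rejected_N = 0L))
  first <- substr(readLines(path, n = 1L), 1L, 1L)
  fmt <- switch(first, "@" = "fastq", ">" = "fasta",
                stop("cannot detect FASTA/FASTQ format in ", path,
                     " (first character '", first, "')"))
  if (fmt == "fastq") {
    nlines <- length(readLines(path))
    if (nlines %% 4L != 0L)
      stop("truncated FASTQ record near line ", nlines, " in ", path)
  }
  set <- Biostrings::readBStringSet(path, format = fmt)
  seqs <- toupper(as.character(set))
  names(seqs) <- sub("\\s.*$", "", names(set))
  seqs <- chartr("T", "U", seqs)
  ok <- !grepl("[^ACGU]", seqs)
  list(seqs = seqs[ok], n_total = length(seqs),
       n_rejected_N = sum(!ok))
}

#' Trim HD-adapter reads
#'
#' Applies the exact trimming rule of the HD-adapter protocol: locate the
#' leftmost perfect occurrence of the 8-nt 3' adapter prefix, discard it and
#' everything after, then remove the four assigned HD nucleotides from each
#' end of what remains. Reads without the adapter, or whose remainder is too
#' short to contain both HD 4-mers plus a minimal insert, are rejected (with
#' a status, never an error).
#'
#' @param seqs Character vector of reads in the RNA alphabet (see
#'   [read_seq_records()]).
#' @param adapter_prefix Adapter prefix to match exactly (default
#'   `"UGGAAUUC"`, the RNA spelling of TGGAATTC).
#' @param hd_len HD bases to strip from each end (default 4).
#' @param min_insert Minimum insert length to accept (default 15).
#' @return A data frame with columns `read_id`, `insert`, `raw_length` and
#'   `status` (`accepted`, `rejected_no_adapter` or `rejected_short`).
#' @export
trim_reads <- function(seqs, adapter_prefix = "UGGAAUUC", hd_len = 4L,
                       min_insert = 15L) {
  adapter_prefix <- normalize_rna(adapter_prefix)
  n <- length(seqs)
  ids <- if (!is.null(names(seqs))) names(seqs) else as.character(seq_len(n))
  raw_length <- nchar(seqs)
  pos <- as.integer(regexpr(adapter_prefix, seqs, fixed = TRUE))
  status <- rep("accepted", n)
  status[pos < 1L] <- "rejected_no_adapter"
  # remainder before the adapter must hold 2*hd_len HD bases plus the insert
  short <- pos >= 1L & (pos - 1L) < (min_insert + 2L * hd_len)
  status[short] <- "rejected_short"
  insert <- rep(NA_character_, n)
  acc <- status == "accepted"
  insert[acc] <- substr(seqs[acc], hd_len + 1L, pos[acc] - 1L - hd_len)
  data.frame(read_id = ids, insert = insert, raw_length = raw_length,
             status = status, row.names = NULL)
}

#' Read and trim a FASTQ/FASTA file in one step
#'
#' @inheritParams read_seq_records
#' @inheritParams trim_reads
#' @return A list of class `trimmed_reads` with `inserts` (named character
#'   vector of accepted inserts), `table` (the full per-read trim table) and
#'   `report` (counts by status, including `rejected_N`).
#' @export
process_fastq <- function(path, adapter_prefix = "UGGAAUUC", hd_len = 4L,
                          min_insert = 15L) {
  rec <- read_seq_records(path)
  tab <- trim_reads(rec$seqs, adapter_prefix = adapter_prefix,
                    hd_len = hd_len, min_insert = min_insert)
  report <- c(total = rec$n_total,
              rejected_N = rec$n_rejected_N,
              rejected_no_adapter = sum(tab$status == "rejected_no_adapter"),
              rejected_short = sum(tab$status == "rejected_short"),
              accepted = sum(tab$status == "accepted"))
  inserts <- tab$insert[tab$status == "accepted"]
  names(inserts) <- tab$read_id[tab$status == "accepted"]
  structure(list(inserts = inserts, table = tab, report = report),
            class = "trimmed_reads")
}

#' @export
print.trimmed_reads <- function(x, ...) {
  cat("Trimmed reads:\n")
  print(x$report)
  invisible(x)
}

#' Write a trimming report / trimmed inserts
#'
#' @param trimmed A `trimmed_reads` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trim_report <- function(trimmed, path) {
  utils::write.table(data.frame(status = names(trimmed$report),
                                count = as.integer(trimmed$report)),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trim_report
#' @export
write_trimmed_fasta <- function(trimmed, path) {
  ins <- trimmed$inserts
  writeLines(as.vector(rbind(paste0(">", names(ins)), chartr("U", "T", ins))),
             path)
  invisible(path)
}
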