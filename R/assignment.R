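#' Assign trimmed reads to a variant library
#'
#' Demultiplexes reads by exact matching: a read is assigned to a variant iff
#' it is an exact substring of that variant's full sequence (no mismatches,
#' mirroring the perfect-match trimming philosophy; reads corrupted by
#' sequencing error fall into the unassigned class, which is reported).
#' Because variants differ only inside the randomized window, a read whose
#' span covers the window identifies exactly one variant; reads that match
#' but do not cover the window carry no per-variant information and are
#' tallied at pool level; reads matching nowhere are unassigned.
#'
#' Reads are classified by their boundaries: a read equal to a full variant
#' sequence is `full_length`; a read ending at the reference 3' end is a 3'
#' fragment with `cut_after = reference length - read length`; a read
#' starting at position 1 is a 5' fragment with `cut_after = read length`.
#' A read that is simultaneously a prefix and a suffix is classified as a 5'
#' fragment and counted in `n_prefix_suffix_ambiguous`. Matches anchored at
#' neither end are tallied as `internal`.
#'
#' @param inserts Character vector of trimmed inserts (RNA alphabet), e.g.
#'   `process_fastq(...)$inserts`.
#' @param library A `variant_library`.
#' @return An object of class `assignment_table` with elements:
#'   `per_variant` (data frame: `ordinal`, `motif`, `full_length`, `frag3`,
#'   `frag5`, `internal` read counts), `frag3_detail` and `frag5_detail`
#'   (data frames: `ordinal` (`NA` = pool level), `cut_after`, `length`,
#'   `count`), `pool_level` (count of window-blind matching reads),
#'   `pool_full_length`, `internal`, `unassigned`, `accepted`,
#'   `n_prefix_suffix_ambiguous`, and `reference_length`.
#' @export
assign_reads <- function(inserts, library) {
  stopifnot(inherits(library, "variant_library"))
  refc <- ref_char(library$reference)
  L <- length(refc)
  ws <- library$window$start
  we <- ws + library$window$length - 1L
  k <- library$window$length

  counts <- table(inserts)
  useqs <- names(counts)
  ucount <- as.integer(counts)

  V <- length(library$motifs)
  pv_full <- integer(V); pv_f3 <- integer(V); pv_f5 <- integer(V); pv_int <- integer(V)
  d3 <- list(); d5 <- list()
  pool_level <- 0L; pool_full <- 0L; internal_total <- 0L
  unassigned <- 0L; ambiguous <- 0L

  add_detail <- function(store, ord, cut, len, cnt) {
    key <- paste(ord, cut, sep = "|")
    if (is.null(store[[key]])) store[[key]] <- c(ord, cut, len, 0L)
    store[[key]][4] <- store[[key]][4] + cnt
    store
  }

  for (u in seq_along(useqs)) {
    s <- useqs[u]; cnt <- ucount[u]
    m <- nchar(s)
    v <- strsplit(s, "")[[1]]
    if (m > L || m < 1L) { unassigned <- unassigned + cnt; next }
    valid <- integer(0)
    for (o in seq_len(L - m + 1L)) {
      mism <- v != refc[o:(o + m - 1L)]
      if (any(mism)) {
        rp <- which(mism) + o - 1L
        if (any(rp < ws | rp > we)) next
      }
      valid <- c(valid, o)
    }
    if (!length(valid)) { unassigned <- unassigned + cnt; next }
    covering <- valid[valid <= ws & valid + m - 1L >= we]
    o <- if (length(covering)) covering[1] else valid[1]
    is_prefix <- 1L %in% valid
    is_suffix <- (L - m + 1L) %in% valid
    if (is_prefix && is_suffix && m < L) ambiguous <- ambiguous + cnt
    # boundary classification at the chosen offset (prefix wins over suffix)
    if (is_prefix) o <- 1L else if (is_suffix && !(o + m - 1L == L))
      o <- L - m + 1L
    type <- if (o == 1L && m == L) "full_length"
            else if (o == 1L) "frag5"
            else if (o + m - 1L == L) "frag3"
            else "internal"
    if (length(covering)) {
      oc <- if (o %in% covering) o else covering[1]
      motif <- paste0(v[(ws - oc + 1L):(we - oc + 1L)], collapse = "")
      ord <- variant_ordinal(motif)
      if (type == "full_length") pv_full[ord + 1L] <- pv_full[ord + 1L] + cnt
      else if (type == "frag3") {
        pv_f3[ord + 1L] <- pv_f3[ord + 1L] + cnt
        d3 <- add_detail(d3, ord, L - m, m, cnt)
      } else if (type == "frag5") {
        pv_f5[ord + 1L] <- pv_f5[ord + 1L] + cnt
        d5 <- add_detail(d5, ord, m, m, cnt)
      } else {
        pv_int[ord + 1L] <- pv_int[ord + 1L] + cnt
        internal_total <- internal_total + cnt
      }
    } else {
      pool_level <- pool_level + cnt
      if (type == "full_length") pool_full <- pool_full + cnt
      else if (type == "frag3") d3 <- add_detail(d3, NA_integer_, L - m, m, cnt)
      else if (type == "frag5") d5 <- add_detail(d5, NA_integer_, m, m, cnt)
      else internal_total <- internal_total + cnt
    }
  }

  as_detail <- function(store) {
    if (!length(store))
      return(data.frame(ordinal = integer(0), cut_after = integer(0),
                        length = integer(0), count = integer(0)))
    m <- do.call(rbind, store)
    df <- data.frame(ordinal = m[, 1], cut_after = m[, 2],
                     length = m[, 3], count = m[, 4])
    df[order(df$ordinal, df$cut_after, na.last = TRUE), , drop = FALSE]
  }
  structure(list(
    per_variant = data.frame(ordinal = 0:(V - 1L), motif = library$motifs,
                             full_length = pv_full, frag3 = pv_f3,
                             frag5 = pv_f5, internal = pv_int),
    frag3_detail = as_detail(d3),
    frag5_detail = as_detail(d5),
    pool_level = pool_level, pool_full_length = pool_full,
    internal = internal_total,
    unassigned = unassigned, accepted = length(inserts),
    n_prefix_suffix_ambiguous = ambiguous,
    reference_length = L, window = library$window),
    class = "assignment_table")
}

#' @export
print.assignment_table <- function(x, ...) {
  pv <- x$per_variant
  cat("Assignment table (window '", x$window$name, "', ", nrow(pv),
      " variants, ", x$accepted, " accepted reads)\n", sep = "")
  cat(sprintf("  per-variant: full-length %d, frag3 %d, frag5 %d\n",
              sum(pv$full_length), sum(pv$frag3), sum(pv$frag5)))
  cat(sprintf("  pool-level (window-blind) %d, unassigned %d\n",
              x$pool_level, x$unassigned))
  invisible(x)
}

# all fragment detail rows of one type, optionally per variant / incl. pool
fragment_detail <- function(table, type = c("frag3", "frag5"),
                            ordinal = NULL, include_pool = TRUE) {
  type <- match.arg(type)
  d <- if (type == "frag3") table$frag3_detail else table$frag5_detail
  if (!is.null(ordinal)) d <- d[!is.na(d$ordinal) & d$ordinal %in% ordinal, , drop = FALSE]
  else if (!include_pool) d <- d[!is.na(d$ordinal), , drop = FALSE]
  d
}

#' Fragment size-class distribution
#'
#' Percentage of fragment reads at each length, the mutant-pool size-class
#' profile. Percentages are over all fragment reads of the requested type(s);
#' lengths outside `length_range` are pooled into overflow bins.
#'
#' @param table An `assignment_table`.
#' @param length_range Two integers, the displayed length range (default
#'   `c(25, 35)`).
#' @param type `"both"` (default), `"frag3"` or `"frag5"`.
#' @param include_pool Include window-blind (pool-level) fragment reads
#'   (default `TRUE`).
#' @return A data frame with columns `bin` (character), `length` (integer,
#'   `NA` for overflow bins), `count` and `percent`. If there are no
#'   fragment reads, all-zero rows are returned with attribute
#'   `attr(, "empty") = TRUE`.
#' @export
size_distribution <- function(table, length_range = c(25, 35),
                              type = c("both", "frag3", "frag5"),
                              include_pool = TRUE) {
  type <- match.arg(type)
  d <- if (type == "both")
    rbind(fragment_detail(table, "frag3", include_pool = include_pool),
          fragment_detail(table, "frag5", include_pool = include_pool))
  else fragment_detail(table, type, include_pool = include_pool)
  lens <- length_range[1]:length_range[2]
  cnt <- vapply(lens, function(l) sum(d$count[d$length == l]), numeric(1))
  under <- sum(d$count[d$length < length_range[1]])
  over  <- sum(d$count[d$length > length_range[2]])
  out <- data.frame(
    bin = c(paste0("<", length_range[1]), as.character(lens),
            paste0(">", length_range[2])),
    length = c(NA_integer_, lens, NA_integer_),
    count = c(under, cnt, over))
  tot <- sum(out$count)
  out$percent <- if (tot > 0) 100 * out$count / tot else 0
  if (tot == 0) attr(out, "empty") <- TRUE
  out
}

#' Modal fragment length
#'
#' @inheritParams size_distribution
#' @return The most frequent fragment length (ties broken toward the
#'   smaller length), or `NA` if there are no fragment reads.
#' @export
modal_length <- function(table, type = c("both", "frag3", "frag5"),
                         include_pool = TRUE) {
  type <- match.arg(type)
  d <- if (type == "both")
    rbind(fragment_detail(table, "frag3", include_pool = include_pool),
          fragment_detail(table, "frag5", include_pool = include_pool))
  else fragment_detail(table, type, include_pool = include_pool)
  if (!nrow(d)) return(NA_integer_)
  agg <- tapply(d$count, d$length, sum)
  lens <- as.integer(names(agg))
  lens[agg == max(agg)][1]
}

#' Infer cleavage positions from read boundaries
#'
#' Aggregates fragment reads into a histogram over cut positions (cut-after
#' coordinates) and reports the modal cut, with ties broken toward the
#' smaller position.
#'
#' @param table An `assignment_table`.
#' @param type `"frag3"` or `"frag5"`.
#' @param ordinal Optional variant ordinal(s) to restrict to; default is the
#'   pool aggregate (all variants plus window-blind reads).
#' @param include_pool Include window-blind fragment reads when `ordinal` is
#'   `NULL`.
#' @return A list of class `cut_histogram` with `histogram` (data frame
#'   `cut_after`, `count`) and `modal_cut`. Signals a classed error
#'   (`ysrna_no_cleavage`) when there are no fragment reads.
#' @export
infer_cut_positions <- function(table, type = c("frag3", "frag5"),
                                ordinal = NULL, include_pool = TRUE) {
  type <- match.arg(type)
  d <- fragment_detail(table, type, ordinal = ordinal, include_pool = include_pool)
  if (!nrow(d) || sum(d$count) == 0L)
    stop(errorCondition(
      paste0("no ", type, " reads: no cleavage signal"),
      class = c("ysrna_no_cleavage", "ysrnaError")))
  agg <- tapply(d$count, d$cut_after, sum)
  hist <- data.frame(cut_after = as.integer(names(agg)),
                     count = as.integer(agg))
  hist <- hist[order(hist$cut_after), , drop = FALSE]
  rownames(hist) <- NULL
  modal <- hist$cut_after[hist$count == max(hist$count)][1]
  structure(list(histogram = hist, modal_cut = modal, type = type),
            class = "cut_histogram")
}

#' @export
print.cut_histogram <- function(x, ...) {
  cat("Inferred ", x$type, " cleavage positions (modal cut after ",
      x$modal_cut, ")\n", sep = "")
  print(x$histogram, row.names = FALSE)
  invisible(x)
}

#' Fragment yield of a pool
#'
#' Fragment reads per full-length read, the sequencing analogue of comparing
#' ysRNA to full-length signal: `frag / (frag + full_length)` over the whole
#' table (including window-blind reads).
#'
#' @param table An `assignment_table`.
#' @param type `"frag3"` or `"frag5"`.
#' @return Numeric yield in `[0, 1]`, or `NA` if the denominator is zero.
#' @export
fragment_yield <- function(table, type = c("frag3", "frag5")) {
  type <- match.arg(type)
  d <- fragment_detail(table, type, include_pool = TRUE)
  frag <- sum(d$count)
  full <- sum(table$per_variant$full_length) + table$pool_full_length
  if (frag + full == 0L) return(NA_real_)
  frag / (frag + full)
}

#' Export assignment tables as tab-separated files
#'
#' Writes `<prefix>_per_variant.tsv`, `<prefix>_frag3.tsv`,
#' `<prefix>_frag5.tsv` and `<prefix>_summary.tsv`.
#'
#' @param table An `assignment_table`.
#' @param prefix Output path prefix.
#' @return Character vector of the paths written, invisibly.
#' @export
write_assignment_tables <- function(table, prefix) {
  paths <- paste0(prefix, c("_per_variant.tsv", "_frag3.tsv", "_frag5.tsv",
                            "_summary.tsv"))
  utils::write.table(table$per_variant, paths[1], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(table$frag3_detail, paths[2], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(table$frag5_detail, paths[3], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  smry <- data.frame(
    key = c("accepted", "pool_level", "pool_full_length", "internal",
            "unassigned", "prefix_suffix_ambiguous", "reference_length"),
    value = c(table$accepted, table$pool_level, table$pool_full_length,
              table$internal, table$unassigned,
              table$n_prefix_suffix_ambiguous, table$reference_length))
  utils::write.table(smry, paths[4], sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(paths)
}
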