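#' Rank variants by a count metric
#'
#' Orders variants by descending read count, breaking ties by ascending
#' ordinal so rankings are fully deterministic. The top-50 / bottom-50
#' selections used throughout mutant-pool analyses are the head and tail of
#' this ranking.
#'
#' @param table An `assignment_table`.
#' @param metric One of `"frag3_count"`, `"frag5_count"`,
#'   `"full_length_count"`.
#' @return The `per_variant` data frame sorted by the metric, with an extra
#'   `rank` column. If every count is zero the ranking is degenerate and the
#'   result carries attribute `attr(, "degenerate") = TRUE`.
#' @export
rank_variants <- function(table, metric = c("frag3_count", "frag5_count",
                                            "full_length_count")) {
  metric <- match.arg(metric)
  col <- sub("_count$", "", metric)
  col <- if (col == "full_length") "full_length" else col
  pv <- table$per_variant
  ord <- order(-pv[[col]], pv$ordinal)
  out <- pv[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  if (all(pv[[col]] == 0L)) attr(out, "degenerate") <- TRUE
  out
}

#' Top / bottom variants of a ranking
#'
#' @inheritParams rank_variants
#' @param k Number of variants (default 50, the usual "most abundant"
#'   selection size).
#' @return Character vector of motifs.
#' @export
top_variants <- function(table, metric = "frag3_count", k = 50) {
  r <- rank_variants(table, metric)
  utils::head(r$motif, k)
}

#' @rdname top_variants
#' @export
bottom_variants <- function(table, metric = "frag3_count", k = 50) {
  r <- rank_variants(table, metric)
  rev(utils::tail(r$motif, k))
}

#' Detect missing variants in a full-length library
#'
#' Variants whose full-length read count falls below `min_count` — with the
#' default of 1, variants never observed at all, the criterion used to call
#' motifs missing from a plasmid pool.
#'
#' @param table An `assignment_table` from a full-length library.
#' @param min_count Minimum full-length count to be called present
#'   (default 1).
#' @return Integer vector of 0-based ordinals of missing variants.
#' @export
missing_variants <- function(table, min_count = 1L) {
  pv <- table$per_variant
  pv$ordinal[pv$full_length < min_count]
}

#' Position weight matrix and information content for a motif set
#'
#' Computes per-position base frequencies with a Laplace-style pseudocount
#' and the information content per column,
#' `IC_j = 2 + sum_b f_bj log2 f_bj` bits (0 = uniform, 2 = fully
#' determined), the quantity a sequence logo displays.
#'
#' @param motifs Character vector of equal-length motifs over A/C/G/U.
#' @param pseudocount Pseudocount added per base (default 0.5).
#' @return An object of class `pwm` with `freq` (4 x k matrix, rows
#'   A/C/G/U, columns summing to 1), `ic` (k-vector of bits),
#'   `consensus` (dominant base per column, collapsed to a string),
#'   `dominant_freq` (frequency of the dominant base per column),
#'   `n` and `pseudocount`.
#' @export
#' @examples
#' pwm_logo(c("UGGGU", "UGGGU", "UGGGA"))$consensus
pwm_logo <- function(motifs, pseudocount = 0.5) {
  if (!length(motifs)) stop("empty motif set")
  motifs <- vapply(motifs, normalize_rna, character(1), USE.NAMES = FALSE)
  k <- nchar(motifs[1])
  if (any(nchar(motifs) != k)) stop("motifs have unequal lengths")
  chars <- do.call(rbind, strsplit(motifs, ""))
  n <- length(motifs)
  freq <- vapply(seq_len(k), function(j) {
    cnt <- vapply(RNA_BASES, function(b) sum(chars[, j] == b), numeric(1))
    (cnt + pseudocount) / (n + 4 * pseudocount)
  }, numeric(4))
  rownames(freq) <- RNA_BASES
  ic <- 2 + colSums(freq * log2(freq))
  dom <- apply(freq, 2L, which.max)
  structure(list(freq = freq, ic = ic,
                 consensus = paste0(RNA_BASES[dom], collapse = ""),
                 dominant_freq = freq[cbind(dom, seq_len(k))],
                 n = n, pseudocount = pseudocount),
            class = "pwm")
}

#' @export
print.pwm <- function(x, digits = 3, ...) {
  cat("Position weight matrix (", x$n, " motifs, pseudocount ",
      x$pseudocount, ")\n", sep = "")
  m <- rbind(round(x$freq, digits), IC = round(x$ic, digits))
  colnames(m) <- seq_len(ncol(m))
  print(m)
  cat("consensus:", x$consensus, "\n")
  invisible(x)
}

#' @param x A `pwm`.
#' @param ... Passed to [graphics::barplot()].
#' @rdname pwm_logo
#' @export
plot.pwm <- function(x, ...) {
  h <- x$freq * rep(x$ic, each = 4)  # logo letter heights: IC * frequency
  graphics::barplot(h, names.arg = seq_len(ncol(h)), ylim = c(0, 2),
                    col = c("#33a02c", "#1f78b4", "#ff7f00", "#e31a1c"),
                    xlab = "position", ylab = "bits",
                    legend.text = rownames(h), ...)
  invisible(x)
}

#' Coupon-collector presence probability
#'
#' Probability that one given variant out of `V` equally likely variants is
#' observed at least once in `n` uniform draws: `1 - (1 - 1/V)^n`.
#'
#' @param V Number of variants (>= 1).
#' @param n Number of draws (>= 0).
#' @return Probability in `[0, 1]`.
#' @export
#' @examples
#' presence_probability(1024, 5000)  # ~0.9925
presence_probability <- function(V, n) {
  if (any(V < 1)) stop("V must be >= 1")
  if (any(n < 0)) stop("n must be >= 0")
  1 - (1 - 1 / V)^n
}

#' Minimum pool size for a target presence probability
#'
#' Smallest number of uniform draws (colonies) such that any given one of
#' `V` variants is present at least once with probability at least `p`:
#' the closed form `ceil(log(1 - p) / log(1 - 1/V))`, safeguarded by a
#' local scan so floating point can never return an off-by-one answer.
#'
#' @param V Number of variants.
#' @param p Target probability, `0 < p < 1`.
#' @return Integer pool size.
#' @export
#' @examples
#' min_pool_size(1024, 0.99)  # 4714
min_pool_size <- function(V, p) {
  if (p <= 0 || p >= 1) stop("p must be in (0, 1)")
  if (V < 1) stop("V must be >= 1")
  if (V == 1) return(1L)
  n <- ceiling(log(1 - p) / log(1 - 1 / V))
  while (n > 1 && presence_probability(V, n - 1) >= p) n <- n - 1
  while (presence_probability(V, n) < p) n <- n + 1
  as.integer(n)
}
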