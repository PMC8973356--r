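# Shared helpers: an exhaustive folding oracle, random-sequence generation,
# and a simulate -> trim -> assign shortcut used across test files.

# Exhaustive enumeration over all nested structures (hairpin >= minh),
# returning the maximum total pair weight. Deliberately memo-free recursion
# so it shares nothing with the package's dynamic program.
oracle_best_weight <- function(seq, minh = 3, weights = c(GC = 3, AU = 2, GU = 1)) {
  b <- strsplit(seq, "")[[1]]
  n <- length(b)
  wm <- matrix(0, 4, 4, dimnames = list(c("A","C","G","U"), c("A","C","G","U")))
  wm["G","C"] <- wm["C","G"] <- weights[["GC"]]
  wm["A","U"] <- wm["U","A"] <- weights[["AU"]]
  wm["G","U"] <- wm["U","G"] <- weights[["GU"]]
  rec <- function(i, j) {
    if (j - i < minh + 1) return(0)
    best <- rec(i + 1, j)
    for (k in (i + minh + 1):j) {
      w <- wm[b[i], b[k]]
      if (w > 0) best <- max(best, w + rec(i + 1, k - 1) + rec(k + 1, j))
    }
    best
  }
  if (n < minh + 2) return(0)
  rec(1L, n)
}

random_rna <- function(n) paste0(sample(c("A","C","G","U"), n, replace = TRUE),
                                 collapse = "")

# simulate a pool and push it through the real FASTQ -> trim -> assign path
sim_assign <- function(library, structures, rules, depth, seed, ...) {
  pool <- simulate_pool(library, structures, rules, depth = depth,
                        seed = seed, ...)
  fq <- tempfile(fileext = ".fastq")
  on.exit(unlink(fq))
  write_fastq(pool, fq)
  tr <- process_fastq(fq)
  list(pool = pool, trimmed = tr, table = assign_reads(tr$inserts, library))
}

# per-variant structures derived from base-pair legality: a variant keeps the
# curated wild-type geometry iff its window content can still form every S3
# pair; otherwise stem S3 is absent. Ground truth for structure-gated tests.
structures_by_pairing <- function(library) {
  wt <- ysrna_wt_structure()
  pt <- wt$pair_table
  broken_db <- paste0(substr(wt$dotbracket, 1, 51), strrep(".", 15),
                      substr(wt$dotbracket, 67, 81))
  legal <- c("AU","UA","GC","CG","GU","UG")
  lapply(library$sequences, function(s) {
    b <- strsplit(s, "")[[1]]
    s3 <- 52:57
    ok <- all(paste0(b[s3], b[pt[s3]]) %in% legal)
    if (ok) secondary_structure(s, wt$dotbracket, check_pairs = FALSE)
    else secondary_structure(s, broken_db, check_pairs = FALSE)
  })
}
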