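#' Variant abundance model
#'
#' Describes how plasmid-pool variants are represented before sequencing:
#' equimolar (`uniform`) or unevenly via a symmetric Dirichlet draw
#' (`dirichlet`, smaller concentration = more skew). An explicit `dropout`
#' set of variant ordinals receives zero abundance, emulating variants lost
#' from the pool (e.g. because the full-length mutant is unstable).
#'
#' @param kind `"uniform"` or `"dirichlet"`.
#' @param concentration Positive Dirichlet concentration (ignored for
#'   uniform).
#' @param dropout Integer vector of 0-based variant ordinals with zero
#'   abundance.
#' @return An object of class `abundance_model`.
#' @export
abundance_model <- function(kind = c("uniform", "dirichlet"),
                            concentration = 1, dropout = integer(0)) {
  kind <- match.arg(kind)
  if (concentration <= 0) stop("concentration must be positive")
  structure(list(kind = kind, concentration = concentration,
                 dropout = as.integer(dropout)),
            class = "abundance_model")
}

abundance_probs <- function(model, n_variants) {
  if (any(model$dropout < 0L | model$dropout >= n_variants))
    stop("dropout ordinals outside 0..", n_variants - 1L)
  p <- switch(model$kind,
    uniform   = rep(1, n_variants),
    dirichlet = stats::rgamma(n_variants, shape = model$concentration))
  p[model$dropout + 1L] <- 0
  if (sum(p) <= 0) stop("abundance model assigns zero probability to every variant")
  p / sum(p)
}

#' Simulate fragment outcomes for one variant
#'
#' Draws `n` transcript molecules of a single variant and applies the
#' cleavage rules: a molecule of a cleavage-competent variant is cleaved
#' with probability `rules$efficiency`, producing a 3' fragment (cut at a
#' sampled offset above stem S3) or a 5' fragment (cut inside the
#' `cut5_region` landmark); all other molecules stay full length. Uses the
#' current RNG state; call `set.seed()` beforehand for reproducibility.
#'
#' @param sequence Variant sequence.
#' @param structure A `secondary_structure` for this variant.
#' @param rules A `cleavage_rules` object.
#' @param landmarks Landmark list or a `reference_rna`.
#' @param n Number of molecules to draw.
#' @return A data frame with columns `type` (`"full_length"`, `"frag3"`,
#'   `"frag5"`) and `cut_after` (`NA` for full length).
#' @export
simulate_variant_fragments <- function(sequence, structure, rules, landmarks, n = 1) {
  if (inherits(landmarks, "reference_rna")) landmarks <- landmarks$landmarks
  ev <- evaluate_rules(sequence, structure, rules, landmarks)
  draw_fragments(ev, rules, landmarks, n)
}

# vectorized molecule draws given a rule evaluation
draw_fragments <- function(ev, rules, landmarks, n) {
  type <- rep("full_length", n)
  cut <- rep(NA_integer_, n)
  passing <- c(if (ev$frag3) "frag3", if (ev$frag5) "frag5")
  if (length(passing) && n > 0L) {
    cleaved <- stats::runif(n) < rules$efficiency
    idx <- which(cleaved)
    if (length(idx)) {
      type[idx] <- if (length(passing) == 1L) passing
                   else sample(passing, length(idx), replace = TRUE)
      i3 <- idx[type[idx] == "frag3"]
      if (length(i3)) {
        offs <- as.integer(names(rules$rule3$offsets))
        o <- offs[sample.int(length(offs), length(i3), replace = TRUE,
                             prob = rules$rule3$offsets)]
        cut[i3] <- ev$stem_start - 1L - o
      }
      i5 <- idx[type[idx] == "frag5"]
      if (length(i5)) {
        region <- landmarks$cut5_region
        if (is.null(region)) stop("landmarks must define 'cut5_region' for the 5' rule")
        pos <- region[1]:region[2]
        pr <- rules$rule5$cut_probs
        if (length(pr) != length(pos)) pr <- rep(1, length(pos))
        cut[i5] <- pos[sample.int(length(pos), length(i5), replace = TRUE, prob = pr)]
      }
    }
  }
  data.frame(type = type, cut_after = cut)
}

#' Simulate a sequenced mutant-pool read set
#'
#' Emulates the mutant-pool small RNA-seq experiment: variants are drawn
#' from the abundance model, each molecule is cleaved (or not) according to
#' the rule set, and every resulting insert is wrapped in the HD-adapter
#' read layout — 4 random nt, the insert, 4 random nt, the 8-nt 3' adapter
#' prefix and a short random tail — with per-base substitution errors and a
#' fraction of random decoy reads standing in for genome-derived background.
#'
#' @param library A `variant_library`.
#' @param structures A single `secondary_structure` applied to every variant
#'   (appropriate when the supplied annotation stands for the pool's shared
#'   geometry), or a list of one structure per variant in ordinal order.
#' @param rules A `cleavage_rules` object.
#' @param abundance An `abundance_model`.
#' @param depth Total number of reads.
#' @param seed Integer seed; the simulation is reproducible per seed.
#' @param error_rate Per-base substitution error probability (default 0.001).
#' @param decoy_frac Fraction of decoy reads (default 0.05).
#' @param hd_len Number of random HD bases at each ligating end (default 4).
#' @param adapter 3' adapter prefix appended after the 3' HD bases
#'   (default `"UGGAAUUC"`).
#' @return An object of class `read_pool`: a list with `reads` (data frame
#'   with columns `read_id`, `raw`, `variant` (0-based ordinal, `NA` for
#'   decoys), `type`, `cut_after`) and the simulation parameters. The
#'   `variant`/`type`/`cut_after` columns are provenance for testing only;
#'   the analysis pipeline never reads them.
#' @export
simulate_pool <- function(library, structures, rules,
                          abundance = abundance_model("uniform"),
                          depth, seed,
                          error_rate = 0.001, decoy_frac = 0.05,
                          hd_len = 4L, adapter = "UGGAAUUC") {
  stopifnot(inherits(library, "variant_library"), inherits(rules, "cleavage_rules"))
  depth <- as.integer(depth)
  if (depth < 0L) stop("depth must be >= 0")
  V <- length(library$motifs)
  one_structure <- inherits(structures, "secondary_structure")
  if (!one_structure && length(structures) != V)
    stop("need one structure per variant (", V, ") or a single shared structure")
  lm <- library$reference$landmarks

  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(as.integer(seed))

  empty <- data.frame(read_id = character(0), raw = character(0),
                      variant = integer(0), type = character(0),
                      cut_after = integer(0))
  if (depth == 0L)
    return(structure(list(reads = empty, depth = 0L, seed = seed,
                          reference = library$reference, window = library$window),
                     class = "read_pool"))

  n_decoy <- stats::rbinom(1L, depth, decoy_frac)
  n_real <- depth - n_decoy
  probs <- abundance_probs(abundance, V)

  reads <- empty
  if (n_real > 0L) {
    ords <- sample.int(V, n_real, replace = TRUE, prob = probs) - 1L
    # evaluate rules once per distinct variant present
    uo <- sort(unique(ords))
    evs <- lapply(uo, function(o) {
      st <- if (one_structure) structures else structures[[o + 1L]]
      evaluate_rules(library$sequences[o + 1L], st, rules, lm)
    })
    names(evs) <- as.character(uo)
    type <- character(n_real); cut <- integer(n_real)
    for (o in uo) {
      idx <- which(ords == o)
      fr <- draw_fragments(evs[[as.character(o)]], rules, lm, length(idx))
      type[idx] <- fr$type; cut[idx] <- fr$cut_after
    }
    seqs <- library$sequences[ords + 1L]
    L <- nchar(library$reference$sequence)
    insert <- ifelse(type == "full_length", seqs,
              ifelse(type == "frag3", substr(seqs, cut + 1L, L),
                     substr(seqs, 1L, cut)))
    reads <- data.frame(read_id = NA_character_, raw = insert,
                        variant = ords, type = type, cut_after = cut)
  }
  if (n_decoy > 0L) {
    dlen <- sample(20:35, n_decoy, replace = TRUE)
    dseq <- vapply(dlen, function(l)
      paste0(sample(RNA_BASES, l, replace = TRUE), collapse = ""), character(1))
    reads <- rbind(reads,
                   data.frame(read_id = NA_character_, raw = dseq,
                              variant = NA_integer_, type = "decoy",
                              cut_after = NA_integer_))
  }
  # wrap inserts in the HD-adapter layout, shuffle, apply errors
  n <- nrow(reads)
  reads <- reads[sample.int(n), , drop = FALSE]
  rand_mers <- function(k, m) {
    if (k == 0L) return(rep("", m))
    matr <- matrix(sample(RNA_BASES, k * m, replace = TRUE), nrow = m)
    apply(matr, 1L, paste0, collapse = "")
  }
  raw <- paste0(rand_mers(hd_len, n), reads$raw, rand_mers(hd_len, n),
                adapter, rand_mers(4L, n))
  if (error_rate > 0) {
    nerr <- stats::rbinom(n, nchar(raw), error_rate)
    for (i in which(nerr > 0L)) {
      ch <- strsplit(raw[i], "")[[1]]
      at <- sample.int(length(ch), nerr[i])
      ch[at] <- vapply(ch[at], function(b) sample(setdiff(RNA_BASES, b), 1L),
                       character(1))
      raw[i] <- paste0(ch, collapse = "")
    }
  }
  reads$raw <- raw
  reads$read_id <- sprintf("read_%06d", seq_len(n))
  rownames(reads) <- NULL
  structure(list(reads = reads, depth = depth, seed = seed,
                 reference = library$reference, window = library$window),
            class = "read_pool")
}

#' @export
print.read_pool <- function(x, ...) {
  cat("Simulated read pool: ", nrow(x$reads), " reads (window '",
      x$window$name, "', seed ", x$seed, ")\n", sep = "")
  if (nrow(x$reads)) print(table(x$reads$type))
  invisible(x)
}

#' Write simulated reads to FASTQ or FASTA
#'
#' Reads are written in the DNA alphabet (U converted back to T, as a
#' sequencer reports) as standard 4-line FASTQ with a constant quality
#' symbol (quality is never used downstream) or as FASTA.
#'
#' @param pool A `read_pool`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(pool, path) {
  r <- pool$reads
  if (nrow(r) == 0L) { writeLines(character(0), path); return(invisible(path)) }
  dna <- chartr("U", "T", r$raw)
  qual <- vapply(nchar(dna), function(l) strrep("I", l), character(1))
  writeLines(as.vector(rbind(paste0("@", r$read_id), dna,
                             rep("+", nrow(r)), qual)), path)
  invisible(path)
}

#' @rdname write_fastq
#' @export
write_fasta <- function(pool, path) {
  r <- pool$reads
  if (nrow(r) == 0L) { writeLines(character(0), path); return(invisible(path)) }
  dna <- chartr("U", "T", r$raw)
  writeLines(as.vector(rbind(paste0(">", r$read_id), dna)), path)
  invisible(path)
}

#' Write / read the provenance sidecar
#'
#' Tab-separated table of each simulated read's true origin (variant
#' ordinal, fragment type, true cut position). For validating the pipeline
#' only; the pipeline itself never consumes it.
#'
#' @param pool A `read_pool`.
#' @param path File path.
#' @return `write_provenance()`: `path` invisibly; `read_provenance()`: a
#'   data frame.
#' @export
write_provenance <- function(pool, path) {
  utils::write.table(pool$reads[, c("read_id", "variant", "type", "cut_after")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_provenance
#' @export
read_provenance <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}
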