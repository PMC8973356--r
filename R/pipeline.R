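#' Build a pipeline configuration
#'
#' Assembles (and validates) the full set of parameters the pipeline runs
#' on: reference and landmarks, randomized window, cleavage rules, abundance
#' model, depth, seed and thresholds. A YAML file can override any subset of
#' the defaults; flags/arguments you pass explicitly override the file.
#'
#' @param path Optional YAML file with overrides (keys mirror the list
#'   below).
#' @param ... Named overrides applied on top of the file: `window` (name of
#'   a packaged window, e.g. `"L3"`, or a list `name`/`start`/`length`),
#'   `depth`, `seed`, `error_rate`, `decoy_frac`, `efficiency`, `rule3`,
#'   `rule5` (lists, see [cleavage_rules()]), `abundance` (list with
#'   `kind`, `concentration`, `dropout`), `min_insert`, `min_count`,
#'   `top_k`, `reference_fasta` plus `landmarks` to replace the packaged
#'   reference, `structure` (path to a dot-bracket file).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(path = NULL, ...) {
  cfg <- list(
    window = "L3", depth = 10000L, seed = 1L,
    error_rate = 0.001, decoy_frac = 0.05, efficiency = 0.5,
    rule3 = list(), rule5 = list(),
    abundance = list(kind = "uniform", concentration = 1, dropout = integer(0)),
    min_insert = 15L, min_count = 1L, top_k = 50L,
    reference_fasta = NULL, landmarks = NULL, structure = NULL)
  if (!is.null(path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("the 'yaml' package is required to read config files")
    cfg <- utils::modifyList(cfg, yaml::read_yaml(path))
  }
  dots <- list(...)
  if (length(dots)) cfg <- utils::modifyList(cfg, dots)
  cfg$depth <- as.integer(cfg$depth)
  cfg$seed <- as.integer(cfg$seed)
  if (is.na(cfg$seed)) stop("config must set an explicit integer seed")
  if (cfg$depth < 0L) stop("depth must be >= 0")
  structure(cfg, class = "pipeline_config")
}

config_reference <- function(cfg) {
  if (!is.null(cfg$reference_fasta))
    load_reference(cfg$reference_fasta, landmarks = cfg$landmarks %||% list())
  else ysrna_reference()
}

config_library <- function(cfg, reference = config_reference(cfg)) {
  w <- cfg$window
  win <- if (is.character(w)) {
    wl <- ysrna_windows(w)
    if (!length(wl) || is.null(wl[[1]])) stop("unknown packaged window '", w, "'")
    wl[[1]]
  } else randomized_window(w$name, w$start, w$length, reference)
  enumerate_variants(reference, win)
}

config_structure <- function(cfg, reference = config_reference(cfg)) {
  if (!is.null(cfg$structure)) read_dotbracket(cfg$structure, check_pairs = FALSE)[[1]]
  else ysrna_wt_structure()
}

config_rules <- function(cfg) {
  cleavage_rules(rule3 = cfg$rule3, rule5 = cfg$rule5,
                 efficiency = cfg$efficiency)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the simulation stage
#'
#' Simulates a mutant-pool read set under the configuration and writes
#' `reads.fastq` plus the provenance sidecar `provenance.tsv` to `out_dir`.
#' Outputs are byte-identical for a fixed seed.
#'
#' @param config A `pipeline_config`.
#' @param out_dir Output directory (created if needed).
#' @return Named character vector of output paths, invisibly.
#' @export
run_simulation <- function(config, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ref <- config_reference(config)
  lib <- config_library(config, ref)
  st <- config_structure(config, ref)
  ab <- abundance_model(config$abundance$kind %||% "uniform",
                        config$abundance$concentration %||% 1,
                        unlist(config$abundance$dropout) %||% integer(0))
  pool <- simulate_pool(lib, st, config_rules(config), abundance = ab,
                        depth = config$depth, seed = config$seed,
                        error_rate = config$error_rate,
                        decoy_frac = config$decoy_frac)
  paths <- c(fastq = file.path(out_dir, "reads.fastq"),
             provenance = file.path(out_dir, "provenance.tsv"))
  write_fastq(pool, paths["fastq"])
  write_provenance(pool, paths["provenance"])
  invisible(paths)
}

#' Run the processing stage
#'
#' Trims a FASTQ/FASTA file, assigns reads to the configured variant
#' library, and writes the trimming report, assignment tables and the
#' fragment size-class table to `out_dir`.
#'
#' @param fastq Path to the input reads.
#' @param config A `pipeline_config`.
#' @param out_dir Output directory.
#' @return The `assignment_table`, invisibly; files as a side effect.
#' @export
run_processing <- function(fastq, config, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ref <- config_reference(config)
  lib <- config_library(config, ref)
  tr <- process_fastq(fastq, min_insert = config$min_insert)
  write_trim_report(tr, file.path(out_dir, "trim_report.tsv"))
  tab <- assign_reads(tr$inserts, lib)
  write_assignment_tables(tab, file.path(out_dir, "assignment"))
  sd3 <- size_distribution(tab, type = "both")
  utils::write.table(sd3, file.path(out_dir, "size_classes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(tab)
}

#' Run the inference stage
#'
#' Recovers the cleavage signature from an assignment table: modal 3' cut
#' offset above stem S3, cut-position histograms, size classes, and (when a
#' 5' window is analysed) the selected motif.
#'
#' @param table An `assignment_table` (e.g. from [run_processing()]).
#' @param config A `pipeline_config`.
#' @param out_path Optional path for a plain-text report.
#' @return A list with the recovered quantities, invisibly when `out_path`
#'   is given.
#' @export
run_inference <- function(table, config, out_path = NULL) {
  ref <- config_reference(config)
  st <- config_structure(config, ref)
  res <- list()
  res$offset <- tryCatch(recover_offset(table, st, ref),
                         ysrnaError = function(e) NULL)
  res$cut3 <- tryCatch(infer_cut_positions(table, "frag3"),
                       ysrna_no_cleavage = function(e) NULL)
  res$cut5 <- tryCatch(infer_cut_positions(table, "frag5"),
                       ysrna_no_cleavage = function(e) NULL)
  res$modal_frag3_length <- modal_length(table, "frag3")
  res$modal_frag5_length <- modal_length(table, "frag5")
  if (!is.null(out_path)) {
    con <- file(out_path, "w"); on.exit(close(con))
    sink(con); on.exit(sink(), add = TRUE, after = FALSE)
    cat("ysrna inference report\n======================\n")
    if (!is.null(res$offset)) print(res$offset)
    if (!is.null(res$cut3)) print(res$cut3)
    if (!is.null(res$cut5)) print(res$cut5)
    cat("modal frag3 length:", res$modal_frag3_length, "\n")
    cat("modal frag5 length:", res$modal_frag5_length, "\n")
    return(invisible(res))
  }
  res
}
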