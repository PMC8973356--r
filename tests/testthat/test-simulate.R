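ref <- ysrna_reference()
wt <- ysrna_wt_structure()

test_that("rule evaluation gates fragments on structure and sequence", {
  rules <- cleavage_rules(efficiency = 1)
  set.seed(1)
  fr <- simulate_variant_fragments(ref$sequence, wt, rules, ref, n = 400)
  expect_setequal(unique(fr$type), c("frag3", "frag5"))
  expect_setequal(unique(fr$cut_after[fr$type == "frag3"]), c(48L, 49L))
  expect_true(all(fr$cut_after[fr$type == "frag5"] %in% c(32L, 33L)))
  expect_gt(sum(fr$cut_after == 32 & fr$type == "frag5"),
            sum(fr$cut_after == 33 & fr$type == "frag5"))

  # loop fully deleted -> no 3' fragment
  d9 <- ysrna_loop_series(0)$loop0
  fr9 <- simulate_variant_fragments(d9$reference$sequence, d9$structure,
                                    rules, d9$reference, n = 200)
  expect_false(any(fr9$type == "frag3"))

  # position-22 motif mutated -> no 5' fragment
  mut <- ref$sequence
  substr(mut, 26, 26) <- "C"  # UGGGU -> UGGGC
  frm <- simulate_variant_fragments(mut, wt, rules, ref, n = 200)
  expect_false(any(frm$type == "frag5"))
  # tolerated when exact matching is relaxed to one mismatch
  loose <- cleavage_rules(rule5 = list(exact_match_required = FALSE),
                          efficiency = 1)
  frl <- simulate_variant_fragments(mut, wt, loose, ref, n = 200)
  expect_true(any(frl$type == "frag5"))
})

test_that("broken RO60 site blocks the 3' rule unless the requirement is lifted", {
  rules <- cleavage_rules(efficiency = 1)
  mut <- ref$sequence
  substr(mut, 68, 68) <- "A"  # 8:68 no longer G:C
  st <- secondary_structure(mut, wt$dotbracket, check_pairs = FALSE)
  set.seed(2)
  expect_false(any(simulate_variant_fragments(mut, st, rules, ref,
                                              n = 150)$type == "frag3"))
  no_ro60 <- cleavage_rules(rule3 = list(require_ro60 = FALSE), efficiency = 1)
  expect_true(any(simulate_variant_fragments(mut, st, no_ro60, ref,
                                             n = 150)$type == "frag3"))
})

test_that("rule-set validation rejects malformed configurations", {
  expect_error(cleavage_rules(rule3 = list(offsets = c("2" = 0.5, "3" = 0.4))),
               "sum to 1")
  expect_error(cleavage_rules(rule3 = list(offsets = c(0.6, 0.4))), "named")
  expect_error(cleavage_rules(efficiency = 1.2), "efficiency")
  expect_error(cleavage_rules(rule5 = list(motif = "")), "non-empty")
})

test_that("pool simulation is seed-reproducible and dropout-aware", {
  lib <- enumerate_variants(ref, ysrna_windows("L3")$L3)
  rules <- cleavage_rules()
  a <- simulate_pool(lib, wt, rules, depth = 400, seed = 5)
  b <- simulate_pool(lib, wt, rules, depth = 400, seed = 5)
  c <- simulate_pool(lib, wt, rules, depth = 400, seed = 6)
  expect_identical(a$reads, b$reads)
  expect_false(identical(a$reads$raw, c$reads$raw))

  expect_equal(nrow(simulate_pool(lib, wt, rules, depth = 0, seed = 1)$reads), 0L)

  drop <- c(3L, 500L, 1023L)
  p <- simulate_pool(lib, wt, rules,
                     abundance = abundance_model(dropout = drop),
                     depth = 2000, seed = 9)
  expect_false(any(p$reads$variant %in% drop))
  expect_error(simulate_pool(lib, wt, rules,
                             abundance = abundance_model(dropout = 4096L),
                             depth = 10, seed = 1),
               "dropout")
})

test_that("error-free reads trim back to exact provenance fragments", {
  lib <- enumerate_variants(ref, ysrna_windows("L2")$L2)
  res <- sim_assign(lib, wt, cleavage_rules(), depth = 600, seed = 21,
                    error_rate = 0, decoy_frac = 0)
  expect_equal(res$trimmed$report[["accepted"]], 600L)
  pool <- res$pool
  ins <- res$trimmed$inserts[pool$reads$read_id]
  L <- nchar(ref$sequence)
  for (i in seq_len(nrow(pool$reads))) {
    v <- lib$sequences[pool$reads$variant[i] + 1L]
    expected <- switch(pool$reads$type[i],
      full_length = v,
      frag3 = substr(v, pool$reads$cut_after[i] + 1L, L),
      frag5 = substr(v, 1L, pool$reads$cut_after[i]))
    expect_identical(ins[[i]], expected)
  }
})

test_that("fragment lengths mirror the offset probabilities", {
  lib <- enumerate_variants(ref, ysrna_windows("L3")$L3)
  res <- sim_assign(lib, wt, cleavage_rules(), depth = 6000, seed = 31,
                    decoy_frac = 0)
  d <- res$table$frag3_detail
  expect_setequal(d$length, c(32L, 33L))
  p32 <- sum(d$count[d$length == 32]) / sum(d$count)
  expect_gt(p32, 0.5); expect_lt(p32, 0.7)  # around the configured 0.6
})

test_that("FASTQ output is standard 4-line and round-trips", {
  lib <- enumerate_variants(ref, randomized_window("w", 44, 1))
  pool <- simulate_pool(lib, wt, cleavage_rules(), depth = 3, seed = 2,
                        decoy_frac = 0)
  fq <- tempfile(fileext = ".fastq")
  write_fastq(pool, fq)
  lines <- readLines(fq)
  expect_length(lines, 12L)
  expect_true(all(startsWith(lines[seq(1, 12, 4)], "@")))
  expect_false(any(grepl("U", lines[seq(2, 12, 4)])))  # DNA alphabet on disk
  empty <- simulate_pool(lib, wt, cleavage_rules(), depth = 0, seed = 1)
  write_fastq(empty, fq)
  expect_length(readLines(fq), 0L)
  # provenance sidecar round-trip
  pv <- tempfile(); write_provenance(pool, pv)
  expect_equal(read_provenance(pv)$variant, pool$reads$variant)
})
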