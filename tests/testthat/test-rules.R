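ref <- ysrna_reference()
wt <- ysrna_wt_structure()

test_that("the 3' offset distribution is recovered from read boundaries", {
  lib <- enumerate_variants(ref, ysrna_windows("L3")$L3)
  res <- sim_assign(lib, wt, cleavage_rules(), depth = 4000, seed = 91)
  ro <- recover_offset(res$table, wt, ref)
  expect_equal(ro$modal_offset, 2L)
  expect_setequal(ro$histogram$offset, c(2L, 3L))
  p2 <- ro$histogram$count[ro$histogram$offset == 2] / ro$n_reads
  expect_gt(p2, 0.45); expect_lt(p2, 0.75)

  # injected offset distribution is recovered exactly
  inj <- cleavage_rules(rule3 = list(offsets = c("4" = 1)))
  res4 <- sim_assign(lib, wt, inj, depth = 2000, seed = 92)
  ro4 <- recover_offset(res4$table, wt, ref)
  expect_equal(ro4$modal_offset, 4L)
  expect_equal(ro4$histogram$offset, 4L)

  none <- assign_reads(character(0), lib)
  expect_error(recover_offset(none, wt, ref), class = "ysrna_no_cleavage")
})

test_that("offset recovery is invariant to variant relabeling", {
  lib <- enumerate_variants(ref, ysrna_windows("L1")$L1)
  res <- sim_assign(lib, ysrna_shifted_structure(), cleavage_rules(),
                    depth = 2500, seed = 93, error_rate = 0, decoy_frac = 0)
  tab <- res$table
  ro <- recover_offset(tab, ysrna_shifted_structure(), ref)
  # permute ordinals in the detail table; pooled histogram must not change
  perm <- tab
  set.seed(1)
  relabel <- sample(0:1023)
  idx <- !is.na(perm$frag3_detail$ordinal)
  perm$frag3_detail$ordinal[idx] <- relabel[perm$frag3_detail$ordinal[idx] + 1L]
  ro_p <- recover_offset(perm, ysrna_shifted_structure(), ref)
  expect_equal(ro_p$histogram, ro$histogram)
  expect_equal(ro_p$modal_offset, ro$modal_offset)
})

loop_tables <- function(rules, depth = 1200, base_seed = 700) {
  series <- ysrna_loop_series(0:9)
  tabs <- lapply(seq_along(series), function(i) {
    x <- series[[i]]
    n <- nchar(x$reference$sequence)
    lib <- enumerate_variants(x$reference, randomized_window("tail", n, 1L))
    sim_assign(lib, x$structure, rules, depth = depth,
               seed = base_seed + i)$table
  })
  list(tables = tabs, sizes = vapply(series, `[[`, integer(1), "loop_size"))
}

test_that("the loop-deletion series recovers the minimal permissive loop", {
  lt <- loop_tables(cleavage_rules())
  lr <- loop_length_response(lt$tables, lt$sizes)
  expect_equal(lr$min_permissive_size, 1L)
  expect_equal(lr$response$yield[lr$response$loop_size == 0], 0)
  expect_true(all(lr$response$yield[lr$response$loop_size >= 1] > 0))

  # an injected stricter loop requirement is recovered
  lt3 <- loop_tables(cleavage_rules(rule3 = list(require_loop_min = 3)))
  lr3 <- loop_length_response(lt3$tables, lt3$sizes)
  expect_equal(lr3$min_permissive_size, 3L)
  expect_true(all(lr3$response$yield[lr3$response$loop_size < 3] == 0))

  # no cleavage anywhere -> undefined, flagged
  lt0 <- loop_tables(cleavage_rules(efficiency = 0), depth = 300)
  lr0 <- loop_length_response(lt0$tables, lt0$sizes)
  expect_true(is.na(lr0$min_permissive_size))
  expect_equal(attr(lr0, "flag"), "all yields zero")
  expect_error(loop_length_response(lt$tables[1], 0), "distinct loop sizes")
})

test_that("motif localization calls the selected 5' motif at position 22", {
  lib <- enumerate_variants(ref, ysrna_windows("L4")$L4)
  res <- sim_assign(lib, wt, cleavage_rules(), depth = 8000, seed = 95)
  pv <- res$table$per_variant
  y <- ifelse(pv$frag5 + pv$full_length > 0,
              pv$frag5 / (pv$frag5 + pv$full_length), NA)
  wty <- y[lib$wildtype_ordinal + 1L]
  competent <- pv$motif[!is.na(y) & y > 0.1 * wty]
  incompetent <- pv$motif[!is.na(y) & y <= 0.1 * wty]
  call <- localize_motif(competent, incompetent, window_start = 22)
  expect_true(call$called)
  expect_equal(call$consensus, "UGGGU")
  expect_equal(call$start, 22L)

  # identical sets: zero IC difference everywhere, no call
  same <- localize_motif(pv$motif[1:50], pv$motif[1:50])
  expect_equal(same$ic_diff, rep(0, 5))
  expect_false(same$called)
  # antisymmetry under swapping the two sets
  a <- pv$motif[1:40]; b <- pv$motif[101:160]
  expect_equal(localize_motif(a, b)$ic_diff, -localize_motif(b, a)$ic_diff)
  expect_error(localize_motif(character(0), "AC"), "empty")
})

test_that("structure association beats sequence association when cleavage is fold-gated", {
  win <- randomized_window("S3head", 52L, 3L)  # 64 variants over the stem
  lib <- enumerate_variants(ref, win)
  sts <- structures_by_pairing(lib)
  res <- sim_assign(lib, sts, cleavage_rules(), depth = 5000, seed = 96,
                    decoy_frac = 0, error_rate = 0)
  rep1 <- structure_vs_sequence_report(res$table, sts, wt, lib)
  expect_gt(rep1$structure_assoc, rep1$sequence_assoc)
  expect_gt(rep1$structure_assoc, 0.5)
  expect_equal(rep1$modal_offset, 2L)
  expect_true(lib$wildtype_ordinal %in% rep1$competent)

  # control inversion: cleavage gated purely on sequence (RO60 base identity)
  win3 <- randomized_window("RO60head", 66L, 3L)  # covers position 68
  lib3 <- enumerate_variants(ref, win3)
  same_structure <- lapply(lib3$sequences, function(s)
    secondary_structure(s, wt$dotbracket, check_pairs = FALSE))
  res3 <- sim_assign(lib3, same_structure, cleavage_rules(), depth = 5000,
                     seed = 97, decoy_frac = 0, error_rate = 0)
  rep3 <- structure_vs_sequence_report(res3$table, same_structure, wt, lib3)
  expect_gt(rep3$sequence_assoc, rep3$structure_assoc)

  expect_error(structure_vs_sequence_report(
    assign_reads(character(0), lib), sts, wt, lib), "defined yield")
})
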