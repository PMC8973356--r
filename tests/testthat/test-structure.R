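test_that("dot-bracket parsing validates structure and pairing", {
  ss <- secondary_structure("GGGAAACCC", "(((...)))")
  expect_equal(ss$pair_table, c(9L, 8L, 7L, 0L, 0L, 0L, 3L, 2L, 1L))
  expect_error(secondary_structure("GGGAAACCC", "(((...))"), "lengths differ")
  expect_error(secondary_structure("GGGAAACCCC", "(((...))).."), "lengths differ")
  expect_error(secondary_structure("GGGAAACCC", "(((...))."), "unbalanced")
  expect_error(secondary_structure("GGGAAACCC", ".((...)))"), "unbalanced")
  expect_error(secondary_structure("GGGAAACCC", "[[[...]]]"), "pseudoknots")
  # A:C is not a legal pair unless checking is disabled
  expect_error(secondary_structure("AAACCC", "(....)"), "illegal base pair")
  expect_silent(secondary_structure("AAACCC", "(....)", check_pairs = FALSE))
})

test_that("fold reproduces known optima with deterministic traceback", {
  f <- fold("GGGAAACCC")
  expect_equal(f$dotbracket, "(((...)))")
  expect_equal(f$score, 9)
  expect_equal(fold("AAAAA")$dotbracket, ".....")
  expect_equal(fold("AAAAA")$score, 0)
  # the hairpin constraint forbids all pairs in a 4-mer
  expect_equal(fold("GCGC")$dotbracket, "....")
  expect_equal(fold("GCGC")$score, 0)
  expect_error(fold("GGXCC"))
})

test_that("fold matches the exhaustive enumeration oracle", {
  set.seed(101)
  for (i in 1:60) {
    s <- random_rna(sample(5:14, 1))
    f <- fold(s)
    expect_equal(f$score, oracle_best_weight(s), info = s)
    expect_equal(structure_weight(f), f$score, info = s)
  }
})

test_that("folded structures respect the hairpin constraint", {
  set.seed(202)
  for (i in 1:25) {
    f <- fold(random_rna(sample(8:30, 1)))
    pt <- f$pair_table
    up <- which(pt > seq_along(pt))
    if (length(up)) expect_true(all(pt[up] - up > 3))
  }
})

test_that("element decomposition identifies stems and loop kinds", {
  el <- parse_elements(secondary_structure("GGGAAACCC", "(((...)))"))
  expect_length(el$stems, 1L)
  expect_equal(el$stems[[1]]$length, 3L)
  expect_equal(el$stems[[1]]$gc_fraction, 1)
  expect_length(el$loops, 1L)
  expect_equal(el$loops[[1]]$kind, "hairpin")
  expect_equal(el$loops[[1]]$size, 3L)

  el2 <- parse_elements(secondary_structure("GGAAGGAAACCAACC",
                                            "((..((...))..))"))
  expect_length(el2$stems, 2L)
  expect_equal(vapply(el2$stems, `[[`, integer(1), "length"), c(2L, 2L))
  kinds <- vapply(el2$loops, `[[`, character(1), "kind")
  expect_setequal(kinds, c("internal", "hairpin"))
  il <- el2$loops[[which(kinds == "internal")]]
  expect_equal(il$size, 4L)
  expect_length(il$spans, 2L)

  el3 <- parse_elements(secondary_structure("GAGAAACAC", "(.(...).)"))
  expect_length(el3$stems, 2L)
  expect_equal(vapply(el3$stems, `[[`, integer(1), "length"), c(1L, 1L))
  il3 <- el3$loops[[which(vapply(el3$loops, `[[`, character(1), "kind") == "internal")]]
  expect_equal(il3$size, 2L)
})

test_that("element decomposition partitions every position", {
  set.seed(303)
  cases <- c(list(ysrna_wt_structure()),
             lapply(1:15, function(i) fold(random_rna(sample(10:40, 1)))))
  for (ss in cases) {
    el <- parse_elements(ss)
    n <- nchar(ss$sequence)
    stem_nt <- sum(vapply(el$stems, `[[`, integer(1), "length")) * 2L
    loop_nt <- sum(vapply(el$loops, `[[`, integer(1), "size"))
    expect_equal(stem_nt + loop_nt + length(el$exterior), n)
  }
})

test_that("stem S3 is located downstream of the cut region", {
  wt <- ysrna_wt_structure()
  s3 <- locate_stem_S3(wt, 49)
  expect_equal(s3$five_prime_span, c(52L, 57L))
  expect_equal(s3$length, 6L)
  expect_equal(s3$gc_fraction, 4 / 6)
  expect_equal(loop_above_stem(wt, s3), 9L)
  # shifted L1-like geometry starts two positions earlier
  sh <- ysrna_shifted_structure()
  expect_equal(locate_stem_S3(sh, 49)$five_prime_span[1], 50L)
  unfolded <- secondary_structure(strrep("A", 60), strrep(".", 60))
  expect_error(locate_stem_S3(unfolded, 49), class = "ysrna_no_stem")
})

test_that("cut offsets follow the cut-after convention", {
  expect_equal(cut_offset(49, 52), 2L)
  expect_equal(cut_offset(51, 52), 0L)
  expect_equal(cut_offset(47, 52), 4L)
  s3 <- locate_stem_S3(ysrna_wt_structure(), 49)
  expect_equal(cut_offset(49, s3), 2L)
  expect_error(cut_offset(52, 52), "strictly 5'")
  # translation invariance
  set.seed(9)
  for (i in 1:20) {
    cut <- sample(1:100, 1); st <- cut + sample(1:20, 1); d <- sample(-50:50, 1)
    expect_equal(cut_offset(cut + d, st + d), cut_offset(cut, st))
  }
})

test_that("the RO60 site call requires the pair, the bases and the bulge", {
  ref <- ysrna_reference()
  wt <- ysrna_wt_structure()
  expect_true(ro60_site_intact(ref$sequence, wt, ref))
  # unpair 8:68 in the supplied dot-bracket -> site lost
  db <- strsplit(wt$dotbracket, "")[[1]]
  db[c(4:8, 68:72)] <- "."
  open_lost <- secondary_structure(ref$sequence, paste0(db, collapse = ""))
  expect_false(ro60_site_intact(ref$sequence, open_lost, ref))
  # bulge cytidine mutated -> site lost
  mut <- ref$sequence
  substr(mut, 9, 9) <- "A"
  expect_false(ro60_site_intact(mut, wt, ref))
  # non-GC pair at 8:68 -> site lost
  mut2 <- ref$sequence
  substr(mut2, 68, 68) <- "U"  # C:U would be illegal; bypass pair checking
  wt_nc <- secondary_structure(mut2, wt$dotbracket, check_pairs = FALSE)
  expect_false(ro60_site_intact(mut2, wt_nc, ref))
  expect_error(ro60_site_intact("ACGU", wt, list(ro60_pair = c(8, 68),
                                                 ro60_bulge_pos = 9)),
               "beyond sequence")
})

test_that("base-pair distance is a symmetric-difference count", {
  a <- secondary_structure("GGGAAACCC", "(((...)))")
  b <- secondary_structure("GGGAAACCC", ".........")
  c <- secondary_structure("GGGAAACCC", "((.....))")
  expect_equal(structure_distance(a, a), 0L)
  expect_equal(structure_distance(a, b), 3L)
  expect_equal(structure_distance(a, c), 1L)
  expect_equal(structure_distance(c, a), 1L)
  expect_error(structure_distance(a, secondary_structure("GC", "..")),
               "different lengths")
  # zero distance preserves the RO60 verdict
  ref <- ysrna_reference()
  wt <- ysrna_wt_structure()
  copy <- secondary_structure(ref$sequence, wt$dotbracket)
  expect_equal(structure_distance(wt, copy), 0L)
  expect_equal(ro60_site_intact(ref$sequence, copy, ref),
               ro60_site_intact(ref$sequence, wt, ref))
})

test_that("dot-bracket files round-trip through the Vienna layout", {
  sts <- list(wt = ysrna_wt_structure(),
              hp = secondary_structure("GGGAAACCC", "(((...)))"))
  path <- tempfile(fileext = ".db")
  write_dotbracket(sts, path)
  back <- read_dotbracket(path)
  expect_equal(names(back), c("wt", "hp"))
  expect_equal(back$wt$dotbracket, sts$wt$dotbracket)
  expect_equal(back$hp$sequence, sts$hp$sequence)
  writeLines(c(">broken", "ACGU"), path)
  expect_error(read_dotbracket(path), "truncated")
})
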