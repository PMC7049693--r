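test_that("cloverleaf heuristic fires on constructed tRNAs and tolerates the
          long-anticodon anomaly", {
  for (i in 1:25) {
    res <- cloverleaf_check(make_trna_seq(seed = i))
    expect_true(res$folds_as_trna)
    expect_identical(res$arms$arm, c("acceptor", "D", "anticodon", "T"))
  }
  # the 7-bp-anticodon, small-loop variant folds under tolerance but the
  # designed arm is rejected by the strict canonical (5 bp) model
  v <- make_trna_seq(seed = 1, ac_stem = 7, ac_loop = 5)
  expect_true(cloverleaf_check(v, ac_stem_max = 7)$folds_as_trna)
  expect_false(cloverleaf_check(v, ac_stem_max = 5)$folds_as_trna)
  arms <- cloverleaf_check(v, ac_stem_max = 7)$arms
  expect_identical(arms$stem_bp[arms$arm == "anticodon"], 7)
  # length gate
  expect_false(cloverleaf_check(random_dna_str(40))$folds_as_trna)
  expect_false(cloverleaf_check(random_dna_str(150))$folds_as_trna)
})

test_that("cloverleaf heuristic is specific on random sequences", {
  set.seed(99)
  fp <- vapply(1:200, function(i)
    cloverleaf_check(random_dna_str(60))$folds_as_trna, logical(1))
  expect_lt(mean(fp), 0.10)
})

test_that("H/ACA heuristic requires the ACA box, central H box and two
          pocketed hairpins", {
  for (i in 1:25) {
    s <- make_haca_seq(seed = i)
    res <- haca_check(s)
    expect_true(res$folds_as_haca)
    # ACA box starts exactly 6 nt before the 3' end (3-nt tail follows)
    expect_identical(res$haca_boxes$aca_start, nchar(s) - 5L)
    # necessary condition: mutating ACA to AGA kills the call
    mut <- s
    substr(mut, nchar(s) - 4, nchar(s) - 4) <- "G"
    expect_false(haca_check(mut)$folds_as_haca)
  }
})

test_that("H/ACA heuristic is specific on shuffled family sequences", {
  set.seed(7)
  fp <- vapply(1:200, function(i) {
    haca_check(shuffle_seq(make_haca_seq()))$folds_as_haca
  }, logical(1))
  expect_lt(mean(fp), 0.05)
})

test_that("C/D detector finds designed boxes and the guide matches the
          exhaustive-window oracle", {
  target <- random_dna_str(600)
  targets <- c(rRNA_18S = target)
  for (i in 1:15) {
    s <- make_cd_seq(target, "rRNA_18S", seed = i)
    res <- cd_check(s, targets)
    expect_false(is.null(res$cd_boxes))
    expect_lt(res$cd_boxes$box_c_start + 6, res$cd_boxes$box_d_start)
    expect_false(is.null(res$guide_target))
    expect_gte(res$guide_target$guide_len, 10)
    # guide position pairs the 5th nt upstream of box D to the planted site
    expect_identical(res$guide_target$target_pos,
      as.integer(attr(s, "target_pos")))
    # exhaustive oracle agrees on the longest admissible guide window
    orc <- oracle_guide(s, res$cd_boxes$box_c_start, res$cd_boxes$box_d_start,
      target)
    expect_identical(res$guide_target$guide_len, as.integer(orc$len))
  }
  # necessary condition: no CTGA in the 3' window, no boxes
  s <- make_cd_seq(target, "rRNA_18S", seed = 3)
  no_d <- gsub("CTGA", "CAGA", s, fixed = TRUE)
  expect_null(cd_check(no_d, targets)$cd_boxes)
})

test_that("base-pair maximization folding is consistent", {
  # a perfect hairpin pairs fully and exposes no pocket
  stem <- "GGGCGGCC"
  hp <- paste0(stem, "AAAA", reverse_complement(stem))
  p <- fold_pairs(hp)
  expect_identical(sum(p > seq_along(p)), nchar(stem))
  expect_false(snclust:::has_interior_loop(p))
  # inserting symmetric bulges opens an interior loop
  hp2 <- paste0("GGGCGGCC", "AA", "GCGGCG", "AAAA",
    reverse_complement("GCGGCG"), "AA", reverse_complement("GGGCGGCC"))
  p2 <- fold_pairs(hp2)
  expect_true(snclust:::has_interior_loop(p2))
})
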