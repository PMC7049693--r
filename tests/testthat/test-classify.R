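ref_set <- function(seed = 2, n_trna = 6) {
  withr::with_seed(seed, {
    dplyr::bind_rows(
      tibble::tibble(id = sprintf("tr%02d", seq_len(n_trna)),
        biotype = "tRNA",
        seq = vapply(seq_len(n_trna), function(i) make_trna_seq(),
          character(1))),
      tibble::tibble(id = "dc01", biotype = "lncRNA",
        seq = random_dna_str(80))
    )
  })
}

test_that("homology_search finds self and planted substrings with sane
          e-values", {
  refs <- ref_set()
  cfg <- pipeline_config()
  # a query identical to a reference: perfect top hit
  hits <- homology_search(refs$seq[1], refs, cfg)
  expect_identical(hits$ref_id[1], "tr01")
  expect_equal(hits$identity[1], 100)
  expect_lt(hits$evalue[1], 1e-10)
  expect_identical(c(hits$r_start[1], hits$r_end[1]),
    c(1L, nchar(refs$seq[1])))
  # a 40-nt exact substring maps back to its planted offset
  frag <- substr(refs$seq[2], 21, 60)
  h2 <- homology_search(frag, refs, cfg)
  expect_identical(h2$ref_id[1], "tr02")
  expect_identical(c(h2$r_start[1], h2$r_end[1]), c(21L, 60L))
  # an antisense query is found on the minus strand with the same span
  h3 <- homology_search(reverse_complement(frag), refs, cfg)
  expect_identical(h3$ref_id[1], "tr02")
  expect_identical(h3$strand[1], "-")
  expect_identical(c(h3$r_start[1], h3$r_end[1]), c(21L, 60L))
  expect_error(homology_search("ACGT", refs[0, ], cfg),
    class = "snc_reference_error")
})

test_that("random queries rarely reach the e-value threshold", {
  refs <- ref_set()
  cfg <- pipeline_config()
  set.seed(17)
  n_hit <- vapply(1:100, function(i) {
    nrow(homology_search(random_dna_str(60), refs, cfg)) > 0
  }, logical(1))
  expect_lt(mean(n_hit), 0.05)
})

test_that("repeat_overlap labels the dominant repeat above the fraction
          threshold", {
  clusters <- mk_clusters(tibble::tibble(
    chrom = "c1", start = c(100L, 300L, 500L), end = c(200L, 400L, 600L),
    strand = "+"))
  annotation <- tibble::tibble(
    chrom = "c1", start = c(100L, 330L), end = c(200L, 400L), strand = "+",
    gene_id = c("alu1", "trep1"), biotype = c("repeat_Alu", "repeat_tRNA"),
    feature = "repeat")
  ov <- repeat_overlap(clusters, annotation)
  expect_identical(ov$repeat_label, c("Alu", "tRNA_repeat", "none"))
  expect_equal(ov$repeat_frac, c(1, 0.7, 0))
  # 30% overlap stays below the 50% threshold
  ann30 <- annotation[2, ]
  ann30$start <- 370L
  ov30 <- repeat_overlap(clusters, ann30)
  expect_identical(ov30$repeat_label[2], "none")
})

test_that("classify_biotype follows the committed decision tree", {
  cfg <- pipeline_config()
  refs <- ref_set()
  target <- withr::with_seed(8, random_dna_str(600))
  targets <- c(rRNA_18S = target)

  seqs <- withr::with_seed(9, list(
    trf58 = substr(refs$seq[1], 6, 63),        # 58 nt, tRNA homology
    trna = refs$seq[3],                        # full mature copy
    pre = paste0(random_dna_str(10), refs$seq[4], random_dna_str(10)),
    cd = as.character(make_cd_seq(target, "rRNA_18S")),
    haca = make_haca_seq(),
    rnd = random_dna_str(80)
  ))
  clusters <- tibble::tibble(
    cluster_id = names(seqs), chrom = "c1",
    start = seq(0L, by = 500L, length.out = 6),
    end = seq(0L, by = 500L, length.out = 6) +
      vapply(seqs, nchar, integer(1)),
    strand = "+", read_count = 200L, unique_read_count = 200L,
    datasets_detected = list(c("d1", "d2")),
    sequence = unlist(seqs))
  annotation <- tibble::tibble(chrom = character(0), start = integer(0),
    end = integer(0), strand = character(0), gene_id = character(0),
    biotype = character(0), feature = character(0))

  ev <- collect_evidence(clusters, refs, targets, annotation, cfg)
  calls <- classify_biotype(ev, clusters, annotation, cfg)
  got <- setNames(calls$biotype, calls$cluster_id)
  expect_identical(got[["trf58"]], "tRNA_fragment")  # < 65 nt rule
  expect_identical(got[["trna"]], "tRNA_like")
  expect_identical(got[["pre"]], "pre_tRNA")         # > 5 nt extension rule
  expect_identical(got[["cd"]], "snoRNA_CD")
  expect_identical(got[["haca"]], "snoRNA_HACA")
  expect_match(calls$rationale[calls$cluster_id == "haca"], "orphan")
  expect_identical(got[["rnd"]], "unknown")

  # the call is a pure function of its evidence
  calls2 <- classify_biotype(ev, clusters, annotation, cfg)
  expect_identical(calls, calls2)
  # every cluster gets exactly one of the eight classes
  expect_true(all(calls$biotype %in% c("tRNA_like", "pre_tRNA",
    "tRNA_fragment", "snoRNA_CD", "snoRNA_HACA", "ITS_RNA", "ETS_RNA",
    "unknown")))
})

test_that("location inside rDNA spacer features takes precedence", {
  cfg <- pipeline_config()
  refs <- ref_set()
  clusters <- mk_clusters(tibble::tibble(
    chrom = "c1", start = c(100L, 2100L), end = c(210L, 2200L),
    strand = "+"), ids = c("ets", "its"))
  clusters$sequence <- withr::with_seed(10,
    c(make_ets_seq(len = 110), make_its_seq(len = 100)))
  annotation <- tibble::tibble(
    chrom = "c1", start = c(0L, 2000L), end = c(1500L, 3500L), strand = "+",
    gene_id = "rdna1", biotype = "rRNA_45S",
    feature = c("rDNA_5ETS", "rDNA_ITS1"))
  ev <- collect_evidence(clusters, refs, NULL, annotation, cfg)
  calls <- classify_biotype(ev, clusters, annotation, cfg)
  expect_identical(calls$biotype, c("ETS_RNA", "ITS_RNA"))
})

test_that("random sequences overwhelmingly classify as unknown", {
  cfg <- pipeline_config()
  refs <- ref_set()
  set.seed(23)
  n <- 40
  lens <- sample(30:200, n, replace = TRUE)
  clusters <- tibble::tibble(
    cluster_id = sprintf("r%02d", 1:n), chrom = "c1",
    start = seq(0L, by = 300L, length.out = n),
    end = seq(0L, by = 300L, length.out = n) + lens,
    strand = "+", read_count = 200L, unique_read_count = 200L,
    datasets_detected = list(c("d1", "d2")),
    sequence = vapply(lens, random_dna_str, character(1)))
  annotation <- tibble::tibble(chrom = character(0), start = integer(0),
    end = integer(0), strand = character(0), gene_id = character(0),
    biotype = character(0), feature = character(0))
  ev <- collect_evidence(clusters, refs, NULL, annotation, cfg)
  calls <- classify_biotype(ev, clusters, annotation, cfg)
  expect_gte(mean(calls$biotype == "unknown"), 0.85)
})
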