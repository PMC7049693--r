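# one small shared simulation for this file (kept deliberately compact)
small_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- build_genome(pipeline_config(),
        sim_design(n_novel_per_class = 2, n_annotated = 40,
          genome_size = 2.5e5), seed = 101)
    }
    cache
  }
})

test_that("planted truth round-trips through genome coordinates", {
  sim <- small_sim()
  # the emitted truth sequence equals a fresh fetch at its coordinates
  expect_identical(sim$loci$sequence, fetch_sequence(sim$genome, sim$loci))
  # every snoRNA locus is intronic, tRNA-family novel loci are intergenic
  sno <- sim$loci[grepl("^snoRNA", sim$loci$true_biotype), ]
  expect_true(all(!is.na(sno$host_gene_id)))
  trn <- sim$loci[!sim$loci$annotated &
    sim$loci$true_biotype %in% c("tRNA_like", "pre_tRNA", "tRNA_fragment"), ]
  hosts <- sim$annotation[sim$annotation$feature == "gene" &
    sim$annotation$biotype == "protein_coding", ]
  ov <- GenomicRanges::findOverlaps(
    snclust:::as_granges(trn), snclust:::as_granges(hosts),
    ignore.strand = TRUE)
  expect_identical(length(ov), 0L)
  # multi-copy loci carry byte-identical sequence at each copy
  multi <- sim$loci[sim$loci$n_copies > 1, ]
  for (id in unique(multi$locus_id)) {
    expect_identical(length(unique(multi$sequence[multi$locus_id == id])), 1L)
  }
  # novel loci are absent from the annotation, annotated loci present
  expect_false(any(sim$loci$locus_id[!sim$loci$annotated] %in%
    sim$annotation$gene_id))
  expect_true(all(sim$loci$locus_id[sim$loci$annotated] %in%
    sim$annotation$gene_id))
})

test_that("planted family sequences satisfy their detectors by
          construction", {
  sim <- small_sim()
  novel <- sim$loci[!sim$loci$annotated & sim$loci$copy == 1, ]
  for (i in seq_len(nrow(novel))) {
    s <- novel$sequence[i]
    if (novel$true_biotype[i] == "snoRNA_HACA") {
      res <- haca_check(s)
      expect_true(res$folds_as_haca)
      # ACA box placed exactly 3 nt from the locus 3' end
      expect_identical(res$haca_boxes$aca_start, nchar(s) - 5L)
    }
    if (novel$true_biotype[i] == "snoRNA_CD") {
      res <- cd_check(s, sim$targets)
      expect_false(is.null(res$cd_boxes))
      expect_false(is.null(res$guide_target))
    }
  }
})

test_that("simulated read counts follow the requested abundances", {
  sim <- small_sim()
  # fixed per-dataset abundances override the stochastic factors: a locus
  # silent in dataset 2 yields no reads there
  loci <- sim$loci[!sim$loci$annotated &
    sim$loci$true_biotype == "unknown", ][1, ]
  loci$tpm_by_dataset <- list(c(10, 0))
  reads <- simulate_reads(sim$genome, loci, n_datasets = 2, depth = 20,
    seed = 5)
  expect_gt(sum(reads$dataset_id == "ds1"), 0)
  expect_identical(sum(reads$dataset_id == "ds2"), 0L)
  # no read exceeds chromosome bounds; jitter stays within 2 nt
  expect_true(all(reads$start >= 0))
  expect_true(all(abs(reads$start - loci$start) <= 2))
  expect_true(all(abs(reads$end - loci$end) <= 2))

  # determinism: identical seed, identical BED bytes
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  r1 <- simulate_reads(sim$genome, sim$loci, sim$annotation,
    n_datasets = 2, depth = 3, seed = 42)
  r2 <- simulate_reads(sim$genome, sim$loci, sim$annotation,
    n_datasets = 2, depth = 3, seed = 42)
  write_reads_bed(r1[r1$dataset_id == "ds1", ], f1)
  write_reads_bed(r2[r2$dataset_id == "ds1", ], f2)
  expect_identical(readLines(f1), readLines(f2))
  # multimapped reads advertise the copy number of their source locus
  multi_ids <- unique(sim$loci$locus_id[sim$loci$n_copies > 1])
  expect_true(any(r1$n_genomic_hits > 1))
  expect_identical(sort(unique(r1$n_genomic_hits)), c(1L, 2L))
})

test_that("per-locus read counts fall inside the Poisson envelope", {
  sim <- small_sim()
  locus <- sim$loci[!sim$loci$annotated &
    sim$loci$true_biotype == "tRNA_like", ][1, ]
  locus$tpm_by_dataset <- list(c(10, 10))
  lambda <- 10 * 10  # tpm x depth
  counts <- vapply(1:50, function(s) {
    r <- simulate_reads(sim$genome, locus, n_datasets = 2, depth = 10,
      seed = 1000 + s)
    sum(r$dataset_id == "ds1")
  }, numeric(1))
  lo <- stats::qpois(0.005, lambda)
  hi <- stats::qpois(0.995, lambda)
  expect_gte(mean(counts >= lo & counts <= hi), 0.94)
})

test_that("the depletion contrast scales only H/ACA loci", {
  sim <- small_sim()
  # null effect: expected counts identical because the RNG stream matches
  dep1 <- simulate_depletion(sim$genome, sim$loci, sim$annotation,
    effect = 1, depth = 5, seed = 77)
  dep5 <- simulate_depletion(sim$genome, sim$loci, sim$annotation,
    effect = 0.5, depth = 5, seed = 77)
  expect_identical(nrow(dep1$control), nrow(dep5$control))
  count_by <- function(reads, loci) {
    g <- GenomicRanges::findOverlaps(snclust:::as_granges(loci),
      snclust:::as_granges(reads))
    tapply(rep(1, length(g)), loci$true_biotype[S4Vectors::queryHits(g)], sum)
  }
  kd1 <- count_by(dep1$knockdown, sim$loci)
  kd5 <- count_by(dep5$knockdown, sim$loci)
  ratio <- kd5[["snoRNA_HACA"]] / kd1[["snoRNA_HACA"]]
  expect_lt(abs(ratio - 0.5), 0.12)
  ratio_cd <- kd5[["snoRNA_CD"]] / kd1[["snoRNA_CD"]]
  expect_lt(abs(ratio_cd - 1), 0.12)
  expect_error(
    simulate_depletion(sim$genome, sim$loci, effect = 0), "effect")
})

test_that("conservation track and orthologs reflect the biotype profile", {
  sim <- small_sim()
  out <- emit_conservation_and_orthologs(sim$genome, sim$loci, seed = 3)
  expect_true(all(out$track$score >= 0 & out$track$score <= 1))
  trna <- sim$loci[sim$loci$true_biotype == "tRNA", ]
  m <- mean_conservation(trna, out$track)
  expect_true(all(abs(m - 0.9) < 0.05))
  # a mutation-free species reproduces the flanked locus; identity 100
  sp <- tibble::tibble(species = "same", identity = 1, rank = 1L)
  o <- emit_conservation_and_orthologs(sim$genome, sim$loci, species = sp,
    seed = 4)$orthologs
  row <- sim$loci[sim$loci$locus_id == o$locus_id[1] & sim$loci$copy == 1, ]
  r <- ortholog_identity(row$sequence, o$seq[1])
  expect_false(r$no_equivalent)
  expect_equal(r$identity, 100)
  # species beyond a biotype's conservation reach report no equivalent
  far <- tibble::tibble(species = "far", identity = 0.8, rank = 6L)
  o2 <- emit_conservation_and_orthologs(sim$genome, sim$loci, species = far,
    seed = 5)$orthologs
  sno <- o2[grepl("snoRNA", o2$locus_id), ]
  expect_true(all(is.na(sno$seq)))
  expect_true(ortholog_identity(row$sequence, NA)$no_equivalent)
})
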