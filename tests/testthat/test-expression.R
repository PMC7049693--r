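test_that("mean_conservation averages per-base scores with missing bases
          as zero", {
  ivl <- genomic_interval("c1", 100, 200, "+")
  uniform <- tibble::tibble(chrom = "c1", start = 100L, end = 200L,
    score = 0.8)
  expect_equal(mean_conservation(ivl, uniform), 0.8)
  empty <- uniform[0, ]
  expect_equal(mean_conservation(ivl, empty), 0)
  # half-covered interval: covered half at 1.0 averages to 0.5
  half <- tibble::tibble(chrom = "c1", start = 100L, end = 150L, score = 1)
  expect_equal(mean_conservation(ivl, half), 0.5)

  set.seed(19)
  for (i in 1:20) {
    # random per-base track over a random interval
    s <- sample(0:400, 1)
    e <- s + sample(20:80, 1)
    ivl <- genomic_interval("c1", s, e, "+")
    pos <- sort(sample(0:500, 120))
    track <- tibble::tibble(chrom = "c1", start = pos, end = pos + 1L,
      score = round(runif(120), 3))
    inside <- track$start >= s & track$start < e
    want <- sum(track$score[inside]) / (e - s)
    expect_equal(mean_conservation(ivl, track), want)
  }
})

test_that("ortholog identity tracks the simulated mutation rate", {
  cfg <- pipeline_config()
  set.seed(29)
  ids <- vapply(1:50, function(i) {
    s <- random_dna_str(120)
    region <- paste0(random_dna_str(100), snclust:::mutate_seq(s, 0.1),
      random_dna_str(100))
    ortholog_identity(s, region, cfg)$identity
  }, numeric(1))
  expect_lt(abs(mean(ids) - 90), 3)
})

test_that("TPM columns sum to one million and respect embedded-gene
          priority", {
  features <- tibble::tibble(
    feature_id = c("host", "sno", "lone"), chrom = "c1",
    start = c(0L, 400L, 3000L), end = c(2000L, 520L, 3200L), strand = "+")
  mk <- function(n, start, end, ds, hits = 1L) {
    tibble::tibble(chrom = "c1", start = start, end = end, strand = "+",
      read_id = sprintf("%s_%d_%d", ds, start, seq_len(n)), dataset_id = ds,
      n_genomic_hits = hits)
  }
  reads <- dplyr::bind_rows(
    mk(30, 100L, 300L, "d1"),        # host exonic
    mk(50, 410L, 515L, "d1"),        # embedded snoRNA, not double counted
    mk(20, 3010L, 3180L, "d1"),
    mk(10, 100L, 300L, "d2"),
    mk(10, 410L, 515L, "d2", hits = 2L)  # multimapped: half weight
  )
  expr <- tpm_quantify(reads, features)
  expect_equal(colSums(expr[, c("d1", "d2")]), c(d1 = 1e6, d2 = 1e6))
  counts <- attr(expr, "counts")
  expect_equal(counts$d1[counts$feature_id == "host"], 30)
  expect_equal(counts$d1[counts$feature_id == "sno"], 50)
  expect_equal(counts$d2[counts$feature_id == "sno"], 5)  # 10 x 1/2
  # single feature takes the whole million; two equal features split it
  single <- tpm_quantify(mk(40, 100L, 300L, "d1"), features[1, ])
  expect_equal(single$d1, 1e6)
  pair <- tpm_quantify(
    dplyr::bind_rows(mk(25, 100L, 200L, "d1"), mk(25, 3000L, 3100L, "d1")),
    tibble::tibble(feature_id = c("a", "b"), chrom = "c1",
      start = c(0L, 2900L), end = c(300L, 3200L), strand = "+"))
  expect_equal(pair$d1, c(5e5, 5e5))
})

test_that("read assignment equals the brute-force per-read oracle", {
  set.seed(37)
  features <- rand_interval_tbl(12, chrom_len = 800)
  features$feature_id <- sprintf("f%02d", 1:12)
  reads <- rand_interval_tbl(300, chrom_len = 800)
  reads$read_id <- sprintf("r%03d", 1:300)
  reads$dataset_id <- "d1"
  reads$n_genomic_hits <- 1L
  expect_identical(assign_reads(reads, features),
    oracle_assign(reads, features))
})

test_that("host correlation separates coupled, anti-coupled and intergenic
          clusters", {
  cfg <- pipeline_config()
  host <- c(10, 40, 20, 80, 60, 30)
  expr <- tibble::tibble(
    feature_id = c("host", "coupled", "anti"),
    ds1 = c(host[1], host[1] * 2, 100 - host[1]),
    ds2 = c(host[2], host[2] * 2, 100 - host[2]),
    ds3 = c(host[3], host[3] * 2, 100 - host[3]),
    ds4 = c(host[4], host[4] * 2, 100 - host[4]),
    ds5 = c(host[5], host[5] * 2, 100 - host[5]),
    ds6 = c(host[6], host[6] * 2, 100 - host[6]))
  up <- host_correlation(expr, "coupled", "host", cfg)
  expect_equal(up$correlation, 1)
  expect_identical(up$mode, "host_dependent")
  dn <- host_correlation(expr, "anti", "host", cfg)
  expect_equal(dn$correlation, -1)
  expect_identical(dn$mode, "independent")
  none <- host_correlation(expr, "coupled", NA_character_, cfg)
  expect_identical(none$mode, "independent")
  expect_error(host_correlation(expr[, 1:3], "coupled", "host", cfg),
    class = "snc_expression_error")
})

test_that("host-coupled simulated loci are recovered as host-dependent", {
  sim <- build_genome(pipeline_config(),
    sim_design(n_novel_per_class = 2, n_annotated = 40,
      genome_size = 2.5e5), seed = 101)
  reads <- simulate_reads(sim$genome, sim$loci, sim$annotation,
    n_datasets = 6, depth = 10, seed = 55)
  feats <- dplyr::transmute(sim$loci,
    feature_id = paste0(locus_id, "_c", copy), chrom, start, end, strand)
  expr <- tpm_quantify(reads, feats)
  sno <- sim$loci[!sim$loci$annotated &
    grepl("snoRNA", sim$loci$true_biotype), ]
  modes <- vapply(seq_len(nrow(sno)), function(i) {
    host_correlation(expr, paste0(sno$locus_id[i], "_c1"),
      paste0(sno$host_gene_id[i], "_c1"))$mode
  }, character(1))
  expect_gte(mean(modes == "host_dependent"), 0.9)
})

test_that("depletion response is antisymmetric and null at effect one", {
  bt <- tibble::tibble(cluster_id = c("a", "b"),
    biotype = c("snoRNA_HACA", "snoRNA_CD"))
  ctrl <- tibble::tibble(feature_id = c("a", "b"), r1 = c(100, 50),
    r2 = c(120, 55))
  kd <- tibble::tibble(feature_id = c("a", "b"), r1 = c(50, 49),
    r2 = c(60, 56))
  dep <- depletion_response(ctrl, kd, bt)
  swapped <- depletion_response(kd, ctrl, bt)
  expect_equal(dep$per_cluster$log2fc, -swapped$per_cluster$log2fc)
  null <- depletion_response(ctrl, ctrl, bt)
  expect_equal(null$per_cluster$log2fc, c(0, 0))
  expect_identical(nrow(dep$per_biotype), 2L)
})
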