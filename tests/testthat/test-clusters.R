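test_that("coverage_profile matches per-base membership counting", {
  one <- tibble::tibble(chrom = "c1", start = 10L, end = 60L, strand = "+",
    read_id = "r1", dataset_id = "d1", n_genomic_hits = 1L)
  cov <- coverage_profile(one, "c1", "+")
  expect_identical(sum(cov == 1), 50L)
  expect_identical(sum(cov), 50)

  empty <- one[0, ]
  expect_identical(coverage_profile(empty, "c1", "+", width = 20), numeric(20))

  set.seed(13)
  reads <- rand_reads(40, max_reads_per_tag = 5, chrom_len = 300)
  reads <- reads[reads$chrom == "c1" & reads$strand == "+", ]
  cov <- coverage_profile(reads, "c1", "+", width = 300)
  expect_equal(cov, oracle_coverage(reads, 300))
  expect_equal(sum(cov), sum(reads$end - reads$start))

  expect_error(coverage_profile(rand_reads(5), "c1", "+"),
    class = "snc_interval_error")
})

test_that("call_clusters applies tag and cluster thresholds", {
  mk <- function(n, start = 100L, end = 160L, strand = "+") {
    tibble::tibble(chrom = "c1", start = start, end = end, strand = strand,
      read_id = sprintf("r%d", seq_len(n)), dataset_id = "d1",
      n_genomic_hits = 1L)
  }
  cfg <- pipeline_config()
  # 150 identical reads over one locus: exactly one cluster
  cl <- call_clusters(mk(150), config = cfg)
  expect_identical(nrow(cl), 1L)
  expect_identical(cl$read_count, 150L)
  expect_identical(c(cl$start, cl$end), c(100L, 160L))
  # 99 reads with min_cluster_reads = 100: nothing
  expect_identical(nrow(call_clusters(mk(99), config = cfg)), 0L)
  # two loci separated by an uncovered base: two clusters
  two <- dplyr::bind_rows(mk(120), mk(120, start = 161L, end = 220L))
  two$read_id <- sprintf("r%d", seq_len(nrow(two)))
  cl2 <- call_clusters(two, config = cfg)
  expect_identical(nrow(cl2), 2L)
  # same loci but antisense second locus: still two, strand-separated
  two$strand[121:240] <- "-"
  expect_identical(nrow(call_clusters(two, config = cfg)), 2L)
})

test_that("call_clusters equals the brute-force coverage-component oracle on
          random layouts", {
  cfg <- pipeline_config(tag_filter = 3, min_cluster_reads = 8)
  set.seed(21)
  for (rep in 1:50) {
    reads <- rand_reads(sample(5:25, 1), max_reads_per_tag = 12,
      chrom_len = 250)
    got <- call_clusters(reads, config = cfg)
    want <- oracle_clusters(reads, cfg)
    expect_identical(
      got[, c("chrom", "start", "end", "strand", "read_count",
        "unique_read_count")],
      want
    )
    # clusters never overlap each other on a strand
    if (nrow(got) > 1) {
      for (std in c("+", "-")) {
        g <- got[got$strand == std, ]
        if (nrow(g) > 1) {
          g <- dplyr::arrange(g, chrom, start)
          same <- g$chrom[-nrow(g)] == g$chrom[-1]
          expect_true(all(g$end[-nrow(g)][same] <= g$start[-1][same]))
        }
      }
    }
  }
})

test_that("detect_in_datasets is strand-aware and respects the read
          threshold", {
  cluster_reads <- tibble::tibble(chrom = "c1", start = 100L, end = 160L,
    strand = "+", read_id = sprintf("r%d", 1:120), dataset_id = "d1",
    n_genomic_hits = 1L)
  cl <- call_clusters(cluster_reads, config = pipeline_config())
  other <- dplyr::bind_rows(
    cluster_reads,
    tibble::tibble(chrom = "c1", start = 110L, end = 150L, strand = "+",
      read_id = "x1", dataset_id = "d2", n_genomic_hits = 1L),
    # antisense-only coverage in d3 must not count
    tibble::tibble(chrom = "c1", start = 110L, end = 150L, strand = "-",
      read_id = "x2", dataset_id = "d3", n_genomic_hits = 1L)
  )
  got <- detect_in_datasets(cl, other, pipeline_config())
  expect_identical(got$datasets_detected[[1]], c("d1", "d2"))
  # raising the detection threshold drops the single-read dataset
  got2 <- detect_in_datasets(cl, other, pipeline_config(detect_min_reads = 2))
  expect_identical(got2$datasets_detected[[1]], "d1")
})
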