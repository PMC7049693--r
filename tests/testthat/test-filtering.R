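test_that("annotation_overlap performs a strand-aware left outer join", {
  clusters <- mk_clusters(tibble::tibble(
    chrom = "c1", start = c(100L, 300L), end = c(172L, 360L),
    strand = c("+", "-")))
  annotation <- tibble::tibble(
    chrom = "c1", start = c(90L, 300L), end = c(180L, 360L),
    strand = c("+", "+"),
    gene_id = c("gA", "gB"), biotype = c("tRNA", "snRNA"),
    feature = c("gene", "gene"))
  ov <- annotation_overlap(clusters, annotation)
  # cluster 1 joins gA on the same strand; cluster 2 is antisense to gB and
  # joins nothing
  expect_identical(ov$gene_id[ov$cluster_id == "cl_1"], "gA")
  expect_true(is.na(ov$gene_id[ov$cluster_id == "cl_2"]))
  expect_identical(nrow(ov), 2L)

  set.seed(31)
  rnd_cl <- mk_clusters(rand_interval_tbl(100, chrom_len = 600))
  rnd_ann <- rand_interval_tbl(60, chrom_len = 600)
  rnd_ann$gene_id <- sprintf("g%d", 1:60)
  rnd_ann$biotype <- "tRNA"
  rnd_ann$feature <- "gene"
  got <- annotation_overlap(rnd_cl, rnd_ann) |>
    dplyr::filter(!is.na(gene_id)) |>
    dplyr::select(cluster_id, gene_id, overlap_bp) |>
    dplyr::arrange(cluster_id, gene_id)
  want <- oracle_annotation_join(rnd_cl, rnd_ann) |>
    dplyr::arrange(cluster_id, gene_id)
  expect_identical(got, want)
})

test_that("the designed fixture yields exactly the designed verdicts", {
  fx <- filter_fixture(seed = 1)
  flt <- filter_cascade(fx$clusters, fx$annotation, pipeline_config(),
    fx$genome)
  v <- tidy(flt)
  expect_identical(v$kept, fx$expected$expected_kept)
  expect_identical(v$failed_filters, fx$expected$expected_filters)
  expect_identical(sum(v$kept), 2L)
  # per-filter tally of the discarded clusters matches the design
  tally <- glance(flt)
  expect_identical(
    as.integer(tally[, c("annotated", "too_short", "too_long", "low_unique",
      "single_dataset", "antisense_45S", "retained_intron")]),
    c(2L, 1L, 1L, 2L, 2L, 1L, 1L))
})

test_that("filter outcome is independent of cluster ordering and partitions
          the input", {
  fx <- filter_fixture(seed = 1)
  flt <- filter_cascade(fx$clusters, fx$annotation, pipeline_config(),
    fx$genome)
  set.seed(3)
  perm <- sample(nrow(fx$clusters))
  flt_p <- filter_cascade(fx$clusters[perm, ], fx$annotation,
    pipeline_config(), fx$genome)
  a <- dplyr::arrange(tidy(flt), cluster_id)[, c("cluster_id", "kept",
    "failed_filters")]
  b <- dplyr::arrange(tidy(flt_p), cluster_id)[, c("cluster_id", "kept",
    "failed_filters")]
  expect_identical(a, b)
  # kept and discarded partition the input
  v <- tidy(flt)
  expect_identical(sort(c(flt$kept$cluster_id,
    v$cluster_id[!v$kept])), sort(fx$clusters$cluster_id))
  expect_identical(v$kept, lengths(v$failed_list) == 0)
})

test_that("the multimap exception requires every partner locus to be a
          non-annotated candidate cluster", {
  fx <- filter_fixture(seed = 1)
  # without the genome the partner scan cannot run: exception never applies
  flt_ng <- filter_cascade(fx$clusters, fx$annotation, pipeline_config())
  v <- tidy(flt_ng)
  expect_identical(v$failed_filters[v$cluster_id == "fx_exception"],
    "low_unique")
  # removing the partner cluster from the candidate set kills the exception
  no_partner <- fx$clusters[fx$clusters$cluster_id != "fx_single_partner", ]
  flt_np <- filter_cascade(no_partner, fx$annotation, pipeline_config(),
    fx$genome)
  v2 <- tidy(flt_np)
  expect_identical(v2$failed_filters[v2$cluster_id == "fx_exception"],
    "low_unique")
})
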