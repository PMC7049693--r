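# Shared fixtures and independent brute-force oracles. The oracles never
# reuse the package's interval machinery: they loop over bases or pairs.

rand_interval_tbl <- function(n, chrom_len = 1000, chroms = "c1",
                              strands = c("+", "-")) {
  start <- sample.int(chrom_len - 60, n, replace = TRUE) - 1L
  len <- sample(10:50, n, replace = TRUE)
  tibble::tibble(
    chrom = sample(chroms, n, replace = TRUE),
    start = start,
    end = as.integer(pmin(start + len, chrom_len)),
    strand = sample(strands, n, replace = TRUE)
  )
}

# per-base set-intersection oracle for overlap_length
oracle_overlap <- function(a, b, same_strand_only = TRUE) {
  if (a$chrom != b$chrom) return(0L)
  if (same_strand_only && a$strand != b$strand) return(0L)
  length(intersect(seq(a$start, a$end - 1L), seq(b$start, b$end - 1L)))
}

# random reads with tag structure (several reads can share an interval)
rand_reads <- function(n_tags, max_reads_per_tag = 30, chrom_len = 400,
                       n_datasets = 2) {
  tags <- rand_interval_tbl(n_tags, chrom_len)
  rows <- lapply(seq_len(n_tags), function(i) {
    k <- sample.int(max_reads_per_tag, 1)
    tibble::tibble(
      chrom = tags$chrom[i], start = tags$start[i], end = tags$end[i],
      strand = tags$strand[i],
      read_id = sprintf("t%d_r%d", i, seq_len(k)),
      dataset_id = sample(sprintf("d%d", seq_len(n_datasets)), k,
        replace = TRUE),
      n_genomic_hits = sample(c(1L, 1L, 1L, 2L), k, replace = TRUE)
    )
  })
  dplyr::bind_rows(rows)
}

# brute-force per-base coverage
oracle_coverage <- function(reads, width) {
  cov <- numeric(width)
  for (i in seq_len(nrow(reads))) {
    for (p in seq(reads$start[i] + 1L, reads$end[i])) {
      if (p <= width) cov[p] <- cov[p] + 1
    }
  }
  cov
}

# brute-force cluster caller: tag filter, per-base coverage components,
# cluster read-count threshold
oracle_clusters <- function(reads, config) {
  key <- paste(reads$chrom, reads$start, reads$end, reads$strand)
  tab <- table(key)
  keep <- key %in% names(tab)[tab >= config$tag_filter]
  reads <- reads[keep, ]
  out <- list()
  for (ch in unique(reads$chrom)) {
    for (std in c("+", "-")) {
      r <- reads[reads$chrom == ch & reads$strand == std, ]
      if (!nrow(r)) next
      width <- max(r$end)
      covered <- rep(FALSE, width)
      for (i in seq_len(nrow(r))) {
        covered[seq(r$start[i] + 1L, r$end[i])] <- TRUE
      }
      rle_cov <- rle(covered)
      ends <- cumsum(rle_cov$lengths)
      starts <- ends - rle_cov$lengths + 1L
      for (j in which(rle_cov$values)) {
        lo <- starts[j] - 1L  # back to 0-based
        hi <- ends[j]
        inside <- r$start >= lo & r$end <= hi
        n_reads <- sum(inside)
        if (n_reads >= config$min_cluster_reads) {
          out[[length(out) + 1]] <- tibble::tibble(
            chrom = ch, start = lo, end = hi, strand = std,
            read_count = n_reads,
            unique_read_count = sum(inside & r$n_genomic_hits == 1L)
          )
        }
      }
    }
  }
  if (!length(out)) {
    return(tibble::tibble(chrom = character(0), start = integer(0),
      end = integer(0), strand = character(0), read_count = integer(0),
      unique_read_count = integer(0)))
  }
  dplyr::arrange(dplyr::bind_rows(out), chrom, start, end, strand)
}

# quadratic all-pairs overlap join oracle
oracle_annotation_join <- function(clusters, annotation) {
  rows <- list()
  for (i in seq_len(nrow(clusters))) {
    for (j in seq_len(nrow(annotation))) {
      if (clusters$chrom[i] != annotation$chrom[j]) next
      if (clusters$strand[i] != annotation$strand[j]) next
      ov <- min(clusters$end[i], annotation$end[j]) -
        max(clusters$start[i], annotation$start[j])
      if (ov > 0) {
        rows[[length(rows) + 1]] <- tibble::tibble(
          cluster_id = clusters$cluster_id[i],
          gene_id = annotation$gene_id[j], overlap_bp = as.integer(ov))
      }
    }
  }
  dplyr::bind_rows(rows)
}

# per-read assignment oracle: smallest containing feature, else max overlap
oracle_assign <- function(reads, features) {
  vapply(seq_len(nrow(reads)), function(i) {
    best <- NA_character_
    best_w <- Inf
    for (j in seq_len(nrow(features))) {
      if (reads$chrom[i] != features$chrom[j]) next
      if (reads$strand[i] != features$strand[j]) next
      if (reads$start[i] >= features$start[j] &&
          reads$end[i] <= features$end[j]) {
        w <- features$end[j] - features$start[j]
        if (w < best_w || (w == best_w && features$feature_id[j] < best)) {
          best <- features$feature_id[j]; best_w <- w
        }
      }
    }
    if (!is.na(best)) return(best)
    best_ov <- 0L
    for (j in seq_len(nrow(features))) {
      if (reads$chrom[i] != features$chrom[j]) next
      if (reads$strand[i] != features$strand[j]) next
      ov <- min(reads$end[i], features$end[j]) -
        max(reads$start[i], features$start[j])
      w <- features$end[j] - features$start[j]
      better <- ov > best_ov ||
        (ov == best_ov && ov > 0 && w < best_w) ||
        (ov == best_ov && ov > 0 && w == best_w && features$feature_id[j] < best)
      if (better) { best <- features$feature_id[j]; best_ov <- ov; best_w <- w }
    }
    best
  }, character(1))
}

# exhaustive guide-window oracle: longest window of the C/D internal region
# (>=10 nt, ending within 20 nt of box D) whose reverse complement occurs in
# the target
oracle_guide <- function(seq, box_c, box_d, target, max_len = 25) {
  best <- NULL
  region_start <- box_c + 7
  for (e in seq(box_d - 1, max(region_start + 9, box_d - 21))) {
    for (len in seq(min(max_len, e - region_start + 1), 10)) {
      if (len < 10) break
      w <- substr(seq, e - len + 1, e)
      rc <- reverse_complement(w)
      if (grepl(rc, target, fixed = TRUE)) {
        if (is.null(best) || len > best$len) best <- list(len = len, end = e)
      }
    }
  }
  best
}

# dinucleotide-preserving-ish shuffle (simple base shuffle is adequate for
# the specificity nulls used here)
shuffle_seq <- function(seq) {
  paste(sample(strsplit(seq, "", fixed = TRUE)[[1]]), collapse = "")
}

random_dna_str <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# dress plain intervals up as a cluster table with permissive tallies
mk_clusters <- function(ivls, ids = sprintf("cl_%d", seq_len(nrow(ivls)))) {
  dplyr::mutate(ivls, cluster_id = ids, read_count = 200L,
    unique_read_count = 200L,
    datasets_detected = list(c("d1", "d2")), sequence = NA_character_)
}
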