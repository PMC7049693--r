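#' Design of a synthetic discovery experiment
#'
#' Describes how many loci of each kind are planted on the toy genome. The
#' annotated complement is split into tRNA genes (40%), intronic C/D and
#' H/ACA snoRNA genes (12.5% each), snRNA-like genes (remainder),
#' protein-coding host genes (20%) and one 45S rDNA unit per chromosome.
#' Novel (withheld-from-annotation) loci are planted in the genomic context
#' their family occupies: snoRNAs intronic, tRNA-family loci intergenic,
#' ETS/ITS loci inside the rDNA spacers as byte-identical multi-copy loci.
#'
#' @param n_novel_per_class Novel loci planted per biotype class (5).
#' @param n_annotated Total annotated gene loci (200).
#' @param genome_size Total genome size in bases (1e6).
#' @param n_chrom Number of chromosomes (2).
#' @param imperfect_frac Fraction of planted novel tRNA-like loci built
#'   with the long-anticodon-stem anomaly (0.2).
#' @param n_trna_refs Distinct tRNA reference sequences (20).
#' @param n_decoy_refs Unrelated decoy references (15).
#' @return A list of class `snc_design`.
#' @export
sim_design <- function(n_novel_per_class = 5, n_annotated = 200,
                       genome_size = 1e6, n_chrom = 2,
                       imperfect_frac = 0.2, n_trna_refs = 20,
                       n_decoy_refs = 15) {
  stopifnot(n_novel_per_class >= 1, n_annotated >= 20, n_chrom >= 1)
  n_host <- round(0.2 * n_annotated)
  n_trna <- round(0.4 * n_annotated)
  n_cd <- round(0.125 * n_annotated)
  n_haca <- round(0.125 * n_annotated)
  n_rrna <- n_chrom
  n_snrna <- n_annotated - n_host - n_trna - n_cd - n_haca - n_rrna
  if (n_snrna < 0 || 2 * n_host < n_cd + n_haca + 2 * n_novel_per_class) {
    rlang::abort("design infeasible: not enough host introns for the snoRNAs",
      class = "snc_design_error")
  }
  structure(list(
    n_novel_per_class = n_novel_per_class, n_annotated = n_annotated,
    genome_size = genome_size, n_chrom = n_chrom,
    imperfect_frac = imperfect_frac, n_trna_refs = n_trna_refs,
    n_decoy_refs = n_decoy_refs,
    n_host = n_host, n_trna = n_trna, n_cd = n_cd, n_haca = n_haca,
    n_rrna = n_rrna, n_snrna = n_snrna
  ), class = "snc_design")
}

# Internal constructors for layout "blocks": self-contained genomic
# segments carrying planted sequences, annotation entries and truth rows at
# block-relative offsets.
new_block <- function(len, strand, seqs = NULL, ann = NULL, truth = NULL) {
  list(len = len, strand = strand, seqs = seqs, ann = ann, truth = truth)
}

truth_row <- function(offset, len, locus_id, biotype, annotated, base_tpm,
                      host_gene_id = NA_character_, n_copies = 1L,
                      copy = 1L) {
  tibble::tibble(offset = offset, len = len, locus_id = locus_id,
    true_biotype = biotype, annotated = annotated, base_tpm = base_tpm,
    host_gene_id = host_gene_id, n_copies = n_copies, copy = copy)
}

ann_row <- function(offset, len, gene_id, biotype, feature) {
  tibble::tibble(offset = offset, len = len, gene_id = gene_id,
    biotype = biotype, feature = feature)
}

#' Build a synthetic genome with planted ncRNA loci
#'
#' Generates a random-background genome and plants: annotated tRNA, snoRNA
#' (intronic in protein-coding hosts), snRNA-like and 45S rDNA genes; and
#' novel loci of the eight biotype classes that are withheld from the
#' emitted annotation (ground-truth novel). Planted family sequences
#' satisfy their internal detector by construction; a configurable fraction
#' of novel tRNA-like loci carries the 7-bp anticodon stem anomaly. The
#' annotation includes host genes with exons and introns, rDNA spacer
#' features (`rDNA_5ETS`, `rDNA_ITS1`), and repeat entries (Alu elements
#' around a share of the novel H/ACA loci, tRNA repeats around a share of
#' the novel fragments, plus unexpressed decoy repeats). ETS/ITS loci are
#' planted byte-identically in every rDNA unit, so their reads multimap.
#'
#' @param config An [pipeline_config()] object.
#' @param design An [sim_design()] object.
#' @param seed Optional RNG seed.
#' @return A list of class `snc_sim`: `genome` (`DNAStringSet`), `loci`
#'   (truth tibble, one row per genomic copy), `annotation`, `refs`,
#'   `targets` (named character vector), `design`.
#' @export
build_genome <- function(config = pipeline_config(), design = sim_design(),
                         seed = NULL) {
  with_rng_seed(seed, {
    targets <- c(rRNA_18S = rand_dna(600))

    refs <- dplyr::bind_rows(
      tibble::tibble(
        id = sprintf("ref_tRNA_%02d", seq_len(design$n_trna_refs)),
        biotype = "tRNA",
        seq = vapply(seq_len(design$n_trna_refs), function(i) make_trna_seq(),
          character(1))
      ),
      tibble::tibble(
        id = sprintf("ref_snoRNA_CD_%02d", 1:5), biotype = "snoRNA_CD",
        seq = vapply(1:5, function(i)
          as.character(make_cd_seq(targets[[1]], names(targets)[1])),
          character(1))
      ),
      tibble::tibble(
        id = sprintf("ref_snoRNA_HACA_%02d", 1:5), biotype = "snoRNA_HACA",
        seq = vapply(1:5, function(i) make_haca_seq(), character(1))
      ),
      tibble::tibble(
        id = sprintf("ref_decoy_%02d", seq_len(design$n_decoy_refs)),
        biotype = "lncRNA",
        seq = vapply(seq_len(design$n_decoy_refs), function(i) rand_dna(80),
          character(1))
      )
    )
    trna_ref_seqs <- refs$seq[refs$biotype == "tRNA"]

    blocks <- list()
    add <- function(b) blocks[[length(blocks) + 1]] <<- b
    rand_strand <- function() sample(c("+", "-"), 1)
    tpm_novel <- function() stats::runif(1, 8, 15)

    # --- annotated tRNA genes: near-copies of the references ------------
    for (i in seq_len(design$n_trna)) {
      s <- mutate_seq(sample(trna_ref_seqs, 1), 0.02)
      id <- sprintf("gene_tRNA_%03d", i)
      add(new_block(nchar(s), rand_strand(),
        seqs = tibble::tibble(offset = 0L, seq = s),
        ann = ann_row(0L, nchar(s), id, "tRNA", "gene"),
        truth = truth_row(0L, nchar(s), id, "tRNA", TRUE,
          stats::runif(1, 30, 80))))
    }

    # --- annotated snRNA-like genes (random sequence) -------------------
    for (i in seq_len(design$n_snrna)) {
      id <- sprintf("gene_snRNA_%03d", i)
      add(new_block(120L, rand_strand(),
        ann = ann_row(0L, 120L, id, "snRNA", "gene"),
        truth = truth_row(0L, 120L, id, "snRNA", TRUE,
          stats::runif(1, 8, 20))))
    }

    # --- intronic snoRNA payloads --------------------------------------
    payload <- list()
    cd_refs <- refs$seq[refs$biotype == "snoRNA_CD"]
    haca_refs <- refs$seq[refs$biotype == "snoRNA_HACA"]
    for (i in seq_len(design$n_cd)) {
      payload[[length(payload) + 1]] <- list(
        locus_id = sprintf("gene_snoRNA_CD_%03d", i), biotype = "snoRNA_CD",
        annotated = TRUE, seq = mutate_seq(sample(cd_refs, 1), 0.03),
        alu = FALSE, tpm = stats::runif(1, 8, 20))
    }
    for (i in seq_len(design$n_haca)) {
      payload[[length(payload) + 1]] <- list(
        locus_id = sprintf("gene_snoRNA_HACA_%03d", i), biotype = "snoRNA_HACA",
        annotated = TRUE, seq = mutate_seq(sample(haca_refs, 1), 0.03),
        alu = FALSE, tpm = stats::runif(1, 8, 20))
    }
    for (i in seq_len(design$n_novel_per_class)) {
      payload[[length(payload) + 1]] <- list(
        locus_id = sprintf("novel_snoRNA_CD_%02d", i), biotype = "snoRNA_CD",
        annotated = FALSE,
        seq = as.character(make_cd_seq(targets[[1]], names(targets)[1])),
        alu = FALSE, tpm = tpm_novel())
      payload[[length(payload) + 1]] <- list(
        locus_id = sprintf("novel_snoRNA_HACA_%02d", i),
        biotype = "snoRNA_HACA", annotated = FALSE, seq = make_haca_seq(),
        alu = i <= ceiling(0.4 * design$n_novel_per_class),
        tpm = tpm_novel())
    }
    payload <- payload[sample(length(payload))]

    # --- protein-coding hosts with up to two intronic payloads ----------
    exon_len <- c(200L, 150L, 200L)
    intron_len <- c(700L, 700L)
    host_len <- sum(exon_len) + sum(intron_len)
    pay_i <- 0
    for (i in seq_len(design$n_host)) {
      id <- sprintf("gene_host_%03d", i)
      strand <- rand_strand()
      offs <- cumsum(c(0L, exon_len[1], intron_len[1], exon_len[2],
        intron_len[2]))
      ann <- dplyr::bind_rows(
        ann_row(0L, host_len, id, "protein_coding", "gene"),
        ann_row(offs[1], exon_len[1], id, "protein_coding", "exon"),
        ann_row(offs[2], intron_len[1], id, "protein_coding", "intron"),
        ann_row(offs[3], exon_len[2], id, "protein_coding", "exon"),
        ann_row(offs[4], intron_len[2], id, "protein_coding", "intron"),
        ann_row(offs[5], exon_len[3], id, "protein_coding", "exon")
      )
      truth <- truth_row(0L, host_len, id, "protein_coding", TRUE,
        stats::runif(1, 8, 15))
      seqs <- NULL
      for (slot in 1:2) {
        if (pay_i >= length(payload)) break
        pay_i <- pay_i + 1
        p <- payload[[pay_i]]
        int_off <- offs[c(2, 4)][slot]
        int_len <- intron_len[slot]
        o <- int_off + as.integer((int_len - nchar(p$seq)) / 2)
        seqs <- dplyr::bind_rows(seqs,
          tibble::tibble(offset = o, seq = p$seq))
        truth <- dplyr::bind_rows(truth,
          truth_row(o, nchar(p$seq), p$locus_id, p$biotype, p$annotated,
            p$tpm, host_gene_id = id))
        if (p$annotated) {
          ann <- dplyr::bind_rows(ann,
            ann_row(o, nchar(p$seq), p$locus_id, p$biotype, "gene"))
        }
        if (isTRUE(p$alu)) {
          ann <- dplyr::bind_rows(ann,
            ann_row(o - 40L, nchar(p$seq) + 80L, sprintf("%s_alu", p$locus_id),
              "repeat_Alu", "repeat"))
        }
      }
      add(new_block(host_len, strand, seqs = seqs, ann = ann, truth = truth))
    }
    if (pay_i < length(payload)) {
      rlang::abort("design infeasible: snoRNA payloads exceed host introns",
        class = "snc_design_error")
    }

    # --- rDNA units with multi-copy ETS/ITS loci ------------------------
    n_units <- design$n_rrna
    nn <- design$n_novel_per_class
    ets_seqs <- lapply(seq_len(nn), function(i) make_ets_seq(len = 110))
    its_seqs <- lapply(seq_len(nn), function(i) make_its_seq(len = 100))
    ets_tpm <- stats::runif(nn, 8, 15) * n_units
    its_tpm <- stats::runif(nn, 8, 15) * n_units
    spacer_len <- max(1500L, 120L + nn * 280L)
    unit_len <- 2L * spacer_len + 1000L
    for (u in seq_len(n_units)) {
      id <- sprintf("gene_rRNA_45S_%d", u)
      ann <- dplyr::bind_rows(
        ann_row(0L, unit_len, id, "rRNA_45S", "gene"),
        ann_row(0L, spacer_len, id, "rRNA_45S", "rDNA_5ETS"),
        ann_row(spacer_len + 500L, spacer_len, id, "rRNA_45S", "rDNA_ITS1")
      )
      seqs <- NULL
      truth <- NULL
      for (j in seq_len(nn)) {
        oe <- 60L + (j - 1L) * 280L
        oi <- spacer_len + 500L + 60L + (j - 1L) * 280L
        seqs <- dplyr::bind_rows(seqs,
          tibble::tibble(offset = c(oe, oi),
            seq = c(ets_seqs[[j]], its_seqs[[j]])))
        truth <- dplyr::bind_rows(truth,
          truth_row(oe, nchar(ets_seqs[[j]]), sprintf("novel_ETS_%02d", j),
            "ETS_RNA", FALSE, ets_tpm[j], n_copies = n_units, copy = u),
          truth_row(oi, nchar(its_seqs[[j]]), sprintf("novel_ITS_%02d", j),
            "ITS_RNA", FALSE, its_tpm[j], n_copies = n_units, copy = u))
      }
      add(new_block(unit_len, "+", seqs = seqs, ann = ann, truth = truth))
    }

    # --- novel intergenic loci ------------------------------------------
    n_imperfect <- round(design$imperfect_frac * nn)
    for (i in seq_len(nn)) {
      s <- if (i <= n_imperfect) {
        make_trna_variant(sample(trna_ref_seqs, 1))
      } else {
        mutate_seq(sample(trna_ref_seqs, 1), 0.06)
      }
      add(new_block(nchar(s), rand_strand(),
        seqs = tibble::tibble(offset = 0L, seq = s),
        truth = truth_row(0L, nchar(s), sprintf("novel_tRNA_like_%02d", i),
          "tRNA_like", FALSE, tpm_novel())))
    }
    for (i in seq_len(nn)) {
      core <- sample(trna_ref_seqs, 1)
      s <- paste0(rand_dna(10), core, rand_dna(10))
      add(new_block(nchar(s), rand_strand(),
        seqs = tibble::tibble(offset = 0L, seq = s),
        truth = truth_row(0L, nchar(s), sprintf("novel_pre_tRNA_%02d", i),
          "pre_tRNA", FALSE, tpm_novel())))
    }
    trf_cut <- function(ref_len) {
      kind <- sample(c("five", "three", "internal", "near"), 1)
      switch(kind,
        five = c(1L, as.integer(round(ref_len / 2))),
        three = c(as.integer(round(ref_len / 2)) + 1L, ref_len),
        internal = c(18L, 52L),
        near = c(6L, ref_len - 4L)
      )
    }
    for (i in seq_len(nn)) {
      ref <- sample(trna_ref_seqs, 1)
      cut <- trf_cut(nchar(ref))
      s <- substr(ref, cut[1], cut[2])
      ann <- if (i <= ceiling(0.6 * nn)) {
        ann_row(-15L, nchar(s) + 30L, sprintf("novel_tRF_%02d_rep", i),
          "repeat_tRNA", "repeat")
      } else NULL
      add(new_block(nchar(s), rand_strand(),
        seqs = tibble::tibble(offset = 0L, seq = s),
        ann = ann,
        truth = truth_row(0L, nchar(s), sprintf("novel_tRF_%02d", i),
          "tRNA_fragment", FALSE, tpm_novel())))
    }
    for (i in seq_len(nn)) {
      len <- sample(28:48, 1)
      add(new_block(len, rand_strand(),
        truth = truth_row(0L, len, sprintf("novel_unknown_%02d", i),
          "unknown", FALSE, tpm_novel())))
    }

    # --- unexpressed decoy repeats --------------------------------------
    for (i in 1:10) {
      add(new_block(300L, rand_strand(),
        ann = ann_row(0L, 300L, sprintf("decoy_Alu_%02d", i),
          "repeat_Alu", "repeat")))
    }

    # --- layout ----------------------------------------------------------
    chrom_len <- as.integer(design$genome_size / design$n_chrom)
    chroms <- sprintf("chr%d", seq_len(design$n_chrom))
    # rDNA units (the last n_units + novel/decoy blocks were appended after
    # hosts); shuffle everything except forcing one rDNA unit per chromosome
    is_rdna <- vapply(blocks, function(b)
      !is.null(b$ann) && any(b$ann$biotype == "rRNA_45S"), logical(1))
    rdna_blocks <- blocks[is_rdna]
    other_blocks <- blocks[!is_rdna]
    other_blocks <- other_blocks[sample(length(other_blocks))]
    assignment <- rep(seq_len(design$n_chrom),
      length.out = length(other_blocks))

    cursors <- stats::setNames(rep(2000L, design$n_chrom), chroms)
    ann_out <- list(); truth_out <- list(); plant <- list()
    place <- function(b, chrom) {
      start <- cursors[[chrom]] + sample(150:800, 1)
      if (start + b$len > chrom_len - 2000L) {
        rlang::abort("design infeasible on requested genome size",
          class = "snc_design_error")
      }
      cursors[[chrom]] <<- start + b$len
      if (!is.null(b$seqs)) {
        s <- b$seqs
        s$chrom <- chrom
        s$strand <- b$strand
        s$start <- start + s$offset
        plant[[length(plant) + 1]] <<- s
      }
      if (!is.null(b$ann)) {
        a <- b$ann
        a$chrom <- chrom
        a$strand <- b$strand
        a$start <- start + a$offset
        a$end <- a$start + a$len
        ann_out[[length(ann_out) + 1]] <<- a
      }
      if (!is.null(b$truth)) {
        tr <- b$truth
        tr$chrom <- chrom
        tr$strand <- b$strand
        tr$start <- start + tr$offset
        tr$end <- tr$start + tr$len
        truth_out[[length(truth_out) + 1]] <<- tr
      }
    }
    for (u in seq_along(rdna_blocks)) {
      place(rdna_blocks[[u]], chroms[((u - 1) %% design$n_chrom) + 1])
    }
    for (i in seq_along(other_blocks)) {
      place(other_blocks[[i]], chroms[assignment[i]])
    }

    # --- genome assembly -------------------------------------------------
    genome <- Biostrings::DNAStringSet(stats::setNames(
      vapply(chroms, function(ch) rand_dna(chrom_len), character(1)), chroms))
    plant <- dplyr::bind_rows(plant)
    for (ch in chroms) {
      p <- plant[plant$chrom == ch, ]
      if (!nrow(p)) next
      vals <- ifelse(p$strand == "-",
        vapply(p$seq, reverse_complement, character(1)), p$seq)
      genome[[ch]] <- Biostrings::replaceAt(genome[[ch]],
        IRanges::IRanges(p$start + 1L, p$start + nchar(p$seq)),
        Biostrings::DNAStringSet(vals))
    }

    annotation <- dplyr::bind_rows(ann_out) |>
      dplyr::select("chrom", "start", "end", "strand", "gene_id", "biotype",
        "feature") |>
      dplyr::arrange(.data$chrom, .data$start, .data$end, .data$feature,
        .data$gene_id)
    loci <- dplyr::bind_rows(truth_out) |>
      dplyr::select("locus_id", "copy", "n_copies", "chrom", "start", "end",
        "strand", "true_biotype", "annotated", "host_gene_id", "base_tpm")
    loci$sequence <- fetch_sequence(genome, loci)
    loci <- dplyr::arrange(loci, .data$locus_id, .data$copy)

    structure(list(genome = genome, loci = loci, annotation = annotation,
      refs = refs, targets = targets, design = design),
      class = "snc_sim")
  })
}

#' @export
print.snc_sim <- function(x, ...) {
  cat(sprintf(
    "<snc_sim> %d chromosome(s), %d planted loci (%d novel), %d annotation rows\n",
    length(x$genome), length(unique(x$loci$locus_id)),
    length(unique(x$loci$locus_id[!x$loci$annotated])), nrow(x$annotation)))
  invisible(x)
}

#' Simulate full-length reads over planted loci
#'
#' Emulates non-fragmented, low-structure-bias coverage: each read spans
#' its source locus with at most 2 nt of independent start/end jitter
#' (jitter 0 with probability 0.9, +-1 with 0.04 each, +-2 with 0.01
#' each — full-length template switching defines ends sharply). Per locus
#' and dataset the read count is Poisson with mean
#' `TPM x depth`, where the dataset-level TPM multiplies the locus base
#' abundance by a lognormal dataset factor; intron-embedded loci share
#' their host gene's factor (host-dependent expression), intergenic loci
#' draw their own. Multi-copy loci emit each read at one uniformly chosen
#' copy with `n_genomic_hits` set to the copy number. Protein-coding hosts
#' emit reads per exon. Output is deterministic for a fixed seed.
#'
#' A locus tibble may carry a `tpm_by_dataset` list-column of fixed
#' per-dataset abundances, which then bypasses the stochastic factors.
#'
#' @param genome Named `DNAStringSet`.
#' @param loci Truth tibble from [build_genome()].
#' @param annotation Annotation tibble (needed for host exons; optional).
#' @param n_datasets Number of datasets (>= 2; the multi-dataset filter
#'   needs replicates).
#' @param depth Reads per TPM unit (30).
#' @param seed Optional RNG seed.
#' @param dataset_ids Dataset labels.
#' @param dataset_sd,host_sd Lognormal sd of the dataset factors for
#'   intergenic loci and hosts.
#' @param coupled_sd Residual lognormal sd of intronic loci around their
#'   host factor.
#' @param jitter_probs Probabilities of end jitters -2..+2.
#' @return A read tibble (`chrom`, `start`, `end`, `strand`, `read_id`,
#'   `dataset_id`, `n_genomic_hits`) with attribute `expression` (tibble of
#'   realised per-dataset TPM per locus).
#' @export
simulate_reads <- function(genome, loci, annotation = NULL, n_datasets = 3,
                           depth = 30, seed = NULL,
                           dataset_ids = sprintf("ds%d", seq_len(n_datasets)),
                           dataset_sd = 0.25, host_sd = 0.5,
                           coupled_sd = 0.15,
                           jitter_probs = c(0.01, 0.04, 0.9, 0.04, 0.01)) {
  stopifnot(n_datasets >= 2, length(dataset_ids) == n_datasets)
  with_rng_seed(seed, {
    chrom_lens <- stats::setNames(Biostrings::width(genome), names(genome))
    groups <- split(loci, loci$locus_id)
    group_ids <- sort(names(groups))

    host_ids <- sort(unique(c(
      loci$locus_id[loci$true_biotype == "protein_coding"],
      stats::na.omit(loci$host_gene_id)
    )))
    host_factor <- matrix(
      exp(stats::rnorm(length(host_ids) * n_datasets,
        -host_sd^2 / 2, host_sd)),
      nrow = length(host_ids), ncol = n_datasets,
      dimnames = list(host_ids, dataset_ids))

    jitter_vals <- c(-2L, -1L, 0L, 1L, 2L)

    expr_rows <- list()
    read_rows <- list()
    for (gid in group_ids) {
      g <- groups[[gid]]
      is_host <- g$true_biotype[1] == "protein_coding"
      hkey <- if (is_host) gid else g$host_gene_id[1]
      fixed <- if ("tpm_by_dataset" %in% names(g)) g$tpm_by_dataset[[1]] else NULL
      for (d in seq_len(n_datasets)) {
        tpm <- if (!is.null(fixed)) {
          fixed[[d]]
        } else if (!is.na(hkey) && hkey %in% host_ids) {
          g$base_tpm[1] * host_factor[hkey, d] *
            (if (is_host) 1 else exp(stats::rnorm(1, -coupled_sd^2 / 2, coupled_sd)))
        } else {
          g$base_tpm[1] * exp(stats::rnorm(1, -dataset_sd^2 / 2, dataset_sd))
        }
        expr_rows[[length(expr_rows) + 1]] <- tibble::tibble(
          locus_id = gid, dataset_id = dataset_ids[d], tpm = tpm)

        spans <- if (is_host && !is.null(annotation)) {
          annotation[annotation$gene_id == gid &
            annotation$feature == "exon", c("chrom", "start", "end", "strand")]
        } else {
          g[, c("chrom", "start", "end", "strand")]
        }
        if (is_host && nrow(spans) > 1) {
          # hosts: Poisson reads per exon
          n_per <- stats::rpois(nrow(spans), tpm * depth)
          idx <- rep(seq_len(nrow(spans)), n_per)
        } else {
          n_tot <- stats::rpois(1, tpm * depth)
          idx <- if (nrow(spans) > 1)
            sample.int(nrow(spans), n_tot, replace = TRUE)
          else rep(1L, n_tot)
        }
        n <- length(idx)
        if (!n) next
        js <- sample(jitter_vals, n, replace = TRUE, prob = jitter_probs)
        je <- sample(jitter_vals, n, replace = TRUE, prob = jitter_probs)
        st <- pmax(0L, spans$start[idx] + js)
        en <- pmin(chrom_lens[spans$chrom[idx]], spans$end[idx] + je)
        bad <- st >= en
        if (any(bad)) { st[bad] <- spans$start[idx][bad]; en[bad] <- spans$end[idx][bad] }
        read_rows[[length(read_rows) + 1]] <- tibble::tibble(
          chrom = spans$chrom[idx], start = st, end = as.integer(en),
          strand = spans$strand[idx],
          read_id = sprintf("%s_%s_r%05d", dataset_ids[d], gid, seq_len(n)),
          dataset_id = dataset_ids[d],
          n_genomic_hits = as.integer(g$n_copies[1])
        )
      }
    }
    reads <- dplyr::bind_rows(read_rows) |>
      dplyr::arrange(.data$dataset_id, .data$chrom, .data$start, .data$end,
        .data$strand, .data$read_id)
    attr(reads, "expression") <- dplyr::bind_rows(expr_rows)
    reads
  })
}

#' Simulate a protein-depletion contrast
#'
#' Produces paired control and knockdown read sets. Knockdown datasets
#' scale the abundance of every H/ACA snoRNA locus (annotated and novel) by
#' `effect`, leaving C/D snoRNAs, tRNAs and all other biotypes untouched —
#' the expected signature of depleting the H/ACA core protein dyskerin.
#' Replicate-level noise is small (`dataset_sd`), reflecting paired
#' replicates of one cell line rather than independent tissues.
#'
#' @param genome,loci,annotation As for [simulate_reads()].
#' @param effect Fold-change applied to H/ACA loci in the knockdown
#'   (0 < effect <= 1; 1 = null experiment).
#' @param n_replicates Replicates per arm (2).
#' @param depth Reads per TPM unit (30).
#' @param seed Optional RNG seed.
#' @param dataset_sd Lognormal replicate noise (0.1).
#' @return A list with read tibbles `control` (datasets `ctrl_*`) and
#'   `knockdown` (datasets `kd_*`).
#' @export
simulate_depletion <- function(genome, loci, annotation = NULL, effect = 0.5,
                               n_replicates = 2, depth = 30, seed = NULL,
                               dataset_sd = 0.1) {
  stopifnot(effect > 0, effect <= 1)
  with_rng_seed(seed, {
    kd_loci <- loci
    scale <- kd_loci$true_biotype == "snoRNA_HACA"
    kd_loci$base_tpm[scale] <- kd_loci$base_tpm[scale] * effect
    control <- simulate_reads(genome, loci, annotation,
      n_datasets = n_replicates, depth = depth,
      dataset_ids = sprintf("ctrl_%d", seq_len(n_replicates)),
      dataset_sd = dataset_sd, host_sd = dataset_sd, coupled_sd = dataset_sd)
    knockdown <- simulate_reads(genome, kd_loci, annotation,
      n_datasets = n_replicates, depth = depth,
      dataset_ids = sprintf("kd_%d", seq_len(n_replicates)),
      dataset_sd = dataset_sd, host_sd = dataset_sd, coupled_sd = dataset_sd)
    list(control = control, knockdown = knockdown)
  })
}

#' Emit a conservation track and ortholog sequences for planted loci
#'
#' The bedGraph-style track draws per-base scores around a biotype-specific
#' mean (tRNA-family loci high, snoRNA/spacer/unknown loci low), truncated
#' to `[0, 1]`; bases outside planted loci are absent from the track.
#' Ortholog sequences are the planted-locus regions extended by the
#' ortholog flank and substitution-mutated at rate `1 - identity` for each
#' species; species beyond a biotype's conservation range lack the region
#' entirely (no equivalent).
#'
#' @param genome Named `DNAStringSet`.
#' @param loci Truth tibble.
#' @param profile Named per-biotype conservation means in `[0,1]`
#'   (defaults: tRNA-family 0.7-0.9, snoRNA/spacers/unknown 0.15-0.2).
#' @param species Tibble `species`, `identity` (target fraction), `rank`
#'   (evolutionary distance order); defaults to six species at identities
#'   0.98-0.75.
#' @param flank Context added on both sides of each locus (300 nt).
#' @param score_sd Per-base score spread (0.05).
#' @param seed Optional RNG seed.
#' @return A list: `track` tibble (`chrom`, `start`, `end`, `score`) and
#'   `orthologs` tibble (`species`, `locus_id`, `seq`; `NA` = no
#'   equivalent).
#' @export
emit_conservation_and_orthologs <- function(genome, loci, profile = NULL,
                                            species = NULL, flank = 300,
                                            score_sd = 0.05, seed = NULL) {
  profile <- profile %||% c(
    tRNA = 0.9, tRNA_like = 0.9, pre_tRNA = 0.85, tRNA_fragment = 0.7,
    snoRNA_CD = 0.2, snoRNA_HACA = 0.2, snRNA = 0.5, protein_coding = 0.4,
    rRNA_45S = 0.3, ITS_RNA = 0.15, ETS_RNA = 0.15, unknown = 0.2
  )
  stopifnot(all(profile >= 0 & profile <= 1))
  species <- species %||% tibble::tibble(
    species = sprintf("species_%s", LETTERS[1:6]),
    identity = c(0.98, 0.95, 0.92, 0.88, 0.82, 0.75),
    rank = 1:6
  )
  with_rng_seed(seed, {
    chrom_lens <- stats::setNames(Biostrings::width(genome), names(genome))
    track <- dplyr::bind_rows(lapply(seq_len(nrow(loci)), function(i) {
      len <- loci$end[i] - loci$start[i]
      mu <- profile[[loci$true_biotype[i]]] %||% 0.2
      tibble::tibble(
        chrom = loci$chrom[i],
        start = loci$start[i] + seq_len(len) - 1L,
        end = loci$start[i] + seq_len(len),
        score = round(pmin(1, pmax(0, stats::rnorm(len, mu, score_sd))), 4)
      )
    })) |>
      dplyr::distinct(.data$chrom, .data$start, .keep_all = TRUE) |>
      dplyr::arrange(.data$chrom, .data$start)

    # conservation range by biotype: how far down the species ranking an
    # equivalent region exists
    reach <- function(biotype) {
      if (grepl("tRNA", biotype)) max(species$rank)
      else if (biotype %in% c("snRNA", "protein_coding")) 4L
      else 2L
    }
    first_copies <- loci[loci$copy == 1, ]
    orth <- list()
    for (s in seq_len(nrow(species))) {
      for (i in seq_len(nrow(first_copies))) {
        row <- first_copies[i, ]
        seq <- if (species$rank[s] <= reach(row$true_biotype)) {
          ivl <- genomic_interval(row$chrom,
            max(0L, row$start - flank),
            min(chrom_lens[[row$chrom]], row$end + flank), row$strand)
          mutate_seq(fetch_sequence(genome, ivl), 1 - species$identity[s])
        } else NA_character_
        orth[[length(orth) + 1]] <- tibble::tibble(
          species = species$species[s], locus_id = row$locus_id, seq = seq)
      }
    }
    list(track = track, orthologs = dplyr::bind_rows(orth))
  })
}
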