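---
title: "Annotation-independent discovery and classification of small non-coding RNAs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Annotation-independent discovery and classification of small non-coding RNAs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Standard RNA-seq pipelines assign reads to annotated genes, so transcripts
missing from the annotation are invisible no matter how strongly they are
expressed. Structured small non-coding RNAs (tRNAs, snoRNAs, rRNA-spacer
products) are particularly affected: retroviral reverse transcriptases
stall on their structures, and gene predictors miss family members with
non-canonical features. Sequencing libraries built with a thermostable
group II intron reverse transcriptase (TGIRT) on non-fragmented RNA read
through structure and cover small RNAs end-to-end, which makes
*annotation-independent* transcript discovery feasible: call read-coverage
clusters, subtract whatever is already annotated, and ask what the robust
leftovers are.

`snclust` implements that pipeline at desk scale: cluster calling from
strand-aware alignments, a filter cascade for robustly expressed
non-annotated candidates, four-evidence biotype classification into eight
classes (tRNA-like, pre-tRNA, tRNA fragment, C/D snoRNA, H/ACA snoRNA,
ITS-RNA, ETS-RNA, unknown), tRNA-fragment positional mapping, conservation
and ortholog-identity scoring, TPM quantification with host-gene
correlation, and depletion-response analysis. A synthetic-data generator
plants ground-truth loci so that every stage can be validated end-to-end.

## Cluster calling

Alignments enter as stranded BED6-like records carrying a read id and the
read's number of genomic hits (1 = uniquely mapped). Calling proceeds in
three steps:

1. reads are collapsed into *tags* (identical chromosome, interval,
   strand); tags with fewer than `tag_filter = 50` reads are discarded;
2. surviving tags are chained into per-strand *coverage components* —
   maximal contiguously covered regions (components are what a per-base
   coverage scan yields, so two tags that abut exactly fuse into one
   component);
3. components totalling at least `min_cluster_reads = 100` reads become
   clusters, spanning their member reads, with read, unique-read and
   dataset tallies attached.

No sub-block decomposition is attempted. The original block-based caller
smooths coverage into Gaussian-ish blocks; with full-length, low-jitter
coverage the cluster itself is the transcript candidate, and the two
thresholds above are interpreted as minimum reads per cluster and per tag.
This is a deliberate semantic simplification, not a re-implementation of
that tool.

## The filter cascade

Candidates are kept only if **none** of the following fire; discarded
clusters record *all* filters they fail, which yields the per-filter
discard tally that `plot_filter_summary()` draws.

| filter | rule | default |
|---|---|---|
| `annotated` | same-strand overlap with a whitelisted gene entry or any exon | see below |
| `too_short` / `too_long` | length outside `[min_len, max_len]` | 20 / 500 nt |
| `low_unique` | `unique_read_count < min_unique_reads`, unless the multimap exception applies | 100 |
| `single_dataset` | detected in fewer than `min_datasets` datasets (>= `detect_min_reads` same-strand reads each) | 2 / 1 |
| `antisense_45S` | positional overlap with a 45S pre-rRNA gene on the opposite strand | — |
| `retained_intron` | reciprocal overlap >= 90% with an annotated intron, both boundaries within 5 nt of the splice sites | 0.9 / 5 nt |

**What counts as annotated.** The subtraction emulates an ncRNA
transcript catalogue: full gene spans count for every biotype except
those in `annotated_exclude_biotypes` (`protein_coding`, `rRNA_45S`),
whose *exons* still count. Protein-coding gene bodies are excluded at the
gene level because ncRNA catalogues do not blanket intronic space — an
intron-embedded snoRNA is exactly the kind of novel locus the pipeline
must keep — while mRNA-fragment clusters on exons are still subtracted.
The 45S precursor unit is excluded because its spacers (5'ETS, ITS1) are
normally degraded and unannotated; spacer-derived clusters are genuine
candidates. The 45S gene entry still powers the antisense filter.

**The multimap exception.** Byte-identical gene copies (the ETS/ITS
situation, where several rDNA units carry the same spacer RNA) share all
their reads, so each copy has near-zero uniquely mapped reads. A
low-unique cluster is rescued when its multimapped reads align only to
loci that are themselves non-annotated candidate clusters of the same
run. Because the simulator represents multimapping as emission at one
uniformly chosen byte-identical copy, partner loci cannot be recovered
from read ids; the implementation instead locates other genomic copies of
the cluster sequence by exact match on both strands and requires every
copy to be covered by a same-strand non-annotated candidate. The
`retained_intron` operationalisation (90% reciprocal overlap, 5 nt
boundary tolerance) is likewise a committed numeric reading of "fully
retained intron" that tolerates caller jitter; both numbers sit in the
configuration.

## Classification evidence

Four channels feed the biotype decision.

**Homology** (`homology_search()`): seeded local alignment against a
reference ncRNA set. A reference is aligned only when it shares an exact
11-mer with the query in either orientation; alignment scores are match
+1, mismatch −2, affine gaps (5 for the first gapped base, 2 per
extension). Raw scores become bits via `S = raw × λ / ln 2` with
`λ = 0.5`, and `E = m·n·2^(−S)` with `m` the query length and `n` the
summed reference length. Hits above `evalue_max = 0.01` are dropped.
These calibration constants are a fixed, documented statistical
convention standing in for a profile-HMM search engine — they make
e-values comparable across runs of this package, not across tools.

**Cloverleaf heuristic** (`cloverleaf_check()`): searches 55–120 nt
sequences for, in 5'→3' order, an acceptor stem of >= 6 bp formed between
the sequence ends (<= 1 mismatch, G·U allowed, <= 2 nt 3' trailer), a D
arm (perfect 3–4 bp stem, 4–12 nt loop), an anticodon arm (4 bp up to
`ac_stem_max = 7`, loop 5–9 nt) and a T arm (4–5 bp, loop 5–9 nt) ending
within 2 nt of the 3' acceptor strand. Stems must be *maximal*: a
candidate whose loop-closing or flanking bases could extend it is
rejected, so a 7-bp anticodon stem cannot be re-read as a canonical 5-bp
stem with a wider loop. The 7-bp default tolerance exists because
non-annotated tRNA-like genes carry exactly this kind of anomaly; pass
`ac_stem_max = 5` for the strict canonical model.

**H/ACA heuristic** (`haca_check()`): 100–250 nt sequences need an ACA
box starting exactly 6 nt before the 3' end (a 3-nt tail follows), an
`ANANNA` H box inside the central window `[0.35L, 0.65L]`, and two halves
that each fold — by Nussinov base-pair maximization with minimum loop 3,
implemented in C++ — into a hairpin with >= 8 pairs and an interior loop
available as a target pocket. The traceback prefers closing the outer
pair, which reconstructs stacked helices whenever they are co-optimal.

**C/D boxes and guide** (`cd_check()`): box C (`RTGATGA`, <= 1 mismatch)
within the first 25 nt, box D (`CTGA`, exact) within the last 25 nt, an
optional terminal stem, and — against a supplied target RNA — a guide: a
>= 10 nt perfect antisense match ending <= 20 nt upstream of box D. The
target descriptor reports the target position paired to the 5th
nucleotide upstream of box D, the canonical 2'-O-methylation site.

**Repeat overlap** (`repeat_overlap()`): the repeat annotation entry with
maximal overlap fraction (cluster length as denominator), reported when
it reaches 0.5.

## The decision tree

The published analysis integrates its predictors without stating a
precedence among conflicting evidence, so the package commits to one and
logs every step in the call's rationale:

1. location first: a cluster >= 50% inside an `rDNA_5ETS` / `rDNA_ITS1`
   feature is `ETS_RNA` / `ITS_RNA` — spacer products are defined by
   where they live, not by their sequence;
2. tRNA homology: shorter than `trf_len_threshold = 65` nt →
   `tRNA_fragment` (too short to form the structure); homology extending
   more than 5 nt beyond the reference's mature ends → `pre_tRNA`;
   otherwise a cloverleaf fold **or** >= 80% full-length identity →
   `tRNA_like`, else `tRNA_fragment`;
3. C/D boxes plus guide → `snoRNA_CD`;
4. H/ACA architecture → `snoRNA_HACA` (with no predicted rRNA target the
   rationale notes "orphan");
5. otherwise `unknown`, with any sub-classification homology and the
   repeat label recorded.

Homology outranks the snoRNA detectors because sequence identity to a
known family is harder to produce by chance than a satisfied structural
heuristic; location outranks both because the rDNA spacers are defined
regions. Each call is a pure function of its evidence.

## tRNA fragments

`map_fragment()` aligns a fragment to its best tRNA reference (lowest
e-value; ties by identity, then reference id) and expresses the aligned
span as fractions of the reference mature length. The genomic locus is
then extended to reference-equivalent coordinates and the extension's
global identity against the full reference decides whether the fragment
looks processed from a full (possibly non-annotated) tRNA gene
(>= `extension_identity_min = 75`%). Reference coordinates are genomic
and CCA-free; whether the original analysis used spliced or CCA-appended
coordinates is unstated, and the genomic choice is documented here.
Positional classes formalise what fragment-position plots show visually;
the windows (start <= 0.1 and end in [0.4, 0.6] for a 5' half, mirrored
for 3' halves, span >= 0.75 for near-full, halves checked before
near-full) are configuration values, not published constants.

## Expression, conservation, depletion

`tpm_quantify()` assigns each read to the smallest same-strand feature
fully containing it — embedded-gene priority, so intronic snoRNA reads are
never double-counted to the host — otherwise to the feature with the
largest overlap; multimapped reads are split `1/n_genomic_hits`. This
fractional split is a documented simplification of dedicated
count-correction pipelines. TPM columns sum to 10^6 by construction.
`host_correlation()` uses Spearman rank correlation across datasets
(>= 3 required) with `host_corr_min = 0.5` for host-dependence and
non-positive correlation for independence; the statistic and threshold
behind "correlates positively" are unstated in the source analysis, so
rank correlation at 0.5 is the committed default. `mean_conservation()`
averages per-base scores over all positions with missing bases scored 0
(the convention for unaligned bases); `ortholog_identity()` reports local
alignment identity within ±300 nt regions, or "no equivalent" when the
species lacks the region or the alignment covers under half the cluster.
`depletion_response()` uses `log2(mean + 1)` pseudo-counted fold-changes
to tolerate zero TPM, and is antisymmetric under swapping the arms.

## What the synthetic data emulates — and what it does not

`build_genome()` plants, on a 1 Mb two-chromosome random background, 200
annotated loci (40% tRNA genes at 30–80 TPM, 12.5% each intronic C/D and
H/ACA snoRNAs, 20% protein-coding hosts, one 45S rDNA unit per
chromosome, snRNA-like genes for the remainder) and 5 novel loci per
biotype class withheld from the annotation. Family constructors emit
sequences that satisfy their detector by construction (designed perfect
stems with non-pairing loop closers, boxes at canonical offsets); novel
tRNA-like loci are 6%-mutated copies of reference tRNAs, a fraction
(`imperfect_frac = 0.2`) carrying the 7-bp anticodon anomaly; fragments
are exact >= 34 nt sub-sequences (long enough that an exact hit clears
the e-value bound under the fixed calibration); ETS/ITS loci are planted
byte-identically in every rDNA unit so their reads multimap.

`simulate_reads()` emulates non-fragmented TGIRT coverage: full-locus
spans with <= 2 nt end jitter, concentrated (0.9 / 0.04 / 0.01 for 0 /
±1 / ±2 per end) because template switching defines ends sharply — the
true jitter magnitude is not quantified anywhere and is an exposed
modeling choice. Counts are Poisson at `TPM × depth` (default 30
reads/TPM; novel loci at 8–15 TPM, matching the moderate abundance
typical of non-annotated RNAs, give ~240–450 reads per locus). Intronic
loci share their host's lognormal dataset factor (sd 0.5) plus small
residual noise — that is what makes host-dependence recoverable — while
intergenic loci draw their own (sd 0.25). The depletion simulator scales
every H/ACA locus by the effect size and leaves all other biotypes
untouched, with small replicate noise (sd 0.1) reflecting paired
replicates of one culture.

Deliberately **not** modeled: sequencing errors and base qualities,
RNA-modification stop signatures, adapter artifacts, partial-homology
multimapping (copies are byte-identical or absent), fragmented-library
coverage shapes, and genome-scale repeat families. Passing the planted
truth therefore demonstrates the pipeline's logic — thresholds, strand
handling, evidence integration — not robustness to alignment noise or
annotation ambiguity in real data.

## Numerical choices and degenerate inputs

All outputs are sorted (chrom, start, end, strand) and every source of
randomness flows from a single seed, so identical configuration and seed
reproduce byte-identical files from every CLI subcommand. Coordinates are
0-based half-open everywhere internally (the native convention of the
pipeline's BED I/O); GTF input is converted at the reader boundary, and
unstranded records are rejected rather than defaulted because every
intersection is strand-specific. Zero-length intervals are invalid by
construction. Empty reference sets raise a named error; clusters outside
a detector's length gate simply fail that detector. Alignment tie-breaks
are deterministic (e-value, then identity, then reference id).

## Problem sizes used by the test suite

The shipped tests validate cluster calling against a per-base brute-force
oracle on 100 random layouts, detector specificity on 200 random or
shuffled sequences, fragment-class recovery on 100 planted fragments, and
the full discovery pipeline on the 1 Mb / 240-locus / 3-dataset reference
simulation described above; `scripts/acceptance.R` re-runs the same
computations from scratch for a supplied seed. These sizes were chosen so
the whole suite exercises every code path in a few minutes on one core
while keeping Monte-Carlo rates stable to a few percent.

## Known limitations

* The e-value calibration is a convention, not a fitted model; absolute
  e-values are not comparable to profile-HMM search tools.
* The structural detectors are heuristics with hard windows; they are
  tuned for the synthetic families and will miss real-family variants
  outside those windows (that is also true of the strict canonical
  models they simplify).
* H/ACA target prediction is not implemented; all H/ACA calls are
  target-orphans by construction, and C/D guide search is restricted to
  user-supplied target RNAs.
* The multimap exception assumes byte-identical copies; diverged copies
  sharing reads through alignment ambiguity are not modeled.
* Host correlation needs at least three datasets and treats intergenic
  clusters as independent by construction.

## A minimal session

```{r example}
library(snclust)
cfg <- pipeline_config()
sim <- build_genome(cfg, sim_design(), seed = 7)
reads <- simulate_reads(sim$genome, sim$loci, sim$annotation,
  n_datasets = 3, depth = 30, seed = 8)
disc <- run_discovery(reads[reads$dataset_id == "ds1", ], reads,
  sim$genome, sim$annotation, sim$refs, sim$targets, cfg)
glance(disc)          # cluster / kept / class counts
tidy(disc)            # per-cluster calls with rationale
autoplot(disc)        # biotype distribution
plot_filter_summary(disc$filter)
```
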