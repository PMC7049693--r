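#' tRNA cloverleaf heuristic
#'
#' Searches a candidate sequence for the four arms of a cloverleaf in
#' 5'-to-3' order: an acceptor stem of >= 6 bp formed between the two
#' sequence ends (at most one mismatch, G-U wobble allowed, up to 2 nt of
#' 3' trailer tolerated), then a D arm (perfect stem of 3-4 bp, loop
#' 4-12 nt), an anticodon arm (stem 4 bp up to `ac_stem_max`, loop 5-9 nt)
#' and a T arm (stem 4-5 bp, loop 5-9 nt) ending within 2 nt of the 3'
#' acceptor strand. The anticodon tolerance defaults to 7 bp because
#' non-annotated tRNA-like genes can carry anticodon stems longer than the
#' canonical 5 bp; pass `ac_stem_max = 5` for the strict canonical model.
#'
#' @param seq Nucleotide string, 55-120 nt (outside this range the flag is
#'   `FALSE`).
#' @param ac_stem_max Maximum anticodon stem length accepted (bp).
#' @return A list: `folds_as_trna` flag and an `arms` tibble giving each
#'   arm's 1-based bounds when the fold is found.
#' @examples
#' cloverleaf_check(make_trna_seq(seed = 1))$folds_as_trna
#' @export
cloverleaf_check <- function(seq, ac_stem_max = 7) {
  seq <- toupper(gsub("U", "T", seq, fixed = TRUE))
  L <- nchar(seq)
  no <- list(folds_as_trna = FALSE, arms = NULL)
  if (L < 55 || L > 120) return(no)
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]

  for (tail3 in 0:2) {
    for (s_acc in 7:6) {
      i2 <- L - tail3 - s_acc + 1
      if (i2 <= s_acc) next
      if (s_acc - stem_matches(chars, 1, i2, s_acc) > 1) next
      limit <- i2 - 1  # interior must finish before the 3' acceptor strand
      d_cands <- find_stemloops(chars, s_acc + 1, s_acc + 4, 3, 4, 4, 12, limit)
      if (is.null(d_cands)) next
      for (di in seq_len(nrow(d_cands))) {
        d <- d_cands[di, ]
        ac_cands <- find_stemloops(chars, d$end + 1, d$end + 4, 4,
          ac_stem_max, 5, 9, limit)
        if (is.null(ac_cands)) next
        for (ai in seq_len(nrow(ac_cands))) {
          ac <- ac_cands[ai, ]
          t_cands <- find_stemloops(chars, ac$end + 1, ac$end + 17, 4, 5,
            5, 9, limit)
          if (is.null(t_cands)) next
          t_ok <- t_cands[t_cands$end >= limit - 2, , drop = FALSE]
          if (!nrow(t_ok)) next
          tt <- t_ok[1, ]
          arms <- tibble::tibble(
            arm = c("acceptor", "D", "anticodon", "T"),
            start = c(1L, d$start, ac$start, tt$start),
            end = c(as.integer(L - tail3), d$end, ac$end, tt$end),
            stem_bp = c(s_acc, d$stem, ac$stem, tt$stem),
            loop_nt = c(NA_integer_, d$loop, ac$loop, tt$loop)
          )
          return(list(folds_as_trna = TRUE, arms = arms))
        }
      }
    }
  }
  no
}

#' H/ACA snoRNA architecture heuristic
#'
#' An H/ACA candidate must carry (i) an ACA box whose first base sits
#' exactly 6 nt before the 3' end (so the box is followed by a 3-nt tail),
#' (ii) an H box matching `ANANNA` inside the central window
#' `[0.35L, 0.65L]`, and (iii) two halves (5' of the H box, and between the
#' H box and the ACA box) that each fold into a hairpin with at least 8
#' base pairs by base-pair maximization (minimum loop 3) and an interior
#' loop available as a target pocket.
#'
#' @param seq Nucleotide string, 100-250 nt (outside this range the flag is
#'   `FALSE`).
#' @return A list: `folds_as_haca` flag and, when boxes are found, a
#'   `haca_boxes` tibble with 1-based `h_start` and `aca_start`.
#' @examples
#' haca_check(make_haca_seq(seed = 1))$folds_as_haca
#' @export
haca_check <- function(seq) {
  seq <- toupper(gsub("U", "T", seq, fixed = TRUE))
  L <- nchar(seq)
  no <- list(folds_as_haca = FALSE, haca_boxes = NULL)
  if (L < 100 || L > 250) return(no)
  if (substr(seq, L - 5, L - 3) != "ACA") return(no)

  m <- gregexpr("(?=A[ACGT]A[ACGT][ACGT]A)", seq, perl = TRUE)[[1]]
  starts <- as.integer(m)
  starts <- starts[starts > 0]
  # the whole 6-mer must sit inside the central window
  starts <- starts[(starts - 1) >= 0.35 * L & (starts + 5) <= 0.65 * L]
  for (p in starts) {
    half1 <- substr(seq, 1, p - 1)
    half2 <- substr(seq, p + 6, L - 6)
    if (hairpin_with_pocket(half1) && hairpin_with_pocket(half2)) {
      return(list(
        folds_as_haca = TRUE,
        haca_boxes = tibble::tibble(h_start = p, aca_start = L - 5L)
      ))
    }
  }
  no
}

#' C/D snoRNA box and guide detection
#'
#' Searches for a box C (consensus `RTGATGA`, at most one mismatch, R = A/G
#' at no cost) within the first 25 nt and a box D (`CTGA`, exact) within the
#' last 25 nt, reports whether a terminal stem of >= 4 bp can form between
#' the sequence ends, and — when target sequences are supplied — looks for a
#' guide: a >= 10 nt perfect antisense match to a target RNA ending at most
#' 20 nt upstream of box D. The target descriptor names the target and the
#' target position paired to the 5th nucleotide upstream of box D (the
#' predicted 2'-O-methylation site), `NA` when that nucleotide falls outside
#' the guide.
#'
#' @param seq Nucleotide string, 50-300 nt (outside this range no boxes are
#'   reported).
#' @param targets Optional named character vector (or `DNAStringSet`) of
#'   target RNAs, typically a synthetic rRNA.
#' @param max_guide_len Longest guide considered (25).
#' @return A list with `cd_boxes` (tibble `box_c_start`, `box_d_start`,
#'   1-based, or `NULL`), `terminal_stem` flag and `guide_target` (tibble
#'   `target_id`, `target_pos`, `guide_start`, `guide_end`, `guide_len`, or
#'   `NULL`).
#' @export
cd_check <- function(seq, targets = NULL, max_guide_len = 25) {
  seq <- toupper(gsub("U", "T", seq, fixed = TRUE))
  L <- nchar(seq)
  no <- list(cd_boxes = NULL, terminal_stem = FALSE, guide_target = NULL)
  if (L < 50 || L > 300) return(no)
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]

  # box C: RTGATGA with <=1 mismatch, fully inside the first 25 nt
  box_c <- NA_integer_
  consensus <- c("TGATGA")
  cons_chars <- strsplit(consensus, "")[[1]]
  for (i in seq_len(max(0, min(25, L) - 6))) {
    mm <- as.integer(!chars[i] %in% c("A", "G")) +
      sum(chars[(i + 1):(i + 6)] != cons_chars)
    if (mm <= 1) { box_c <- i; break }
  }
  if (is.na(box_c)) return(no)

  # box D: exact CTGA inside the last 25 nt; take the 3'-most occurrence
  win_start <- max(1, L - 24)
  hits <- gregexpr("CTGA", substr(seq, win_start, L), fixed = TRUE)[[1]]
  if (hits[1] == -1) return(no)
  box_d <- win_start + max(hits) - 1
  if (box_c + 6 >= box_d) return(no)

  terminal_stem <- L >= 8 &&
    sum(bases_pair(chars[1:4], chars[L:(L - 3)])) >= 4

  guide <- NULL
  if (!is.null(targets)) {
    if (!methods::is(targets, "DNAStringSet")) {
      targets <- Biostrings::DNAStringSet(
        vapply(targets, function(x) gsub("U", "T", toupper(x), fixed = TRUE),
          character(1)))
    }
    best_len <- 0
    region_start <- box_c + 7
    e_min <- max(region_start + 9, box_d - 21)
    e_vals <- if (box_d - 1 >= e_min) seq(box_d - 1, e_min) else integer(0)
    for (e in e_vals) {
      max_len_e <- min(max_guide_len, e - region_start + 1)
      if (max_len_e < 10) next
      for (len in seq(max_len_e, 10, by = -1)) {
        if (len <= best_len) break
        w <- substr(seq, e - len + 1, e)
        rc <- reverse_complement(w)
        found <- FALSE
        for (ti in seq_along(targets)) {
          mt <- Biostrings::matchPattern(rc, targets[[ti]])
          if (length(mt) > 0) {
            t1 <- Biostrings::start(mt)[1]
            p5 <- box_d - 5
            tpos <- if (p5 <= e && p5 >= e - len + 1) t1 + (e - p5) else NA_integer_
            guide <- tibble::tibble(
              target_id = names(targets)[ti] %||% as.character(ti),
              target_pos = as.integer(tpos),
              guide_start = as.integer(e - len + 1),
              guide_end = as.integer(e),
              guide_len = as.integer(len)
            )
            best_len <- len
            found <- TRUE
            break
          }
        }
        if (found) break
      }
    }
  }

  list(
    cd_boxes = tibble::tibble(box_c_start = box_c, box_d_start = box_d),
    terminal_stem = terminal_stem,
    guide_target = guide
  )
}
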