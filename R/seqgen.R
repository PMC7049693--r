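# Family-sequence constructors for the synthetic-data generator. Each
# constructor emits a sequence that satisfies the corresponding internal
# detector by construction (designed perfect stems, boxes at canonical
# offsets), which is what makes planted-truth recovery a meaningful test.

# Run expr under a temporary RNG seed, restoring the caller's RNG state.
with_rng_seed <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  force(expr)
}

rand_dna <- function(n, alphabet = c("A", "C", "G", "T")) {
  if (n <= 0) return("")
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# Substitution-mutate a sequence at a fixed per-base rate.
mutate_seq <- function(seq, rate) {
  if (rate <= 0) return(seq)
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  hit <- which(stats::runif(length(chars)) < rate)
  for (i in hit) {
    chars[i] <- sample(setdiff(c("A", "C", "G", "T"), chars[i]), 1)
  }
  paste(chars, collapse = "")
}

rc <- function(s) reverse_complement(s)

#' Construct a cloverleaf-foldable tRNA-like sequence
#'
#' Assembles acceptor stem (7 bp), D arm (4 bp stem, 8 nt loop), anticodon
#' arm, variable region, T arm (5 bp stem, 7 nt loop) and a single
#' discriminator base, with perfect Watson-Crick stems. The canonical
#' geometry (`ac_stem = 5`, `ac_loop = 7`, `var_len = 4`) yields exactly
#' 72 nt. `ac_stem = 7, ac_loop = 5` reproduces the long-anticodon-stem
#' anomaly seen in non-annotated tRNA-like genes.
#'
#' @param seed Optional RNG seed (caller RNG untouched when given).
#' @param ac_stem,ac_loop Anticodon stem (bp) and loop (nt) sizes.
#' @param var_len Variable-region length (nt).
#' @return A DNA string.
#' @export
make_trna_seq <- function(seed = NULL, ac_stem = 5, ac_loop = 7, var_len = 4) {
  with_rng_seed(seed, {
    # loops closed by non-pairing bases (A/C) so the designed stems are the
    # maximal ones; bases flanking each arm likewise cannot extend a stem
    loop_dna <- function(n) {
      if (n <= 2) return(rand_dna(n, c("A", "C")))
      paste0(rand_dna(1, c("A", "C")), rand_dna(n - 2), rand_dna(1, c("A", "C")))
    }
    for (try in 1:30) {
      acc5 <- rand_dna(7)
      d5 <- rand_dna(4)
      a5 <- rand_dna(ac_stem)
      t5 <- rand_dna(5)
      acc3 <- rc(acc5)
      var_first <- rand_dna(1, c("A", "C"))
      var_last <- if (substr(acc3, 1, 1) == "T") "C" else "A"
      var_mid <- rand_dna(max(0, var_len - 2))
      s <- paste0(
        acc5, rand_dna(1), rand_dna(1, c("A", "C")),
        d5, loop_dna(8), rc(d5), rand_dna(1, c("A", "C")),
        a5, loop_dna(ac_loop), rc(a5),
        var_first, var_mid, var_last,
        t5, loop_dna(7), rc(t5),
        acc3, rand_dna(1)
      )
      if (cloverleaf_check(s, ac_stem_max = max(5, ac_stem))$folds_as_trna) {
        return(s)
      }
    }
    rlang::abort("could not construct a tRNA sequence passing its detector",
      class = "snc_design_error")
  })
}

#' Derive a structurally anomalous tRNA-like variant from a reference
#'
#' Extends the anticodon stem of a canonical 72-nt reference (as produced
#' by [make_trna_seq()] with default geometry) inward by two base pairs,
#' complementing two loop-closing bases: the result carries a 7-bp
#' anticodon stem with a tiny 3-nt loop while staying ~97% identical to
#' its reference. Such loci keep strong tRNA homology but deviate from the
#' canonical cloverleaf geometry, so structure-only prediction misses them
#' — the anomaly pattern seen in non-annotated tRNA-like genes.
#'
#' @param ref A 72-nt reference sequence from `make_trna_seq()`.
#' @return A DNA string of length 72.
#' @export
make_trna_variant <- function(ref) {
  stopifnot(nchar(ref) == 72)
  paste0(substr(ref, 1, 36),
    rc(substr(ref, 33, 33)), rc(substr(ref, 32, 32)),
    substr(ref, 39, 72))
}

#' Construct an H/ACA snoRNA-like sequence
#'
#' Two hairpins (10 + 6 bp designed stems each, with a 4-nt interior
#' pocket on both strands and a 6-nt apical loop) joined by a hinge that
#' carries an `ANANNA` H box, followed by an `ACA` box placed exactly 6 nt
#' before the 3' end. Loop and pocket bases are drawn from {A, C} so that
#' base-pair maximization recovers the designed helices and leaves the
#' pockets open. Total length 108 nt.
#'
#' @param seed Optional RNG seed.
#' @return A DNA string of length 108.
#' @export
make_haca_seq <- function(seed = NULL) {
  with_rng_seed(seed, {
    # G/C-only stems with A-only pockets and loops: no loop base can pair,
    # so base-pair maximization recovers the designed helices and leaves
    # the target pocket open
    half <- function() {
      s1 <- rand_dna(10, c("G", "C"))
      s2 <- rand_dna(6, c("G", "C"))
      paste0(s1, rand_dna(4, c("A")), s2, rand_dna(6, c("A")),
        rc(s2), rand_dna(4, c("A")), rc(s1))
    }
    for (try in 1:30) {
      h_box <- paste0("A", rand_dna(1), "A", rand_dna(2), "A")
      s <- paste0(
        half(),
        rand_dna(2, c("C")), h_box, rand_dna(2, c("C")),
        half(),
        "ACA", rand_dna(3)
      )
      if (haca_check(s)$folds_as_haca) return(s)
    }
    rlang::abort("could not construct an H/ACA sequence passing its detector",
      class = "snc_design_error")
  })
}

#' Construct a C/D snoRNA-like sequence with a guide against a target RNA
#'
#' Layout: 4-nt terminal stem, box C (`RTGATGA`), internal spacer, a guide
#' that is the perfect antisense of a randomly chosen `guide_len`-nt window
#' of the target and ends directly at box D (`CTGA`), then the 3' side of
#' the terminal stem. The constructor re-draws until [cd_check()] locates
#' the designed boxes and guide, so planted loci are positive by
#' construction.
#'
#' @param target_seq Target RNA (DNA alphabet string), e.g. a synthetic
#'   rRNA.
#' @param target_name Target identifier recorded in the guide descriptor.
#' @param seed Optional RNG seed.
#' @param guide_len Guide length in nt (12).
#' @param mid_len Spacer length between box C and the guide (30).
#' @return A DNA string with attributes `target_pos` (1-based target
#'   position paired to the 5th nt upstream of box D) and `target_id`.
#' @export
make_cd_seq <- function(target_seq, target_name = "target", seed = NULL,
                        guide_len = 12, mid_len = 30) {
  with_rng_seed(seed, {
    tlen <- nchar(target_seq)
    for (try in 1:50) {
      stem5 <- rand_dna(4)
      if (rc(stem5) == "CTGA") next
      box_c <- paste0(sample(c("A", "G"), 1), "TGATGA")
      tpos <- sample.int(tlen - guide_len + 1, 1)
      guide <- rc(substr(target_seq, tpos, tpos + guide_len - 1))
      s <- paste0(stem5, box_c, rand_dna(mid_len), guide, "CTGA", rc(stem5))
      chk <- cd_check(s, setNames(target_seq, target_name))
      if (!is.null(chk$cd_boxes) && !is.null(chk$guide_target) &&
          chk$guide_target$guide_len >= guide_len) {
        # the 5th nt upstream of box D is the 5th-from-3' guide base, which
        # pairs the 5th-from-5' base of the matched target window
        attr(s, "target_pos") <- tpos + 4
        attr(s, "target_id") <- target_name
        return(s)
      }
    }
    rlang::abort("could not construct a C/D sequence passing its detector",
      class = "snc_design_error")
  })
}

#' Construct rDNA spacer-like sequences
#'
#' `make_its_seq()` emits a GA-rich repetitive sequence (internal
#' transcribed spacer flavour); `make_ets_seq()` emits a long single
#' stem-loop (5' external transcribed spacer flavour).
#'
#' @param seed Optional RNG seed.
#' @param len Approximate sequence length (nt).
#' @return A DNA string.
#' @export
make_its_seq <- function(seed = NULL, len = 100) {
  with_rng_seed(seed, {
    units <- c("GA", "GAA", "GGA", "GAG", "GAGA")
    out <- character(0)
    total <- 0
    while (total < len) {
      u <- if (stats::runif(1) < 0.85) sample(units, 1) else rand_dna(2)
      out <- c(out, u)
      total <- total + nchar(u)
    }
    substr(paste(out, collapse = ""), 1, len)
  })
}

#' @rdname make_its_seq
#' @export
make_ets_seq <- function(seed = NULL, len = 110) {
  with_rng_seed(seed, {
    stem <- floor((len - 8) / 2)
    s <- rand_dna(stem)
    paste0(s, rand_dna(len - 2 * stem), rc(s))
  })
}
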