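#' Base-pair maximization folding
#'
#' Folds a sequence by Nussinov-style base-pair maximization (Watson-Crick
#' plus G-U wobble, minimum hairpin loop of `min_loop` bases) and returns
#' one maximal structure as a pairing table. This deliberately simple
#' folding model backs the H/ACA hairpin heuristic; it is not a free-energy
#' model.
#'
#' @param seq Nucleotide string (DNA or RNA alphabet).
#' @param min_loop Minimum unpaired bases enclosed by a pair (3).
#' @return Integer vector: position `i` pairs with `partner[i]` (1-based),
#'   0 when unpaired.
#' @export
fold_pairs <- function(seq, min_loop = 3) {
  s <- toupper(gsub("U", "T", seq, fixed = TRUE))
  .nussinov_pairs(s, as.integer(min_loop))
}

# Count pairs in a pairing table.
n_pairs <- function(partner) sum(partner > seq_along(partner))

# TRUE when the structure contains an interior loop: a pair (i,j) whose next
# nested pair (k,l) leaves >=1 unpaired base on both strands, i.e. a target
# pocket opened inside a stem.
has_interior_loop <- function(partner) {
  idx <- which(partner > seq_along(partner))
  for (i in idx) {
    j <- partner[i]
    # find the directly nested pair: smallest k in (i, j) that is paired
    # with some l < j, with everything between i..k and l..j unpaired
    k <- i + 1
    while (k < j && partner[k] == 0) k <- k + 1
    if (k >= j) next
    l <- partner[k]
    if (l <= k || l >= j) next
    left_gap <- k - i - 1
    right_gap <- j - l - 1
    if (left_gap >= 1 && right_gap >= 1) {
      if (all(partner[seq(l + 1, j - 1)] == 0)) return(TRUE)
    }
  }
  FALSE
}

# One half of an H/ACA layout must fold into a hairpin: >=min_pairs pairs by
# base-pair maximization and an interior loop available as a target pocket.
hairpin_with_pocket <- function(seq, min_pairs = 8, min_loop = 3) {
  if (nchar(seq) < 2 * min_pairs + min_loop) return(FALSE)
  p <- fold_pairs(seq, min_loop)
  n_pairs(p) >= min_pairs && has_interior_loop(p)
}

# --- stem utilities shared by the cloverleaf heuristic -----------------------

# Pairing indicator between two character vectors (Watson-Crick + G-U).
bases_pair <- function(a, b) {
  (a == "A" & b == "T") | (a == "T" & b == "A") |
    (a == "G" & (b == "C" | b == "T")) | (a == "C" & b == "G") |
    (a == "T" & b == "G")
}

# Count paired positions when x[i] is stacked against rev(y)[i].
stem_matches <- function(chars, i1, i2, s) {
  a <- chars[i1:(i1 + s - 1)]
  b <- chars[(i2 + s - 1):i2]
  sum(bases_pair(a, b))
}

# Enumerate stem-loops (hairpins) with stem length in [stem_min, stem_max],
# loop length in [loop_min, loop_max], starting at positions
# [from_min, from_max], fully inside chars[1..limit]. Stems must be perfect
# and maximal: candidates whose closing loop bases could extend the stem
# inward, or whose flanking bases could extend it outward, are rejected —
# a 7-bp stem therefore cannot be re-read as a 5-bp stem with a wider loop.
find_stemloops <- function(chars, from_min, from_max, stem_min, stem_max,
                           loop_min, loop_max, limit) {
  out <- list()
  from_max <- min(from_max, limit)
  if (from_min > from_max) return(NULL)
  n <- length(chars)
  for (i in from_min:from_max) {
    for (s in stem_max:stem_min) {
      for (l in loop_min:loop_max) {
        j <- i + 2 * s + l - 1  # hairpin end
        if (j > limit) next
        if (stem_matches(chars, i, i + s + l, s) < s) next
        if (l >= 2 && bases_pair(chars[i + s], chars[i + s + l - 1])) next
        if (i > 1 && j < n && bases_pair(chars[i - 1], chars[j + 1])) next
        out[[length(out) + 1]] <- c(start = i, stem = s, loop = l, end = j)
      }
    }
  }
  if (!length(out)) return(NULL)
  as.data.frame(do.call(rbind, out))
}
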