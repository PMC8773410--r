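# Nearest-neighbour energy model shared by the folding engine and the
# miRNA:target duplex scorer. Six pair types are allowed (Watson-Crick plus
# G:U wobble); energies are stacking terms between consecutive pairs read
# along the 5'->3' top strand, with a single helix-initiation penalty per
# helix and a minimum hairpin loop of 3 nt. Values are kcal/mol, loosely
# modelled on measured RNA nearest-neighbour parameters (G:U stacks are kept
# moderately strong, as wobble pairs are thermodynamically respectable).

PAIR_TYPES <- c("AU", "UA", "GC", "CG", "GU", "UG")

STACK_ENERGIES <- matrix(c(
  # inner:  AU    UA    GC    CG    GU    UG
  -0.9, -1.1, -2.2, -2.1, -1.4, -1.6, # outer AU
  -1.3, -0.9, -2.4, -2.1, -1.6, -1.4, # outer UA
  -2.1, -2.3, -3.3, -3.2, -1.9, -2.1, # outer GC
  -2.4, -2.1, -3.4, -3.3, -2.1, -1.9, # outer CG
  -1.4, -1.6, -2.1, -1.9, -1.2, -1.4, # outer GU
  -1.6, -1.4, -1.9, -2.1, -1.4, -1.2  # outer UG
), nrow = 6, byrow = TRUE, dimnames = list(PAIR_TYPES, PAIR_TYPES))

HELIX_INIT <- 3.5
MIN_LOOP <- 3L

#' Energy parameters of the folding and duplex model
#'
#' Returns the constant nearest-neighbour table the package ships: stacking
#' energies (kcal/mol) for the 36 ordered combinations of the six allowed
#' pair types (AU, UA, GC, CG, GU, UG; first base on the 5'->3' top strand),
#' the helix initiation penalty charged once per helix, and the minimum
#' hairpin loop length.
#'
#' @return list with elements `stacks` (6x6 named matrix), `helix_init`
#'   (positive scalar, kcal/mol) and `min_loop` (integer).
#' @export
rna_energy_params <- function() {
  list(stacks = STACK_ENERGIES, helix_init = HELIX_INIT, min_loop = MIN_LOOP)
}

# pair type label for top-strand base a paired with bottom-strand base b
# (both given 5'->3' on their own strands); "" if a:b is not a valid pair.
pair_label <- function(a, b) {
  a <- chartr("T", "U", a)
  b <- chartr("T", "U", b)
  lab <- paste0(a, b)
  ifelse(lab %in% PAIR_TYPES, lab, "")
}

#' Score a miRNA:target duplex position by position
#'
#' Aligns a miRNA (5'->3') against a same-length transcript window (sense
#' strand, 5'->3') in antiparallel orientation: miRNA position 1 (its 5' end)
#' pairs with the last base of the window. Each miRNA position is classified
#' as `match` (Watson-Crick), `gu` (G:U wobble in duplex orientation) or
#' `mismatch`, and the mismatch score is the weighted sum with weights
#' mismatch = 1, G:U = 0.5, match = 0.
#'
#' @param mirna miRNA sequence (20-23 nt typical; any length accepted).
#' @param window transcript window of the same length.
#' @return object of class `duplex_alignment`: list with `mirna`, `window`,
#'   `states` (character vector over miRNA positions 1..L), `score`.
#' @examples
#' score_duplex("AUGGC", as.character(
#'   Biostrings::reverseComplement(Biostrings::DNAString("ATGGC"))))
#' @export
score_duplex <- function(mirna, window) {
  m <- strsplit(toupper(as_dna(mirna)), "")[[1]]
  w <- strsplit(toupper(as_dna(window)), "")[[1]]
  if (length(m) != length(w)) {
    stop("miRNA and window must have equal length (ungapped duplex model)")
  }
  t <- rev(w) # base opposite miRNA position k is window position L + 1 - k
  wc <- c(A = "T", C = "G", G = "C", T = "A")
  states <- ifelse(t == wc[m], "match",
            ifelse((m == "G" & t == "T") | (m == "T" & t == "G"), "gu",
                   "mismatch"))
  score <- sum(c(match = 0, gu = 0.5, mismatch = 1)[states])
  structure(list(mirna = paste(m, collapse = ""),
                 window = paste(w, collapse = ""),
                 states = unname(states), score = score),
            class = "duplex_alignment")
}

#' @export
print.duplex_alignment <- function(x, ...) {
  sym <- c(match = "|", gu = "o", mismatch = " ")
  cat("miRNA  5'-", as_rna(x$mirna), "-3'\n", sep = "")
  cat("          ", paste(sym[x$states], collapse = ""), "\n", sep = "")
  cat("target 3'-", paste(rev(strsplit(x$window, "")[[1]]), collapse = ""),
      "-5'  (score ", format(x$score), ")\n", sep = "")
  invisible(x)
}

#' Duplex energies under the nearest-neighbour model
#'
#' `duplex_energy()` sums stacking energies over consecutive paired positions
#' of a miRNA:window duplex (mismatches interrupt stacks and contribute
#' nothing); `perfect_duplex_energy()` is the energy of the miRNA bound to
#' its exact complement. Both are deterministic stack sums without helix
#' initiation terms, so a fully mismatched duplex has energy 0 and the ratio
#' `duplex_energy / perfect_duplex_energy` lies in `[0, 1]`.
#'
#' @inheritParams score_duplex
#' @return energy in kcal/mol (<= 0).
#' @export
duplex_energy <- function(mirna, window) {
  aln <- if (inherits(mirna, "duplex_alignment")) mirna
         else score_duplex(mirna, window)
  m <- strsplit(aln$mirna, "")[[1]]
  t <- rev(strsplit(aln$window, "")[[1]])
  paired <- aln$states != "mismatch"
  labs <- pair_label(m, t)
  e <- 0
  for (k in seq_len(length(m) - 1L)) {
    if (paired[k] && paired[k + 1L]) {
      e <- e + STACK_ENERGIES[labs[k], labs[k + 1L]]
    }
  }
  e
}

#' @rdname duplex_energy
#' @export
perfect_duplex_energy <- function(mirna) {
  duplex_energy(mirna, revcomp(mirna))
}
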