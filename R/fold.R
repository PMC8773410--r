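#' Fold an RNA sequence into its minimum-free-energy nested structure
#'
#' Deterministic dynamic-programming folding over nested (pseudoknot-free)
#' structures under the package's nearest-neighbour energy model (see
#' [rna_energy_params()]): stacking energies between adjacent base pairs, one
#' helix-initiation penalty per helix, minimum hairpin loop of 3 nt,
#' Watson-Crick and G:U pairs. The empty structure has energy 0, so the MFE
#' is never positive; a homopolymer folds to all dots with MFE 0.
#'
#' @param sequence a single sequence string over A/C/G/T/U (case-insensitive);
#'   lengths up to 400 nt are accepted.
#' @return object of class `rna_fold`: list with `sequence` (RNA alphabet),
#'   `dotbracket` (balanced, non-crossing), `mfe` (kcal/mol, <= 0) and
#'   `pairs` (integer vector of 1-based partners, NA when unpaired).
#' @examples
#' fold_rna("GGGGGAAAACCCCC")
#' @export
fold_rna <- function(sequence) {
  stopifnot(length(sequence) == 1L)
  s <- toupper(as_dna(sequence))
  ch <- strsplit(s, "")[[1]]
  if (length(ch) > 400L) stop("sequences longer than 400 nt are not supported")
  code <- match(ch, c("A", "C", "G", "T")) - 1L
  if (anyNA(code)) {
    stop("sequence contains non-ACGTU characters: ",
         paste(unique(ch[is.na(code)]), collapse = ", "))
  }
  res <- .fold_mfe_cpp(code, STACK_ENERGIES, HELIX_INIT, MIN_LOOP)
  pairs <- res$pairs + 1L
  pairs[pairs == 0L] <- NA_integer_
  db <- rep(".", length(ch))
  db[!is.na(pairs) & seq_along(pairs) < pairs] <- "("
  db[!is.na(pairs) & seq_along(pairs) > pairs] <- ")"
  structure(list(sequence = as_rna(s),
                 dotbracket = paste(db, collapse = ""),
                 mfe = res$mfe,
                 pairs = pairs),
            class = "rna_fold")
}

#' @export
print.rna_fold <- function(x, ...) {
  cat(x$sequence, "\n", x$dotbracket, "  (", format(x$mfe), " kcal/mol)\n",
      sep = "")
  invisible(x)
}

# TRUE when the structure has a single hairpin loop (every "(" precedes
# every ")"), i.e. a simple stem-loop rather than a multibranched fold.
is_single_hairpin <- function(fold) {
  db <- strsplit(fold$dotbracket, "")[[1]]
  op <- which(db == "(")
  cl <- which(db == ")")
  length(op) > 0L && length(cl) > 0L && max(op) < min(cl)
}

# 1-based [start, end] of the hairpin loop (the unpaired stretch between the
# innermost pair); NULL when not a single hairpin.
hairpin_loop_span <- function(fold) {
  if (!is_single_hairpin(fold)) return(NULL)
  db <- strsplit(fold$dotbracket, "")[[1]]
  c(max(which(db == "(")) + 1L, min(which(db == ")")) - 1L)
}
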