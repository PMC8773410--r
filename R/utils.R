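#' Sequence string helpers
#'
#' The package works on DNA-alphabet strings internally (A/C/G/T) and converts
#' to the RNA alphabet only at RNA-facing boundaries (folding output, duplex
#' pair labels). `as_dna()` and `as_rna()` convert between the two alphabets;
#' `revcomp()` reverse-complements DNA strings.
#'
#' @param x character vector of sequences.
#' @return character vector of the same length.
#' @examples
#' as_rna("ACGT")
#' revcomp("ACGT")
#' @export
as_dna <- function(x) chartr("Uu", "Tt", x)

#' @rdname as_dna
#' @export
as_rna <- function(x) chartr("Tt", "Uu", x)

#' @rdname as_dna
#' @export
revcomp <- function(x) {
  if (length(x) == 0L) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(as_dna(x))))
}

#' Random DNA sequences
#'
#' Draws `n` independent sequences. `len` is recycled to length `n`, so mixed
#' lengths (e.g. 18-30 nt background tags) can be drawn in one call. Sampling
#' consumes the current RNG stream; seed management is left to callers.
#'
#' @param n number of sequences.
#' @param len integer vector of lengths (recycled).
#' @param gc GC content in `[0, 1]`.
#' @return character vector of length `n`.
#' @export
random_dna <- function(n, len, gc = 0.5) {
  if (n == 0L) return(character(0))
  len <- rep_len(as.integer(len), n)
  prob <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  out <- character(n)
  for (L in unique(len)) {
    idx <- which(len == L)
    mat <- matrix(sample(c("A", "C", "G", "T"), length(idx) * L,
                         replace = TRUE, prob = prob),
                  nrow = length(idx))
    out[idx] <- do.call(paste0, as.data.frame(mat, stringsAsFactors = FALSE))
  }
  out
}

#' Dinucleotide shuffle
#'
#' Shuffles a sequence while approximately preserving its dinucleotide
#' composition (random Eulerian-walk style reassembly of the dinucleotide
#' graph, with retries falling back to a plain shuffle when the walk gets
#' stuck). Used to build null sequences for hairpin-calling specificity
#' checks.
#'
#' @param x a single sequence string.
#' @return a shuffled sequence of the same length and (approximate)
#'   dinucleotide composition.
#' @export
shuffle_dinucleotide <- function(x) {
  ch <- strsplit(as_dna(x), "")[[1]]
  n <- length(ch)
  if (n < 3L) return(x)
  # successor lists of the dinucleotide graph
  succ <- split(ch[-1], ch[-n])
  succ <- lapply(succ, sample)
  out <- character(n)
  out[1] <- ch[1]
  for (i in 2:n) {
    cur <- out[i - 1]
    nxt <- succ[[cur]]
    if (is.null(nxt) || length(nxt) == 0L) {
      # walk stuck: fall back to plain shuffle of the remainder
      rest <- unlist(succ, use.names = FALSE)
      out[i:n] <- sample(rest)[seq_len(n - i + 1L)]
      return(paste(out, collapse = ""))
    }
    out[i] <- nxt[1]
    succ[[cur]] <- nxt[-1]
  }
  paste(out, collapse = "")
}

#' Read and write FASTA files
#'
#' Thin wrappers around [Biostrings::readDNAStringSet()] /
#' [Biostrings::writeXStringSet()] returning plain named character vectors,
#' which is the currency of this package. `read_collapsed_fasta()` additionally
#' parses count-encoded headers of the form `>tagN_xCOUNT` into a tag tibble,
#' so pre-collapsed libraries can bypass the FASTQ stages.
#'
#' @param path file path.
#' @param x named character vector of sequences.
#' @return `read_fasta()`: named character vector. `read_collapsed_fasta()`:
#'   tibble with columns `sequence`, `count`.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), names(x))
}

#' @rdname read_fasta
#' @export
write_fasta <- function(x, path) {
  stopifnot(!is.null(names(x)))
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(as_dna(x)), path)
  invisible(path)
}

#' @rdname read_fasta
#' @export
read_collapsed_fasta <- function(path) {
  x <- read_fasta(path)
  cnt <- suppressWarnings(as.integer(sub(".*_x(\\d+)$", "\\1", names(x))))
  if (anyNA(cnt)) {
    stop("collapsed FASTA headers must end in '_x<count>'; offending header: ",
         names(x)[which(is.na(cnt))[1]])
  }
  tibble(sequence = unname(x), count = cnt)
}

#' @rdname read_fasta
#' @param tags tibble with columns `sequence` and one count column.
#' @param count_col name of the count column to encode in headers.
#' @export
write_collapsed_fasta <- function(tags, path, count_col = "count") {
  seqs <- setNames(tags$sequence,
                   sprintf("tag%d_x%d", seq_len(nrow(tags)), tags[[count_col]]))
  write_fasta(seqs, path)
}
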