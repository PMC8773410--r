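#' Map tags to a genome with up to one mismatch
#'
#' Reports every locus of each tag on both strands with at most
#' `max_mismatches` substitutions (no indels). Tags with zero loci are
#' dropped. Coordinates are 1-based inclusive on the forward strand of the
#' contig; minus-strand loci mean the reverse complement of the genomic
#' window equals the tag (up to the allowed mismatches).
#'
#' @param tags character vector of tag sequences, or a tibble with a
#'   `sequence` column.
#' @param genome named character vector of contig sequences.
#' @param max_mismatches maximum substitutions per locus (default 1).
#' @return tibble with columns `sequence`, `contig`, `start`, `end`,
#'   `strand`, `n_mismatches`.
#' @export
map_tags <- function(tags, genome, max_mismatches = 1L) {
  seqs <- if (inherits(tags, "data.frame")) tags$sequence else tags
  seqs <- unique(toupper(as_dna(seqs)))
  subj <- Biostrings::DNAStringSet(toupper(as_dna(genome)))
  rows <- list()
  for (tg in seqs) {
    for (strand in c("+", "-")) {
      pat <- if (strand == "+") tg else revcomp(tg)
      m <- Biostrings::vmatchPattern(pat, subj, max.mismatch = max_mismatches)
      for (ci in seq_along(m)) {
        ir <- m[[ci]]
        if (length(ir) == 0L) next
        st <- BiocGenerics::start(ir)
        en <- BiocGenerics::end(ir)
        keep <- st >= 1L & en <= nchar(genome[[ci]])
        if (!any(keep)) next
        st <- st[keep]; en <- en[keep]
        nmm <- vapply(seq_along(st), function(k) {
          g <- substr(genome[[ci]], st[k], en[k])
          sum(strsplit(g, "")[[1]] != strsplit(pat, "")[[1]])
        }, integer(1))
        rows[[length(rows) + 1L]] <-
          tibble(sequence = tg, contig = names(genome)[ci],
                 start = st, end = en, strand = strand, n_mismatches = nmm)
      }
    }
  }
  if (length(rows) == 0L) {
    return(tibble(sequence = character(), contig = character(),
                  start = integer(), end = integer(), strand = character(),
                  n_mismatches = integer()))
  }
  bind_rows(rows) |> arrange(.data$sequence, .data$contig, .data$start)
}

#' Enumerate candidate precursor windows around a mapped tag
#'
#' Emits genomic windows that could be the hairpin precursor of a mapped
#' tag: for every window length in `[min_len, max_len]` the tag is placed
#' near the window's 5' end (mature on the 5' arm) or near its 3' end
#' (mature on the 3' arm), at offsets `0..max_offset` from the respective
#' window edge. Windows are truncated at contig boundaries (coordinates are
#' never negative) and windows left shorter than `min_len`, or no longer
#' containing the tag, are dropped. Minus-strand loci are handled in read
#' orientation: the emitted `window` column is always the precursor sequence
#' 5'->3' as transcribed.
#'
#' @param genome named character vector of contigs.
#' @param contig,start,end,strand one mapped locus (1-based inclusive).
#' @param min_len,max_len precursor length sweep (defaults 62-96 nt).
#' @param max_offset maximum distance of the mature from its window edge
#'   (default 8 nt).
#' @return tibble with columns `w_start`, `w_end` (genome coordinates),
#'   `window` (precursor sequence in read orientation), `mature_offset`
#'   (0-based offset of the tag within `window`), `arm` (`"5p"`/`"3p"`).
#' @export
excise_precursor_windows <- function(genome, contig, start, end, strand,
                                     min_len = 62L, max_len = 96L,
                                     max_offset = 8L) {
  glen <- nchar(genome[[contig]])
  stopifnot(start >= 1L, end <= glen)
  grid <- tidyr::expand_grid(L = seq(min_len, max_len),
                             d = seq(0L, max_offset),
                             arm = c("5p", "3p"))
  if (strand == "+") {
    ws <- ifelse(grid$arm == "5p", start - grid$d, end + grid$d - grid$L + 1L)
    we <- ws + grid$L - 1L
  } else {
    # in read orientation the mature's 5' end sits at genomic `end`
    we <- ifelse(grid$arm == "5p", end + grid$d, start - grid$d + grid$L - 1L)
    ws <- we - grid$L + 1L
  }
  ws <- pmax(ws, 1L)
  we <- pmin(we, glen)
  out <- tibble(w_start = as.integer(ws), w_end = as.integer(we),
                arm = grid$arm) |>
    filter(.data$w_end - .data$w_start + 1L >= min_len,
           .data$w_start <= start, .data$w_end >= end) |>
    dplyr::distinct(.data$w_start, .data$w_end, .keep_all = TRUE)
  win <- substring(genome[[contig]], out$w_start, out$w_end)
  if (strand == "-") win <- revcomp(win)
  off <- if (strand == "+") start - out$w_start else out$w_end - end
  out |> mutate(window = win, mature_offset = as.integer(off))
}

# rejection reasons ordered by how far the window got through the checks
REJECT_ORDER <- c("length_out_of_range", "energy_too_high", "no_hairpin",
                  "mature_in_loop", "too_many_mismatches")

#' Call a novel miRNA candidate from folded precursor windows
#'
#' Applies the plant-miRNA hairpin criteria to every candidate window of a
#' tag and accepts the best (lowest-MFE) window satisfying all of them:
#' mature length 20-23 nt; window MFE at or below `mfe_ceiling`; the window
#' folds into a single stem-loop; the mature lies entirely within one arm
#' (no loop overlap); and the mature/star duplex has a weighted mismatch
#' score of at most `max_duplex_mismatches`, read off the folded structure
#' (unpaired mature positions count 1, G:U pairs 0.5; bulges shift the
#' pairing register, so the structure is authoritative).
#' Rejections report the reason of the furthest-advancing window.
#'
#' @param windows window tibble from [excise_precursor_windows()].
#' @param tag the mature candidate sequence.
#' @param counts integer length-2 `(count_a, count_b)`.
#' @param mfe_ceiling maximum acceptable precursor MFE in kcal/mol
#'   (default -18).
#' @param max_duplex_mismatches mature/star duplex score ceiling (default 4).
#' @param fold_cache optional environment memoizing [fold_rna()] calls by
#'   window sequence.
#' @return list with `candidate` (one-row tibble or NULL) and `reason`
#'   (NULL or one of `r REJECT_ORDER`).
#' @export
call_novel_mirna <- function(windows, tag, counts = c(0L, 0L),
                             mfe_ceiling = -18, max_duplex_mismatches = 4,
                             fold_cache = NULL) {
  mlen <- nchar(tag)
  if (mlen < 20L || mlen > 23L) {
    return(list(candidate = NULL, reason = "length_out_of_range"))
  }
  if (is.null(fold_cache)) fold_cache <- new.env(parent = emptyenv())
  best <- NULL
  furthest <- "length_out_of_range"
  note <- function(reason) {
    if (match(reason, REJECT_ORDER) > match(furthest, REJECT_ORDER)) {
      furthest <<- reason
    }
  }
  for (i in seq_len(nrow(windows))) {
    win <- windows$window[i]
    f <- fold_cache[[win]]
    if (is.null(f)) {
      f <- fold_rna(win)
      fold_cache[[win]] <- f
    }
    if (f$mfe > mfe_ceiling) { note("energy_too_high"); next }
    if (!is_single_hairpin(f)) { note("no_hairpin"); next }
    mspan <- (windows$mature_offset[i] + 1L):(windows$mature_offset[i] + mlen)
    loop <- hairpin_loop_span(f)
    if (loop[1] <= loop[2] &&
        any(mspan >= loop[1] & mspan <= loop[2])) {
      note("mature_in_loop"); next
    }
    partners <- f$pairs[mspan]
    if (all(is.na(partners))) { note("too_many_mismatches"); next }
    star_span <- range(partners, na.rm = TRUE)
    star <- substr(win, star_span[1], star_span[2])
    # duplex mismatches read off the structure (robust to bulges that shift
    # the register): unpaired mature positions count 1, G:U pairs 0.5
    wchars <- strsplit(win, "")[[1]]
    pair_lab <- pair_label(wchars[mspan],
                           ifelse(is.na(partners), "A", wchars[partners]))
    mm <- sum(is.na(partners)) +
      0.5 * sum(!is.na(partners) & pair_lab %in% c("GU", "UG"))
    if (mm > max_duplex_mismatches) { note("too_many_mismatches"); next }
    if (is.null(best) || f$mfe < best$mfe) {
      best <- tibble(mature = tag, star = star, precursor = win,
                     dotbracket = f$dotbracket, mfe = f$mfe,
                     precursor_length = nchar(win),
                     arm = windows$arm[i],
                     w_start = windows$w_start[i], w_end = windows$w_end[i],
                     duplex_mismatches = mm,
                     count_a = counts[1], count_b = counts[2])
    }
  }
  if (is.null(best)) list(candidate = NULL, reason = furthest)
  else list(candidate = best, reason = NULL)
}

#' Discover novel miRNAs from unannotated tags
#'
#' The full discovery stage: keeps unannotated tags of mature length with a
#' minimum combined count, maps them to the genome (<= `max_mismatches`
#' substitutions), excises candidate precursor windows around every locus,
#' folds them, and calls candidates with [call_novel_mirna()]. Multi-locus
#' tags are reported once with their locus count (`n_loci`); counts are not
#' multiplied across loci.
#'
#' @param tags classified tag tibble from [classify_tags()] (two-library
#'   collapsed form).
#' @param genome named character vector of contigs.
#' @param min_count minimum `count_a + count_b` for a tag to enter discovery
#'   (default 3; singleton background never folds well and dominates
#'   runtime).
#' @param max_mismatches genome-mapping mismatch ceiling (default 1).
#' @inheritParams call_novel_mirna
#' @inheritParams excise_precursor_windows
#' @return tibble of accepted candidates with columns `id`, `mature`,
#'   `star`, `precursor`, `dotbracket`, `mfe`, `precursor_length`, `arm`,
#'   `contig`, `w_start`, `w_end`, `strand`, `n_loci`, `count_a`, `count_b`.
#'   The attribute `"rejections"` tabulates rejected tags by reason.
#' @export
discover_novel_mirnas <- function(tags, genome, min_count = 3L,
                                  max_mismatches = 1L, mfe_ceiling = -18,
                                  max_duplex_mismatches = 4,
                                  min_len = 62L, max_len = 96L,
                                  max_offset = 8L) {
  stopifnot("class" %in% names(tags))
  cand <- tags |>
    filter(.data$class == "unannotated",
           .data$count_a + .data$count_b >= min_count)
  mapped <- map_tags(cand, genome, max_mismatches = max_mismatches)
  cache <- new.env(parent = emptyenv())
  out <- list()
  rejections <- list()
  for (tg in unique(mapped$sequence)) {
    loci <- filter(mapped, .data$sequence == tg)
    cnt <- cand[match(tg, cand$sequence), ]
    res <- NULL
    for (li in seq_len(nrow(loci))) {
      win <- excise_precursor_windows(genome, loci$contig[li],
                                      loci$start[li], loci$end[li],
                                      loci$strand[li], min_len = min_len,
                                      max_len = max_len,
                                      max_offset = max_offset)
      r <- call_novel_mirna(win, tg,
                            counts = c(cnt$count_a, cnt$count_b),
                            mfe_ceiling = mfe_ceiling,
                            max_duplex_mismatches = max_duplex_mismatches,
                            fold_cache = cache)
      if (!is.null(r$candidate)) {
        r$candidate <- mutate(r$candidate, contig = loci$contig[li],
                              strand = loci$strand[li])
        if (is.null(res) || r$candidate$mfe < res$candidate$mfe) res <- r
      } else if (is.null(res)) {
        if (is.null(rejections[[tg]]) ||
            match(r$reason, REJECT_ORDER) >
            match(rejections[[tg]], REJECT_ORDER)) {
          rejections[[tg]] <- r$reason
        }
      }
    }
    if (!is.null(res)) {
      rejections[[tg]] <- NULL
      out[[tg]] <- mutate(res$candidate, n_loci = nrow(loci))
    }
  }
  res <- if (length(out)) {
    bind_rows(out) |>
      arrange(dplyr::desc(.data$count_a + .data$count_b)) |>
      mutate(id = sprintf("novel-%d", dplyr::row_number()), .before = 1)
  } else {
    tibble(id = character(), mature = character(), star = character(),
           precursor = character(), dotbracket = character(), mfe = numeric(),
           precursor_length = integer(), arm = character(),
           w_start = integer(), w_end = integer(), duplex_mismatches = numeric(),
           count_a = integer(), count_b = integer(), contig = character(),
           strand = character(), n_loci = integer())
  }
  rej <- tibble(sequence = names(rejections),
                reason = unlist(rejections, use.names = FALSE) %||% character())
  structure(res, rejections = rej)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Export novel miRNA candidates as GFF3
#'
#' Writes precursor loci as `miRNA_primary_transcript` features (1-based
#' inclusive coordinates, per GFF3), with mature id, MFE and counts carried
#' as attributes.
#'
#' @param candidates tibble from [discover_novel_mirnas()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_candidates_gff3 <- function(candidates, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = candidates$contig,
    ranges = IRanges::IRanges(candidates$w_start, candidates$w_end),
    strand = candidates$strand,
    type = "miRNA_primary_transcript",
    ID = candidates$id,
    mfe = candidates$mfe,
    count_a = candidates$count_a,
    count_b = candidates$count_b)
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}
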