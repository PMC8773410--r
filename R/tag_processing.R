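#' Read a FASTQ file into a read tibble
#'
#' Wraps [Biostrings::readDNAStringSet()] (Sanger Phred+33). On a malformed
#' file a light diagnostic pass locates the first offending record so the
#' error carries a record index.
#'
#' @param path FASTQ file path.
#' @return tibble with columns `id`, `seq`, `qual`.
#' @export
read_fastq <- function(path) {
  tryCatch({
    x <- Biostrings::readDNAStringSet(path, format = "fastq",
                                      with.qualities = TRUE)
    tibble(id = names(x),
           seq = as.character(x),
           qual = as.character(S4Vectors::mcols(x)$qualities))
  }, error = function(e) {
    idx <- locate_bad_fastq_record(path)
    stop("malformed FASTQ record at record index ", idx, " in ", path,
         ": ", conditionMessage(e), call. = FALSE)
  })
}

# best-effort scan for the first structurally broken 4-line FASTQ record
locate_bad_fastq_record <- function(path) {
  lines <- tryCatch(readLines(path, warn = FALSE), error = function(e) character())
  n_rec <- ceiling(length(lines) / 4)
  for (i in seq_len(n_rec)) {
    rec <- lines[(4 * (i - 1) + 1):min(4 * i, length(lines))]
    ok <- length(rec) == 4 && startsWith(rec[1], "@") && rec[3] == "+" ||
      (length(rec) == 4 && startsWith(rec[1], "@") && startsWith(rec[3], "+") &&
         nchar(rec[2]) == nchar(rec[4]))
    if (!ok) return(i)
  }
  n_rec
}

#' Trim 3' adaptors and filter raw small-RNA reads
#'
#' Locates the 3' adaptor in each read (exact match of the adaptor's first 8
#' bases anywhere in the read; failing that, a 7- then 6-base adaptor prefix
#' at the very end of the read), excises the insert, and filters by length
#' and quality. Discard classes are tallied per read: `no_adaptor`,
#' `too_short`, `too_long`, `ambiguous` (insert contains N), `low_quality`
#' (mean Phred of the insert below `quality_floor`).
#'
#' @param reads a read tibble from [read_fastq()] (columns `seq`, `qual`;
#'   `qual` may be absent for FASTA-derived input) or a FASTQ file path.
#' @param adaptor3 3' adaptor sequence (>= 6 nt; >= 8 nt recommended).
#' @param min_len,max_len retained insert length range (default 18-30 nt).
#' @param quality_floor minimum mean Phred score of the insert (default 20).
#' @return tibble of class `srna_clean` with columns `id`, `insert`,
#'   `status` (`kept` or a discard class); see [cleaning_accounting()].
#' @export
clean_reads <- function(reads, adaptor3, min_len = 18L, max_len = 30L,
                        quality_floor = 20) {
  if (is.character(reads) && length(reads) == 1L) reads <- read_fastq(reads)
  adaptor3 <- toupper(as_dna(adaptor3))
  if (nchar(adaptor3) < 6L) stop("adaptor3 must be at least 6 nt")
  sq <- toupper(as_dna(reads$seq))
  n <- length(sq)
  seed_len <- min(8L, nchar(adaptor3))
  seed <- substr(adaptor3, 1L, seed_len)
  pos <- unname(stringr::str_locate(sq, stringr::fixed(seed))[, "start"])
  # fall back to short adaptor prefixes flush with the read end
  for (ov in (seed_len - 1L):6L) {
    if (ov < 6L) break
    pre <- substr(adaptor3, 1L, ov)
    miss <- is.na(pos)
    if (!any(miss)) break
    hit <- miss & endsWith(sq, pre)
    pos[hit] <- nchar(sq[hit]) - ov + 1L
  }
  insert <- ifelse(is.na(pos), NA_character_, substr(sq, 1L, pos - 1L))
  len <- nchar(insert)
  status <- rep("kept", n)
  status[is.na(pos)] <- "no_adaptor"
  ok <- status == "kept"
  status[ok & len < min_len] <- "too_short"
  status[ok & len > max_len] <- "too_long"
  ok <- status == "kept"
  status[ok & grepl("N", insert, fixed = TRUE)] <- "ambiguous"
  ok <- status == "kept"
  if (!is.null(reads$qual) && any(ok)) {
    iq <- substr(reads$qual[ok], 1L, len[ok])
    mean_q <- vapply(iq, function(q) mean(utf8ToInt(q) - 33L), numeric(1),
                     USE.NAMES = FALSE)
    status[which(ok)[mean_q < quality_floor]] <- "low_quality"
  }
  out <- tibble(id = if (!is.null(reads$id)) reads$id else
                  sprintf("read_%d", seq_len(n)),
                insert = insert, status = status)
  class(out) <- c("srna_clean", class(out))
  out
}

#' Per-class accounting of a cleaning run
#'
#' @param x an `srna_clean` tibble from [clean_reads()].
#' @return tibble with one row per status (`kept` first) and columns
#'   `status`, `n`; the sum over rows equals the raw read count.
#' @export
cleaning_accounting <- function(x) {
  lv <- c("kept", "no_adaptor", "too_short", "too_long", "ambiguous",
          "low_quality")
  x |>
    count(status = factor(.data$status, levels = lv), .drop = FALSE) |>
    mutate(status = as.character(.data$status))
}

#' Collapse clean sequences into unique tags with per-library counts
#'
#' One row per distinct sequence; counts are occurrence tallies, so the
#' column sums equal the clean-read counts of each library. Collapsing an
#' already-collapsed tag set is a no-op. A single library may be collapsed
#' by omitting `b`.
#'
#' @param a,b clean sequences of the two libraries: character vectors or
#'   `srna_clean` tibbles (only `status == "kept"` inserts are used).
#' @return tibble with columns `sequence`, `count_a`, `count_b` (and only
#'   `count_a` when `b` is missing), sorted by decreasing total count.
#' @export
collapse_tags <- function(a, b = NULL) {
  pull_seq <- function(x) {
    if (inherits(x, "data.frame")) x$insert[x$status == "kept"] else x
  }
  tally <- function(s) {
    if (length(s) == 0) return(tibble(sequence = character(), n = integer()))
    as_tibble(table(sequence = s), n = "n") |>
      mutate(n = as.integer(.data$n))
  }
  ta <- tally(pull_seq(a))
  if (is.null(b)) {
    return(ta |> dplyr::rename(count_a = "n") |>
             arrange(dplyr::desc(.data$count_a), .data$sequence))
  }
  tb <- tally(pull_seq(b))
  dplyr::full_join(ta |> dplyr::rename(count_a = "n"),
                   tb |> dplyr::rename(count_b = "n"),
                   by = "sequence") |>
    mutate(count_a = dplyr::coalesce(.data$count_a, 0L),
           count_b = dplyr::coalesce(.data$count_b, 0L)) |>
    arrange(dplyr::desc(.data$count_a + .data$count_b), .data$sequence)
}

#' Library-level accounting arithmetic
#'
#' The identity each library satisfies: `specific = unique - common`, where
#' `common` is the number of sequences shared by both libraries. Provided as
#' a plain-arithmetic helper so printed totals can be checked directly.
#'
#' @param unique_a,unique_b distinct tag counts of the two libraries.
#' @param common number of shared distinct sequences.
#' @param clean_a,clean_b optional clean-read totals.
#' @return tibble with columns `library`, `unique_tags`, `common_tags`,
#'   `specific_tags`, `clean_reads` and a final `total` row.
#' @examples
#' tag_accounting(891186, 1403685, 220552, 13790887, 14571121)
#' @export
tag_accounting <- function(unique_a, unique_b, common,
                           clean_a = NA_real_, clean_b = NA_real_) {
  stopifnot(common <= unique_a, common <= unique_b)
  tibble(library = c("a", "b", "total"),
         unique_tags = c(unique_a, unique_b, unique_a + unique_b - common),
         common_tags = common,
         specific_tags = c(unique_a - common, unique_b - common,
                           unique_a + unique_b - 2 * common),
         clean_reads = c(clean_a, clean_b, clean_a + clean_b))
}

#' Overlap accounting of two collapsed libraries
#'
#' @param tags collapsed tag tibble from [collapse_tags()] (two-library
#'   form).
#' @return the [tag_accounting()] tibble computed from the tag set.
#' @export
library_overlap <- function(tags) {
  stopifnot(all(c("count_a", "count_b") %in% names(tags)))
  tag_accounting(unique_a = sum(tags$count_a > 0),
                 unique_b = sum(tags$count_b > 0),
                 common = sum(tags$count_a > 0 & tags$count_b > 0),
                 clean_a = sum(tags$count_a),
                 clean_b = sum(tags$count_b))
}

#' Length distribution of tags
#'
#' Histogram of tag lengths over a fixed range (default 10-32 nt, the
#' plotting window used for small-RNA length profiles); out-of-range lengths
#' are excluded. Weighting is by distinct sequences (`"unique"`) or by read
#' counts (`"abundance"`).
#'
#' @param tags collapsed tag tibble (one- or two-library form).
#' @param weight `"unique"` or `"abundance"`.
#' @param range integer length window (inclusive).
#' @return long tibble with columns `length`, `library`, `n` covering every
#'   length in `range` (zeros included).
#' @export
tag_length_histogram <- function(tags, weight = c("unique", "abundance"),
                                 range = c(10L, 32L)) {
  weight <- match.arg(weight)
  lens <- nchar(tags$sequence)
  keep <- lens >= range[1] & lens <= range[2]
  libs <- intersect(c("count_a", "count_b", "count"), names(tags))
  grid <- tidyr::expand_grid(length = seq(range[1], range[2]),
                             library = sub("count_?", "", libs))
  counts <- purrr::map(libs, function(cl) {
    cnt <- tags[[cl]][keep]
    w <- if (weight == "unique") as.integer(cnt > 0) else cnt
    tibble(length = lens[keep],
           library = sub("count_?", "", cl), w = w) |>
      group_by(.data$length, .data$library) |>
      summarise(n = sum(.data$w), .groups = "drop")
  }) |> bind_rows()
  grid |>
    left_join(counts, by = c("length", "library")) |>
    mutate(n = dplyr::coalesce(.data$n, 0L))
}
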