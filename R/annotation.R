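#' Classify tags against ordered reference sets
#'
#' Assigns each unique tag the class of the first reference set that
#' contains it, by exact full-length identity on the given strand; tags in
#' no set are `unannotated`. The default precedence (rRNA > tRNA > snRNA >
#' snoRNA > known_miRNA) reflects the convention of annotating structural
#' noncoding RNAs before mature miRNAs, and is configurable through the
#' order of `refsets`.
#'
#' @param tags collapsed tag tibble (column `sequence`).
#' @param refsets named list of reference sets in precedence order; each a
#'   character vector of sequences (names optional).
#' @return `tags` with an added `class` column; every tag receives exactly
#'   one class.
#' @export
classify_tags <- function(tags, refsets) {
  stopifnot(!is.null(names(refsets)))
  cls <- rep("unannotated", nrow(tags))
  for (nm in rev(names(refsets))) {
    hit <- tags$sequence %in% toupper(as_dna(refsets[[nm]]))
    cls[hit] <- nm
  }
  mutate(tags, class = cls)
}

#' Per-miRNA count and TPM profiles for known miRNAs
#'
#' Matches tags exactly (full length, no mismatches) against a mature miRNA
#' reference and reports, for every reference miRNA with a nonzero count in
#' either library, its counts, TPM values (normalized by the clean-read
#' totals) and presence class (`both` / `a_only` / `b_only`). Star sequences
#' carry their own reference ids (e.g. a `*` suffix) and are profiled as
#' separate features.
#'
#' @param tags collapsed two-library tag tibble.
#' @param mirna_ref named character vector of mature miRNA sequences.
#' @param totals numeric length-2: clean-read totals `(N_a, N_b)` used for
#'   TPM.
#' @return tibble with columns `mirna_id`, `sequence`, `count_a`, `count_b`,
#'   `tpm_a`, `tpm_b`, `presence`.
#' @export
profile_known_mirnas <- function(tags, mirna_ref, totals) {
  stopifnot(!is.null(names(mirna_ref)), length(totals) == 2L)
  ref <- tibble(mirna_id = names(mirna_ref),
                sequence = unname(toupper(as_dna(mirna_ref))))
  ref |>
    dplyr::inner_join(tags, by = "sequence") |>
    filter(.data$count_a + .data$count_b >= 1L) |>
    mutate(tpm_a = tpm(.data$count_a, totals[1]),
           tpm_b = tpm(.data$count_b, totals[2]),
           presence = dplyr::case_when(
             .data$count_a > 0 & .data$count_b > 0 ~ "both",
             .data$count_a > 0 ~ "a_only",
             TRUE ~ "b_only")) |>
    arrange(dplyr::desc(.data$count_a + .data$count_b))
}
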