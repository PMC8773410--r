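#' Apply the six plant miRNA target-prediction rules
#'
#' Evaluates an ungapped miRNA:target alignment (see [score_duplex()])
#' against the rule set used for plant miRNA target search, with miRNA
#' positions numbered 1-based from the 5' end:
#'
#' 1. total mismatch score <= `max_score` (G:U wobbles count 0.5);
#' 2. no run of three or more consecutive mismatches anywhere;
#' 3. no two adjacent mismatches within positions 2-12;
#' 4. positions 10 and 11 are not mismatches;
#' 5. mismatch score over positions 1-12 <= `max_seed_score`;
#' 6. duplex MFE at least `min_mfe_ratio` of the MFE of the miRNA bound to
#'    its perfect complement (compared on magnitudes of the negative
#'    energies).
#'
#' G:U wobbles are weighted in rules 1 and 5 but do not count as mismatches
#' for the adjacency rules 2-3 or for rule 4.
#'
#' @param alignment a `duplex_alignment` from [score_duplex()].
#' @param duplex_mfe,perfect_mfe energies from [duplex_energy()] and
#'   [perfect_duplex_energy()]; computed from the alignment when omitted.
#' @param max_score rule 1 threshold (default 4).
#' @param max_seed_score rule 5 threshold (default 2.5).
#' @param min_mfe_ratio rule 6 threshold (default 0.75).
#' @return named logical vector `rule1`..`rule6` (TRUE = rule satisfied).
#' @export
target_rules <- function(alignment, duplex_mfe = NULL, perfect_mfe = NULL,
                         max_score = 4, max_seed_score = 2.5,
                         min_mfe_ratio = 0.75) {
  stopifnot(inherits(alignment, "duplex_alignment"))
  st <- alignment$states
  L <- length(st)
  mm <- st == "mismatch"
  w <- c(match = 0, gu = 0.5, mismatch = 1)[st]
  runs <- rle(mm)
  adj_seed <- if (L < 3L) FALSE else {
    seed <- seq(2L, min(12L, L))
    any(mm[seed[-length(seed)]] & mm[seed[-1L]])
  }
  if (is.null(duplex_mfe)) {
    duplex_mfe <- duplex_energy(alignment)
  }
  if (is.null(perfect_mfe)) {
    perfect_mfe <- perfect_duplex_energy(alignment$mirna)
  }
  c(rule1 = sum(w) <= max_score,
    rule2 = !any(runs$values & runs$lengths >= 3L),
    rule3 = !adj_seed,
    rule4 = !any(mm[intersect(c(10L, 11L), seq_len(L))]),
    rule5 = sum(w[seq_len(min(12L, L))]) <= max_seed_score,
    rule6 = abs(duplex_mfe) >= min_mfe_ratio * abs(perfect_mfe))
}

# score + rules + energies for one miRNA against one window; returns a
# one-row tibble used by both the scanner and the truth-set validator.
evaluate_site <- function(mirna, window, max_score = 4, max_seed_score = 2.5,
                          min_mfe_ratio = 0.75) {
  aln <- score_duplex(mirna, window)
  dmfe <- duplex_energy(aln)
  pmfe <- perfect_duplex_energy(aln$mirna)
  rv <- target_rules(aln, dmfe, pmfe, max_score = max_score,
                     max_seed_score = max_seed_score,
                     min_mfe_ratio = min_mfe_ratio)
  tibble(score = aln$score,
         duplex_mfe = dmfe, perfect_mfe = pmfe,
         mfe_ratio = if (pmfe < 0) dmfe / pmfe else NA_real_,
         !!!as.list(rv),
         accepted = all(rv))
}

# weighted mismatch score of a miRNA against every window of a transcript,
# vectorized over window starts. Returns the numeric score per start.
window_scores <- function(m_chars, t_chars) {
  L <- length(m_chars)
  n <- length(t_chars)
  if (n < L) return(numeric(0))
  W <- n - L + 1L
  wc <- c(A = "T", C = "G", G = "C", T = "A")
  score <- numeric(W)
  starts <- seq_len(W)
  for (k in seq_len(L)) {
    tk <- t_chars[starts + L - k] # base opposite miRNA position k
    mk <- m_chars[k]
    s <- ifelse(tk == wc[[mk]], 0,
         ifelse((mk == "G" & tk == "T") | (mk == "T" & tk == "G"), 0.5, 1))
    score <- score + s
  }
  score
}

#' Scan transcripts for miRNA target sites
#'
#' Slides each miRNA over every window of every transcript (sense strand,
#' antiparallel duplex, ungapped), prefilters windows by total mismatch
#' score, then applies the full six-rule evaluation of [target_rules()] to
#' the surviving windows. By default only accepted sites are returned; with
#' `keep_rejected = TRUE` near-miss windows (score <= `max_score` + 2) are
#' retained with their per-rule verdicts for rejected-site reporting.
#'
#' @param mirnas named character vector of mature miRNA sequences.
#' @param transcripts named character vector of transcript sequences.
#' @inheritParams target_rules
#' @param keep_rejected keep scoring-window near misses with verdicts.
#' @return tibble with columns `mirna_id`, `transcript_id`, `site_start`
#'   (1-based position of the window on the transcript), `score`,
#'   `duplex_mfe`, `perfect_mfe`, `mfe_ratio`, `rule1`..`rule6`, `accepted`.
#' @export
predict_targets <- function(mirnas, transcripts, max_score = 4,
                            max_seed_score = 2.5, min_mfe_ratio = 0.75,
                            keep_rejected = FALSE) {
  stopifnot(!is.null(names(mirnas)), !is.null(names(transcripts)))
  mirnas <- toupper(as_dna(mirnas))
  transcripts <- toupper(as_dna(transcripts))
  cutoff <- if (keep_rejected) max_score + 2 else max_score
  t_split <- lapply(transcripts, function(s) strsplit(s, "")[[1]])
  rows <- list()
  for (mi in names(mirnas)) {
    m_chars <- strsplit(mirnas[[mi]], "")[[1]]
    L <- length(m_chars)
    for (ti in names(transcripts)) {
      sc <- window_scores(m_chars, t_split[[ti]])
      hits <- which(sc <= cutoff)
      for (s0 in hits) {
        win <- substr(transcripts[[ti]], s0, s0 + L - 1L)
        ev <- evaluate_site(mirnas[[mi]], win, max_score = max_score,
                            max_seed_score = max_seed_score,
                            min_mfe_ratio = min_mfe_ratio)
        rows[[length(rows) + 1L]] <-
          dplyr::bind_cols(tibble(mirna_id = mi, transcript_id = ti,
                                  site_start = s0), ev)
      }
    }
  }
  out <- if (length(rows)) bind_rows(rows) else
    dplyr::bind_cols(tibble(mirna_id = character(), transcript_id = character(),
                            site_start = integer()),
                     evaluate_site("A", "A")[0, ])
  if (!keep_rejected) out <- filter(out, .data$accepted)
  out
}

#' Unique genes among accepted target sites
#'
#' Deduplicates a hit table to the unique target gene list used for
#' functional (KOG) counting: multiple sites or multiple miRNAs hitting one
#' gene count it once.
#'
#' @param hits tibble from [predict_targets()].
#' @return character vector of unique transcript/gene ids with at least one
#'   accepted site.
#' @export
unique_target_genes <- function(hits) {
  sort(unique(hits$transcript_id[hits$accepted]))
}
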