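# Synthetic-data generator: genomes with planted miRNA hairpins, raw read
# libraries at two conditions with planted fold changes, reference sets, and
# transcripts carrying target sites that satisfy or individually violate each
# prediction rule. Everything is seeded and deterministic, and every planted
# fact is returned as a truth table so downstream stages can be tested
# without external data.

DEFAULT_ADAPTOR3 <- "TCGTATGCCGTCTTCTGCTT" # fixed 20-nt synthetic 3' adaptor

# length distribution of simulated small-RNA inserts: peaked at 21 nt, the
# Dicer-product mode real libraries show
sample_tag_lengths <- function(n, lens = 18:30, center = 21, sd = 2.2) {
  sample(lens, n, replace = TRUE, prob = stats::dnorm(lens, center, sd))
}

#' Default 3' adaptor used by the simulator
#' @return a 20-nt adaptor sequence string.
#' @export
default_adaptor <- function() DEFAULT_ADAPTOR3

# one hairpin: 5' arm + loop + 3' arm ~ revcomp(5' arm) with <= 3 mutations;
# the mature sits within max_offset nt of one precursor end so the window
# sweep of the discovery stage can recover it exactly.
make_hairpin <- function(prec_len, mature_len, max_offset = 8L) {
  loop_len <- sample(6:9, 1)
  arm <- (prec_len - loop_len) %/% 2L
  loop_len <- prec_len - 2L * arm
  arm5 <- random_dna(1, arm, gc = 0.55)
  arm_side <- sample(c("5p", "3p"), 1)
  d <- sample(0:min(max_offset, arm - mature_len), 1)
  m_start <- if (arm_side == "5p") d + 1L else prec_len - d - mature_len + 1L
  m_end <- m_start + mature_len - 1L
  # mutate the 3' arm: 2-3 substitutions inside the region opposite the
  # mature (or inside the mature itself when it sits on the 3' arm), so the
  # mature never cross-maps onto the star arm within one mismatch. Wherever
  # possible the substitution turns a Watson-Crick pair into a G:U wobble
  # (C->T opposite G, A->G opposite U), keeping the stem paired so the
  # mature/star duplex stays well under 4 structural mismatches; at most one
  # further substitution lands elsewhere in the arm.
  arm3_local <- function(p) p - (arm + loop_len)
  duplex_win <- if (arm_side == "5p") {
    arm3_local((prec_len - m_end + 1L):(prec_len - m_start + 1L))
  } else {
    arm3_local(m_start:m_end)
  }
  duplex_win <- duplex_win[duplex_win >= 1L & duplex_win <= arm]
  ch <- strsplit(revcomp(arm5), "")[[1]]
  n_dup <- sample(2:3, 1)
  wobble_ok <- duplex_win[ch[duplex_win] %in% c("A", "C")]
  wob_at <- sample(wobble_ok, min(length(wobble_ok), n_dup))
  mm_at <- sample(setdiff(duplex_win, wob_at),
                  max(0L, n_dup - length(wob_at)))
  for (p in wob_at) ch[p] <- if (ch[p] == "C") "T" else "G"
  for (p in c(mm_at,
              sample(setdiff(seq_len(arm), duplex_win), sample(0:1, 1)))) {
    ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1)
  }
  prec <- paste0(arm5, random_dna(1, loop_len, gc = 0.3),
                 paste(ch, collapse = ""))
  mature <- substr(prec, m_start, m_end)
  star <- substr(prec, prec_len - m_end + 1L, prec_len - m_start + 1L)
  list(precursor = prec, mature = mature, star = star, arm = arm_side,
       mature_start = m_start)
}

#' Build a genome with planted miRNA hairpins
#'
#' Generates random contigs and plants `n_hairpins` fold-back precursors
#' (62-96 nt, mature 20-23 nt within 8 nt of a precursor end, mature/star
#' duplex with at most 3 mismatches) at non-overlapping loci separated by
#' random flanks. About 30% of miRNAs are multi-locus (2-5 identical copies;
#' when there are at least ten hairpins, one miRNA gets 9 loci). Each miRNA
#' carries planted TPM values for the two conditions: a log2 fold change
#' drawn from `log2fc_values` and a baseline TPM log-uniform on `tpm_range`;
#' the less-expressed side of each pair sits at the baseline, so both counts
#' of every planted feature stay in the detectable range at the default
#' depth.
#'
#' @param n_hairpins number of distinct miRNA hairpins to plant.
#' @param genome_length total genome length in nt (split over `n_contigs`).
#' @param seed integer seed; fully determines the output.
#' @param n_contigs number of contigs (default 2).
#' @param tpm_range baseline (less-expressed side) TPM range (default
#'   `c(100, 500)`), chosen so every planted feature keeps expected counts
#'   of roughly 20 or more in both libraries at the default 200,000-read
#'   depth.
#' @param log2fc_values planted log2 fold changes to sample from.
#' @return list with `genome` (named character), `hairpins` (truth tibble:
#'   `id`, `mature`, `star`, `precursor`, `arm`, `n_loci`, `tpm_a`, `tpm_b`,
#'   `log2fc_true`) and `loci` (tibble `id`, `contig`, `start`, `end`,
#'   `strand`, 1-based inclusive coordinates of each planted precursor
#'   copy).
#' @export
simulate_genome_hairpins <- function(n_hairpins = 30L, genome_length = 50000L,
                                     seed = 1L, n_contigs = 2L,
                                     tpm_range = c(100, 500),
                                     log2fc_values = c(-3, -2, -1, 0, 0, 1, 2, 3)) {
  withr::local_seed(seed)
  if (n_hairpins == 0L) {
    contigs <- setNames(random_dna(n_contigs, genome_length %/% n_contigs),
                        sprintf("contig_%d", seq_len(n_contigs)))
    return(list(genome = contigs,
                hairpins = tibble(id = character(), mature = character(),
                                  star = character(), precursor = character(),
                                  arm = character(), n_loci = integer(),
                                  tpm_a = numeric(), tpm_b = numeric(),
                                  log2fc_true = numeric()),
                loci = tibble(id = character(), contig = character(),
                              start = integer(), end = integer(),
                              strand = character())))
  }
  hp <- purrr::map(seq_len(n_hairpins), function(i) {
    make_hairpin(prec_len = sample(62:96, 1),
                 mature_len = sample(20:23, 1,
                                     prob = c(0.25, 0.4, 0.2, 0.15)))
  })
  n_multi <- round(0.3 * n_hairpins)
  n_loci <- rep(1L, n_hairpins)
  if (n_multi >= 1L) {
    multi <- sample(n_hairpins, n_multi)
    n_loci[multi] <- sample(2:5, n_multi, replace = TRUE)
    if (n_hairpins >= 10L) n_loci[multi[1]] <- 9L
  }
  base_tpm <- 10^runif(n_hairpins, log10(tpm_range[1]), log10(tpm_range[2]))
  fc <- sample(log2fc_values, n_hairpins, replace = TRUE)
  # the less-expressed side of each pair sits at baseline, so both counts of
  # every planted feature stay in the detectable range at the default depth
  tpm_a <- ifelse(fc >= 0, base_tpm, base_tpm * 2^(-fc))
  tpm_b <- tpm_a * 2^fc
  hairpins <- tibble(
    id = sprintf("mir-%02d", seq_len(n_hairpins)),
    mature = purrr::map_chr(hp, "mature"),
    star = purrr::map_chr(hp, "star"),
    precursor = purrr::map_chr(hp, "precursor"),
    arm = purrr::map_chr(hp, "arm"),
    n_loci = n_loci,
    tpm_a = tpm_a, tpm_b = tpm_b, log2fc_true = fc)
  # place every precursor copy on random contigs without overlap
  total_loci <- sum(n_loci)
  placements <- tibble(
    id = rep(hairpins$id, n_loci),
    precursor = rep(hairpins$precursor, n_loci),
    strand = sample(c("+", "-"), total_loci, replace = TRUE))
  contig_len <- rep(genome_length %/% n_contigs, n_contigs)
  gap <- 40L
  need <- sum(nchar(placements$precursor) + gap)
  if (need > sum(contig_len) - gap * n_contigs) {
    stop("genome_length too small to place ", total_loci,
         " precursor copies without overlap")
  }
  ord <- sample(total_loci)
  placements <- placements[ord, ]
  assign_contig <- sort(rep_len(seq_len(n_contigs), total_loci))
  contigs <- character(n_contigs)
  loci <- list()
  for (ci in seq_len(n_contigs)) {
    rows <- placements[assign_contig == ci, ]
    pieces <- character(0)
    pos <- 0L
    # random slack distributed between precursors
    slack_total <- contig_len[ci] - sum(nchar(rows$precursor))
    if (slack_total < (nrow(rows) + 1L) * 10L) {
      stop("genome_length too small to place precursors without overlap")
    }
    cuts <- sort(sample(seq_len(slack_total - 1L), nrow(rows)))
    slacks <- diff(c(0L, cuts))
    for (ri in seq_len(nrow(rows))) {
      filler <- random_dna(1, slacks[ri])
      pieces <- c(pieces, filler)
      pos <- pos + slacks[ri]
      ins <- if (rows$strand[ri] == "+") rows$precursor[ri] else
        revcomp(rows$precursor[ri])
      pieces <- c(pieces, ins)
      loci[[length(loci) + 1L]] <-
        tibble(id = rows$id[ri], contig = sprintf("contig_%d", ci),
               start = pos + 1L, end = pos + nchar(ins),
               strand = rows$strand[ri])
      pos <- pos + nchar(ins)
    }
    pieces <- c(pieces, random_dna(1, contig_len[ci] - pos))
    contigs[ci] <- paste(pieces, collapse = "")
  }
  names(contigs) <- sprintf("contig_%d", seq_len(n_contigs))
  list(genome = contigs, hairpins = hairpins, loci = bind_rows(loci))
}

#' Simulated reference sets for annotation
#'
#' Builds pools of noncoding-RNA fragment sequences (rRNA, tRNA, snRNA,
#' snoRNA; 18-30 nt each, mimicking the degradation fragments a small-RNA
#' library actually contains) plus a mature "known miRNA" reference of
#' 20-23 nt sequences with planted TPM pairs drawn like the hairpins'.
#'
#' @param seed integer seed.
#' @param n_fragments named integer vector: fragment pool sizes per ncRNA
#'   class.
#' @param n_known number of known mature miRNAs.
#' @inheritParams simulate_genome_hairpins
#' @return list with `refsets` (named list of named character vectors, in
#'   annotation precedence order) and `known` (tibble `id`, `sequence`,
#'   `tpm_a`, `tpm_b`, `log2fc_true`).
#' @export
simulate_reference_sets <- function(seed = 1L,
                                    n_fragments = c(rRNA = 150L, tRNA = 120L,
                                                    snRNA = 60L, snoRNA = 60L),
                                    n_known = 20L,
                                    tpm_range = c(100, 500),
                                    log2fc_values = c(-3, -2, -1, 0, 0, 1, 2, 3)) {
  withr::local_seed(seed)
  refsets <- purrr::imap(as.list(n_fragments), function(n, nm) {
    setNames(random_dna(n, sample_tag_lengths(n)),
             sprintf("%s_frag_%03d", nm, seq_len(n)))
  })
  base_tpm <- 10^runif(n_known, log10(tpm_range[1]), log10(tpm_range[2]))
  fc <- sample(log2fc_values, n_known, replace = TRUE)
  tpm_a <- ifelse(fc >= 0, base_tpm, base_tpm * 2^(-fc))
  known <- tibble(id = sprintf("known-mir-%02d", seq_len(n_known)),
                  sequence = random_dna(n_known,
                                        sample(20:23, n_known, replace = TRUE)),
                  tpm_a = tpm_a, tpm_b = tpm_a * 2^fc, log2fc_true = fc)
  refsets$known_miRNA <- setNames(known$sequence, known$id)
  list(refsets = refsets, known = known)
}

#' Library simulation settings
#'
#' @param depth total clean reads to emit.
#' @param adaptor3 3' adaptor ligated to every insert.
#' @param error_rate per-base substitution error rate in `[0, 1)`.
#' @param background_fraction fraction of background (non-miRNA) reads drawn
#'   from the ncRNA fragment references; the rest are uniform random
#'   18-30-mers emulating unannotated degradation products.
#' @param read_length fixed raw read length (insert + adaptor + padding).
#' @param seed integer seed; fully determines the emitted reads.
#' @return list of class `library_sim_spec`.
#' @export
library_sim_spec <- function(depth, adaptor3 = default_adaptor(),
                             error_rate = 0.005, background_fraction = 0.5,
                             read_length = 40L, seed = 1L) {
  stopifnot(depth >= 1, error_rate >= 0, error_rate < 1,
            background_fraction >= 0, background_fraction <= 1)
  structure(list(depth = as.integer(depth), adaptor3 = toupper(adaptor3),
                 error_rate = error_rate,
                 background_fraction = background_fraction,
                 read_length = as.integer(read_length),
                 seed = as.integer(seed)),
            class = "library_sim_spec")
}

# draw reads for one library; returns tibble(id, seq, qual) plus bookkeeping
simulate_one_library <- function(inserts, tpms, spec, refsets, prefix) {
  withr::local_seed(spec$seed)
  counts <- rpois(length(inserts), tpms * spec$depth / 1e6)
  n_mirna <- sum(counts)
  n_bg <- max(0L, spec$depth - n_mirna)
  ref_pool <- unlist(lapply(refsets, unname), use.names = FALSE)
  n_ref <- if (length(ref_pool)) round(n_bg * spec$background_fraction) else 0L
  bg <- c(if (n_ref > 0) sample(ref_pool, n_ref, replace = TRUE),
          random_dna(n_bg - n_ref, sample_tag_lengths(n_bg - n_ref)))
  all_inserts <- c(rep(inserts, counts), bg)
  all_inserts <- sample(all_inserts) # shuffle read order
  reads <- substr(paste0(all_inserts, spec$adaptor3,
                         strrep("A", spec$read_length)),
                  1L, spec$read_length)
  if (spec$error_rate > 0) {
    n <- length(reads)
    n_err <- rpois(1, n * spec$read_length * spec$error_rate)
    if (n_err > 0) {
      at_read <- sample(n, n_err, replace = TRUE)
      at_pos <- sample(spec$read_length, n_err, replace = TRUE)
      for (k in seq_len(n_err)) {
        old <- substr(reads[at_read[k]], at_pos[k], at_pos[k])
        substr(reads[at_read[k]], at_pos[k], at_pos[k]) <-
          sample(setdiff(c("A", "C", "G", "T"), old), 1)
      }
    }
  }
  list(reads = tibble(id = sprintf("%s_read_%d", prefix, seq_along(reads)),
                      seq = reads,
                      qual = strrep("I", spec$read_length)),
       counts = counts, n_background = n_bg)
}

#' Simulate two raw small-RNA libraries from planted truth
#'
#' Per-miRNA counts are drawn Poisson with mean `tpm x depth / 1e6`; each
#' emitted read is the insert followed by the 3' adaptor (padded to a fixed
#' read length, substitution-mutated at `error_rate`). Background reads fill
#' the library to its target depth: a `background_fraction` share sampled
#' from the ncRNA fragment references, the rest uniform random 18-30-mers.
#' The expected count table is recorded for recovery tests, and per-library
#' read counts conserve exactly: depth = miRNA reads + background reads.
#'
#' @param hairpins truth tibble from [simulate_genome_hairpins()].
#' @param spec_a,spec_b [library_sim_spec()] objects for the control (a) and
#'   nitrogen-deprived (b) libraries.
#' @param refsets reference list from [simulate_reference_sets()] (used for
#'   background sampling); NULL for purely random background.
#' @param known known-miRNA tibble from [simulate_reference_sets()]; its
#'   sequences are emitted with their own TPM pairs.
#' @return list with `reads_a`, `reads_b` (read tibbles), `expected` (tibble
#'   `id`, `sequence`, `type`, `count_a`, `count_b`: realized planted
#'   counts) and `n_background` (named integer vector).
#' @export
simulate_libraries <- function(hairpins, spec_a, spec_b, refsets = NULL,
                               known = NULL) {
  stopifnot(inherits(spec_a, "library_sim_spec"),
            inherits(spec_b, "library_sim_spec"))
  feats <- bind_rows(
    tibble(id = hairpins$id, sequence = hairpins$mature, type = "novel",
           tpm_a = hairpins$tpm_a, tpm_b = hairpins$tpm_b),
    if (!is.null(known))
      tibble(id = known$id, sequence = known$sequence, type = "known",
             tpm_a = known$tpm_a, tpm_b = known$tpm_b))
  if (nrow(feats) == 0 && spec_a$background_fraction < 1) {
    stop("no planted features: background_fraction must be 1")
  }
  ref_frag <- if (is.null(refsets)) list() else
    refsets[setdiff(names(refsets), "known_miRNA")]
  a <- simulate_one_library(feats$sequence, feats$tpm_a, spec_a, ref_frag, "a")
  b <- simulate_one_library(feats$sequence, feats$tpm_b, spec_b, ref_frag, "b")
  list(reads_a = a$reads, reads_b = b$reads,
       expected = tibble(id = feats$id, sequence = feats$sequence,
                         type = feats$type,
                         count_a = a$counts, count_b = b$counts),
       n_background = c(a = a$n_background, b = b$n_background))
}

#' Write a read tibble as FASTQ (Sanger Phred+33)
#'
#' @param reads tibble with columns `id`, `seq`, `qual`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  x <- Biostrings::DNAStringSet(setNames(reads$seq, reads$id))
  Biostrings::writeXStringSet(x, path, format = "fastq",
                              qualities = Biostrings::BStringSet(reads$qual))
  invisible(path)
}
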