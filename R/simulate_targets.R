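# Planted target sites: for each prediction rule, transcripts carrying a
# site that violates exactly that rule (and sites violating nothing). Each
# modification set is validated against the package's own scorer before it
# is emitted, so a site tagged "rule4" is guaranteed to fail rule 4 and only
# rule 4.

# bases that mismatch miRNA base m (neither Watson-Crick nor wobble partner)
mismatch_choices <- function(m) {
  switch(m,
         A = c("A", "C", "G"),
         C = c("A", "C", "T"),
         G = c("A", "G"),
         T = c("C", "T"))
}

# apply a modification set to the perfect-complement window of `mature`;
# mods is a list of list(pos = miRNA position, kind = "mismatch"|"gu")
modified_window <- function(mature, mods) {
  m <- strsplit(mature, "")[[1]]
  L <- length(m)
  w <- strsplit(revcomp(mature), "")[[1]]
  for (md in mods) {
    wi <- L + 1L - md$pos
    if (md$kind == "gu") {
      w[wi] <- switch(m[md$pos], G = "T", T = "G",
                      stop("no wobble partner for base ", m[md$pos]))
    } else {
      w[wi] <- sample(mismatch_choices(m[md$pos]), 1)
    }
  }
  paste(w, collapse = "")
}

# random candidate modification sets aiming at one specific rule violation
propose_mods <- function(mature, violation) {
  m <- strsplit(mature, "")[[1]]
  L <- length(m)
  gu_ok <- which(m %in% c("G", "T"))
  gu_seed <- intersect(gu_ok, 1:12)
  gu_tail <- setdiff(gu_ok, 1:12)
  mm <- function(pos) lapply(pos, function(p) list(pos = p, kind = "mismatch"))
  gu <- function(pos) lapply(pos, function(p) list(pos = p, kind = "gu"))
  switch(violation,
    none = list(),
    rule1 = {
      # weight > 4 via wobbles only (pairing intact, rule 6 keeps holding):
      # seed weight capped at 2.5, the rest beyond position 12
      if (length(gu_tail) < 4L) return(NULL)
      tail_pick <- sample(gu_tail, min(length(gu_tail), sample(4:5, 1)))
      need_seed <- 4.5 - 0.5 * length(tail_pick) # target total weight 4.5
      if (length(gu_seed) >= 2 * need_seed && stats::runif(1) < 0.7) {
        c(gu(sample(gu_seed, 2 * need_seed)), gu(tail_pick))
      } else if (need_seed >= 1.5 &&
                 length(setdiff(gu_seed, 1L)) >= 2 * (need_seed - 1)) {
        c(mm(1L), gu(sample(setdiff(gu_seed, 1L), 2 * (need_seed - 1))),
          gu(tail_pick))
      } else NULL
    },
    rule2 = {
      p <- sample(13:(L - 2L), 1)
      mm(p:(p + 2L))
    },
    rule3 = {
      p <- sample(4:8, 1)
      mm(c(p, p + 1L))
    },
    rule4 = mm(sample(10:11, 1)),
    rule5 = {
      if (length(gu_seed) >= 6 && stats::runif(1) < 0.5) {
        gu(sample(gu_seed, 6))
      } else if (length(setdiff(gu_seed, 1:2)) >= 4) {
        c(mm(1L), gu(sample(setdiff(gu_seed, 1:2), 4)))
      } else NULL
    },
    rule6 = {
      pool <- seq(13L, L - 1L, by = 2L)
      mm(sample(pool, min(4L, length(pool))))
    },
    stop("unknown violation: ", violation))
}

# verdicts must show exactly the tagged rule failing (all six TRUE for none)
verdict_matches <- function(ev, violation) {
  rv <- unlist(ev[paste0("rule", 1:6)])
  if (violation == "none") all(rv)
  else !rv[[violation]] && all(rv[setdiff(names(rv), violation)])
}

#' Simulate transcripts with planted miRNA target sites
#'
#' For every rule of the target-prediction rule set (see [target_rules()]),
#' plants `n_sites_per_rule` sites that violate exactly that rule, plus the
#' same number of clean sites (perfect or rule-respecting complements).
#' Modification sets are drawn per miRNA and validated with the package's
#' own scorer; a violation that cannot be realized for any supplied miRNA is
#' a construction error naming the rule. Each transcript carries one site
#' embedded in random flanks; decoy transcripts carry none. A gene-to-KOG
#' mapping table is emitted alongside, with a fraction of genes deliberately
#' left unannotated.
#'
#' @param mirnas named character vector of mature miRNA sequences (e.g.
#'   `setNames(hairpins$mature, hairpins$id)`).
#' @param n_sites_per_rule sites per violation class (default 2).
#' @param n_decoys transcripts without any planted site (default 20).
#' @param transcript_length total transcript length (default 300 nt).
#' @param seed integer seed.
#' @param unannotated_fraction genes omitted from the KOG map (default 0.1).
#' @param max_tries random proposals per (miRNA, violation) before moving to
#'   the next miRNA.
#' @return list with `transcripts` (named character), `sites` (tibble
#'   `transcript_id`, `site_start` 1-based, `mirna_id`, `violation`,
#'   `expected_pass`) and `kog_map` (tibble `gene_id`, `kog_id`,
#'   `category_letter`).
#' @export
simulate_target_transcripts <- function(mirnas, n_sites_per_rule = 2L,
                                        n_decoys = 20L,
                                        transcript_length = 300L, seed = 1L,
                                        unannotated_fraction = 0.1,
                                        max_tries = 40L) {
  stopifnot(!is.null(names(mirnas)), n_sites_per_rule >= 1L)
  withr::local_seed(seed)
  mirnas <- toupper(as_dna(mirnas))
  violations <- c("none", paste0("rule", 1:6))
  transcripts <- character(0)
  sites <- list()
  t_idx <- 0L
  for (v in violations) {
    made <- 0L
    order_m <- sample(names(mirnas))
    for (mi in rep(order_m, length.out = length(order_m) * 3L)) {
      if (made >= n_sites_per_rule) break
      mature <- mirnas[[mi]]
      win <- NULL
      for (try in seq_len(max_tries)) {
        mods <- propose_mods(mature, v)
        if (is.null(mods) && v != "none") break
        cand <- modified_window(mature, mods)
        ev <- evaluate_site(mature, cand)
        if (verdict_matches(ev, v)) { win <- cand; break }
      }
      if (is.null(win)) next
      t_idx <- t_idx + 1L
      L <- nchar(win)
      pos <- sample(seq(20L, transcript_length - L - 20L), 1)
      tx <- paste0(random_dna(1, pos - 1L), win,
                   random_dna(1, transcript_length - pos + 1L - L))
      id <- sprintf("gene_%03d", t_idx)
      transcripts[id] <- tx
      sites[[length(sites) + 1L]] <-
        tibble(transcript_id = id, site_start = pos, mirna_id = mi,
               violation = v, expected_pass = v == "none")
      made <- made + 1L
    }
    if (made < n_sites_per_rule) {
      stop("could not construct ", n_sites_per_rule, " sites violating ", v,
           " for the supplied miRNAs (", made, " built)")
    }
  }
  for (k in seq_len(n_decoys)) {
    t_idx <- t_idx + 1L
    transcripts[sprintf("gene_%03d", t_idx)] <-
      random_dna(1, transcript_length)
  }
  kog_map <- simulate_kog_map(names(transcripts), unannotated_fraction)
  list(transcripts = transcripts, sites = bind_rows(sites), kog_map = kog_map)
}

# gene -> KOG assignment table with a composition loosely matching what a
# mixed eukaryotic gene set looks like (signalling, transcription and
# general-prediction categories heavy, lipid metabolism well represented)
simulate_kog_map <- function(gene_ids, unannotated_fraction = 0.1) {
  letters25 <- kog_categories$category_letter
  w <- rep(1, length(letters25))
  names(w) <- letters25
  w[c("T", "K", "R", "I", "O", "G")] <- c(4, 3, 3, 2.5, 2, 2)
  keep <- stats::runif(length(gene_ids)) >= unannotated_fraction
  ids <- gene_ids[keep]
  tibble(gene_id = ids,
         kog_id = sprintf("KOG%04d", sample(4000L, length(ids), replace = TRUE)),
         category_letter = sample(letters25, length(ids), replace = TRUE,
                                  prob = w))
}

#' Simulate a complete small-RNA experiment with ground truth
#'
#' One-call wrapper around the generator: genome with planted hairpins,
#' reference sets, two raw libraries at the given depths, and a transcript
#' set with planted target sites and KOG map. When `outdir` is given, all
#' inputs are written as plain files (FASTA/FASTQ/TSV) laid out the way
#' [run_pipeline()] expects.
#'
#' @inheritParams simulate_genome_hairpins
#' @param depth_a,depth_b clean-read depths of the two libraries.
#' @param error_rate,background_fraction passed to [library_sim_spec()].
#' @param n_sites_per_rule passed to [simulate_target_transcripts()].
#' @param outdir optional directory to write all files into.
#' @return list with `genome`, `hairpins`, `loci`, `refsets`, `known`,
#'   `reads_a`, `reads_b`, `expected`, `n_background`, `transcripts`,
#'   `sites`, `kog_map`, `adaptor3` and (when written) `paths`.
#' @export
simulate_srna_experiment <- function(n_hairpins = 30L, depth_a = 200000L,
                                     depth_b = 200000L, seed = 1L,
                                     genome_length = 50000L,
                                     error_rate = 0.005,
                                     background_fraction = 0.5,
                                     n_sites_per_rule = 2L, outdir = NULL) {
  gen <- simulate_genome_hairpins(n_hairpins = n_hairpins,
                                  genome_length = genome_length, seed = seed)
  refs <- simulate_reference_sets(seed = seed + 1000L)
  spec_a <- library_sim_spec(depth_a, error_rate = error_rate,
                             background_fraction = background_fraction,
                             seed = seed + 2000L)
  spec_b <- library_sim_spec(depth_b, error_rate = error_rate,
                             background_fraction = background_fraction,
                             seed = seed + 3000L)
  libs <- simulate_libraries(gen$hairpins, spec_a, spec_b,
                             refsets = refs$refsets, known = refs$known)
  tgt <- if (n_hairpins > 0) {
    simulate_target_transcripts(setNames(gen$hairpins$mature,
                                         gen$hairpins$id),
                                n_sites_per_rule = n_sites_per_rule,
                                seed = seed + 4000L)
  } else list(transcripts = character(0),
              sites = tibble(), kog_map = tibble())
  out <- c(gen, refs, libs, tgt, list(adaptor3 = spec_a$adaptor3))
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    p <- list(
      genome = file.path(outdir, "genome.fa"),
      reads_a = file.path(outdir, "reads_a.fastq"),
      reads_b = file.path(outdir, "reads_b.fastq"),
      transcripts = file.path(outdir, "transcripts.fa"),
      kog_map = file.path(outdir, "kog_map.tsv"))
    write_fasta(gen$genome, p$genome)
    write_fastq(libs$reads_a, p$reads_a)
    write_fastq(libs$reads_b, p$reads_b)
    if (length(tgt$transcripts)) write_fasta(tgt$transcripts, p$transcripts)
    readr::write_tsv(tgt$kog_map, p$kog_map, col_names = FALSE)
    for (nm in names(refs$refsets)) {
      p[[paste0("ref_", nm)]] <- file.path(outdir, paste0("ref_", nm, ".fa"))
      write_fasta(refs$refsets[[nm]], p[[paste0("ref_", nm)]])
    }
    readr::write_tsv(gen$hairpins, file.path(outdir, "truth_hairpins.tsv"))
    readr::write_tsv(libs$expected, file.path(outdir, "truth_counts.tsv"))
    if (nrow(tgt$sites)) {
      readr::write_tsv(tgt$sites, file.path(outdir, "truth_sites.tsv"))
    }
    out$paths <- p
  }
  out
}
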