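#' Pipeline configuration
#'
#' A single flat configuration object holding all input paths and stage
#' thresholds, with every threshold at its standard default. Round-trips
#' through YAML unchanged ([write_config()] / [read_config()]).
#'
#' @param reads_a,reads_b FASTQ paths of the control and nitrogen-deprived
#'   libraries.
#' @param genome genome FASTA path.
#' @param refsets named character vector of reference FASTA paths in
#'   annotation precedence order (the `known_miRNA` entry doubles as the
#'   known-miRNA reference).
#' @param transcripts transcript FASTA path (optional; skips target stages
#'   when NULL).
#' @param kog_map gene-to-KOG TSV path (optional).
#' @param outdir output directory for all stage tables.
#' @param adaptor3 3' adaptor sequence.
#' @param min_len,max_len,quality_floor tag cleaning thresholds.
#' @param min_count,max_mismatches,mfe_ceiling,max_duplex_mismatches novel
#'   miRNA discovery thresholds.
#' @param min_tpm,lfc_threshold,alpha,strict_alpha differential-expression
#'   thresholds.
#' @param max_score,max_seed_score,min_mfe_ratio target-prediction
#'   thresholds.
#' @param seed integer seed (reserved for stages with sampling; the
#'   pipeline itself is deterministic).
#' @param verbose print per-stage progress to stderr.
#' @return list of class `nitromir_config`.
#' @export
pipeline_config <- function(reads_a, reads_b, genome, refsets,
                            transcripts = NULL, kog_map = NULL,
                            outdir = "nitromir_out",
                            adaptor3 = default_adaptor(),
                            min_len = 18L, max_len = 30L, quality_floor = 20,
                            min_count = 3L, max_mismatches = 1L,
                            mfe_ceiling = -18, max_duplex_mismatches = 4,
                            min_tpm = 1, lfc_threshold = 1, alpha = 0.05,
                            strict_alpha = 0.01, max_score = 4,
                            max_seed_score = 2.5, min_mfe_ratio = 0.75,
                            seed = 1L, verbose = TRUE) {
  cfg <- as.list(environment())
  structure(cfg, class = "nitromir_config")
}

#' @rdname pipeline_config
#' @param config a `nitromir_config`.
#' @param path YAML file path.
#' @export
write_config <- function(config, path) {
  cfg <- unclass(config)
  cfg$refsets <- as.list(cfg$refsets) # keep names through YAML
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  cfg$refsets <- unlist(cfg$refsets)
  do.call(pipeline_config, cfg)
}

#' Run the full small-RNA analysis pipeline
#'
#' Executes the stages in fixed order: read cleaning, tag collapsing and
#' accounting, classification against the reference sets, known-miRNA
#' profiling, novel miRNA discovery, differential expression of known +
#' novel miRNAs, target prediction for the significant miRNAs, and KOG
#' summarization of the unique target genes. Every intermediate table is
#' written to `config$outdir` as TSV; identical config and inputs give
#' identical outputs. A stage failure aborts with the stage name.
#'
#' @param config a [pipeline_config()] object.
#' @return invisible list with `accounting_a`, `accounting_b`, `tags`,
#'   `overlap`, `length_histogram`, `known_profile`, `novel`, `de`,
#'   `target_hits`, `kog_summary`, `kog_main_summary` (the last three NULL
#'   without transcript/KOG inputs).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "nitromir_config"))
  say <- function(...) if (config$verbose) message("[nitromir] ", ...)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  out <- list()

  clean_a <- stage("tag_processing", {
    x <- clean_reads(config$reads_a, config$adaptor3, config$min_len,
                     config$max_len, config$quality_floor)
    if (nrow(x) == 0L) stop("no reads in ", config$reads_a)
    x
  })
  clean_b <- stage("tag_processing", {
    x <- clean_reads(config$reads_b, config$adaptor3, config$min_len,
                     config$max_len, config$quality_floor)
    if (nrow(x) == 0L) stop("no reads in ", config$reads_b)
    x
  })
  out$accounting_a <- cleaning_accounting(clean_a)
  out$accounting_b <- cleaning_accounting(clean_b)
  say("cleaned reads: ", sum(clean_a$status == "kept"), " / ",
      nrow(clean_a), " (a), ", sum(clean_b$status == "kept"), " / ",
      nrow(clean_b), " (b)")

  tags <- stage("tag_processing", collapse_tags(clean_a, clean_b))
  out$overlap <- library_overlap(tags)
  out$length_histogram <- tag_length_histogram(tags)
  totals <- c(sum(tags$count_a), sum(tags$count_b))
  say("unique tags: ", nrow(tags), "; clean totals ", totals[1], " / ",
      totals[2])

  refsets <- stage("annotation", lapply(config$refsets, read_fasta))
  tags <- stage("annotation", classify_tags(tags, refsets))
  out$tags <- tags
  out$known_profile <- stage("annotation", {
    profile_known_mirnas(tags, refsets$known_miRNA, totals)
  })
  say("known miRNAs detected: ", nrow(out$known_profile))

  genome <- stage("hairpin_discovery", read_fasta(config$genome))
  out$novel <- stage("hairpin_discovery", {
    discover_novel_mirnas(tags, genome, min_count = config$min_count,
                          max_mismatches = config$max_mismatches,
                          mfe_ceiling = config$mfe_ceiling,
                          max_duplex_mismatches = config$max_duplex_mismatches)
  })
  say("novel miRNA candidates: ", nrow(out$novel))

  de_input <- bind_rows(
    tibble(feature_id = out$known_profile$mirna_id,
           count_a = out$known_profile$count_a,
           count_b = out$known_profile$count_b),
    tibble(feature_id = out$novel$id, count_a = out$novel$count_a,
           count_b = out$novel$count_b))
  out$de <- stage("differential_expression", {
    run_de(de_input, totals[1], totals[2], min_tpm = config$min_tpm,
           lfc_threshold = config$lfc_threshold, alpha = config$alpha,
           strict_alpha = config$strict_alpha)
  })
  say("differential expression: ", sum(out$de$label %in% c("*", "**")),
      " significant of ", nrow(out$de))

  if (!is.null(config$transcripts)) {
    transcripts <- stage("target_prediction", read_fasta(config$transcripts))
    sig <- filter(out$de, .data$label %in% c("*", "**"))
    seqs <- c(setNames(out$known_profile$sequence,
                       out$known_profile$mirna_id),
              setNames(out$novel$mature, out$novel$id))
    sig_seqs <- seqs[intersect(sig$feature_id, names(seqs))]
    out$target_hits <- stage("target_prediction", {
      if (length(sig_seqs) == 0) NULL else
        predict_targets(sig_seqs, transcripts,
                        max_score = config$max_score,
                        max_seed_score = config$max_seed_score,
                        min_mfe_ratio = config$min_mfe_ratio)
    })
    say("target hits: ",
        if (is.null(out$target_hits)) 0 else nrow(out$target_hits))
    if (!is.null(config$kog_map) && !is.null(out$target_hits) &&
        nrow(out$target_hits)) {
      ass <- stage("function_annotation", {
        assign_kog(unique_target_genes(out$target_hits), config$kog_map)
      })
      out$kog_assignments <- ass
      if (any(!is.na(ass$category_letter))) {
        out$kog_summary <- summarize_kog(ass, "category")
        out$kog_main_summary <- summarize_kog(ass, "main_class")
      }
    }
  }

  # write every tabular intermediate
  for (nm in names(out)) {
    if (inherits(out[[nm]], "data.frame")) {
      readr::write_tsv(tidy_if_needed(out[[nm]]),
                       file.path(config$outdir, paste0(nm, ".tsv")))
    }
  }
  invisible(out)
}

tidy_if_needed <- function(x) {
  if (inherits(x, "srna_de")) tidy(x) else x
}
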