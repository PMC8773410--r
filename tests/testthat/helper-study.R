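# The full-size study fixture: 30 planted hairpins, 200,000 clean reads per
# library, fixed seed — the scaled-down conditions of the study the package
# re-implements. Built once and shared by the acceptance blocks.

study_fixture <- function() {
  if (is.null(.fixture_env$study)) {
    .fixture_env$study <- simulate_srna_experiment(
      n_hairpins = 30L, depth_a = 200000L, depth_b = 200000L, seed = 1L)
  }
  .fixture_env$study
}

study_pipeline_results <- function() {
  if (is.null(.fixture_env$study_results)) {
    exp <- study_fixture()
    cl_a <- clean_reads(exp$reads_a, exp$adaptor3)
    cl_b <- clean_reads(exp$reads_b, exp$adaptor3)
    tags <- classify_tags(collapse_tags(cl_a, cl_b), exp$refsets)
    totals <- c(sum(tags$count_a), sum(tags$count_b))
    novel <- discover_novel_mirnas(tags, exp$genome)
    prof <- profile_known_mirnas(tags, exp$refsets$known_miRNA, totals)
    de <- run_de(dplyr::bind_rows(
      tibble::tibble(feature_id = prof$mirna_id, count_a = prof$count_a,
                     count_b = prof$count_b),
      tibble::tibble(feature_id = novel$id, count_a = novel$count_a,
                     count_b = novel$count_b)), totals[1], totals[2])
    .fixture_env$study_results <-
      list(tags = tags, totals = totals, novel = novel, profile = prof,
           de = de)
  }
  .fixture_env$study_results
}
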