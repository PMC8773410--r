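test_that("the generator is byte-identical under a fixed seed", {
  a <- simulate_genome_hairpins(8, 20000, seed = 91)
  b <- simulate_genome_hairpins(8, 20000, seed = 91)
  expect_identical(a, b)
  spec <- function() library_sim_spec(5000, seed = 92)
  la <- simulate_libraries(a$hairpins, spec(), spec())
  lb <- simulate_libraries(b$hairpins, spec(), spec())
  expect_identical(la, lb)
  # and file output is byte-identical too
  f1 <- tempfile(); f2 <- tempfile()
  write_fastq(la$reads_a, f1); write_fastq(lb$reads_a, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  ta <- simulate_target_transcripts(setNames(a$hairpins$mature,
                                             a$hairpins$id), seed = 93)
  tb <- simulate_target_transcripts(setNames(a$hairpins$mature,
                                             a$hairpins$id), seed = 93)
  expect_identical(ta, tb)
})

test_that("an empty truth list still yields a genome", {
  g <- simulate_genome_hairpins(0, 10000, seed = 94)
  expect_equal(nrow(g$hairpins), 0L)
  expect_equal(sum(nchar(g$genome)), 10000L)
})

test_that("planted hairpins satisfy their structural invariants", {
  g <- simulate_genome_hairpins(30, 60000, seed = 95)
  h <- g$hairpins
  expect_true(all(nchar(h$precursor) >= 62 & nchar(h$precursor) <= 96))
  expect_true(all(nchar(h$mature) >= 20 & nchar(h$mature) <= 23))
  for (i in seq_len(nrow(h))) {
    # mature and star both occur within the precursor, on opposite arms
    expect_true(grepl(h$mature[i], h$precursor[i], fixed = TRUE))
    expect_true(grepl(h$star[i], h$precursor[i], fixed = TRUE))
    mm <- score_duplex(h$mature[i], h$star[i])$score
    expect_lte(mm, 4)
  }
  # multi-locus structure mirrors the study-like composition
  expect_equal(sum(h$n_loci > 1), round(0.3 * 30))
  expect_equal(sum(h$n_loci == 9), 1L)
  expect_equal(nrow(g$loci), sum(h$n_loci))
})

test_that("library counts conserve depth and match the expected table", {
  g <- simulate_genome_hairpins(5, 15000, seed = 96)
  spec <- function(s) library_sim_spec(8000, error_rate = 0, seed = s)
  libs <- simulate_libraries(g$hairpins, spec(1), spec(2))
  expect_equal(nrow(libs$reads_a),
               sum(libs$expected$count_a) + unname(libs$n_background["a"]))
  expect_equal(nrow(libs$reads_b),
               sum(libs$expected$count_b) + unname(libs$n_background["b"]))
  # error_rate 0: every insert is a planted mature or a background sequence
  cl <- clean_reads(libs$reads_a, default_adaptor())
  kept <- cl$insert[cl$status == "kept"]
  refs <- simulate_reference_sets(seed = 97)
  known_pool <- c(g$hairpins$mature)
  expect_true(all(nchar(kept) >= 18 & nchar(kept) <= 30))
  planted <- kept %in% known_pool
  expect_equal(sum(planted), sum(libs$expected$count_a))
})

test_that("a degenerate one-miRNA library is essentially pure", {
  h <- simulate_genome_hairpins(1, 5000, seed = 98)$hairpins
  h$tpm_a <- 1e6; h$tpm_b <- 1e6
  spec <- function(s) library_sim_spec(1000, error_rate = 0, seed = s)
  libs <- simulate_libraries(h, spec(3), spec(4))
  expect_gt(libs$expected$count_a, 900)
  expect_equal(nrow(libs$reads_a),
               max(1000, libs$expected$count_a))
})

test_that("planted fold changes are recovered within Poisson error", {
  # tpm_b / tpm_a = 4 at high depth: empirical log2 ratio ~ 2 within the
  # normal-approximation CI of the two Poisson counts
  g <- simulate_genome_hairpins(1, 5000, seed = 99)
  g$hairpins$tpm_a <- 5000; g$hairpins$tpm_b <- 20000
  spec <- function(s) library_sim_spec(50000, error_rate = 0, seed = s)
  libs <- simulate_libraries(g$hairpins, spec(5), spec(6))
  x <- libs$expected$count_a; y <- libs$expected$count_b
  lfc <- log2(y / x)
  se <- sqrt(1 / x + 1 / y) / log(2)
  expect_lt(abs(lfc - 2), 4 * se)
})

test_that("every tagged target site fails exactly its tagged rule", {
  exp <- small_experiment()
  mirnas <- setNames(exp$hairpins$mature, exp$hairpins$id)
  for (i in seq_len(nrow(exp$sites))) {
    s <- exp$sites[i, ]
    m <- mirnas[[s$mirna_id]]
    win <- substr(exp$transcripts[[s$transcript_id]], s$site_start,
                  s$site_start + nchar(m) - 1L)
    ev <- nitromir:::evaluate_site(m, win)
    rv <- unlist(ev[paste0("rule", 1:6)])
    if (s$violation == "none") {
      expect_true(all(rv), info = paste(s$transcript_id, s$violation))
      expect_true(ev$accepted)
    } else {
      expect_false(rv[[s$violation]],
                   info = paste(s$transcript_id, s$violation))
      expect_true(all(rv[setdiff(names(rv), s$violation)]),
                  info = paste(s$transcript_id, s$violation))
    }
  }
  expect_setequal(unique(exp$sites$violation),
                  c("none", paste0("rule", 1:6)))
})

test_that("scanning the truth transcripts accepts clean sites only", {
  exp <- small_experiment()
  mirnas <- setNames(exp$hairpins$mature, exp$hairpins$id)
  hits <- predict_targets(mirnas[unique(exp$sites$mirna_id)],
                          exp$transcripts)
  clean <- exp$sites[exp$sites$violation == "none", ]
  for (i in seq_len(nrow(clean))) {
    expect_true(any(hits$mirna_id == clean$mirna_id[i] &
                      hits$transcript_id == clean$transcript_id[i] &
                      hits$site_start == clean$site_start[i]),
                info = clean$transcript_id[i])
  }
  viol <- exp$sites[exp$sites$violation != "none", ]
  for (i in seq_len(nrow(viol))) {
    expect_false(any(hits$mirna_id == viol$mirna_id[i] &
                       hits$transcript_id == viol$transcript_id[i] &
                       hits$site_start == viol$site_start[i]),
                 info = viol$transcript_id[i])
  }
})
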