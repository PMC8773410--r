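adaptor <- default_adaptor()

read_of <- function(insert, read_length = 40L, qual_char = "I") {
  seq <- substr(paste0(insert, adaptor, strrep("A", read_length)), 1,
                read_length)
  tibble::tibble(id = "r", seq = seq, qual = strrep(qual_char, read_length))
}

test_that("adaptor trimming keeps in-range inserts and tallies discards", {
  insert21 <- random_dna(1, 21)
  got <- clean_reads(read_of(insert21), adaptor)
  expect_equal(got$status, "kept")
  expect_equal(got$insert, insert21)
  # 12-nt insert: adaptor found, insert too short
  expect_equal(clean_reads(read_of(random_dna(1, 12)), adaptor)$status,
               "too_short")
  # 31-nt insert: too long
  expect_equal(clean_reads(read_of(random_dna(1, 31), 45L), adaptor)$status,
               "too_long")
  # no adaptor anywhere
  no_ad <- tibble::tibble(id = "r", seq = strrep("C", 40),
                          qual = strrep("I", 40))
  expect_equal(clean_reads(no_ad, adaptor)$status, "no_adaptor")
  # low quality: mean Phred below 20 ("#" is Phred 2)
  expect_equal(clean_reads(read_of(random_dna(1, 21), qual_char = "#"),
                           adaptor)$status, "low_quality")
  # ambiguous base in the insert
  amb <- read_of(paste0(strrep("A", 10), "N", strrep("G", 10)))
  expect_equal(clean_reads(amb, adaptor)$status, "ambiguous")
})

test_that("a truncated adaptor at the read end is still found", {
  insert <- random_dna(1, 30)
  # only 7 adaptor bases fit before the read ends
  seq <- paste0(insert, substr(adaptor, 1, 7))
  got <- clean_reads(tibble::tibble(id = "r", seq = seq,
                                    qual = strrep("I", nchar(seq))), adaptor)
  expect_equal(got$status, "kept")
  expect_equal(got$insert, insert)
})

test_that("cleaning accounting covers every read exactly once", {
  withr::local_seed(21)
  reads <- dplyr::bind_rows(lapply(random_dna(50, sample(10:32, 50, TRUE)),
                                   read_of))
  cl <- clean_reads(reads, adaptor)
  acc <- cleaning_accounting(cl)
  expect_equal(sum(acc$n), nrow(reads))
  expect_setequal(acc$status, c("kept", "no_adaptor", "too_short", "too_long",
                                "ambiguous", "low_quality"))
})

test_that("malformed FASTQ fails with a record index", {
  bad <- tempfile(fileext = ".fastq")
  writeLines(c("@r1", "ACGT", "+", "IIII", "@r2", "ACGT", "+", "III"), bad)
  expect_error(read_fastq(bad), "record index 2")
})

test_that("tag collapsing equals a brute-force tally and is idempotent", {
  expect_equal(nrow(collapse_tags(character(0))), 0L)
  simple <- collapse_tags(c("AAAT", "AAAT", "CCCG"))
  expect_equal(simple$count_a[simple$sequence == "AAAT"], 2L)
  expect_equal(simple$count_a[simple$sequence == "CCCG"], 1L)
  withr::local_seed(31)
  reads_a <- sample(random_dna(300, 20), 5000, replace = TRUE)
  reads_b <- sample(random_dna(300, 20), 5000, replace = TRUE)
  tags <- collapse_tags(reads_a, reads_b)
  expect_equal(sum(tags$count_a), length(reads_a))
  expect_equal(sum(tags$count_b), length(reads_b))
  naive_a <- table(reads_a)
  expect_equal(tags$count_a[match(names(naive_a), tags$sequence)],
               unname(as.integer(naive_a)))
  # idempotence: collapsing the collapsed set leaves counts untouched
  again <- collapse_tags(tags$sequence)
  expect_true(all(again$count_a == 1L))
  expect_setequal(again$sequence, tags$sequence)
})

test_that("overlap accounting reproduces the printed library arithmetic", {
  acc <- tag_accounting(891186, 1403685, 220552, 13790887, 14571121)
  expect_equal(acc$specific_tags[acc$library == "a"], 670634)
  expect_equal(acc$specific_tags[acc$library == "b"], 1183133)
  expect_equal(acc$clean_reads[acc$library == "total"], 28362008)
  # identity: specific + common = unique, per library
  expect_equal(acc$specific_tags[1:2] + acc$common_tags[1:2],
               acc$unique_tags[1:2])
})

test_that("identical libraries have zero specific tags", {
  x <- c("AAAACCCCGGGGTTTTAA", "ACGTACGTACGTACGTAC")
  tags <- collapse_tags(x, x)
  ov <- library_overlap(tags)
  expect_equal(ov$specific_tags[1:2], c(0L, 0L))
  expect_equal(ov$common_tags[1], 2L)
})

test_that("length histogram matches a direct recount and drops out-of-range", {
  withr::local_seed(41)
  tags <- collapse_tags(random_dna(200, sample(c(8:34), 200, replace = TRUE)),
                        random_dna(50, 21))
  h <- tag_length_histogram(tags, weight = "unique")
  expect_setequal(unique(h$length), 10:32)
  lens <- nchar(tags$sequence)
  for (L in c(10, 21, 32)) {
    expect_equal(h$n[h$length == L & h$library == "a"],
                 sum(lens == L & tags$count_a > 0))
  }
  # abundance weighting counts reads, not sequences
  ha <- tag_length_histogram(tags, weight = "abundance")
  expect_equal(sum(ha$n[ha$library == "b"]),
               sum(tags$count_b[lens >= 10 & lens <= 32]))
  # all mass at one length for a single-length tag set
  single <- tag_length_histogram(collapse_tags(random_dna(10, 21)))
  expect_equal(sum(single$n[single$length != 21]), 0)
})
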