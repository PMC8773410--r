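test_that("tags map to all loci on both strands within one mismatch", {
  withr::local_seed(81)
  tag <- random_dna(1, 22)
  filler <- function(n) random_dna(1, n)
  genome <- c(c1 = paste0(filler(50), tag, filler(40), revcomp(tag),
                          filler(30)),
              c2 = paste0(filler(20), tag, filler(25)))
  mp <- map_tags(tag, genome)
  expect_equal(nrow(mp), 3L)
  expect_setequal(mp$strand[mp$contig == "c1"], c("+", "-"))
  expect_equal(mp$start[mp$contig == "c1" & mp$strand == "+"], 51L)
  # one substitution still maps, two do not (default ceiling)
  ch <- strsplit(tag, "")[[1]]
  ch[5] <- setdiff(c("A", "C", "G", "T"), ch[5])[1]
  one_mm <- paste(ch, collapse = "")
  expect_equal(unique(map_tags(one_mm, genome)$n_mismatches), 1L)
  ch[9] <- setdiff(c("A", "C", "G", "T"), ch[9])[1]
  expect_equal(nrow(map_tags(paste(ch, collapse = ""), genome)), 0L)
})

test_that("a 9-locus planting is reported at 9 loci", {
  g <- simulate_genome_hairpins(12, 30000, seed = 5)
  nine <- g$hairpins[g$hairpins$n_loci == 9L, ]
  expect_equal(nrow(nine), 1L)
  mp <- map_tags(nine$mature, g$genome)
  expect_equal(nrow(mp), 9L)
})

test_that("precursor windows sweep lengths and respect contig bounds", {
  withr::local_seed(82)
  genome <- c(c1 = random_dna(1, 400))
  w <- excise_precursor_windows(genome, "c1", 150L, 171L, "+")
  expect_true(all(w$w_end - w$w_start + 1L >= 62L))
  expect_true(all(w$w_end - w$w_start + 1L <= 96L))
  expect_true(all(w$w_start >= 1L & w$w_end <= 400L))
  expect_true(all(substr(w$window, w$mature_offset + 1L,
                         w$mature_offset + 22L) ==
                    substr(genome, 150, 171)))
  # locus at the contig start: windows truncate, coordinates stay positive
  w0 <- excise_precursor_windows(genome, "c1", 3L, 24L, "+")
  expect_true(all(w0$w_start >= 1L))
  # planted precursors are exactly covered by at least one window
  g <- simulate_genome_hairpins(6, 20000, seed = 83)
  for (i in seq_len(nrow(g$loci))) {
    l <- g$loci[i, ]
    h <- g$hairpins[match(l$id, g$hairpins$id), ]
    mstart <- regexpr(h$mature, h$precursor, fixed = TRUE)[1]
    gm <- if (l$strand == "+") {
      c(l$start + mstart - 1L, l$start + mstart + nchar(h$mature) - 2L)
    } else {
      c(l$end - mstart - nchar(h$mature) + 2L, l$end - mstart + 1L)
    }
    w <- excise_precursor_windows(g$genome, l$contig, gm[1], gm[2], l$strand)
    expect_true(any(w$w_start == l$start & w$w_end == l$end), info = l$id)
  }
})

test_that("planted hairpins are called with the planted mature", {
  g <- simulate_genome_hairpins(10, 25000, seed = 42)
  mp <- map_tags(g$hairpins$mature, g$genome)
  cache <- new.env(parent = emptyenv())
  called <- 0L
  for (i in seq_len(nrow(g$hairpins))) {
    h <- g$hairpins[i, ]
    loci <- mp[mp$sequence == h$mature, ]
    for (li in seq_len(nrow(loci))) {
      w <- excise_precursor_windows(g$genome, loci$contig[li],
                                    loci$start[li], loci$end[li],
                                    loci$strand[li])
      r <- call_novel_mirna(w, h$mature, c(5L, 5L), fold_cache = cache)
      if (!is.null(r$candidate)) {
        expect_equal(r$candidate$mature, h$mature)
        expect_lte(r$candidate$mfe, -18)
        expect_gte(r$candidate$precursor_length, 62L)
        expect_lte(r$candidate$precursor_length, 96L)
        expect_lte(r$candidate$duplex_mismatches, 4)
        called <- called + 1L
        break
      }
    }
  }
  expect_gte(called / nrow(g$hairpins), 0.9)
})

test_that("degenerate candidates are rejected with the right reason", {
  # mature of the wrong length never enters calling
  r <- call_novel_mirna(tibble::tibble(), random_dna(1, 18))
  expect_equal(r$reason, "length_out_of_range")
  # a mature spanning the loop is rejected as mature_in_loop
  stem <- "GCAUGGCAUCGAUCGGAUGCAUCGAUCGAUGG" # 32 nt
  prec <- paste0(stem, "CAAAAC", revcomp(stem))
  windows <- tibble::tibble(w_start = 1L, w_end = nchar(prec),
                            window = as_dna(prec),
                            mature_offset = 22L, arm = "5p")
  r <- call_novel_mirna(windows, substr(as_dna(prec), 23L, 43L))
  expect_equal(r$reason, "mature_in_loop")
  # an unstructured A/C window cannot reach the energy ceiling
  flat <- tibble::tibble(w_start = 1L, w_end = 70L,
                         window = paste0(strrep("AC", 25), strrep("A", 20)),
                         mature_offset = 0L, arm = "5p")
  r <- call_novel_mirna(flat, substr(flat$window, 1, 21))
  expect_equal(r$reason, "energy_too_high")
})

test_that("dinucleotide-shuffled precursors are rejected nearly always", {
  withr::local_seed(84)
  g <- simulate_genome_hairpins(5, 15000, seed = 85)
  h <- g$hairpins[1, ]
  mstart <- regexpr(h$mature, h$precursor, fixed = TRUE)[1]
  cache <- new.env(parent = emptyenv())
  rejected <- 0L
  for (k in 1:100) {
    shuf <- shuffle_dinucleotide(h$precursor)
    windows <- tibble::tibble(w_start = 1L, w_end = nchar(shuf),
                              window = shuf,
                              mature_offset = mstart - 1L, arm = h$arm)
    r <- call_novel_mirna(windows, substr(shuf, mstart,
                                          mstart + nchar(h$mature) - 1L),
                          fold_cache = cache)
    if (is.null(r$candidate)) rejected <- rejected + 1L
  }
  expect_gte(rejected, 90L)
})

test_that("full discovery recovers planted miRNAs from classified tags", {
  exp <- small_experiment()
  cl_a <- clean_reads(exp$reads_a, exp$adaptor3)
  cl_b <- clean_reads(exp$reads_b, exp$adaptor3)
  tags <- classify_tags(collapse_tags(cl_a, cl_b), exp$refsets)
  nov <- discover_novel_mirnas(tags, exp$genome)
  expect_gte(sum(exp$hairpins$mature %in% nov$mature) /
               nrow(exp$hairpins), 0.9)
  # locus counts carried through for the recovered matures
  j <- match(nov$mature, exp$hairpins$mature)
  expect_equal(nov$n_loci[!is.na(j)], exp$hairpins$n_loci[j[!is.na(j)]])
  # GFF3 export round-trips coordinates
  gff <- tempfile(fileext = ".gff3")
  write_candidates_gff3(nov, gff)
  back <- rtracklayer::import(gff)
  expect_equal(length(back), nrow(nov))
  expect_setequal(BiocGenerics::start(back), nov$w_start)
})
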