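# Independent oracles, deliberately naive: exhaustive enumeration for the
# folding DP, direct binomial-coefficient arithmetic for the Poisson test,
# position-by-position loops for the duplex scorer. None of them share code
# with the implementation paths they check.

# all nested structures (lists of c(i, j) pairs) on positions i..j
enumerate_structures <- function(chars, minloop = 3L) {
  pairable <- function(i, j) nitromir:::pair_label(chars[i], chars[j]) != ""
  rec <- function(i, j) {
    if (j - i < minloop + 1L) return(list(list()))
    out <- rec(i + 1L, j) # i unpaired
    for (k in seq(i + minloop + 1L, j)) {
      if (!pairable(i, k)) next
      inner <- rec(i + 1L, k - 1L)
      outer <- if (k + 1L > j) list(list()) else rec(k + 1L, j)
      for (a in inner) for (b in outer) {
        out[[length(out) + 1L]] <- c(list(c(i, k)), a, b)
      }
    }
    out
  }
  rec(1L, length(chars))
}

# canonical energy of a pair set: stacks over adjacent nested pairs plus one
# initiation per helix (pairs with no adjacent inner pair)
structure_energy <- function(pairs, chars) {
  par <- rna_energy_params()
  if (length(pairs) == 0L) return(0)
  key <- vapply(pairs, function(p) paste(p, collapse = ","), "")
  has_inner <- vapply(pairs, function(p) {
    paste(c(p[1] + 1L, p[2] - 1L), collapse = ",") %in% key
  }, logical(1))
  e <- sum(par$helix_init * !has_inner)
  for (idx in which(has_inner)) {
    p <- pairs[[idx]]
    lab_out <- nitromir:::pair_label(chars[p[1]], chars[p[2]])
    lab_in <- nitromir:::pair_label(chars[p[1] + 1L], chars[p[2] - 1L])
    e <- e + par$stacks[lab_out, lab_in]
  }
  e
}

oracle_fold_mfe <- function(sequence) {
  chars <- strsplit(toupper(as_dna(sequence)), "")[[1]]
  structs <- enumerate_structures(chars)
  min(0, vapply(structs, structure_energy, numeric(1), chars = chars))
}

# direct (non-log-space) evaluation of the Audic-Claverie conditional and
# its tails, via choose() and plain powers
oracle_ac <- function(x, y, n1, n2) {
  r <- n2 / n1
  pmf <- function(yy) choose(x + yy, yy) * r^yy / (1 + r)^(x + yy + 1)
  C <- sum(pmf(0:y))
  # upper tail through the negative-binomial identity (stats code path),
  # which stays accurate when the tail is far smaller than 1 - C's precision
  D <- stats::pnbinom(y - 1, size = x + 1, prob = n1 / (n1 + n2),
                      lower.tail = FALSE)
  c(C = C, D = D, p = min(1, 2 * min(C, D)))
}

# naive per-position duplex scorer (independent of score_duplex internals)
oracle_duplex_score <- function(mirna, window) {
  m <- strsplit(toupper(as_dna(mirna)), "")[[1]]
  w <- strsplit(toupper(as_dna(window)), "")[[1]]
  L <- length(m)
  total <- 0
  for (k in seq_len(L)) {
    t <- w[L + 1 - k]
    comp <- switch(m[k], A = "T", C = "G", G = "C", T = "A")
    if (t == comp) next
    wob <- (m[k] == "G" && t == "T") || (m[k] == "T" && t == "G")
    total <- total + if (wob) 0.5 else 1
  }
  total
}

# brute-force transcript scan: evaluate every window of every transcript
oracle_scan <- function(mirnas, transcripts, ...) {
  rows <- list()
  for (mi in names(mirnas)) {
    L <- nchar(mirnas[[mi]])
    for (ti in names(transcripts)) {
      tx <- transcripts[[ti]]
      for (s0 in seq_len(nchar(tx) - L + 1L)) {
        win <- substr(tx, s0, s0 + L - 1L)
        ev <- nitromir:::evaluate_site(mirnas[[mi]], win, ...)
        if (ev$accepted) {
          rows[[length(rows) + 1L]] <-
            tibble::tibble(mirna_id = mi, transcript_id = ti,
                           site_start = s0)
        }
      }
    }
  }
  if (length(rows)) dplyr::bind_rows(rows) else
    tibble::tibble(mirna_id = character(), transcript_id = character(),
                   site_start = integer())
}
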