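#' Transcripts-per-million normalization
#'
#' `tpm(count, total) = count / total * 1e6`, the "normalized expression"
#' used throughout the two-library comparison. `total` is the clean-read
#' total of the library the count comes from.
#'
#' @param count non-negative count(s).
#' @param total positive clean-read total (recycled).
#' @return numeric TPM values.
#' @examples
#' tpm(9, 13790887)
#' @export
tpm <- function(count, total) {
  if (any(total < 1)) stop("`total` must be >= 1")
  count / total * 1e6
}

#' Log2 fold change with zero substitution
#'
#' Computes `log2(ne_b / ne_a)` (condition B over condition A, i.e.
#' nitrogen-deprived over control) after replacing zero TPM values by
#' `zero_sub` so the ratio is always finite. Library-specific presence
#' (exactly one side zero) is flagged separately by [run_de()]; this function
#' always returns the numeric value. Antisymmetric under swapping the two
#' arguments.
#'
#' @param ne_a,ne_b non-negative normalized expressions (TPM).
#' @param zero_sub replacement for zero TPM (default 0.01).
#' @return numeric log2 fold changes.
#' @examples
#' log2_fold_change(5.80, 73.84) # 3.6701
#' @export
log2_fold_change <- function(ne_a, ne_b, zero_sub = 0.01) {
  if (any(ne_a < 0) || any(ne_b < 0)) stop("TPM values must be non-negative")
  log2(pmax(ne_b, zero_sub) / pmax(ne_a, zero_sub))
}

# log pmf of the conditional p(y | x) for two libraries of sizes n1, n2:
# p(y|x) = (n2/n1)^y (x+y)! / (x! y! (1 + n2/n1)^(x+y+1)),
# evaluated in log space via log-gamma so large counts cannot overflow.
ac_log_pmf <- function(y, x, n1, n2) {
  lr <- log(n2) - log(n1)
  lgamma(x + y + 1) - lgamma(x + 1) - lgamma(y + 1) +
    y * lr - (x + y + 1) * log1p(exp(lr))
}

ac_test_one <- function(x, y, n1, n2) {
  yy <- 0:y
  p_all <- exp(ac_log_pmf(yy, x, n1, n2))
  p_y <- p_all[length(p_all)]
  C <- sum(p_all)
  if (C <= 0.5) {
    # upper tail is >= 0.5: the complement loses no precision
    D <- 1 - C + p_y
  } else {
    # sum the infinite tail directly (geometric decay past the mode), so a
    # tiny D is not destroyed by cancellation against 1
    q <- n2 / n1
    ratio_base <- q / (1 + q)
    D <- 0
    term <- p_y
    k <- y
    while (term > 0 && (D == 0 || term > D * 1e-18) && k < y + 1e6) {
      D <- D + term
      term <- term * (x + k + 1) / (k + 1) * ratio_base
      k <- k + 1
    }
  }
  c(min(C, 1), min(max(D, 0), 1))
}

#' Exact Poisson (Audic-Claverie) test for two-library counts
#'
#' For a feature with raw counts `x` (library 1, total `n1`) and `y`
#' (library 2, total `n2`), evaluates the conditional distribution
#' \deqn{p(y \mid x) = \left(\frac{N_2}{N_1}\right)^y
#'   \frac{(x+y)!}{x!\,y!\,(1 + N_2/N_1)^{x+y+1}}}
#' and its tail sums `C = sum(p(y'|x), y' = 0..y)` (lower) and
#' `D = sum(p(y'|x), y' = y..Inf)` (upper, computed through the complement
#' `1 - C + p(y|x)`). All terms are evaluated in log space via log-gamma, so
#' overflow is impossible by construction. The reported two-sided p-value is
#' `min(1, 2 * min(C, D))`; set `alternative = "one.sided"` for `min(C, D)`.
#'
#' The same distribution is a negative binomial with size `x + 1` and success
#' probability `n1 / (n1 + n2)`, which the test suite uses as an independent
#' cross-check.
#'
#' @param x,y non-negative integer counts (vectors, recycled).
#' @param n1,n2 positive clean-read totals of the two libraries.
#' @param alternative `"two.sided"` (default) or `"one.sided"`.
#' @return tibble with columns `p_lower` (C), `p_upper` (D), `p_value`.
#' @examples
#' ac_test(0, 0, 1e6, 1e6) # p(0|0) = 0.5, p_value = 1
#' @export
ac_test <- function(x, y, n1, n2, alternative = c("two.sided", "one.sided")) {
  alternative <- match.arg(alternative)
  k <- max(length(x), length(y))
  x <- rep_len(x, k); y <- rep_len(y, k)
  if (any(x < 0) || any(y < 0)) stop("counts must be non-negative")
  if (any(x != round(x)) || any(y != round(y))) {
    stop("counts must be integers (the test operates on raw counts)")
  }
  res <- vapply(seq_len(k), function(i) ac_test_one(x[i], y[i], n1, n2),
                numeric(2))
  p_lower <- unname(res[1, ]); p_upper <- unname(res[2, ])
  p <- pmin(1, if (alternative == "two.sided") 2 * pmin(p_lower, p_upper)
            else pmin(p_lower, p_upper))
  tibble(p_lower = p_lower, p_upper = p_upper, p_value = p)
}

#' Label features by significance of differential expression
#'
#' `"**"` for `p < strict_alpha` and `|log2FC| > lfc_threshold`; `"*"` for
#' `strict_alpha <= p < alpha` and `|log2FC| > lfc_threshold`; `"ns"`
#' otherwise. Non-finite fold changes yield `"ns"` (library-specific features
#' are flagged through `presence`, not starred).
#'
#' @param log2fc numeric log2 fold changes.
#' @param p_value numeric p-values.
#' @param lfc_threshold absolute log2 fold-change threshold (default 1).
#' @param alpha significance level (default 0.05).
#' @param strict_alpha strong-significance level (default 0.01).
#' @return character vector of labels in `{"ns", "*", "**"}`.
#' @export
classify_significance <- function(log2fc, p_value, lfc_threshold = 1,
                                  alpha = 0.05, strict_alpha = 0.01) {
  big <- is.finite(log2fc) & abs(log2fc) > lfc_threshold
  dplyr::case_when(
    big & p_value < strict_alpha ~ "**",
    big & p_value < alpha ~ "*",
    TRUE ~ "ns"
  )
}

#' Two-library differential expression of miRNA counts
#'
#' Implements the full per-feature comparison: TPM normalization in each
#' library, removal of features with TPM < `min_tpm` in both libraries,
#' log2 fold change (nitrogen-deprived over control) with zero substitution,
#' and the exact Poisson test of [ac_test()] on the raw counts. Features seen
#' in only one library are flagged `a_specific` / `b_specific` and are never
#' starred.
#'
#' @param counts tibble with columns `feature_id`, `count_a`, `count_b`
#'   (raw counts in the control and nitrogen-deprived libraries).
#' @param n1,n2 clean-read totals of libraries a and b.
#' @param min_tpm low-expression filter: features below this TPM in *both*
#'   libraries are removed before testing (default 1).
#' @param lfc_threshold,alpha,strict_alpha see [classify_significance()].
#' @param zero_sub zero replacement for the fold change (default 0.01).
#' @param adjust apply Benjamini-Hochberg adjustment before labelling
#'   (default FALSE; the raw-p convention).
#' @return tibble of class `srna_de` with columns `feature_id`, `count_a`,
#'   `count_b`, `tpm_a`, `tpm_b`, `log2fc`, `presence`
#'   (`both`/`a_only`/`b_only`), `p_lower`, `p_upper`, `p_value`, `label`.
#'   Attributes record totals and thresholds; see [glance.srna_de()].
#' @export
run_de <- function(counts, n1, n2, min_tpm = 1, lfc_threshold = 1,
                   alpha = 0.05, strict_alpha = 0.01, zero_sub = 0.01,
                   adjust = FALSE) {
  stopifnot(all(c("feature_id", "count_a", "count_b") %in% names(counts)))
  if (anyDuplicated(counts$feature_id)) {
    stop("duplicate feature_id: ",
         counts$feature_id[duplicated(counts$feature_id)][1])
  }
  out <- counts |>
    mutate(tpm_a = tpm(.data$count_a, n1),
           tpm_b = tpm(.data$count_b, n2)) |>
    filter(.data$tpm_a >= min_tpm | .data$tpm_b >= min_tpm)
  n_removed <- nrow(counts) - nrow(out)
  if (nrow(out) == 0) {
    res <- tibble(feature_id = character(), count_a = integer(),
                  count_b = integer(), tpm_a = numeric(), tpm_b = numeric(),
                  log2fc = numeric(), presence = character(),
                  p_lower = numeric(), p_upper = numeric(),
                  p_value = numeric(), label = character())
  } else {
    test <- ac_test(out$count_a, out$count_b, n1, n2)
    res <- out |>
      mutate(log2fc = log2_fold_change(.data$tpm_a, .data$tpm_b,
                                       zero_sub = zero_sub),
             presence = dplyr::case_when(
               .data$count_a > 0 & .data$count_b == 0 ~ "a_only",
               .data$count_a == 0 & .data$count_b > 0 ~ "b_only",
               TRUE ~ "both"),
             p_lower = test$p_lower,
             p_upper = test$p_upper,
             p_value = if (adjust) p.adjust(test$p_value, "BH")
                       else test$p_value,
             label = ifelse(
               .data$presence == "both",
               classify_significance(.data$log2fc, .data$p_value,
                                     lfc_threshold, alpha, strict_alpha),
               sub("_only", "_specific", .data$presence)))
  }
  structure(res,
            class = c("srna_de", class(res)),
            totals = c(n1 = n1, n2 = n2),
            thresholds = c(min_tpm = min_tpm, lfc_threshold = lfc_threshold,
                           alpha = alpha, strict_alpha = strict_alpha),
            n_removed = n_removed)
}

#' @describeIn run_de tidy() returns the result as a plain tibble.
#' @param x an `srna_de` object.
#' @param ... unused.
#' @export
tidy.srna_de <- function(x, ...) {
  out <- x
  class(out) <- c("tbl_df", "tbl", "data.frame")
  attr(out, "totals") <- NULL
  attr(out, "thresholds") <- NULL
  attr(out, "n_removed") <- NULL
  out
}

#' One-row summary of a differential-expression run
#'
#' @param x an `srna_de` object.
#' @param ... unused.
#' @return tibble with the numbers a reader wants first: features tested,
#'   features removed by the low-expression filter, significant features and
#'   their split into up- and down-regulated, and library-specific counts.
#' @export
glance.srna_de <- function(x, ...) {
  sig <- x$label %in% c("*", "**")
  tibble(n_tested = nrow(x),
         n_removed_low_tpm = attr(x, "n_removed"),
         n_significant = sum(sig),
         n_up = sum(sig & x$log2fc > 0),
         n_down = sum(sig & x$log2fc < 0),
         n_a_specific = sum(x$label == "a_specific"),
         n_b_specific = sum(x$label == "b_specific"))
}
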