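#' The 25 KOG functional categories
#'
#' The standard letter-coded categories of the eukaryotic orthologous groups
#' (KOG) classification, each mapped to exactly one of the four main
#' classes: Cellular Processes and Signaling, Information Storage and
#' Processing, Metabolism, and Poorly characterized.
#'
#' @format tibble with columns `category_letter`, `category`, `main_class`.
#' @export
kog_categories <- tibble::tribble(
  ~category_letter, ~category, ~main_class,
  "J", "Translation, ribosomal structure and biogenesis", "Information Storage and Processing",
  "A", "RNA processing and modification", "Information Storage and Processing",
  "K", "Transcription", "Information Storage and Processing",
  "L", "Replication, recombination and repair", "Information Storage and Processing",
  "B", "Chromatin structure and dynamics", "Information Storage and Processing",
  "D", "Cell cycle control, cell division, chromosome partitioning", "Cellular Processes and Signaling",
  "Y", "Nuclear structure", "Cellular Processes and Signaling",
  "V", "Defense mechanisms", "Cellular Processes and Signaling",
  "T", "Signal transduction mechanisms", "Cellular Processes and Signaling",
  "M", "Cell wall/membrane/envelope biogenesis", "Cellular Processes and Signaling",
  "N", "Cell motility", "Cellular Processes and Signaling",
  "Z", "Cytoskeleton", "Cellular Processes and Signaling",
  "W", "Extracellular structures", "Cellular Processes and Signaling",
  "U", "Intracellular trafficking, secretion, and vesicular transport", "Cellular Processes and Signaling",
  "O", "Posttranslational modification, protein turnover, chaperones", "Cellular Processes and Signaling",
  "C", "Energy production and conversion", "Metabolism",
  "G", "Carbohydrate transport and metabolism", "Metabolism",
  "E", "Amino acid transport and metabolism", "Metabolism",
  "F", "Nucleotide transport and metabolism", "Metabolism",
  "H", "Coenzyme transport and metabolism", "Metabolism",
  "I", "Lipid transport and metabolism", "Metabolism",
  "P", "Inorganic ion transport and metabolism", "Metabolism",
  "Q", "Secondary metabolites biosynthesis, transport and catabolism", "Metabolism",
  "R", "General function prediction only", "Poorly characterized",
  "S", "Function unknown", "Poorly characterized"
)

#' Read and validate a gene-to-KOG mapping table
#'
#' Expects a headerless TSV with columns gene_id, kog_id, category_letter.
#' Malformed rows (wrong column count, unknown category letter) raise an
#' error naming the line number.
#'
#' @param path TSV file path.
#' @return tibble with columns `gene_id`, `kog_id`, `category_letter`.
#' @export
read_kog_map <- function(path) {
  lines <- readLines(path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 3L)
  if (length(bad)) {
    stop("malformed KOG map row at line ", bad[1], " of ", path,
         " (expected 3 tab-separated fields)")
  }
  out <- tibble(gene_id = vapply(parts, `[[`, "", 1),
                kog_id = vapply(parts, `[[`, "", 2),
                category_letter = vapply(parts, `[[`, "", 3))
  unknown <- which(!out$category_letter %in% kog_categories$category_letter)
  if (length(unknown)) {
    stop("unknown KOG category letter '", out$category_letter[unknown[1]],
         "' at line ", unknown[1], " of ", path)
  }
  out
}

#' Assign genes to KOG categories from a mapping table
#'
#' Joins a gene list against a gene-to-KOG table and attaches the category
#' name and main class for each letter. Genes absent from the map are
#' returned with NA annotation columns, never dropped silently; genes with
#' multiple KOG letters keep one row per letter.
#'
#' @param gene_ids character vector of gene ids.
#' @param kog_map tibble from [read_kog_map()] (columns `gene_id`, `kog_id`,
#'   `category_letter`) or a path to one.
#' @return tibble with columns `gene_id`, `kog_id`, `category_letter`,
#'   `category`, `main_class` (NA for unannotated genes).
#' @export
assign_kog <- function(gene_ids, kog_map) {
  if (is.character(kog_map) && length(kog_map) == 1L) {
    kog_map <- read_kog_map(kog_map)
  }
  tibble(gene_id = unique(gene_ids)) |>
    left_join(kog_map, by = "gene_id") |>
    left_join(kog_categories, by = "category_letter")
}

#' Summarize KOG assignments as category percentages
#'
#' Percentages are over assigned gene-KOG pairs (a gene with two letters
#' counts once per letter) and sum to 100 at each level.
#'
#' @param assignments tibble from [assign_kog()]; NA rows (unannotated
#'   genes) are excluded from the denominator.
#' @param level `"category"` (25 sub-categories) or `"main_class"` (the four
#'   main classes).
#' @return tibble with the level column, `n` and `percent`, covering every
#'   category of that level (zeros included), ordered as in
#'   [kog_categories].
#' @export
summarize_kog <- function(assignments, level = c("category", "main_class")) {
  level <- match.arg(level)
  ass <- filter(assignments, !is.na(.data$category_letter))
  if (nrow(ass) == 0L) stop("no annotated genes to summarize")
  lv <- unique(kog_categories[[level]])
  ass |>
    count(!!rlang::sym(level)) |>
    dplyr::right_join(tibble(!!rlang::sym(level) := lv), by = level) |>
    mutate(n = dplyr::coalesce(.data$n, 0L),
           percent = 100 * .data$n / sum(.data$n)) |>
    arrange(match(.data[[level]], lv))
}

#' Classify miRNA/target expression concordance
#'
#' A miRNA-target pair is `opposite` when the two fold changes have opposite
#' signs (consistent with miRNA-guided cleavage of the target mRNA) and
#' `positive` when they share a sign (coexpression, consistent with
#' translational repression rather than cleavage). Inputs are signed log2
#' fold changes; a zero fold change has no direction and is an error.
#'
#' @param pairs tibble with columns `mirna_id`, `gene_id` (or `gene`),
#'   `mirna_log2fc`, `target_log2fc`.
#' @return `pairs` with added `mirna_direction`, `target_direction`
#'   (`up`/`down`), `call` (`opposite`/`positive`) and `interpretation`.
#' @export
classify_concordance <- function(pairs) {
  stopifnot(all(c("mirna_log2fc", "target_log2fc") %in% names(pairs)))
  if (any(pairs$mirna_log2fc == 0 | pairs$target_log2fc == 0)) {
    stop("zero fold change: direction undefined")
  }
  pairs |>
    mutate(mirna_direction = ifelse(.data$mirna_log2fc > 0, "up", "down"),
           target_direction = ifelse(.data$target_log2fc > 0, "up", "down"),
           call = ifelse(.data$mirna_direction == .data$target_direction,
                         "positive", "opposite"),
           interpretation = ifelse(
             .data$call == "opposite",
             "consistent with target mRNA cleavage",
             "consistent with translational repression"))
}
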