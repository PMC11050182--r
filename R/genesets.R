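#' Classify genes from a differential-expression results table
#'
#' Applies the usual DESeq2-style screening rule: `up` when
#' `log2fc >= lfc_min` and `padj <= padj_max`, `down` when
#' `log2fc <= -lfc_min` and `padj <= padj_max`, otherwise `nDEG`
#' (both boundaries inclusive). A missing adjusted p-value (as produced
#' by independent filtering in standard DE tools) yields `nDEG`.
#'
#' @param de Tibble/data frame with columns `gene_id`, `log2fc`, `padj`
#'   (see `col_map` to rename).
#' @param lfc_min Minimum absolute log2 fold change (default 1).
#' @param padj_max Maximum adjusted p-value (default 0.05).
#' @param col_map Named character vector mapping the expected column
#'   names to those present, e.g.
#'   `c(gene_id = "gene", log2fc = "log2FoldChange", padj = "padj")`.
#' @return Tibble `gene_id`, `log2fc`, `padj`, `status` with
#'   `status` in `up`/`down`/`nDEG`.
#' @export
#' @examples
#' classify_deg(data.frame(gene_id = c("a", "b"),
#'                         log2fc = c(1.0, -0.5), padj = c(0.05, 0.001)))
classify_deg <- function(de, lfc_min = 1, padj_max = 0.05, col_map = NULL) {
  if (!is.null(col_map)) {
    for (std in names(col_map)) {
      names(de)[names(de) == col_map[[std]]] <- std
    }
  }
  need <- c("gene_id", "log2fc", "padj")
  if (!all(need %in% names(de))) {
    abort(paste0("DE table must have columns: ",
                 paste(need, collapse = ", ")))
  }
  if (anyDuplicated(de$gene_id)) {
    abort(paste0("Duplicate gene id(s): ",
                 paste(unique(de$gene_id[duplicated(de$gene_id)]),
                       collapse = ", ")))
  }
  as_tibble(de) |>
    mutate(
      status = dplyr::case_when(
        !is.na(.data$padj) & .data$padj <= padj_max &
          .data$log2fc >= lfc_min ~ "up",
        !is.na(.data$padj) & .data$padj <= padj_max &
          .data$log2fc <= -lfc_min ~ "down",
        TRUE ~ "nDEG"
      )
    ) |>
    select("gene_id", "log2fc", "padj", "status")
}

#' Promoter G4-count gene classes
#'
#' Counts G4 regions in each gene's upstream promoter window under a
#' strand context and maps the count to the seven classes
#' `"0" ... "5", "6+"`.
#'
#' @param models Gene-model tibble.
#' @param g4 G4 tibble.
#' @param chrom_len Named chromosome lengths (for promoter clipping).
#' @param promoter_len Upstream window width in bp (default 2000, the
#'   widest conventional promoter definition).
#' @param context Strand context (see [assign_g4()]).
#' @return Tibble of class `g4_promoter_classes`: `gene_id`, `g4_count`,
#'   `promoter_class` (factor with levels `0`..`5`, `6+`).
#' @export
promoter_class_table <- function(models, g4, chrom_len,
                                 promoter_len = 2000L,
                                 context = "double") {
  regions <- derive_region_sets(models, chrom_len,
                                promoter_lengths = promoter_len) |>
    filter(.data$region_class == paste0("promoter", promoter_len))
  out <- count_g4_per_gene(g4, regions, models, context) |>
    mutate(promoter_class = factor(
      ifelse(.data$g4_count >= 6L, "6+", as.character(.data$g4_count)),
      levels = c(as.character(0:5), "6+")
    ))
  class(out) <- c("g4_promoter_classes", class(out))
  out
}

#' Select genes with many promoter template-strand G4s
#'
#' Genes whose promoter carries strictly more than `min_exclusive` G4
#' regions under the given context (default: template strand, more than
#' 10) — the usual input set for over-representation analysis.
#'
#' @inheritParams promoter_class_table
#' @param min_exclusive Exclusive lower bound on the per-gene count.
#' @return Character vector of gene ids.
#' @export
select_high_g4_genes <- function(models, g4, chrom_len,
                                 promoter_len = 2000L,
                                 context = "template",
                                 min_exclusive = 10L) {
  regions <- derive_region_sets(models, chrom_len,
                                promoter_lengths = promoter_len) |>
    filter(.data$region_class == paste0("promoter", promoter_len))
  counts <- count_g4_per_gene(g4, regions, models, context)
  counts$gene_id[counts$g4_count > min_exclusive]
}

#' Hypergeometric term over-representation
#'
#' One-sided hypergeometric test per term: with a universe of `N` genes
#' of which `K` carry the term, and a selected set of `n` genes of which
#' `k` carry it, the p-value is `P[X >= k]` for
#' `X ~ Hypergeometric(N, K, n)`, followed by Benjamini-Hochberg
#' correction across all tested terms.
#'
#' @param selected Character vector of selected gene ids (must be a
#'   subset of the universe).
#' @param gene2term Tibble/data frame with columns `gene_id`, `term_id`
#'   and optionally `term_name`.
#' @param universe Character vector of universe gene ids; default: every
#'   gene with at least one term annotation.
#' @return Tibble of class `g4_enrichment`, sorted by `p_adj` then
#'   `p_value`: `term_id` (`term_name` if provided), `k`, `K`, `n`, `N`,
#'   `p_value`, `p_adj`.
#' @export
#' @examples
#' g2t <- data.frame(gene_id = letters[1:10],
#'                   term_id = rep(c("T1", "T2"), 5))
#' hypergeom_enrichment(c("a", "c", "e", "g"), g2t)
hypergeom_enrichment <- function(selected, gene2term, universe = NULL) {
  gene2term <- as_tibble(gene2term)
  stopifnot(all(c("gene_id", "term_id") %in% names(gene2term)))
  if (is.null(universe)) universe <- unique(gene2term$gene_id)
  universe <- unique(universe)
  selected <- unique(selected)
  outside <- setdiff(selected, universe)
  if (length(outside)) {
    abort(paste0("Selected gene(s) absent from universe: ",
                 paste(outside, collapse = ", ")))
  }
  g2t <- gene2term |>
    filter(.data$gene_id %in% universe) |>
    dplyr::distinct(.data$gene_id, .data$term_id,
                    dplyr::across(any_of("term_name")))
  N <- length(universe)
  n <- length(selected)
  res <- g2t |>
    group_by(.data$term_id) |>
    summarise(
      K = dplyr::n_distinct(.data$gene_id),
      k = sum(unique(.data$gene_id) %in% selected),
      term_name = if ("term_name" %in% names(g2t))
        dplyr::first(.data$term_name) else NA_character_,
      .groups = "drop"
    ) |>
    mutate(
      n = n, N = N,
      p_value = phyper(.data$k - 1L, .data$K, N - .data$K, n,
                       lower.tail = FALSE),
      p_adj = p.adjust(.data$p_value, method = "BH")
    ) |>
    arrange(.data$p_adj, .data$p_value, .data$term_id) |>
    select("term_id", "term_name", "k", "K", "n", "N", "p_value", "p_adj")
  if (all(is.na(res$term_name))) res$term_name <- NULL
  class(res) <- c("g4_enrichment", class(res))
  res
}

#' @importFrom dplyr any_of
NULL
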