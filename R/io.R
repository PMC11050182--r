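# provenance line written at the top of every pipeline output
prov_line <- function(params = NULL) {
  ver <- as.character(utils::packageVersion("g4landscape"))
  extra <- if (length(params)) {
    paste(sprintf("%s=%s", names(params),
                  vapply(params, function(x) paste(x, collapse = ","),
                         character(1))),
          collapse = " ")
  } else ""
  trimws(sprintf("# g4landscape %s %s", ver, extra))
}

write_tsv_prov <- function(df, path, params = NULL) {
  writeLines(prov_line(params), path)
  readr::write_tsv(df, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' Write G4 regions as BED6
#'
#' Columns: chrom, start, end (0-based half-open), name (the G-rich
#' sequence), score (`round(1000 * abs_score)`), strand.
#'
#' @param g4 G4 tibble from [scan_g4()].
#' @param path Output path.
#' @param params Optional named parameters for the provenance comment.
#' @return `path`, invisibly.
#' @export
write_g4_bed <- function(g4, path, params = NULL) {
  bed <- g4 |>
    mutate(name = .data$g_rich_seq,
           score_bed = round(1000 * .data$abs_score)) |>
    select("chrom", "start", "end", "name", "score_bed", "strand")
  writeLines(prov_line(params), path)
  readr::write_tsv(bed, path, append = TRUE, col_names = FALSE)
  invisible(path)
}

#' Write G4 regions as TSV with full-precision signed scores
#' @inheritParams write_g4_bed
#' @return `path`, invisibly.
#' @export
write_g4_tsv <- function(g4, path, params = NULL) {
  write_tsv_prov(g4, path, params)
}

#' Write SSRs as a MISA-style TSV
#'
#' Columns `ID` (chromosome), `SSR nr.` (per-chromosome ordinal), `SSR
#' type` (`p1`..`p6`/`compound`), `SSR` (motif notation `(AGG)8`),
#' `size`, `start`, `end`; start/end are 1-based inclusive as in MISA
#' output.
#'
#' @param ssrs SSR tibble from [scan_ssrs()] or [merge_compound()].
#' @inheritParams write_g4_bed
#' @return `path`, invisibly.
#' @export
write_ssr_tsv <- function(ssrs, path, params = NULL) {
  misa <- ssrs |>
    group_by(.data$chrom) |>
    mutate(ssr_nr = row_number()) |>
    ungroup() |>
    mutate(
      notation = ifelse(.data$ssr_class == "compound", "compound",
                        sprintf("(%s)%d", .data$motif, .data$n_repeats)),
      size = .data$end - .data$start
    ) |>
    select(ID = "chrom", `SSR nr.` = "ssr_nr", `SSR type` = "ssr_class",
           SSR = "notation", "size", "start", "end") |>
    mutate(start = .data$start + 1L) # 1-based inclusive
  write_tsv_prov(misa, path, params)
}

#' Write SSRs as GFF3 features of type SSR
#' @inheritParams write_ssr_tsv
#' @return `path`, invisibly.
#' @export
write_ssr_gff <- function(ssrs, path, params = NULL) {
  lines <- c("##gff-version 3", prov_line(params))
  if (nrow(ssrs) > 0L) {
    attrs <- sprintf(
      "ID=ssr%d;class=%s%s", seq_len(nrow(ssrs)), ssrs$ssr_class,
      ifelse(is.na(ssrs$motif), "",
             sprintf(";motif=%s;repeats=%d", ssrs$motif, ssrs$n_repeats))
    )
    lines <- c(lines, paste(ssrs$chrom, "g4landscape", "SSR",
                            ssrs$start + 1L, ssrs$end, ".", ".", ".",
                            attrs, sep = "\t"))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Write a binned track column as bedGraph
#'
#' @param tracks Tibble from [binned_tracks()].
#' @param value_col Which column to emit (`gc_fraction`, `gene_count`,
#'   `ssr_count` or `g4_count`).
#' @inheritParams write_g4_bed
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(tracks, value_col, path, params = NULL) {
  stopifnot(value_col %in% names(tracks))
  writeLines(c(prov_line(params),
               sprintf('track type=bedGraph name="%s"', value_col)), path)
  readr::write_tsv(
    select(tracks, "chrom", "bin_start", "bin_end", all_of(value_col)),
    path, append = TRUE, col_names = FALSE
  )
  invisible(path)
}

#' Read a differential-expression results table
#'
#' Expects a TSV with gene id, log2 fold change and adjusted p columns
#' (default header names `gene_id`, `log2FoldChange`, `padj`).
#'
#' @param path TSV path.
#' @param gene_col,lfc_col,padj_col Header names to use.
#' @return Tibble `gene_id`, `log2fc`, `padj`.
#' @export
read_de_table <- function(path, gene_col = "gene_id",
                          lfc_col = "log2FoldChange", padj_col = "padj") {
  d <- readr::read_tsv(path, comment = "#", show_col_types = FALSE)
  need <- c(gene_col, lfc_col, padj_col)
  if (!all(need %in% names(d))) {
    abort(paste0("DE table is missing column(s): ",
                 paste(setdiff(need, names(d)), collapse = ", ")))
  }
  tibble(
    gene_id = as.character(d[[gene_col]]),
    log2fc = as.numeric(d[[lfc_col]]),
    padj = as.numeric(d[[padj_col]])
  )
}

#' Read a gene-to-term annotation map
#'
#' @param path TSV with columns `gene_id`, `term_id` and optionally
#'   `term_name`.
#' @return Tibble.
#' @export
read_gene2term <- function(path) {
  d <- readr::read_tsv(path, comment = "#", show_col_types = FALSE)
  if (!all(c("gene_id", "term_id") %in% names(d))) {
    abort("gene2term table must have columns gene_id and term_id.")
  }
  as_tibble(d)
}
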