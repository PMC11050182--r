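#' Per-chromosome G4 summary table
#'
#' Chromosome length, GC content (N excluded from the denominator), G4
#' count and density per kbp, in FASTA record order. The display column
#' rounds density to one decimal in the style of published genome tables.
#'
#' @param genome Named character vector of sequences.
#' @param g4 G4 tibble from [scan_g4()] on the same genome.
#' @return Tibble `chrom`, `length_bp`, `gc_percent`, `g4_count`,
#'   `g4_density_per_kbp`, `g4_density_display`.
#' @export
chromosome_summary <- function(genome, g4) {
  extra <- setdiff(unique(g4$chrom), names(genome))
  if (length(extra)) {
    abort(paste0("G4 table references chromosome(s) absent from genome: ",
                 paste(extra, collapse = ", ")))
  }
  af <- Biostrings::alphabetFrequency(
    Biostrings::DNAStringSet(unname(genome))
  )
  acgt <- af[, c("A", "C", "G", "T"), drop = FALSE]
  counts <- table(factor(g4$chrom, levels = names(genome)))
  tibble(
    chrom = names(genome),
    length_bp = unname(nchar(genome)),
    gc_percent = as.numeric(100 * (acgt[, "G"] + acgt[, "C"]) /
                              rowSums(acgt)),
    g4_count = as.integer(counts)
  ) |>
    mutate(
      g4_density_per_kbp = .data$g4_count / (.data$length_bp / 1000),
      g4_density_display = sprintf("%.1f", .data$g4_density_per_kbp)
    )
}

#' Motif-family frequency table
#'
#' Groups detected G4 regions by their exact G-rich sequence and tabulates
#' genome-wide occurrence and the strand split. The score column is
#' recomputed from the sequence so the table has a single source of truth.
#'
#' @param g4 G4 tibble from [scan_g4()].
#' @param top_n Keep the `top_n` most frequent families (default all).
#' @return Tibble `g_rich_seq`, `total`, `plus_count`, `minus_count`,
#'   `length`, `abs_score`, sorted by descending `total` (ties broken by
#'   sequence).
#' @export
motif_family_table <- function(g4, top_n = Inf) {
  out <- g4 |>
    group_by(.data$g_rich_seq) |>
    summarise(
      total = n(),
      plus_count = sum(.data$strand == "+"),
      minus_count = sum(.data$strand == "-"),
      .groups = "drop"
    ) |>
    mutate(
      length = nchar(.data$g_rich_seq),
      abs_score = vapply(.data$g_rich_seq,
                         function(s) abs(hunter_score(s)), numeric(1),
                         USE.NAMES = FALSE)
    ) |>
    arrange(desc(.data$total), .data$g_rich_seq)
  if (is.finite(top_n)) out <- head(out, top_n)
  out
}

#' G4 density over feature regions, strand contexts and gene sets
#'
#' Full cross-product of region classes x strand contexts x gene sets.
#' For a named gene set, class intervals are restricted to that set's
#' genes before counting and the total bp is re-merged; the `"all"` set
#' uses every interval (including `intergenic`). Gene-less classes are
#' skipped under `template`/`coding` contexts, which are only defined
#' relative to a gene strand.
#'
#' @param g4 G4 tibble from [scan_g4()].
#' @param regions Region tibble from [derive_region_sets()].
#' @param contexts Strand contexts to evaluate.
#' @param gene_sets Named list of gene-id vectors (e.g. `list(up = ...,
#'   down = ...)`); the `"all"` set is always included.
#' @return Tibble of class `g4_density`: `region_class`,
#'   `strand_context`, `gene_set`, `g4_count`, `total_bp`,
#'   `density_per_kbp`. Records with zero total bp are omitted with a
#'   warning (empty gene sets yield zero-count records, also with a
#'   warning).
#' @export
density_profile <- function(g4, regions,
                            contexts = c("double", "template", "coding"),
                            gene_sets = NULL) {
  sets <- c(list(all = NULL), gene_sets)
  if (is.null(names(sets)) || any(names(sets)[-1] == "")) {
    abort("`gene_sets` must be a named list.")
  }
  out <- purrr::imap(sets, function(set, label) {
    if (is.null(set)) {
      sub <- regions
    } else {
      if (length(set) == 0L) {
        warn(sprintf("Gene set '%s' is empty; reporting zero counts.",
                     label))
      }
      sub <- filter(regions, .data$gene_id %in% set)
    }
    totals <- region_totals(sub)
    purrr::map(contexts, function(ctx) {
      rsub <- if (ctx == "double") sub else
        filter(sub, !is.na(.data$gene_strand))
      cls <- if (is.null(set)) unique(regions$region_class) else
        setdiff(unique(regions$region_class), "intergenic")
      if (ctx != "double") cls <- setdiff(cls, "intergenic")
      counts <- assign_g4(g4, rsub, ctx)
      tibble(region_class = cls) |>
        left_join(counts, by = "region_class") |>
        left_join(totals, by = "region_class") |>
        mutate(
          strand_context = ctx,
          gene_set = label,
          g4_count = dplyr::coalesce(.data$g4_count, 0L),
          total_bp = dplyr::coalesce(.data$total_bp, 0L)
        )
    }) |> bind_rows()
  }) |> bind_rows()

  zero <- out$total_bp == 0L & out$gene_set == "all"
  empty_set <- out$total_bp == 0L & out$gene_set != "all"
  if (any(zero)) {
    warn(sprintf("Omitting %d record(s) with zero total bp (classes: %s).",
                 sum(zero),
                 paste(unique(out$region_class[zero]), collapse = ", ")))
  }
  out <- out[!zero, , drop = FALSE]
  out <- out |>
    mutate(density_per_kbp = ifelse(.data$total_bp > 0,
                                    .data$g4_count / (.data$total_bp / 1000),
                                    NA_real_)) |>
    select("region_class", "strand_context", "gene_set", "g4_count",
           "total_bp", "density_per_kbp")
  if (any(empty_set)) {
    warn("Some gene-set records have zero total bp; densities set to NA.")
  }
  class(out) <- c("g4_density", class(out))
  out
}

#' Binned genome tracks: GC, gene, SSR and G4 density
#'
#' Splits each chromosome into `bin_bp` bins (last bin truncated at the
#' chromosome end) and reports the GC fraction (N excluded) plus gene,
#' SSR and G4 counts per bin. A feature is assigned to the bin containing
#' its start coordinate, so per-bin counts sum exactly to the totals.
#'
#' @param genome Named character vector of sequences.
#' @param g4,ssrs Feature tibbles with `chrom` and `start` columns (pass
#'   `NULL` to skip a track).
#' @param models Gene-model tibble (or `NULL`).
#' @param bin_bp Bin width in bp (default 10 Mb).
#' @return Tibble `chrom`, `bin_start`, `bin_end`, `gc_fraction`,
#'   `gene_count`, `ssr_count`, `g4_count`.
#' @export
binned_tracks <- function(genome, g4 = NULL, ssrs = NULL, models = NULL,
                          bin_bp = 10000000L) {
  stopifnot(bin_bp >= 1L)
  purrr::imap(as.list(genome), function(seq, nm) {
    len <- nchar(seq)
    starts <- seq.int(0L, len - 1L, by = bin_bp)
    ends <- pmin(starts + bin_bp, len)
    gc <- vapply(seq_along(starts), function(i) {
      af <- Biostrings::alphabetFrequency(
        Biostrings::DNAString(substr(seq, starts[i] + 1L, ends[i]))
      )
      denom <- sum(af[c("A", "C", "G", "T")])
      if (denom == 0L) NA_real_ else
        (af[["G"]] + af[["C"]]) / denom
    }, numeric(1))
    count_in <- function(d) {
      if (is.null(d) || nrow(d) == 0L) return(integer(length(starts)))
      s <- d$start[d$chrom == nm]
      tabulate(pmin(s %/% bin_bp + 1L, length(starts)), length(starts))
    }
    tibble(
      chrom = nm, bin_start = starts, bin_end = ends, gc_fraction = gc,
      gene_count = count_in(models), ssr_count = count_in(ssrs),
      g4_count = count_in(g4)
    )
  }) |> bind_rows()
}
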