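#' Feature-region classes handled by the package
#' @return Character vector of the twelve region class names.
#' @export
region_classes <- function() {
  c("exon", "CDS", "intron", "5UTR", "3UTR", "gene", "intergenic",
    "promoter2000", "promoter1500", "promoter1000", "promoter500", "TSS500")
}

#' Derive feature regions from gene models
#'
#' Builds the twelve feature-region classes from gene models: per-gene
#' `exon`, `CDS`, `intron` (gene span minus exon union), `5UTR`, `3UTR`
#' and `gene` intervals; chromosome-wide `intergenic` (complement of the
#' merged gene spans); strand-aware upstream `promoterN` windows
#' (`[TSS - N, TSS)` on `+`, mirrored on `-`) for N = 2000, 1500, 1000,
#' 500; and the TSS-centred `TSS500` window of 250 bp either side of the
#' transcription start site (always 500 bp before clipping). The TSS is
#' the strand-aware 5' end of the gene span. All intervals are clipped to
#' `[0, chromosome length)`; promoters of neighbouring genes are not
#' masked against each other.
#'
#' @param models Gene-model tibble from [parse_gff()].
#' @param chrom_len Named vector of chromosome lengths covering every
#'   chromosome in `models`.
#' @param promoter_lengths Upstream window widths in bp.
#' @param tss_halfwidth Half-width of the TSS window in bp.
#' @return A tibble of intervals: `region_class`, `chrom`, `start`, `end`
#'   (0-based half-open), `gene_id` and `gene_strand` (`NA` for
#'   `intergenic`).
#' @export
derive_region_sets <- function(models, chrom_len,
                               promoter_lengths = c(2000L, 1500L, 1000L,
                                                    500L),
                               tss_halfwidth = 250L) {
  missing <- setdiff(unique(models$chrom), names(chrom_len))
  if (length(missing)) {
    abort(paste0("chrom_len missing chromosome(s): ",
                 paste(missing, collapse = ", ")))
  }

  gene_rows <- function(cls, iv_col) {
    purrr::pmap(
      list(models$gene_id, models$chrom, models$strand, models[[iv_col]]),
      function(gid, chrom, strand, iv) {
        if (nrow(iv) == 0L) return(NULL)
        tibble(region_class = cls, chrom = chrom, start = iv$start,
               end = iv$end, gene_id = gid, gene_strand = strand)
      }
    ) |> bind_rows()
  }

  models <- models |>
    mutate(
      introns = purrr::pmap(list(.data$start, .data$end, .data$exons),
                            function(s, e, ex) iv_setdiff(iv_df(s, e), ex)),
      span = purrr::map2(.data$start, .data$end, iv_df)
    )

  out <- bind_rows(
    gene_rows("exon", "exons"),
    gene_rows("CDS", "cds"),
    gene_rows("intron", "introns"),
    gene_rows("5UTR", "utr5"),
    gene_rows("3UTR", "utr3"),
    gene_rows("gene", "span")
  )

  # promoters and TSS windows (may clip at chromosome edges)
  tss <- ifelse(models$strand == "+", models$start, models$end - 1L)
  for (N in promoter_lengths) {
    p_start <- ifelse(models$strand == "+", tss - N, models$end)
    p_end <- ifelse(models$strand == "+", models$start, models$end + N)
    out <- bind_rows(out, tibble(
      region_class = paste0("promoter", N), chrom = models$chrom,
      start = as.integer(p_start), end = as.integer(p_end),
      gene_id = models$gene_id, gene_strand = models$strand
    ))
  }
  t_start <- ifelse(models$strand == "+", tss - tss_halfwidth,
                    tss - tss_halfwidth + 1L)
  out <- bind_rows(out, tibble(
    region_class = "TSS500", chrom = models$chrom,
    start = as.integer(t_start),
    end = as.integer(t_start + 2L * tss_halfwidth),
    gene_id = models$gene_id, gene_strand = models$strand
  ))

  # clip to chromosomes
  clen <- as.integer(chrom_len[out$chrom])
  clipped <- pmax(out$start, 0L) != out$start | pmin(out$end, clen) != out$end
  if (any(clipped)) {
    warn(sprintf("%d region interval(s) clipped at chromosome boundaries.",
                 sum(clipped)))
  }
  out$start <- pmax(out$start, 0L)
  out$end <- pmin(out$end, clen)
  out <- filter(out, .data$end > .data$start)

  # intergenic = chromosome minus merged gene spans
  inter <- purrr::imap(as.list(chrom_len), function(len, nm) {
    g <- filter(models, .data$chrom == nm)
    iv <- iv_setdiff(iv_df(0L, as.integer(len)),
                     iv_reduce(iv_df(g$start, g$end)))
    if (nrow(iv) == 0L) return(NULL)
    tibble(region_class = "intergenic", chrom = nm, start = iv$start,
           end = iv$end, gene_id = NA_character_,
           gene_strand = NA_character_)
  }) |> bind_rows()

  bind_rows(out, inter) |>
    arrange(.data$region_class, .data$chrom, .data$start)
}

#' Total merged base pairs per region class
#'
#' Intervals of a class are merged strand-agnostically per chromosome
#' before summing, so overlapping promoters or shared exons are counted
#' once.
#'
#' @param regions Region tibble from [derive_region_sets()].
#' @return Tibble with `region_class` and `total_bp`.
#' @export
region_totals <- function(regions) {
  regions |>
    group_by(.data$region_class, .data$chrom) |>
    summarise(
      bp = iv_total(iv_reduce(iv_df(.data$start, .data$end))),
      .groups = "drop"
    ) |>
    group_by(.data$region_class) |>
    summarise(total_bp = sum(.data$bp), .groups = "drop")
}

# overlap pairs between a g4 tibble and a region tibble, with the strand
# context applied; returns tibble(g4_row, region_row)
g4_region_pairs <- function(g4, regions, context) {
  context <- match.arg(context, c("double", "template", "coding"))
  if (context != "double" && anyNA(regions$gene_strand)) {
    abort(sprintf(
      "Strand context '%s' requires gene-linked regions; class(es) %s have no gene strand.",
      context,
      paste(unique(regions$region_class[is.na(regions$gene_strand)]),
            collapse = ", ")
    ))
  }
  if (nrow(g4) == 0L || nrow(regions) == 0L) {
    return(tibble(g4_row = integer(0), region_row = integer(0)))
  }
  q <- GenomicRanges::GRanges(
    g4$chrom, IRanges::IRanges(g4$start + 1L, g4$end)
  )
  s <- GenomicRanges::GRanges(
    regions$chrom, IRanges::IRanges(regions$start + 1L, regions$end)
  )
  ov <- GenomicRanges::findOverlaps(q, s, minoverlap = 1L)
  pairs <- tibble(
    g4_row = S4Vectors::queryHits(ov),
    region_row = S4Vectors::subjectHits(ov)
  )
  if (context == "coding") {
    pairs <- filter(
      pairs, g4$strand[.data$g4_row] == regions$gene_strand[.data$region_row]
    )
  } else if (context == "template") {
    pairs <- filter(
      pairs, g4$strand[.data$g4_row] != regions$gene_strand[.data$region_row]
    )
  }
  pairs
}

#' Count G4 regions per feature-region class
#'
#' A G4 counts once per class when it overlaps (by at least 1 bp) any
#' interval of that class, under the chosen strand context: `double`
#' counts G4s on both strands, `coding` only G4s whose G-rich strand
#' equals the linked gene's strand, `template` the opposite. Stranded
#' contexts error on gene-less classes such as `intergenic`.
#'
#' @param g4 G4 tibble from [scan_g4()].
#' @param regions Region tibble from [derive_region_sets()] (any subset).
#' @param context `"double"`, `"template"` or `"coding"`.
#' @return Tibble `region_class`, `context`, `g4_count`; every class
#'   present in `regions` appears (count 0 when none overlap).
#' @export
assign_g4 <- function(g4, regions, context = "double") {
  pairs <- g4_region_pairs(g4, regions, context)
  counted <- tibble(
    region_class = regions$region_class[pairs$region_row],
    g4_row = pairs$g4_row
  ) |>
    dplyr::distinct() |>
    dplyr::count(.data$region_class, name = "g4_count")
  tibble(region_class = sort(unique(regions$region_class))) |>
    left_join(counted, by = "region_class") |>
    mutate(
      context = context,
      g4_count = dplyr::coalesce(.data$g4_count, 0L)
    ) |>
    select("region_class", "context", "g4_count")
}

#' Count G4 regions per gene over one region class
#'
#' @inheritParams assign_g4
#' @param models Gene-model tibble; genes absent from `regions` get
#'   count 0.
#' @return Tibble `gene_id`, `g4_count` (distinct G4s per gene).
#' @export
count_g4_per_gene <- function(g4, regions, models, context = "double") {
  pairs <- g4_region_pairs(g4, regions, context)
  counted <- tibble(
    gene_id = regions$gene_id[pairs$region_row],
    g4_row = pairs$g4_row
  ) |>
    dplyr::distinct() |>
    dplyr::count(.data$gene_id, name = "g4_count")
  tibble(gene_id = models$gene_id) |>
    left_join(counted, by = "gene_id") |>
    mutate(g4_count = dplyr::coalesce(.data$g4_count, 0L))
}
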