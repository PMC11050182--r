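#' Default pipeline configuration
#'
#' @param fasta,gff Input genome FASTA and gene-model GFF3 paths.
#' @param de Optional DE results TSV (`gene_id`, `log2FoldChange`,
#'   `padj`).
#' @param gene2term Optional gene-to-term TSV for enrichment.
#' @param out_dir Output directory.
#' @param window,threshold,trim G4 detection parameters.
#' @param promoter_lengths,tss_halfwidth Feature-region parameters.
#' @param promoter_len Promoter width for the G4-count gene classes.
#' @param bin_bp Track bin width.
#' @param lfc_min,padj_max DEG screening thresholds.
#' @return A named list, usable as `config` in [run_pipeline()].
#' @export
pipeline_config <- function(fasta, gff, out_dir, de = NULL,
                            gene2term = NULL, window = 25L,
                            threshold = 1.2, trim = TRUE,
                            promoter_lengths = c(2000L, 1500L, 1000L, 500L),
                            tss_halfwidth = 250L, promoter_len = 2000L,
                            bin_bp = 10000000L, lfc_min = 1,
                            padj_max = 0.05) {
  as.list(environment())
}

#' Run the full G4 landscape pipeline
#'
#' Orchestrates detection, summarisation and gene-set analysis:
#' G4 scan (`g4.bed`, `g4.tsv`), SSR scan with compound merging
#' (`ssr.tsv`, `ssr.gff3`), SSR-G4 association (`ssr_g4.tsv`),
#' feature-region BEDs (`regions/<class>.bed`) and totals
#' (`region_totals.tsv`), chromosome summary
#' (`chromosome_summary.tsv`), motif families (`motif_families.tsv`),
#' density profile over strand contexts and (when a DE table is given)
#' DEG/nDEG/up/down gene sets (`densities.tsv`), promoter G4-count
#' classes (`promoter_classes.tsv`), binned bedGraph tracks, and (when a
#' gene-to-term map is given) hypergeometric enrichment of high-G4
#' genes (`enrichment.tsv`). Every output carries a provenance comment
#' echoing the parameters. On error, files created during the run are
#' removed.
#'
#' @param config Named list (see [pipeline_config()]) or path to a YAML
#'   file with the same fields.
#' @return Invisibly, a named list of output paths.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  defaults <- formals(pipeline_config)
  for (nm in names(defaults)) {
    if (is.null(config[[nm]]) && !nm %in% c("fasta", "gff", "out_dir")) {
      config[[nm]] <- eval(defaults[[nm]])
    }
  }
  for (nm in c("fasta", "gff", "out_dir")) {
    if (is.null(config[[nm]])) abort(sprintf("config$%s is required.", nm))
  }
  for (nm in c("fasta", "gff", "de", "gene2term")) {
    p <- config[[nm]]
    if (!is.null(p) && !file.exists(p)) {
      abort(sprintf("config$%s: file not found: %s", nm, p))
    }
  }
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(out_dir, "regions"), showWarnings = FALSE)
  created <- character(0)
  note <- function(p) {
    created <<- c(created, p)
    p
  }
  prov <- config[c("window", "threshold", "trim", "promoter_len",
                   "bin_bp", "lfc_min", "padj_max")]
  stage <- "setup"
  paths <- list()

  run <- function() {
    stage <<- "g4-scan"
    genome <- read_genome(config$fasta)
    g4 <- scan_g4(genome, window = config$window,
                  threshold = config$threshold, trim = config$trim)
    message(sprintf("[g4-scan] %d region(s) on %d chromosome(s)",
                    nrow(g4), length(genome)))
    paths$g4_bed <<- note(write_g4_bed(g4, file.path(out_dir, "g4.bed"),
                                       prov))
    paths$g4_tsv <<- note(write_g4_tsv(g4, file.path(out_dir, "g4.tsv"),
                                       prov))

    stage <<- "ssr-scan"
    ssr <- scan_ssrs(genome)
    ssr_c <- merge_compound(ssr)
    message(sprintf("[ssr-scan] %d simple SSR(s), %d after compounding",
                    nrow(ssr), nrow(ssr_c)))
    paths$ssr_tsv <<- note(write_ssr_tsv(ssr_c,
                                         file.path(out_dir, "ssr.tsv"),
                                         prov))
    paths$ssr_gff <<- note(write_ssr_gff(ssr_c,
                                         file.path(out_dir, "ssr.gff3"),
                                         prov))
    assoc <- ssr_g4_association(ssr, g4) |>
      select(-"g4_ids")
    paths$ssr_g4 <<- note(write_tsv_prov(
      assoc, file.path(out_dir, "ssr_g4.tsv"), prov
    ))

    stage <<- "regions"
    models <- parse_gff(config$gff)
    clen <- chrom_lengths(genome)
    regions <- derive_region_sets(
      models, clen, promoter_lengths = config$promoter_lengths,
      tss_halfwidth = config$tss_halfwidth
    )
    for (cls in unique(regions$region_class)) {
      sub <- filter(regions, .data$region_class == cls)
      bed <- tibble(
        chrom = sub$chrom, start = sub$start, end = sub$end,
        name = dplyr::coalesce(sub$gene_id, "."), score = 0L,
        strand = dplyr::coalesce(sub$gene_strand, ".")
      )
      p <- file.path(out_dir, "regions", paste0(cls, ".bed"))
      writeLines(prov_line(prov), p)
      readr::write_tsv(bed, p, append = TRUE, col_names = FALSE)
      note(p)
    }
    paths$region_totals <<- note(write_tsv_prov(
      region_totals(regions), file.path(out_dir, "region_totals.tsv"),
      prov
    ))
    message(sprintf("[regions] %d gene(s), %d interval(s) over %d classes",
                    nrow(models), nrow(regions),
                    length(unique(regions$region_class))))

    stage <<- "landscape"
    paths$chrom_summary <<- note(write_tsv_prov(
      chromosome_summary(genome, g4),
      file.path(out_dir, "chromosome_summary.tsv"), prov
    ))
    paths$motif_families <<- note(write_tsv_prov(
      motif_family_table(g4),
      file.path(out_dir, "motif_families.tsv"), prov
    ))
    tracks <- binned_tracks(genome, g4 = g4, ssrs = ssr, models = models,
                            bin_bp = config$bin_bp)
    for (v in c("gc_fraction", "gene_count", "ssr_count", "g4_count")) {
      p <- file.path(out_dir, paste0("track_", v, ".bedgraph"))
      note(write_bedgraph(tracks, v, p, prov))
    }

    stage <<- "gene-sets"
    gene_sets <- NULL
    if (!is.null(config$de)) {
      deg <- classify_deg(read_de_table(config$de),
                          lfc_min = config$lfc_min,
                          padj_max = config$padj_max)
      gene_sets <- list(
        DEG = deg$gene_id[deg$status != "nDEG"],
        nDEG = deg$gene_id[deg$status == "nDEG"],
        up = deg$gene_id[deg$status == "up"],
        down = deg$gene_id[deg$status == "down"]
      )
      message(sprintf("[gene-sets] %d up / %d down / %d nDEG",
                      length(gene_sets$up), length(gene_sets$down),
                      length(gene_sets$nDEG)))
    }
    dens <- density_profile(g4, regions, gene_sets = gene_sets)
    paths$densities <<- note(write_tsv_prov(
      dens, file.path(out_dir, "densities.tsv"), prov
    ))
    pct <- promoter_class_table(models, g4, clen,
                                promoter_len = config$promoter_len)
    paths$promoter_classes <<- note(write_tsv_prov(
      pct, file.path(out_dir, "promoter_classes.tsv"), prov
    ))

    if (!is.null(config$gene2term)) {
      stage <<- "enrichment"
      g2t <- read_gene2term(config$gene2term)
      universe <- unique(g2t$gene_id)
      hi <- intersect(
        select_high_g4_genes(models, g4, clen,
                             promoter_len = config$promoter_len),
        universe
      )
      enr <- hypergeom_enrichment(hi, g2t, universe = universe)
      message(sprintf("[enrichment] %d gene(s) tested over %d term(s)",
                      length(hi), nrow(enr)))
      paths$enrichment <<- note(write_tsv_prov(
        enr, file.path(out_dir, "enrichment.tsv"), prov
      ))
    }
    invisible(NULL)
  }

  tryCatch(run(), error = function(e) {
    unlink(created)
    abort(sprintf("Pipeline failed at stage '%s': %s", stage,
                  conditionMessage(e)), parent = e)
  })
  message("[done] outputs in ", out_dir)
  invisible(paths)
}
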