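#' Specification for a synthetic G4/SSR study genome
#'
#' Defaults describe the package's standard desk-scale study: a 1 Mb
#' AT-rich genome (two 500 kb chromosomes, GC 0.20) with planted
#' G4-forming motifs (a telomeric-repeat motif and a genome-survey motif
#' family, about half on each strand), planted SSRs spanning unit lengths
#' 1-4 and including the G4-capable `(GGA)13` trinucleotide repeat, 120
#' gene models with exons/introns/UTRs, two genes carrying a `(GGA)13`
#' SSR on the coding strand of their promoter, and a DE table with 30
#' planted up- and 50 planted down-regulated genes.
#'
#' @param n_chroms Number of chromosomes.
#' @param chrom_length_bp Length of each chromosome.
#' @param background_gc Background GC fraction (i.i.d. bases).
#' @param planted_g4s List of `list(motif =, count =)` entries; each copy
#'   is planted on a uniformly chosen strand (reverse-complemented on
#'   `-`).
#' @param planted_ssrs List of `list(motif =, n_repeats =, count =)`
#'   entries, planted as literal plus-strand repeats.
#' @param n_genes Number of gene models (split evenly across
#'   chromosomes).
#' @param promoter_ssr_genes Number of genes given a `(GGA)13` SSR on
#'   their promoter's coding strand.
#' @param n_up,n_down Planted up-/down-regulated gene counts.
#' @return A list of class `g4_sim_spec`.
#' @export
g4_sim_spec <- function(n_chroms = 2L,
                        chrom_length_bp = 500000L,
                        background_gc = 0.2,
                        planted_g4s = list(
                          list(motif = "GGGTTAGGGTTAGGGTTAGGG", count = 60L),
                          list(motif = "GGGGGTGTGTACAGACTCCGGAGGGG",
                               count = 40L)
                        ),
                        planted_ssrs = list(
                          list(motif = "GGA", n_repeats = 13L, count = 10L),
                          list(motif = "AT", n_repeats = 8L, count = 15L),
                          list(motif = "AAG", n_repeats = 6L, count = 10L),
                          list(motif = "A", n_repeats = 22L, count = 10L),
                          list(motif = "ACAT", n_repeats = 5L, count = 10L)
                        ),
                        n_genes = 120L,
                        promoter_ssr_genes = 2L,
                        n_up = 30L, n_down = 50L) {
  spec <- list(
    n_chroms = as.integer(n_chroms),
    chrom_length_bp = as.integer(chrom_length_bp),
    background_gc = background_gc,
    planted_g4s = planted_g4s,
    planted_ssrs = planted_ssrs,
    n_genes = as.integer(n_genes),
    promoter_ssr_genes = as.integer(promoter_ssr_genes),
    n_up = as.integer(n_up), n_down = as.integer(n_down)
  )
  stopifnot(spec$n_chroms >= 1L, spec$chrom_length_bp >= 10000L,
            background_gc > 0, background_gc < 1,
            spec$n_up + spec$n_down <= spec$n_genes)
  class(spec) <- "g4_sim_spec"
  spec
}

# sample gene models into per-chromosome slots so every gene has room for
# a full promoter2000 upstream
sim_gene_models <- function(spec, chrom_names) {
  per_chrom <- as.integer(diff(round(seq(0, spec$n_genes, length.out =
                                           spec$n_chroms + 1L))))
  gene_no <- 0L
  rows <- list()
  for (ci in seq_len(spec$n_chroms)) {
    ng <- per_chrom[ci]
    if (ng == 0L) next
    slot <- spec$chrom_length_bp %/% ng
    if (slot < 8000L) {
      abort("Too many genes per chromosome for the gene architecture.")
    }
    for (gi in seq_len(ng)) {
      gene_no <- gene_no + 1L
      slot_start <- (gi - 1L) * slot
      n_ex <- sample(2:4, 1L)
      ex_len <- sample(300:800, n_ex, replace = TRUE)
      in_len <- if (n_ex > 1L) sample(200:500, n_ex - 1L, replace = TRUE)
                else integer(0)
      g0 <- slot_start + 2200L + sample(0:300, 1L)
      pos <- g0
      ex <- matrix(0L, n_ex, 2L)
      for (e in seq_len(n_ex)) {
        ex[e, ] <- c(pos, pos + ex_len[e])
        pos <- pos + ex_len[e] + if (e < n_ex) in_len[e] else 0L
      }
      g1 <- ex[n_ex, 2L]
      strand <- sample(c("+", "-"), 1L)
      exons <- iv_df(ex[, 1L], ex[, 2L])
      first <- if (strand == "+") 1L else n_ex
      last <- if (strand == "+") n_ex else 1L
      utr5 <- if (strand == "+") iv_df(ex[first, 1L], ex[first, 1L] + 150L)
              else iv_df(ex[first, 2L] - 150L, ex[first, 2L])
      utr3 <- if (strand == "+") iv_df(ex[last, 2L] - 150L, ex[last, 2L])
              else iv_df(ex[last, 1L], ex[last, 1L] + 150L)
      cds <- iv_setdiff(iv_setdiff(exons, utr5), utr3)
      rows[[gene_no]] <- tibble(
        gene_id = sprintf("gene%03d", gene_no),
        chrom = chrom_names[ci], start = as.integer(g0),
        end = as.integer(g1), strand = strand,
        exons = list(exons), cds = list(cds), utr5 = list(utr5),
        utr3 = list(utr3)
      )
    }
  }
  bind_rows(rows)
}

#' Simulate a genome, annotation and DE table with planted ground truth
#'
#' Draws i.i.d. background bases at the requested GC fraction, lays out
#' gene models in non-overlapping slots (each with room for a 2 kb
#' promoter), then plants G4 motifs and SSR repeats at uniformly drawn
#' positions with a 50 bp exclusion zone between insertions (gene
#' coordinates are independent of insertion positions, so planted motifs
#' can fall in any feature region). Planted repeats receive guard bases
#' at both flanks so the maximal perfect repeat coincides exactly with
#' the planted span. `promoter_ssr_genes` genes additionally get a
#' `(GGA)13` repeat on the coding strand of their 2 kb promoter. The DE
#' table has planted `up` genes with `log2fc` in (1.5, 4) and `padj`
#' below 0.01, `down` genes mirrored, and background genes that fail both
#' screening thresholds.
#'
#' All randomness comes from R's RNG: fix it (e.g.
#' `withr::with_seed(1, simulate_g4_study())`) for byte-identical output.
#'
#' @param spec A [g4_sim_spec()].
#' @return A list of class `g4_simulation` with elements `genome` (named
#'   character vector), `models` (gene-model tibble), `de` (tibble
#'   `gene_id`, `log2fc`, `padj`) and `truth` (tibble `kind`
#'   (`g4`/`ssr`/`gene`/`deg`), `chrom`, `start`, `end`, `strand`,
#'   `motif`, `n_repeats`, `gene_id`, `label`).
#' @export
simulate_g4_study <- function(spec = g4_sim_spec()) {
  stopifnot(inherits(spec, "g4_sim_spec"))
  chrom_names <- sprintf("chr%d", seq_len(spec$n_chroms))
  len <- spec$chrom_length_bp
  gc <- spec$background_gc
  chars <- lapply(seq_len(spec$n_chroms), function(i) {
    sample(c("A", "C", "G", "T"), len, replace = TRUE,
           prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
  })
  names(chars) <- chrom_names

  models <- sim_gene_models(spec, chrom_names)

  occupied <- lapply(chrom_names, function(x) iv_df())
  names(occupied) <- chrom_names
  truth <- list()

  place_guard <- function(ci, at, forbidden) {
    # guard base breaking repeat periodicity at position `at` (0-based)
    if (at < 0L || at >= len) return(invisible(NULL))
    chars[[ci]][at + 1L] <<- if (forbidden == "T") "A" else "T"
    invisible(NULL)
  }
  insert_at <- function(ci, pos0, ins, guard_unit = NULL) {
    n <- nchar(ins)
    chars[[ci]][(pos0 + 1L):(pos0 + n)] <<-
      strsplit(ins, "", fixed = TRUE)[[1]]
    if (!is.null(guard_unit)) {
      k <- nchar(guard_unit)
      place_guard(ci, pos0 - 1L, substr(guard_unit, k, k))
      place_guard(ci, pos0 + n, substr(guard_unit, 1L, 1L))
    }
    occupied[[ci]] <<- iv_reduce(bind_rows(
      occupied[[ci]], iv_df(pos0 - 1L, pos0 + n + 1L)
    ))
    invisible(NULL)
  }
  draw_position <- function(ins_len, gap = 50L) {
    for (try in 1:2000) {
      ci <- sample(chrom_names, 1L)
      pos0 <- sample.int(len - ins_len - 2L * gap, 1L) + gap
      cand <- iv_df(pos0 - gap, pos0 + ins_len + gap)
      ov <- IRanges::findOverlaps(
        IRanges::IRanges(cand$start + 1L, cand$end),
        IRanges::IRanges(occupied[[ci]]$start + 1L, occupied[[ci]]$end)
      )
      if (length(ov) == 0L) return(list(chrom = ci, pos0 = pos0))
    }
    abort("Infeasible planted-feature packing; reduce counts or lengthen chromosomes.")
  }

  # Fig-9-style promoter SSRs first (their positions are gene-relative)
  if (spec$promoter_ssr_genes > 0L) {
    idx <- sample(nrow(models), spec$promoter_ssr_genes)
    for (i in idx) {
      g <- models[i, ]
      rep_len <- 39L
      off <- 800L + sample(0:200, 1L)
      if (g$strand == "+") {
        pos0 <- g$start - off
        ins <- strrep("GGA", 13L)
        unit <- "GGA"
      } else {
        pos0 <- g$end + off - rep_len
        ins <- strrep("TCC", 13L)
        unit <- "TCC"
      }
      insert_at(g$chrom, pos0, ins, guard_unit = unit)
      truth[[length(truth) + 1L]] <- tibble(
        kind = "ssr", chrom = g$chrom, start = pos0, end = pos0 + rep_len,
        strand = g$strand, motif = unit, n_repeats = 13L,
        gene_id = g$gene_id, label = "promoter_ssr"
      )
    }
  }

  for (pg in spec$planted_g4s) {
    for (j in seq_len(pg$count)) {
      strand <- sample(c("+", "-"), 1L)
      ins <- if (strand == "+") pg$motif else revcomp(pg$motif)
      at <- draw_position(nchar(ins))
      insert_at(at$chrom, at$pos0, ins)
      truth[[length(truth) + 1L]] <- tibble(
        kind = "g4", chrom = at$chrom, start = at$pos0,
        end = at$pos0 + nchar(ins), strand = strand, motif = pg$motif,
        n_repeats = NA_integer_, gene_id = NA_character_,
        label = NA_character_
      )
    }
  }

  for (ps in spec$planted_ssrs) {
    ins <- strrep(ps$motif, ps$n_repeats)
    for (j in seq_len(ps$count)) {
      at <- draw_position(nchar(ins))
      insert_at(at$chrom, at$pos0, ins, guard_unit = ps$motif)
      truth[[length(truth) + 1L]] <- tibble(
        kind = "ssr", chrom = at$chrom, start = at$pos0,
        end = at$pos0 + nchar(ins), strand = "+", motif = ps$motif,
        n_repeats = ps$n_repeats, gene_id = NA_character_,
        label = NA_character_
      )
    }
  }

  # DE table with planted labels
  ids <- sample(models$gene_id)
  status <- rep("nDEG", length(ids))
  status[seq_len(spec$n_up)] <- "up"
  status[spec$n_up + seq_len(spec$n_down)] <- "down"
  de <- tibble(
    gene_id = ids,
    log2fc = dplyr::case_when(
      status == "up" ~ runif(length(ids), 1.5, 4),
      status == "down" ~ -runif(length(ids), 1.5, 4),
      TRUE ~ runif(length(ids), -0.95, 0.95)
    ),
    padj = ifelse(status == "nDEG",
                  runif(length(ids), 0.06, 1),
                  runif(length(ids), 1e-8, 0.01))
  ) |> arrange(.data$gene_id)

  truth_genes <- models |>
    mutate(kind = "gene", motif = NA_character_, n_repeats = NA_integer_,
           label = NA_character_) |>
    select("kind", "chrom", "start", "end", "strand", "motif",
           "n_repeats", "gene_id", "label")
  truth_deg <- tibble(
    kind = "deg", chrom = NA_character_, start = NA_integer_,
    end = NA_integer_, strand = NA_character_, motif = NA_character_,
    n_repeats = NA_integer_, gene_id = ids, label = status
  )

  genome <- vapply(chars, paste, character(1), collapse = "")
  out <- list(
    genome = genome,
    models = models,
    de = de,
    truth = bind_rows(c(truth, list(truth_genes, truth_deg)))
  )
  class(out) <- "g4_simulation"
  out
}

#' Write a simulation to disk
#'
#' Produces `genome.fa`, `annotation.gff3`, `de_table.tsv` (columns
#' `gene_id`, `log2FoldChange`, `padj`) and `truth.tsv`.
#'
#' @param sim Result of [simulate_g4_study()].
#' @param out_dir Output directory (created if needed).
#' @return Named character vector of the four paths, invisibly.
#' @export
write_simulation <- function(sim, out_dir) {
  stopifnot(inherits(sim, "g4_simulation"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    genome = file.path(out_dir, "genome.fa"),
    annotation = file.path(out_dir, "annotation.gff3"),
    de = file.path(out_dir, "de_table.tsv"),
    truth = file.path(out_dir, "truth.tsv")
  )
  write_genome(sim$genome, paths[["genome"]])
  write_gff3(sim$models, paths[["annotation"]])
  readr::write_tsv(
    dplyr::rename(sim$de, log2FoldChange = "log2fc"), paths[["de"]]
  )
  readr::write_tsv(sim$truth, paths[["truth"]])
  invisible(paths)
}
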