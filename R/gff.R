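# Interval list-columns hold data.frames with 0-based half-open start/end,
# sorted and non-overlapping.

iv_df <- function(start = integer(0), end = integer(0)) {
  d <- data.frame(start = as.integer(start), end = as.integer(end))
  d <- d[d$end > d$start, , drop = FALSE]
  d <- d[order(d$start), , drop = FALSE]
  rownames(d) <- NULL
  d
}

# merge overlapping/adjacent intervals of an iv_df
iv_reduce <- function(iv) {
  if (nrow(iv) == 0L) return(iv)
  r <- IRanges::reduce(IRanges::IRanges(iv$start + 1L, iv$end))
  iv_df(IRanges::start(r) - 1L, IRanges::end(r))
}

# set difference a \ b on iv_dfs
iv_setdiff <- function(a, b) {
  if (nrow(a) == 0L) return(a)
  ra <- IRanges::IRanges(a$start + 1L, a$end)
  rb <- IRanges::IRanges(b$start + 1L, b$end)
  r <- IRanges::setdiff(ra, rb)
  iv_df(IRanges::start(r) - 1L, IRanges::end(r))
}

iv_total <- function(iv) sum(iv$end - iv$start)

#' Parse gene models from a GFF3 file
#'
#' Reads `gene`/`mRNA`/`exon`/`CDS` (and optional
#' `five_prime_UTR`/`three_prime_UTR`) features, converts the 1-based
#' inclusive GFF coordinates to 0-based half-open, unions exon and CDS
#' intervals across isoforms of a gene, and derives UTRs as exon-minus-CDS
#' (split 5'/3' by strand) when UTR features are absent.
#'
#' @param path Path to a GFF3 file.
#' @return A tibble with one row per gene: `gene_id`, `chrom`, `start`,
#'   `end` (0-based half-open span), `strand`, and list-columns `exons`,
#'   `cds`, `utr5`, `utr3` of interval data frames (`start`, `end`).
#' @export
parse_gff <- function(path) {
  gr <- rtracklayer::import(path)
  md <- as.data.frame(gr)
  md$Parent <- vapply(
    as.list(md$Parent %||% rep(list(character(0)), nrow(md))),
    function(p) if (length(p)) as.character(p)[1] else NA_character_,
    character(1)
  )
  md$ID <- as.character(md$ID %||% rep(NA_character_, nrow(md)))
  md$start0 <- md$start - 1L # to 0-based half-open
  md$end0 <- md$end

  genes <- md[md$type == "gene", , drop = FALSE]
  if (nrow(genes) == 0L) abort("No 'gene' features found in GFF3.")
  if (anyNA(genes$ID)) abort("GFF3 'gene' feature without an ID attribute.")
  mrna <- md[md$type == "mRNA", , drop = FALSE]
  mrna2gene <- setNames(mrna$Parent, mrna$ID)
  if (nrow(mrna) > 0L && anyNA(mrna$Parent)) {
    abort("GFF3 'mRNA' feature without a Parent gene.")
  }

  child_gene <- function(d) {
    if (nrow(d) == 0L) return(character(0))
    g <- ifelse(d$Parent %in% names(mrna2gene),
                unname(mrna2gene[d$Parent]), d$Parent)
    if (anyNA(g)) abort(sprintf("GFF3 '%s' feature without a Parent.",
                                as.character(d$type[1])))
    missing <- setdiff(unique(g), genes$ID)
    if (length(missing)) {
      abort(sprintf("GFF3 child features reference unknown gene(s): %s",
                    paste(missing, collapse = ", ")))
    }
    g
  }

  pick <- function(types) {
    d <- md[md$type %in% types, , drop = FALSE]
    d$gene_id <- child_gene(d)
    split(d[, c("start0", "end0")], d$gene_id)
  }
  exon_by <- pick("exon")
  cds_by <- pick("CDS")
  utr5_by <- pick(c("five_prime_UTR", "5UTR"))
  utr3_by <- pick(c("three_prime_UTR", "3UTR"))
  have_utr_features <- length(utr5_by) > 0L || length(utr3_by) > 0L

  out <- purrr::pmap(
    list(genes$ID, as.character(genes$seqnames), genes$start0, genes$end0,
         as.character(genes$strand)),
    function(gid, chrom, g0, g1, strand) {
      if (!strand %in% c("+", "-")) {
        abort(sprintf("Gene %s has undefined strand.", gid))
      }
      grab <- function(byl) {
        d <- byl[[gid]]
        if (is.null(d)) iv_df() else iv_reduce(iv_df(d$start0, d$end0))
      }
      exons <- grab(exon_by)
      cds <- grab(cds_by)
      if (nrow(exons) == 0L) exons <- iv_df(g0, g1)
      if (nrow(exons) > 0L &&
          (min(exons$start) < g0 || max(exons$end) > g1)) {
        abort(sprintf("Gene %s has exons outside its span.", gid))
      }
      if (nrow(iv_setdiff(cds, exons)) > 0L) {
        abort(sprintf("Gene %s has CDS outside its exons.", gid))
      }
      if (have_utr_features) {
        utr5 <- grab(utr5_by)
        utr3 <- grab(utr3_by)
      } else if (nrow(cds) > 0L) {
        rest <- iv_setdiff(exons, cds)
        c0 <- min(cds$start)
        c1 <- max(cds$end)
        left <- iv_df(rest$start[rest$end <= c0], rest$end[rest$end <= c0])
        right <- iv_df(rest$start[rest$start >= c1],
                       rest$end[rest$start >= c1])
        if (strand == "+") {
          utr5 <- left
          utr3 <- right
        } else {
          utr5 <- right
          utr3 <- left
        }
      } else {
        utr5 <- iv_df()
        utr3 <- iv_df()
      }
      tibble(
        gene_id = gid, chrom = chrom, start = g0, end = g1, strand = strand,
        exons = list(exons), cds = list(cds), utr5 = list(utr5),
        utr3 = list(utr3)
      )
    }
  ) |>
    bind_rows() |>
    arrange(.data$chrom, .data$start)
  out
}

#' Write gene models to GFF3
#'
#' Emits one `gene`, one `mRNA` and the `exon`/`CDS`/UTR children per
#' gene, converting 0-based half-open coordinates back to 1-based
#' inclusive GFF3.
#'
#' @param models Gene-model tibble (see [parse_gff()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(models, path) {
  lines <- c("##gff-version 3")
  for (i in seq_len(nrow(models))) {
    g <- models[i, ]
    gid <- g$gene_id
    mid <- paste0(gid, ".t1")
    row9 <- function(type, s0, e0, id = NULL, parent = NULL) {
      attrs <- c(
        if (!is.null(id)) paste0("ID=", id),
        if (!is.null(parent)) paste0("Parent=", parent)
      )
      paste(g$chrom, "g4landscape", type, s0 + 1L, e0, ".", g$strand, ".",
            paste(attrs, collapse = ";"), sep = "\t")
    }
    lines <- c(lines, row9("gene", g$start, g$end, id = gid))
    lines <- c(lines, row9("mRNA", g$start, g$end, id = mid, parent = gid))
    emit <- function(iv, type) {
      if (nrow(iv) == 0L) return(character(0))
      vapply(seq_len(nrow(iv)), function(j) {
        row9(type, iv$start[j], iv$end[j], parent = mid)
      }, character(1))
    }
    lines <- c(lines,
               emit(g$exons[[1]], "exon"),
               emit(g$cds[[1]], "CDS"),
               emit(g$utr5[[1]], "five_prime_UTR"),
               emit(g$utr3[[1]], "three_prime_UTR"))
  }
  writeLines(lines, path)
  invisible(path)
}
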