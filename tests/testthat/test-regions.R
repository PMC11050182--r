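gff_text <- function(lines) {
  f <- withr::local_tempfile(fileext = ".gff3",
                             .local_envir = parent.frame())
  writeLines(c("##gff-version 3", lines), f)
  f
}

row9 <- function(chrom, type, start1, end1, strand, attrs) {
  paste(chrom, "test", type, start1, end1, ".", strand, ".", attrs,
        sep = "\t")
}

test_that("UTRs are derived from exon minus CDS with strand geometry", {
  plus <- gff_text(c(
    row9("c1", "gene", 1001, 2000, "+", "ID=g1"),
    row9("c1", "mRNA", 1001, 2000, "+", "ID=m1;Parent=g1"),
    row9("c1", "exon", 1001, 1200, "+", "Parent=m1"),
    row9("c1", "exon", 1501, 2000, "+", "Parent=m1"),
    row9("c1", "CDS", 1101, 1200, "+", "Parent=m1"),
    row9("c1", "CDS", 1501, 1900, "+", "Parent=m1")
  ))
  m <- parse_gff(plus)
  expect_identical(m$start, 1000L)
  expect_identical(m$end, 2000L)
  expect_identical(m$utr5[[1]], data.frame(start = 1000L, end = 1100L))
  expect_identical(m$utr3[[1]], data.frame(start = 1900L, end = 2000L))

  minus <- gff_text(c(
    row9("c1", "gene", 1001, 2000, "-", "ID=g1"),
    row9("c1", "mRNA", 1001, 2000, "-", "ID=m1;Parent=g1"),
    row9("c1", "exon", 1001, 1200, "-", "Parent=m1"),
    row9("c1", "exon", 1501, 2000, "-", "Parent=m1"),
    row9("c1", "CDS", 1101, 1200, "-", "Parent=m1"),
    row9("c1", "CDS", 1501, 1900, "-", "Parent=m1")
  ))
  mm <- parse_gff(minus)
  expect_identical(mm$utr5[[1]], data.frame(start = 1900L, end = 2000L))
  expect_identical(mm$utr3[[1]], data.frame(start = 1000L, end = 1100L))

  nc <- gff_text(c(
    row9("c1", "gene", 501, 800, "+", "ID=g2"),
    row9("c1", "mRNA", 501, 800, "+", "ID=m2;Parent=g2"),
    row9("c1", "exon", 501, 800, "+", "Parent=m2")
  ))
  mn <- parse_gff(nc)
  expect_identical(nrow(mn$utr5[[1]]), 0L)
  expect_identical(nrow(mn$utr3[[1]]), 0L)
  expect_identical(mn$exons[[1]], data.frame(start = 500L, end = 800L))
})

test_that("malformed annotations are rejected", {
  orphan <- gff_text(c(
    row9("c1", "gene", 1, 100, "+", "ID=g1"),
    row9("c1", "exon", 10, 50, "+", "Parent=missing")
  ))
  expect_error(parse_gff(orphan), "unknown gene")
  outside <- gff_text(c(
    row9("c1", "gene", 101, 200, "+", "ID=g1"),
    row9("c1", "mRNA", 101, 200, "+", "ID=m1;Parent=g1"),
    row9("c1", "exon", 51, 150, "+", "Parent=m1")
  ))
  expect_error(parse_gff(outside), "outside its span")
})

test_that("promoter and TSS windows follow strand-aware definitions", {
  m <- make_gene("g1", "c1", 3000, 4000, "+")
  r <- derive_region_sets(m, c(c1 = 10000L))
  p500 <- r[r$region_class == "promoter500", ]
  expect_identical(c(p500$start, p500$end), c(2500L, 3000L))
  t500 <- r[r$region_class == "TSS500", ]
  expect_identical(c(t500$start, t500$end), c(2750L, 3250L))
  p2000 <- r[r$region_class == "promoter2000", ]
  expect_identical(c(p2000$start, p2000$end), c(1000L, 3000L))

  mneg <- make_gene("g1", "c1", 3000, 4000, "-")
  rn <- derive_region_sets(mneg, c(c1 = 10000L))
  p500n <- rn[rn$region_class == "promoter500", ]
  expect_identical(c(p500n$start, p500n$end), c(4000L, 4500L))
  t500n <- rn[rn$region_class == "TSS500", ]
  # mirrored 500 bp window centred on the TSS base at 3999
  expect_identical(c(t500n$start, t500n$end), c(3750L, 4250L))
})

test_that("regions are clipped at chromosome boundaries with a warning", {
  m <- make_gene("g1", "c1", 100, 600, "+")
  expect_warning(r <- derive_region_sets(m, c(c1 = 1000L)), "clipped")
  p2000 <- r[r$region_class == "promoter2000", ]
  expect_identical(c(p2000$start, p2000$end), c(0L, 100L))
})

test_that("gene/intergenic and exon/intron partitions are exact", {
  withr::with_seed(71, sim <- simulate_g4_study(small_sim_spec()))
  clen <- chrom_lengths(sim$genome)
  r <- derive_region_sets(sim$models, clen)
  tot <- region_totals(r)
  bp <- function(cls) tot$total_bp[tot$region_class == cls]
  expect_identical(bp("exon") + bp("intron"), bp("gene"))
  expect_identical(bp("gene") + bp("intergenic"),
                   as.integer(sum(clen)))
  # per-gene partition
  for (i in seq_len(nrow(sim$models))) {
    g <- sim$models[i, ]
    span <- g$end - g$start
    ex <- sum(g$exons[[1]]$end - g$exons[[1]]$start)
    intr <- r |>
      dplyr::filter(region_class == "intron", gene_id == g$gene_id)
    expect_identical(ex + sum(intr$end - intr$start), span)
  }
  # promoter nesting per gene
  for (N in c(500L, 1000L, 1500L)) {
    a <- r[r$region_class == paste0("promoter", N), ]
    b <- r[r$region_class == paste0("promoter", N + 500L), ]
    ab <- dplyr::inner_join(a, b, by = "gene_id")
    expect_true(all(ab$end.x - ab$start.x <= ab$end.y - ab$start.y))
  }
})

test_that("G4 assignment matches a quadratic brute-force overlap count", {
  withr::with_seed(81, {
    for (rep in 1:5) {
      n_r <- sample(20:60, 1)
      regions <- tibble::tibble(
        region_class = sample(c("exon", "gene", "promoter500"), n_r,
                              replace = TRUE),
        chrom = sample(c("c1", "c2"), n_r, replace = TRUE),
        start = sample(0:900, n_r, replace = TRUE)
      ) |>
        dplyr::mutate(end = start + sample(10:120, n_r, replace = TRUE),
                      gene_id = paste0("g", seq_len(n_r)),
                      gene_strand = sample(c("+", "-"), n_r,
                                           replace = TRUE))
      n_g <- sample(20:80, 1)
      g4 <- tibble::tibble(
        chrom = sample(c("c1", "c2"), n_g, replace = TRUE),
        start = sample(0:980, n_g, replace = TRUE)
      ) |>
        dplyr::mutate(end = start + sample(15:40, n_g, replace = TRUE),
                      strand = sample(c("+", "-"), n_g, replace = TRUE))
      for (ctx in c("double", "template", "coding")) {
        got <- assign_g4(g4, regions, ctx)
        want <- oracle_assign_g4(g4, regions, ctx)
        expect_identical(setNames(got$g4_count, got$region_class), want)
      }
      # context additivity
      d <- assign_g4(g4, regions, "double")
      t <- assign_g4(g4, regions, "template")
      co <- assign_g4(g4, regions, "coding")
      expect_true(all(t$g4_count + co$g4_count >= d$g4_count))
    }
  })
})

test_that("template and coding counts add to double counts per class", {
  withr::with_seed(91, sim <- simulate_g4_study(small_sim_spec()))
  g4 <- scan_g4(sim$genome)
  r <- derive_region_sets(sim$models, chrom_lengths(sim$genome)) |>
    dplyr::filter(!is.na(gene_strand))
  d <- assign_g4(g4, r, "double")
  t <- assign_g4(g4, r, "template")
  co <- assign_g4(g4, r, "coding")
  expect_identical(t$g4_count + co$g4_count, d$g4_count)
})

test_that("stranded contexts reject gene-less region classes", {
  m <- make_gene("g1", "c1", 3000, 4000, "+")
  r <- derive_region_sets(m, c(c1 = 10000L))
  inter <- r[r$region_class == "intergenic", ]
  g4 <- tibble::tibble(chrom = "c1", start = 10L, end = 40L, strand = "+")
  expect_error(assign_g4(g4, inter, "template"), "gene-linked")
  expect_silent(assign_g4(g4, inter, "double"))
})
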