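test_that("minimum repeat thresholds gate SSR detection per unit length", {
  fill <- ssr_free_filler(60)
  # 19 A's are below the mononucleotide minimum of 20
  s19 <- paste0(fill, "T", strrep("A", 19), "T", fill)
  expect_identical(nrow(find_ssrs(s19)), 0L)
  s20 <- paste0(fill, "T", strrep("A", 20), "T", fill)
  hit <- find_ssrs(s20)
  expect_identical(hit$motif, "A")
  expect_identical(hit$ssr_class, "p1")
  expect_identical(hit$n_repeats, 20L)

  agg <- find_ssrs(paste0("TTTT", strrep("AGG", 8), "TTTT"))
  expect_identical(nrow(agg), 1L)
  expect_identical(agg$motif, "AGG")
  expect_identical(agg$unit_len, 3L)
  expect_identical(agg$n_repeats, 8L)
  expect_identical(agg$ssr_class, "p3")
  expect_identical(agg$start, 4L)
  expect_identical(agg$end, 4L + 24L)

  at <- find_ssrs(paste0("GGCC", strrep("AT", 6), "GGCC"))
  expect_identical(at$motif, "AT")
  expect_identical(at$ssr_class, "p2")
})

test_that("reported motifs are primitive and spans cover whole units", {
  # a pure A run is p1, never AA/AAA
  run <- find_ssrs(paste0("T", strrep("A", 24), "T"))
  expect_identical(run$motif, "A")
  expect_identical(nrow(run), 1L)
  # (AT)8 is p2 only, not ATAT
  at <- find_ssrs(strrep("AT", 8))
  expect_identical(at$motif, "AT")
  # trailing partial unit is excluded from the span
  tr <- find_ssrs(paste0("TT", strrep("AGG", 6), "AG", "TT"))
  expect_identical(tr$end - tr$start, 18L)
})

test_that("detection is deterministic", {
  s <- paste0(ssr_free_filler(40), strrep("GGA", 13), ssr_free_filler(40))
  expect_identical(find_ssrs(s), find_ssrs(s))
})

test_that("compound merging groups SSRs within the interruption limit", {
  fill <- ssr_free_filler(300)
  two <- function(gap) {
    paste0("T", strrep("AGG", 5), substr(fill, 1, gap), strrep("TCT", 5),
           "G")
  }
  near <- merge_compound(find_ssrs(two(7)))
  expect_identical(near$ssr_class, "compound")
  expect_identical(near$n_members, 2L)
  at_limit <- merge_compound(find_ssrs(two(100)))
  expect_identical(at_limit$ssr_class, "compound")
  far <- merge_compound(find_ssrs(two(101)))
  expect_identical(nrow(far), 2L)
  expect_true(all(far$n_members == 1L))
})

test_that("the printed six-member compound repeat reconstructs exactly", {
  s <- paste0(strrep("AAG", 5), "ATTTTGG", strrep("ATA", 5),
              strrep("AGA", 6), "GGTTGGATA", strrep("AGG", 8), "AT",
              strrep("GAG", 8), "A", strrep("AGG", 5))
  expect_identical(nchar(s), 130L)
  simple <- find_ssrs(s)
  expect_identical(nrow(simple), 6L)
  expect_identical(simple$motif, c("AAG", "ATA", "AGA", "AGG", "GAG",
                                   "AGG"))
  comp <- merge_compound(simple)
  expect_identical(nrow(comp), 1L)
  expect_identical(comp$ssr_class, "compound")
  expect_identical(comp$n_members, 6L)
  expect_identical(comp$start, 0L)
  expect_identical(comp$end, 130L)
  expect_identical(nrow(comp$members[[1]]), 6L)
})

test_that("trinucleotide G4 capability follows the two-G/two-C rule", {
  expect_true(p3_g4_potential("AGG"))
  expect_false(p3_g4_potential("AAG"))
  expect_true(p3_g4_potential("GCG"))
  expect_true(all(p3_g4_potential(c("CCA", "TCC", "GGT", "CGC"))))
  expect_false(any(p3_g4_potential(c("ATG", "TTA", "ACT", "AAA"))))
  expect_error(p3_g4_potential("AG"), "3-base")
})

test_that("motif family normalisation groups rotations and complements", {
  expect_identical(normalize_motif("GGA"), normalize_motif("AGG"))
  expect_identical(normalize_motif("GGA"), normalize_motif("TCC"))
  expect_identical(normalize_motif("GGA"), normalize_motif("CCT"))
  expect_identical(normalize_motif("AT"), "AT")
})

test_that("SSR-G4 association counts half-open overlaps within flanks", {
  ssrs <- tibble::tibble(chrom = "c", start = 100L, end = 130L,
                         motif = "AGG", motif_norm = "AGG", unit_len = 3L,
                         n_repeats = 10L, ssr_class = "p3")
  g4 <- tibble::tibble(chrom = "c", start = 125L, end = 150L,
                       strand = "+", score = 1.5, abs_score = 1.5,
                       length = 25L, g_rich_seq = "x")
  expect_identical(ssr_g4_association(ssrs, g4)$g4_count, 1L)
  g4b <- dplyr::mutate(g4, start = 130L)
  expect_identical(ssr_g4_association(ssrs, g4b)$g4_count, 0L)
  expect_identical(ssr_g4_association(ssrs, g4b, flank = 1L)$g4_count, 1L)
  g4c <- dplyr::mutate(g4, chrom = "other")
  expect_error(ssr_g4_association(ssrs, g4c), "no chromosome names")
})

test_that("planted GGA repeats each associate with a detected G4", {
  withr::with_seed(61, {
    spec <- g4_sim_spec(
      n_chroms = 1L, chrom_length_bp = 80000L, background_gc = 0.2,
      planted_g4s = list(),
      planted_ssrs = list(list(motif = "GGA", n_repeats = 13L,
                               count = 10L)),
      n_genes = 6L, promoter_ssr_genes = 0L, n_up = 2L, n_down = 2L
    )
    sim <- simulate_g4_study(spec)
  })
  g4 <- scan_g4(sim$genome)
  ssrs <- scan_ssrs(sim$genome)
  planted <- dplyr::semi_join(
    ssrs, dplyr::filter(sim$truth, kind == "ssr"),
    by = c("chrom", "start", "end")
  )
  expect_identical(nrow(planted), 10L)
  assoc <- ssr_g4_association(planted, g4)
  expect_true(all(assoc$g4_count >= 1L))
  # incidence symmetry: the same total computed G4-first
  total_ssr_first <- sum(ssr_g4_association(ssrs, g4)$g4_count)
  q <- GenomicRanges::GRanges(g4$chrom,
                              IRanges::IRanges(g4$start + 1L, g4$end))
  s <- GenomicRanges::GRanges(ssrs$chrom,
                              IRanges::IRanges(ssrs$start + 1L, ssrs$end))
  total_g4_first <- sum(GenomicRanges::countOverlaps(q, s))
  expect_identical(total_ssr_first, total_g4_first)
})
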