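test_that("per-base run scores follow the capped run rule", {
  expect_identical(base_scores("GGG"), c(3L, 3L, 3L))
  expect_identical(base_scores("ATATN"), rep(0L, 5))
  expect_identical(sum(base_scores("GGGGGTGTGTACAGACTCCGGAGGGG")), 37L)
  expect_identical(base_scores("GGGGGG"), rep(4L, 6))
  expect_identical(base_scores("CCcc"), rep(-4L, 4))
  # N breaks runs
  expect_identical(base_scores("GGNGG"), c(2L, 2L, 0L, 2L, 2L))
  withr::with_seed(5, {
    for (i in 1:25) {
      s <- random_seq(sample(10:80, 1), gc = runif(1, 0.2, 0.8))
      expect_identical(base_scores(s), oracle_base_scores(s))
    }
  })
})

test_that("whole-sequence scores reproduce published motif values", {
  expect_equal(hunter_score("GGGGGTGTGTACAGACTCCGGAGGGG"), 1.423077,
               tolerance = 1e-6)
  expect_equal(hunter_score("GGGGGCCTCGGGTGTGTTTCGGATG"), 1.200000,
               tolerance = 1e-6)
  expect_equal(hunter_score("GGGGTGTGTACAGACTCCGGAGGGG"), 1.320000,
               tolerance = 1e-6)
  expect_equal(hunter_score("CTGGGGGTGTACAGACTCCGGAGGGGCT"), 1.214286,
               tolerance = 1e-6)
  expect_identical(hunter_score("CCCC"), -4)
})

test_that("scoring is antisymmetric under reverse complement and bounded", {
  withr::with_seed(11, {
    for (i in 1:50) {
      s <- random_seq(sample(5:120, 1), gc = runif(1, 0.1, 0.9))
      expect_identical(hunter_score(revcomp(s)), -hunter_score(s))
      expect_true(all(abs(base_scores(s)) <= 4))
    }
  })
})

test_that("window scores match the naive per-window mean", {
  s25 <- random_seq(25)
  expect_equal(window_scores(s25, 25), hunter_score(s25))
  expect_identical(window_scores(strrep("A", 30), 25), rep(0, 6))
  # whole sequence is one window when shorter than the window
  s10 <- "GGGGGTTTTT"
  expect_equal(window_scores(s10, 25), hunter_score(s10))
  withr::with_seed(21, {
    for (i in 1:50) {
      s <- random_seq(100, gc = runif(1, 0.2, 0.8))
      expect_equal(window_scores(s, 25), oracle_window_scores(s, 25),
                   tolerance = 1e-12)
    }
  })
})

test_that("reverse complement is a valid involution", {
  expect_identical(revcomp("ACGT"), "ACGT")
  expect_identical(revcomp("GGG"), "CCC")
  expect_identical(revcomp("AN"), "NT")
  withr::with_seed(31, {
    for (i in 1:20) {
      s <- random_seq(sample(1:60, 1))
      expect_identical(revcomp(revcomp(s)), s)
    }
  })
  expect_error(revcomp("ACGU"), "Invalid character")
})

test_that("invalid characters are rejected with their position", {
  expect_error(base_scores("ACGX"), "position 4")
  expect_error(detect_g4("AC-GT"), "position 3")
})

test_that("detection finds planted quadruplex tracts with exact merging", {
  expect_identical(nrow(detect_g4(strrep("A", 200))), 0L)

  s <- paste0(strrep("T", 50), "GGGTTAGGGTTAGGGTTAGGG", strrep("T", 50))
  hit <- detect_g4(s)
  expect_identical(nrow(hit), 1L)
  expect_identical(hit$start, 50L)
  expect_identical(hit$end, 71L)
  expect_identical(hit$strand, "+")
  expect_equal(hit$score, 36 / 21)
  expect_identical(hit$g_rich_seq, "GGGTTAGGGTTAGGGTTAGGG")

  mir <- detect_g4(revcomp(s))
  expect_identical(nrow(mir), 1L)
  expect_identical(mir$start, 50L)
  expect_identical(mir$end, 71L)
  expect_identical(mir$strand, "-")
  expect_identical(mir$g_rich_seq, hit$g_rich_seq)
  expect_equal(mir$score, -hit$score)
})

test_that("detection is exactly strand-symmetric on random sequences", {
  withr::with_seed(41, {
    for (i in 1:40) {
      n <- sample(150:400, 1)
      s <- random_seq(n, gc = 0.45)
      if (i %% 2 == 0) {
        p <- sample(seq_len(n - 30), 1)
        substr(s, p, p + 20) <- "GGGTTAGGGTTAGGGTTAGGG"
      }
      a <- detect_g4(s)
      b <- detect_g4(revcomp(s))
      key_a <- paste(a$start, a$end, a$strand,
                     signif(a$score, 12), a$g_rich_seq)
      key_b <- paste(n - b$end, n - b$start,
                     ifelse(b$strand == "+", "-", "+"),
                     signif(-b$score, 12), b$g_rich_seq)
      expect_setequal(key_a, key_b)
    }
  })
})

test_that("reported regions satisfy score and overlap invariants", {
  withr::with_seed(51, {
    for (i in 1:20) {
      s <- random_seq(500, gc = 0.6)
      hits <- detect_g4(s)
      if (nrow(hits) == 0L) next
      expect_true(all(hits$abs_score >= 1.2))
      expect_true(all(abs(hits$score) <= 4))
      expect_true(all((hits$strand == "+") == (hits$score > 0)))
      expect_true(all(nchar(hits$g_rich_seq) == hits$length))
      # same-strand regions never overlap
      for (st in c("+", "-")) {
        h <- hits[hits$strand == st, ]
        if (nrow(h) > 1L) {
          h <- h[order(h$start), ]
          expect_true(all(h$start[-1] >= h$end[-nrow(h)]))
        }
      }
      # score recomputation from the reported sequence agrees
      expect_equal(vapply(hits$g_rich_seq, hunter_score, numeric(1),
                          USE.NAMES = FALSE),
                   hits$abs_score)
    }
  })
})

test_that("trimming can be disabled and a huge threshold empties output", {
  s <- paste0("TT", strrep("G", 30), "TT")
  no_trim <- detect_g4(s, trim = FALSE)
  expect_identical(nrow(no_trim), 1L)
  # untrimmed region is the full merged window union, including T flanks
  expect_lt(no_trim$start, 2L)
  trimmed <- detect_g4(s, trim = TRUE)
  expect_identical(trimmed$start, 2L)
  expect_identical(trimmed$end, 32L)
  expect_identical(nrow(detect_g4(s, threshold = 4.5)), 0L)
})

test_that("genome scanning binds per-chromosome detections", {
  genome <- c(
    c1 = paste0(strrep("T", 40), "GGGTTAGGGTTAGGGTTAGGG", strrep("T", 40)),
    c2 = strrep("A", 120)
  )
  g4 <- scan_g4(genome)
  expect_identical(g4$chrom, "c1")
  expect_identical(g4$start, 40L)
})
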