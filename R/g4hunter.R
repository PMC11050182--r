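#' Per-base run scores of a nucleotide sequence
#'
#' The run-based guanine-skew score underlying G4Hunter-style detection:
#' every base in a maximal run of `k` consecutive `G` scores `+min(k, 4)`,
#' every base in a maximal run of `k` consecutive `C` scores `-min(k, 4)`,
#' and `A`, `T`, `N` score 0. `N` breaks G/C runs.
#'
#' @param seq A single A/C/G/T/N string (case-insensitive).
#' @return Integer vector of per-base scores, one per base, each in
#'   `[-4, 4]`.
#' @export
#' @examples
#' base_scores("GGG")          # 3 3 3
#' base_scores("GGGGGTGTGTACAGACTCCGGAGGGG")
base_scores <- function(seq) {
  seq <- validate_sequence(seq)
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  r <- rle(chars)
  run_score <- integer(length(r$values))
  is_g <- r$values == "G"
  is_c <- r$values == "C"
  run_score[is_g] <- pmin(r$lengths[is_g], 4L)
  run_score[is_c] <- -pmin(r$lengths[is_c], 4L)
  rep(run_score, r$lengths)
}

#' Mean run score of a whole sequence
#'
#' Arithmetic mean of [base_scores()]; positive when the sequence is
#' G-rich, negative when C-rich, bounded by `[-4, 4]`. The absolute value
#' of this quantity is the score reported for detected G4 regions.
#'
#' @inheritParams base_scores
#' @return A single signed numeric score.
#' @export
#' @examples
#' hunter_score("GGGGGTGTGTACAGACTCCGGAGGGG") # 1.423077
#' hunter_score("CCCC")                       # -4
hunter_score <- function(seq) {
  mean(base_scores(seq))
}

#' Sliding-window mean run scores
#'
#' Mean of [base_scores()] over every window of width `window`; a sequence
#' shorter than `window` is scored as one whole-sequence window.
#'
#' @inheritParams base_scores
#' @param window Window width in bases (default 25).
#' @return Numeric vector of length `max(1, nchar(seq) - window + 1)`;
#'   element `i` is the mean over bases `[i, i + window)` (1-based).
#' @export
window_scores <- function(seq, window = 25L) {
  stopifnot(window >= 1L)
  s <- base_scores(seq)
  n <- length(s)
  w <- min(as.integer(window), n)
  cs <- c(0, cumsum(s))
  (cs[(w + 1L):(n + 1L)] - cs[1L:(n - w + 1L)]) / w
}

#' Detect potential G-quadruplex forming regions in one sequence
#'
#' Slides a window of width `window` along the sequence; windows whose mean
#' run score is `>= threshold` nominate plus-strand (G-rich) regions and
#' windows `<= -threshold` nominate minus-strand (C-rich) regions.
#' Overlapping or book-ended nominating windows of the same sign are merged
#' into one maximal region. When `trim = TRUE` each merged region is then
#' trimmed so it starts and ends on `G` (plus strand) or `C` (minus strand)
#' and the score is recomputed on the extracted subsequence. Because a merge
#' can absorb diluting flank bases (including stray isolated G or C), a
#' region whose recomputed mean falls below the threshold is shrunk: the
#' terminal base whose removal leaves the better-scoring interval is
#' dropped and the region re-trimmed and rescored until the threshold holds
#' again. Every reported region therefore satisfies
#' `abs_score >= threshold`.
#'
#' Minus-strand (C-rich) regions are defined as plus-orientation regions
#' of the reverse complement, mirrored back into forward coordinates, so
#' detection is exactly strand-symmetric. Opposite-strand regions are
#' detected independently and may overlap each other; same-strand regions
#' never overlap.
#'
#' @inheritParams window_scores
#' @param chrom Name to record in the `chrom` column.
#' @param threshold Minimum absolute window mean (default 1.2).
#' @param trim Trim merged regions to the outermost G (or C)? Default `TRUE`.
#' @return A tibble with one row per region: `chrom`, `start`, `end`
#'   (0-based half-open), `strand` (`+`/`-`), `score` (signed mean run score
#'   of the region), `abs_score`, `length`, and `g_rich_seq` (the region in
#'   G-rich orientation, i.e. reverse-complemented for minus-strand
#'   regions). Sorted by `start`, then `strand`.
#' @export
#' @examples
#' s <- paste0(strrep("T", 50), "GGGTTAGGGTTAGGGTTAGGG", strrep("T", 50))
#' detect_g4(s)
detect_g4 <- function(seq, chrom = "seq", window = 25L, threshold = 1.2,
                      trim = TRUE) {
  seq <- validate_sequence(seq)
  stopifnot(threshold > 0)
  n <- nchar(seq)

  # G-rich (plus-orientation) detection on one sequence; returns 0-based
  # half-open intervals with recomputed scores
  detect_plus <- function(sq) {
    ws <- window_scores(sq, window)
    w <- min(as.integer(window), n)
    chars <- strsplit(sq, "", fixed = TRUE)[[1]]
    sc_of <- function(a, b) hunter_score(substr(sq, a, b))
    # refine one merged span [a, b] (1-based): trim to the outermost G,
    # rescore the extracted subsequence; while the mean is still below
    # threshold, drop whichever terminal base leaves the better-scoring
    # interval and re-trim
    refine_span <- function(a, b) {
      for (iter in 1:500) {
        if (trim) {
          hit <- which(chars[a:b] == "G")
          if (length(hit) == 0L) return(NULL)
          b <- a + hit[length(hit)] - 1L
          a <- a + hit[1L] - 1L
        }
        sc <- sc_of(a, b)
        if (sc >= threshold) return(c(a, b, sc))
        if (!trim || b - a + 1L <= max(2L, w %/% 2L)) return(NULL)
        if (sc_of(a + 1L, b) >= sc_of(a, b - 1L)) a <- a + 1L else b <- b - 1L
      }
      NULL
    }
    idx <- which(ws >= threshold)
    if (length(idx) == 0L) return(NULL)
    win <- IRanges::reduce(IRanges::IRanges(start = idx, end = idx + w - 1L))
    spans <- purrr::map(seq_along(win), function(i) {
      refine_span(IRanges::start(win)[i], IRanges::end(win)[i])
    })
    spans <- spans[!vapply(spans, is.null, logical(1))]
    if (length(spans) == 0L) return(NULL)
    m <- do.call(rbind, spans)
    tibble(
      start = as.integer(m[, 1L]) - 1L, end = as.integer(m[, 2L]),
      score = m[, 3L],
      g_rich_seq = substring(sq, m[, 1L], m[, 2L])
    )
  }

  plus <- detect_plus(seq)
  if (!is.null(plus)) plus <- mutate(plus, strand = "+")
  # minus-strand regions are, by definition, plus-orientation regions of
  # the reverse complement, mirrored back; this makes detection exactly
  # strand-symmetric
  minus <- detect_plus(revcomp(seq))
  if (!is.null(minus)) {
    minus <- mutate(minus,
                    start2 = n - .data$end, end = n - .data$start,
                    start = .data$start2, score = -.data$score,
                    strand = "-") |>
      select(-"start2")
  }
  out <- bind_rows(plus, minus)
  if (nrow(out) == 0L) {
    return(tibble(
      chrom = character(), start = integer(), end = integer(),
      strand = character(), score = numeric(), abs_score = numeric(),
      length = integer(), g_rich_seq = character()
    ))
  }
  out |>
    mutate(
      chrom = chrom,
      abs_score = abs(.data$score),
      length = .data$end - .data$start
    ) |>
    select("chrom", "start", "end", "strand", "score", "abs_score",
           "length", "g_rich_seq") |>
    arrange(.data$start, .data$strand)
}

#' Detect G4 regions across a whole genome
#'
#' Applies [detect_g4()] to every record of a genome and binds the results.
#'
#' @param genome Named character vector of chromosome sequences (e.g. from
#'   [read_genome()]).
#' @inheritParams detect_g4
#' @return A tibble of G4 regions (see [detect_g4()]), chromosomes in
#'   genome order.
#' @export
scan_g4 <- function(genome, window = 25L, threshold = 1.2, trim = TRUE) {
  stopifnot(length(genome) == 0L || !is.null(names(genome)))
  purrr::imap(as.list(genome), function(s, nm) {
    detect_g4(s, chrom = nm, window = window, threshold = threshold,
              trim = trim)
  }) |>
    bind_rows()
}
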