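# brute-force oracles and fixture builders shared across test files

# random sequence at a given GC fraction
random_seq <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# per-base run scores by direct per-position run expansion (no rle)
oracle_base_scores <- function(seq) {
  ch <- strsplit(toupper(seq), "")[[1]]
  n <- length(ch)
  vapply(seq_len(n), function(i) {
    if (!ch[i] %in% c("G", "C")) return(0L)
    a <- i
    while (a > 1L && ch[a - 1L] == ch[i]) a <- a - 1L
    b <- i
    while (b < n && ch[b + 1L] == ch[i]) b <- b + 1L
    k <- min(b - a + 1L, 4L)
    if (ch[i] == "G") k else -k
  }, integer(1))
}

# naive per-window mean of the base-score vector
oracle_window_scores <- function(seq, w) {
  s <- oracle_base_scores(seq)
  n <- length(s)
  w <- min(w, n)
  vapply(seq_len(n - w + 1L), function(i) mean(s[i:(i + w - 1L)]),
         numeric(1))
}

# quadratic all-pairs overlap count of g4 rows against region rows under a
# strand context; returns per-class counts of distinct overlapping g4s
oracle_assign_g4 <- function(g4, regions, context = "double") {
  classes <- sort(unique(regions$region_class))
  counts <- setNames(integer(length(classes)), classes)
  for (cls in classes) {
    rg <- regions[regions$region_class == cls, , drop = FALSE]
    hit <- logical(nrow(g4))
    for (i in seq_len(nrow(g4))) {
      for (j in seq_len(nrow(rg))) {
        if (g4$chrom[i] != rg$chrom[j]) next
        if (g4$start[i] >= rg$end[j] || g4$end[i] <= rg$start[j]) next
        ok <- switch(context,
          double = TRUE,
          coding = g4$strand[i] == rg$gene_strand[j],
          template = g4$strand[i] != rg$gene_strand[j]
        )
        if (isTRUE(ok)) {
          hit[i] <- TRUE
          break
        }
      }
    }
    counts[cls] <- sum(hit)
  }
  counts
}

# exact hypergeometric upper tail by full enumeration of n-subsets
oracle_hyper_tail <- function(N, K, n, k) {
  if (n == 0L) return(as.numeric(k <= 0))
  subsets <- utils::combn(N, n)
  in_term <- seq_len(K) # first K elements carry the term
  hits <- apply(subsets, 2, function(cols) sum(cols %in% in_term))
  mean(hits >= k)
}

# filler sequence guaranteed to contain no SSR at default thresholds
ssr_free_filler <- function(n, seed = 424) {
  withr::with_seed(seed, {
    repeat {
      s <- random_seq(n, gc = 0.5)
      if (nrow(find_ssrs(s)) == 0L) return(s)
    }
  })
}

# small simulation spec used by fast unit tests
small_sim_spec <- function(...) {
  g4_sim_spec(
    n_chroms = 1L, chrom_length_bp = 60000L, background_gc = 0.2,
    planted_g4s = list(
      list(motif = "GGGTTAGGGTTAGGGTTAGGG", count = 8L)
    ),
    planted_ssrs = list(
      list(motif = "GGA", n_repeats = 13L, count = 3L),
      list(motif = "AT", n_repeats = 8L, count = 3L)
    ),
    n_genes = 6L, promoter_ssr_genes = 1L, n_up = 2L, n_down = 2L,
    ...
  )
}

# gene-model tibble built directly (bypasses GFF I/O); intervals are
# data.frames of 0-based half-open start/end
make_gene <- function(gene_id, chrom, start, end, strand,
                      exons = NULL, cds = NULL, utr5 = NULL, utr3 = NULL) {
  df <- function(x) {
    if (is.null(x)) {
      data.frame(start = integer(0), end = integer(0))
    } else {
      data.frame(start = as.integer(x[[1]]), end = as.integer(x[[2]]))
    }
  }
  tibble::tibble(
    gene_id = gene_id, chrom = chrom, start = as.integer(start),
    end = as.integer(end), strand = strand,
    exons = list(df(exons %||% list(start, end))), cds = list(df(cds)),
    utr5 = list(df(utr5)), utr3 = list(df(utr3))
  )
}

`%||%` <- rlang::`%||%`
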