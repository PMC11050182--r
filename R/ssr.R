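#' Default MISA-style SSR thresholds
#'
#' Minimum number of perfect repeats per unit length (1-mer through 6-mer):
#' 20, 6, 5, 5, 5, 5; compound SSRs allow interruptions of up to 100 bp.
#'
#' @return A list with elements `min_repeats` (named integer vector,
#'   names `"1"`..`"6"`) and `max_interruption` (integer bp).
#' @export
misa_params <- function() {
  list(
    min_repeats = c(`1` = 20L, `2` = 6L, `3` = 5L, `4` = 5L, `5` = 5L,
                    `6` = 5L),
    max_interruption = 100L
  )
}

# TRUE iff motif is not a whole-number repetition of a shorter unit
is_primitive_motif <- function(motif) {
  k <- nchar(motif)
  if (k == 1L) return(TRUE)
  for (d in seq_len(k - 1L)) {
    if (k %% d == 0L &&
        strrep(substr(motif, 1L, d), k / d) == motif) {
      return(FALSE)
    }
  }
  TRUE
}

#' Canonical motif family of a repeat unit
#'
#' The lexicographically minimal string among all rotations of the motif
#' and all rotations of its reverse complement, so that e.g. `AGG`, `GGA`,
#' `GAG`, `CCT`, `CTC` and `TCC` share one family key.
#'
#' @param motif Character vector of repeat units.
#' @return Character vector of family keys.
#' @export
#' @examples
#' normalize_motif(c("GGA", "TCC", "AT"))
normalize_motif <- function(motif) {
  vapply(motif, function(m) {
    k <- nchar(m)
    rots <- vapply(seq_len(k), function(i) {
      paste0(substr(m, i, k), substr(m, 1L, i - 1L))
    }, character(1))
    rc <- revcomp(m)
    rots_rc <- vapply(seq_len(k), function(i) {
      paste0(substr(rc, i, k), substr(rc, 1L, i - 1L))
    }, character(1))
    min(c(rots, rots_rc))
  }, character(1), USE.NAMES = FALSE)
}

#' Find perfect simple sequence repeats in one sequence
#'
#' MISA-style detection of maximal perfect tandem repeats of primitive
#' 1-6 bp units meeting the per-unit-length minimum repeat count. Spans
#' cover whole units only (a trailing partial unit is excluded); scanning
#' is left-to-right and reported repeats of a given unit length never
#' overlap each other. Runs of a short unit are never re-reported as a
#' longer non-primitive unit (an `A` run is `p1`, not `AA`/`p2`).
#'
#' @inheritParams base_scores
#' @param chrom Name recorded in the `chrom` column.
#' @param params Threshold list from [misa_params()].
#' @return A tibble with columns `chrom`, `start`, `end` (0-based
#'   half-open), `motif` (unit as it occurs, anchored at the repeat start),
#'   `motif_norm` (family key, see [normalize_motif()]), `unit_len`,
#'   `n_repeats`, `ssr_class` (`p1`..`p6`), sorted by `start` then
#'   `unit_len`.
#' @export
#' @examples
#' find_ssrs(paste0("TTTT", strrep("AGG", 8), "TTTT"))
find_ssrs <- function(seq, chrom = "seq", params = misa_params()) {
  seq <- validate_sequence(seq)
  rows <- list()
  for (k in 1:6) {
    m <- params$min_repeats[[as.character(k)]]
    pat <- sprintf("([ACGT]{%d})\\1{%d,}", k, m - 1L)
    hits <- gregexpr(pat, seq, perl = TRUE)[[1]]
    if (hits[1] == -1L) next
    len <- attr(hits, "match.length")
    motif <- substring(seq, hits, hits + k - 1L)
    keep <- vapply(motif, is_primitive_motif, logical(1), USE.NAMES = FALSE)
    if (!any(keep)) next
    rows[[k]] <- tibble(
      chrom = chrom,
      start = as.integer(hits[keep] - 1L),
      end = as.integer(hits[keep] - 1L + len[keep]),
      motif = motif[keep],
      unit_len = k,
      n_repeats = as.integer(len[keep] / k),
      ssr_class = paste0("p", k)
    )
  }
  out <- bind_rows(rows)
  if (nrow(out) == 0L) {
    return(tibble(
      chrom = character(), start = integer(), end = integer(),
      motif = character(), motif_norm = character(), unit_len = integer(),
      n_repeats = integer(), ssr_class = character()
    ))
  }
  out |>
    mutate(motif_norm = normalize_motif(.data$motif)) |>
    select("chrom", "start", "end", "motif", "motif_norm", "unit_len",
           "n_repeats", "ssr_class") |>
    arrange(.data$start, .data$unit_len)
}

#' Find SSRs across a whole genome
#'
#' @param genome Named character vector of chromosome sequences.
#' @inheritParams find_ssrs
#' @return A tibble of SSR records (see [find_ssrs()]).
#' @export
scan_ssrs <- function(genome, params = misa_params()) {
  purrr::imap(as.list(genome), function(s, nm) {
    find_ssrs(s, chrom = nm, params = params)
  }) |>
    bind_rows()
}

#' Group nearby SSRs into compound records
#'
#' Simple SSRs on the same chromosome separated by at most
#' `params$max_interruption` bp (MISA's interruption rule; overlap counts
#' as separation 0 or less) are merged into one compound record spanning
#' from the first start to the last end. Compound records carry
#' `ssr_class = "compound"`, `n_members`, and the constituent simple
#' records in the `members` list-column; isolated SSRs pass through
#' unchanged with `n_members = 1`.
#'
#' @param ssrs SSR tibble from [find_ssrs()]/[scan_ssrs()].
#' @inheritParams find_ssrs
#' @return A tibble with columns of `ssrs` plus `n_members` and `members`;
#'   compound rows have `NA` motif/unit_len/n_repeats.
#' @export
merge_compound <- function(ssrs, params = misa_params()) {
  if (nrow(ssrs) == 0L) {
    return(mutate(ssrs, n_members = integer(), members = list()))
  }
  gap_max <- params$max_interruption
  ssrs <- arrange(ssrs, .data$chrom, .data$start, .data$end)
  # group: consecutive records whose gap to the running span end <= gap_max
  grp <- integer(nrow(ssrs))
  g <- 0L
  span_end <- -Inf
  last_chrom <- ""
  for (i in seq_len(nrow(ssrs))) {
    if (ssrs$chrom[i] != last_chrom ||
        ssrs$start[i] - span_end > gap_max) {
      g <- g + 1L
      span_end <- ssrs$end[i]
    } else {
      span_end <- max(span_end, ssrs$end[i])
    }
    grp[i] <- g
    last_chrom <- ssrs$chrom[i]
  }
  ssrs$._grp <- grp
  out <- ssrs |>
    group_by(.data$._grp) |>
    dplyr::group_map(function(d, key) {
      if (nrow(d) == 1L) {
        return(mutate(d, n_members = 1L, members = list(NULL)))
      }
      tibble(
        chrom = d$chrom[1],
        start = min(d$start),
        end = max(d$end),
        motif = NA_character_,
        motif_norm = NA_character_,
        unit_len = NA_integer_,
        n_repeats = NA_integer_,
        ssr_class = "compound",
        n_members = nrow(d),
        members = list(d)
      )
    }) |>
    bind_rows() |>
    arrange(.data$chrom, .data$start)
  out
}

#' Can a trinucleotide repeat unit support G-quadruplex formation?
#'
#' A 3-mer unit is G4-capable when its tandem repetition carries guanine
#' runs on one strand, i.e. the unit contains at least two `G` or at least
#' two `C` (the CCN/NGG/NCC/GGN/CNC/GNG families); AAN/NTT-type units are
#' not.
#'
#' @param motif Character vector of 3-base units.
#' @return Logical vector.
#' @export
#' @examples
#' p3_g4_potential(c("AGG", "AAG", "GCG"))
p3_g4_potential <- function(motif) {
  if (any(nchar(motif) != 3L)) {
    abort("`motif` must contain 3-base units only.")
  }
  motif <- toupper(motif)
  ng <- stringr::str_count(motif, "G")
  nc <- stringr::str_count(motif, "C")
  ng >= 2L | nc >= 2L
}

#' Associate SSRs with overlapping G4 regions
#'
#' Counts, for every SSR, the detected G4 regions (either strand) that
#' overlap the SSR span extended by `flank` bp on each side by at least
#' 1 bp. One G4 may associate with several SSRs.
#'
#' @param ssrs SSR tibble (`chrom`, `start`, `end`, ...).
#' @param g4 G4 region tibble from [scan_g4()].
#' @param flank Flank width in bp added to both sides of each SSR
#'   (default 0).
#' @return `ssrs` with two extra columns: `g4_count` and `g4_ids`
#'   (list-column of row indices into `g4`).
#' @export
ssr_g4_association <- function(ssrs, g4, flank = 0L) {
  if (nrow(ssrs) > 0L && nrow(g4) > 0L) {
    shared <- intersect(unique(ssrs$chrom), unique(g4$chrom))
    if (length(shared) == 0L) {
      abort(sprintf(
        "SSR and G4 tables share no chromosome names (SSR: %s; G4: %s).",
        paste(unique(ssrs$chrom), collapse = ","),
        paste(unique(g4$chrom), collapse = ",")
      ))
    }
  }
  g4_ids <- rep(list(integer(0)), nrow(ssrs))
  if (nrow(ssrs) > 0L && nrow(g4) > 0L) {
    q <- GenomicRanges::GRanges(
      ssrs$chrom,
      IRanges::IRanges(start = ssrs$start + 1L - flank, end = ssrs$end + flank)
    )
    s <- GenomicRanges::GRanges(
      g4$chrom, IRanges::IRanges(start = g4$start + 1L, end = g4$end)
    )
    ov <- GenomicRanges::findOverlaps(q, s, minoverlap = 1L)
    hits <- split(S4Vectors::subjectHits(ov), S4Vectors::queryHits(ov))
    for (nm in names(hits)) g4_ids[[as.integer(nm)]] <- unname(hits[[nm]])
  }
  ssrs |>
    mutate(
      g4_count = vapply(g4_ids, length, integer(1)),
      g4_ids = g4_ids
    )
}
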