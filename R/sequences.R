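#' Validate a nucleotide sequence
#'
#' Checks that a sequence contains only `A`, `C`, `G`, `T` or `N`
#' (case-insensitive) and returns it upper-cased. Used at every parse
#' boundary so downstream scoring can assume a clean alphabet.
#'
#' @param seq A single character string.
#' @param allow_empty Permit the empty string (default `FALSE`).
#' @return The validated, upper-cased sequence.
#' @export
#' @examples
#' validate_sequence("acgTN")
validate_sequence <- function(seq, allow_empty = FALSE) {
  if (!is.character(seq) || length(seq) != 1L || is.na(seq)) {
    abort("`seq` must be a single character string.")
  }
  seq <- toupper(seq)
  if (!allow_empty && nchar(seq) == 0L) {
    abort("`seq` must be non-empty.")
  }
  bad <- regexpr("[^ACGTN]", seq)
  if (bad > 0L) {
    abort(sprintf(
      "Invalid character '%s' at position %d; allowed alphabet is A/C/G/T/N.",
      substr(seq, bad, bad), bad
    ))
  }
  seq
}

#' Reverse complement of a DNA sequence
#'
#' Vectorised over its input; `N` maps to `N`. An involution:
#' `revcomp(revcomp(x)) == x`.
#'
#' @param seq Character vector of A/C/G/T/N sequences (case-insensitive).
#' @return Character vector of reverse complements, upper case.
#' @export
#' @examples
#' revcomp("ACGT")
#' revcomp(c("GGG", "ATTN"))
revcomp <- function(seq) {
  if (length(seq) == 0L) return(character(0))
  out <- vapply(seq, function(s) {
    s <- validate_sequence(s, allow_empty = TRUE)
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  }, character(1), USE.NAMES = FALSE)
  out
}

#' Read a multi-record genome FASTA
#'
#' Wraps [Biostrings::readDNAStringSet()] and returns a named character
#' vector (record name, first whitespace-delimited token, to upper-cased
#' sequence), validating the A/C/G/T/N alphabet.
#'
#' @param path Path to a FASTA file (wrapped or unwrapped).
#' @return Named character vector of sequences, in file order.
#' @export
read_genome <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  seqs <- toupper(as.character(ss))
  names(seqs) <- sub("\\s.*$", "", names(ss))
  for (i in seq_along(seqs)) {
    bad <- regexpr("[^ACGTN]", seqs[[i]])
    if (bad > 0L) {
      abort(sprintf(
        "Record '%s': invalid character '%s' at position %d.",
        names(seqs)[i], substr(seqs[[i]], bad, bad), bad
      ))
    }
  }
  seqs
}

#' Write a genome to FASTA
#'
#' @param genome Named character vector of sequences.
#' @param path Output path.
#' @param width Line-wrap width in bases.
#' @return `path`, invisibly.
#' @export
write_genome <- function(genome, path, width = 70L) {
  ss <- Biostrings::DNAStringSet(unname(genome))
  names(ss) <- names(genome)
  Biostrings::writeXStringSet(ss, path, width = width)
  invisible(path)
}

#' Chromosome lengths of a genome
#'
#' @param genome Named character vector of sequences.
#' @return Named integer vector of lengths.
#' @export
chrom_lengths <- function(genome) {
  setNames(nchar(genome), names(genome))
}
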