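#' @keywords internal
"_PACKAGE"

# Internal coordinate convention: 0-based, half-open [start, end) on the
# forward strand.  Minus-strand features keep forward-strand intervals with a
# strand flag; conversion to 1-based inclusive happens only at the GFF3
# boundary.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Reverse complement of DNA strings
#'
#' Vectorised over character input; works on plain uppercase/lowercase DNA.
#'
#' @param x character vector of DNA sequences.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  vapply(x, function(s) {
    if (is.na(s)) return(NA_character_)
    rawToChar(rev(charToRaw(chartr("ACGTacgt", "TGCAtgca", s))))
  }, character(1), USE.NAMES = FALSE)
}

#' Extract a strand-aware subsequence
#'
#' @param sequence forward-strand sequence (character scalar).
#' @param start,end 0-based half-open interval.
#' @param strand "+" or "-"; minus-strand extraction returns the reverse
#'   complement (the transcript reading).
#' @return character scalar.
#' @export
seq_extract <- function(sequence, start, end, strand = "+") {
  stopifnot(start >= 0, end >= start, end <= nchar(sequence))
  s <- substr(sequence, start + 1L, end)
  if (identical(strand, "-")) revcomp(s) else s
}

# Split a DNA string into a character vector of single bases.
seq_chars <- function(sequence) strsplit(sequence, "", fixed = TRUE)[[1]]

# Base pairing weight under RNA rules on DNA alphabet: Watson-Crick = 1,
# G/U wobble (G-T) = gu_weight, otherwise 0.
pair_weight <- function(a, b, gu_weight = 0.5) {
  wc <- (a == "A" & b == "T") | (a == "T" & b == "A") |
    (a == "G" & b == "C") | (a == "C" & b == "G")
  gu <- (a == "G" & b == "T") | (a == "T" & b == "G")
  ifelse(wc, 1, ifelse(gu, gu_weight, 0))
}

can_pair <- function(a, b, gu = TRUE) {
  w <- pair_weight(a, b, gu_weight = if (gu) 0.5 else 0)
  w > 0
}

# Hamming distance between equal-length strings.
hamming <- function(a, b) {
  sum(seq_chars(a) != seq_chars(b))
}

gc_fraction <- function(s) {
  if (nchar(s) == 0) return(NA_real_)
  ch <- seq_chars(s)
  mean(ch %in% c("G", "C"))
}

# The 5'-most forward coordinate of an interval given its strand
# (the biological start of the transcript).
five_prime_pos <- function(start, end, strand) {
  ifelse(strand == "-", end - 1L, start)
}

three_prime_pos <- function(start, end, strand) {
  ifelse(strand == "-", start, end - 1L)
}

# Random DNA of length n using the active RNG stream.
random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

stop_fmt <- function(...) stop(sprintf(...), call. = FALSE)
warn_fmt <- function(...) warning(sprintf(...), call. = FALSE)
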