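#' Construct a genome record
#'
#' A genome record holds one contig: its identifier, uppercase DNA sequence
#' (U converted to T), length and circularity flag.
#'
#' @param contig_id contig identifier.
#' @param sequence DNA string over A/C/G/T (U and lowercase are normalised).
#' @param is_circular logical; archaeal chromosomes are circular by default.
#' @return an object of class `genome_record`.
#' @export
genome_record <- function(contig_id, sequence, is_circular = TRUE) {
  stopifnot(is.character(contig_id), length(contig_id) == 1L, nzchar(contig_id))
  sequence <- chartr("u", "t", sequence)
  sequence <- chartr("U", "T", toupper(sequence))
  bad <- regmatches(sequence, regexpr("[^ACGT]", sequence))
  if (length(bad) > 0) {
    stop_fmt("non-nucleotide character '%s' in sequence for contig '%s'",
             bad, contig_id)
  }
  structure(
    list(contig_id = contig_id, sequence = sequence,
         length = nchar(sequence), is_circular = is_circular),
    class = "genome_record"
  )
}

#' @export
print.genome_record <- function(x, ...) {
  cat(sprintf("<genome_record> %s: %d nt%s\n", x$contig_id, x$length,
              if (x$is_circular) " (circular)" else ""))
  invisible(x)
}

#' Read a FASTA file into genome records
#'
#' Sequences are uppercased and U is transliterated to T.  Non-nucleotide
#' characters are a format error; the message names the offending line.
#'
#' @param path FASTA file.
#' @param is_circular circularity flag applied to all records.
#' @return list of [genome_record()] objects, in file order.
#' @export
read_fasta <- function(path, is_circular = TRUE) {
  if (!file.exists(path)) stop_fmt("FASTA file not found: %s", path)
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) stop_fmt("invalid FASTA '%s': %s",
                                               path, conditionMessage(e)))
  if (length(set) == 0) stop_fmt("empty FASTA file: %s", path)
  ids <- sub("\\s.*$", "", names(set))
  out <- vector("list", length(set))
  for (i in seq_along(set)) {
    seqchr <- as.character(set[[i]])
    norm <- chartr("Uu", "Tt", seqchr)
    if (grepl("[^ACGTacgt]", norm)) {
      # locate offending line for the error message
      lines <- readLines(path, warn = FALSE)
      bad_line <- which(!startsWith(lines, ">") &
                          grepl("[^ACGTUacgtu[:space:]]", lines))[1]
      stop_fmt("non-nucleotide alphabet in FASTA '%s' at line %s (record '%s')",
               path, bad_line %||% NA, ids[i])
    }
    out[[i]] <- genome_record(ids[i], norm, is_circular = is_circular)
  }
  out
}

#' Write genome records (or any named sequences) to FASTA
#'
#' @param records list of [genome_record()] objects, or a named character
#'   vector of sequences.
#' @param path output file.
#' @param width line width.
#' @export
write_fasta <- function(records, path, width = 70L) {
  if (is.character(records)) {
    seqs <- records
  } else {
    if (inherits(records, "genome_record")) records <- list(records)
    seqs <- vapply(records, function(r) r$sequence, character(1))
    names(seqs) <- vapply(records, function(r) r$contig_id, character(1))
  }
  set <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(set, filepath = path, width = width)
  invisible(path)
}

#' Read a FASTQ file (Sanger Phred+33)
#'
#' @param path FASTQ file.
#' @return data.frame with columns `read_id`, `seq`, `qual`.
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) stop_fmt("FASTQ file not found: %s", path)
  set <- Biostrings::readDNAStringSet(path, format = "fastq",
                                      with.qualities = TRUE)
  data.frame(
    read_id = sub("\\s.*$", "", names(set)),
    seq = as.character(set),
    qual = as.character(S4Vectors::mcols(set)$qualities),
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Write reads to FASTQ (Sanger Phred+33)
#'
#' @param reads data.frame with columns `read_id`, `seq`, `qual`.
#' @param path output file.
#' @export
write_fastq <- function(reads, path) {
  if (nrow(reads) == 0) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  qual <- reads$qual
  if (is.null(qual) || anyNA(qual)) {
    qual <- vapply(nchar(reads$seq),
                   function(n) strrep("?", n), character(1))
  }
  set <- Biostrings::DNAStringSet(reads$seq)
  names(set) <- reads$read_id
  Biostrings::writeXStringSet(
    set, filepath = path, format = "fastq",
    qualities = Biostrings::BStringSet(qual))
  invisible(path)
}
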