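#' Read-trimming configuration
#'
#' @param adapter_sequences 3' adapter sequences searched as read suffixes
#'   (default: the Illumina TruSeq adapter prefix).
#' @param quality_error_limit error-probability limit for the running-sum
#'   quality trimmer (default 0.05).
#' @param min_length reads shorter than this after trimming are discarded
#'   (default 15 nt).
#' @param polyA_min_run minimum length of a terminal poly-A run to strip
#'   (default 6).
#' @return a `trim_config` list.
#' @export
trim_config <- function(adapter_sequences = "AGATCGGAAGAGC",
                        quality_error_limit = 0.05,
                        min_length = 15L, polyA_min_run = 6L) {
  stopifnot(quality_error_limit > 0, quality_error_limit < 1, min_length >= 1)
  structure(list(adapter_sequences = toupper(adapter_sequences),
                 quality_error_limit = quality_error_limit,
                 min_length = as.integer(min_length),
                 polyA_min_run = as.integer(polyA_min_run)),
            class = "trim_config")
}

# Best semi-global suffix match of an adapter against a read: the adapter
# prefix is aligned to the read suffix starting at each position; a hit needs
# >= min_overlap aligned bases at >= min_identity.  Returns the 1-based trim
# position (first adapter base) or NA.
adapter_hit <- function(seq, adapter, min_overlap = 8L, min_identity = 0.9) {
  n <- nchar(seq); m <- nchar(adapter)
  if (n < min_overlap) return(NA_integer_)
  sc <- charToRaw(seq)
  ac <- charToRaw(adapter)
  best <- NA_integer_; best_id <- -1
  for (i in seq_len(n - min_overlap + 1L)) {
    len <- min(m, n - i + 1L)
    id <- mean(sc[i:(i + len - 1L)] == ac[seq_len(len)])
    if (len >= min_overlap && id >= min_identity && id > best_id) {
      best <- i; best_id <- id
    }
  }
  best
}

# Running-sum quality trim: with per-base error probabilities p and limit L,
# accumulate s_i = max(0, s_{i-1} + (L - p_i)); the kept segment ends at the
# position where s is maximal and starts after the last reset to zero before
# it.  Returns c(start, end) (1-based inclusive; c(0, -1) when nothing kept).
mott_segment <- function(p, limit) {
  n <- length(p)
  s <- numeric(n); run_start <- integer(n)
  acc <- 0; rs <- 1L
  for (i in seq_len(n)) {
    acc <- acc + (limit - p[i])
    if (acc <= 0) { acc <- 0; rs <- i + 1L }
    s[i] <- acc; run_start[i] <- rs
  }
  if (all(s <= 0)) return(c(0L, -1L))
  iend <- which.max(s)
  c(run_start[iend], iend)
}

#' Trim reads: adapters, poly-A tails, low-quality segments
#'
#' Adapter suffixes are removed by best semi-global match (>= 90% identity
#' over >= 8 nt); 3' poly-A runs of at least `polyA_min_run` are stripped;
#' quality trimming uses the running-sum error-probability method with the
#' configured limit (skipped for reads without qualities); reads shorter than
#' `min_length` are discarded and counted.
#'
#' @param reads data.frame with `read_id`, `seq` and optional `qual`
#'   (Phred+33; NA allowed).
#' @param config a [trim_config()].
#' @return list with `reads` (trimmed data.frame) and `log` (counts).
#' @export
trim_reads <- function(reads, config = trim_config()) {
  n0 <- nrow(reads)
  has_qual <- "qual" %in% colnames(reads)
  n_adapter <- 0L; n_polya <- 0L; n_qual <- 0L
  out_seq <- character(n0); out_qual <- rep(NA_character_, n0)
  for (i in seq_len(n0)) {
    s <- reads$seq[i]
    q <- if (has_qual) reads$qual[i] else NA_character_
    for (ad in config$adapter_sequences) {
      hit <- adapter_hit(s, ad)
      if (!is.na(hit)) {
        s <- substr(s, 1L, hit - 1L)
        if (!is.na(q)) q <- substr(q, 1L, hit - 1L)
        n_adapter <- n_adapter + 1L
        break
      }
    }
    tail_run <- attr(regexpr(sprintf("A{%d,}$", config$polyA_min_run), s),
                     "match.length")
    if (tail_run > 0) {
      s <- substr(s, 1L, nchar(s) - tail_run)
      if (!is.na(q)) q <- substr(q, 1L, nchar(s))
      n_polya <- n_polya + 1L
    }
    if (!is.na(q) && nchar(q) > 0) {
      perr <- 10^(-(utf8ToInt(q) - 33) / 10)
      seg <- mott_segment(perr, config$quality_error_limit)
      if (seg[1] > 1L || seg[2] < nchar(s)) n_qual <- n_qual + 1L
      if (seg[2] < seg[1]) { s <- ""; q <- "" } else {
        s <- substr(s, seg[1], seg[2]); q <- substr(q, seg[1], seg[2])
      }
    }
    out_seq[i] <- s; out_qual[i] <- q
  }
  keep <- nchar(out_seq) >= config$min_length
  trimmed <- data.frame(read_id = reads$read_id[keep],
                        seq = out_seq[keep], qual = out_qual[keep],
                        stringsAsFactors = FALSE, row.names = NULL)
  list(reads = trimmed,
       log = list(input = n0, adapter_trimmed = n_adapter,
                  polya_trimmed = n_polya, quality_trimmed = n_qual,
                  discarded_short = n0 - nrow(trimmed),
                  output = nrow(trimmed)))
}
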