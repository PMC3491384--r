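#' CRISPR detection parameters
#'
#' Bounds follow common CRISPR definitions: repeats 20-50 nt at >= 0.9
#' pairwise identity to the consensus, spacers 17-50 nt (soft maximum 1.5x
#' the upper bound, flagged rather than chain-breaking, because real arrays
#' can contain one unusually long spacer), at least 3 repeats.
#'
#' @param repeat_len c(min, max) repeat length in nt.
#' @param spacer_len c(min, max) spacer length in nt.
#' @param spacer_soft_max_factor soft multiplier on the spacer maximum.
#' @param min_repeats minimum repeats per array.
#' @param min_identity minimum repeat identity to consensus.
#' @param k seed k-mer length for self-match chaining.
#' @return a `crispr_params` list.
#' @export
crispr_params <- function(repeat_len = c(20L, 50L), spacer_len = c(17L, 50L),
                          spacer_soft_max_factor = 1.5, min_repeats = 3L,
                          min_identity = 0.9, k = 13L) {
  structure(list(repeat_len = repeat_len, spacer_len = spacer_len,
                 spacer_soft_max_factor = spacer_soft_max_factor,
                 min_repeats = as.integer(min_repeats),
                 min_identity = min_identity, k = as.integer(k)),
            class = "crispr_params")
}

# Per-column majority base and its fraction across a set of equal-offset
# positions (1-based) in a sequence.
column_majority <- function(gchr, positions) {
  bases <- substring(gchr, positions, positions)
  tab <- sort(table(bases), decreasing = TRUE)
  list(base = names(tab)[1], frac = tab[[1]] / length(positions))
}

#' Detect CRISPR repeat-spacer arrays de novo
#'
#' Finds maximal chains of >= 3 near-identical repeats separated by spacers
#' via k-mer seeded self-match chaining: k-mers occurring >= 3 times at
#' regular gaps compatible with a repeat + spacer period seed candidate
#' chains, which are extended column-wise while the majority base is carried
#' by at least `min_identity` of the chain, then validated against the
#' length bounds.  The consensus is the per-column majority; orientation is
#' left unset (see [orient_array()]).
#'
#' @param genome a [genome_record()].
#' @param params a [crispr_params()].
#' @return list of `crispr_array` objects (possibly empty), each with
#'   repeats, spacers (with `flag_long` / `is_duplicate` flags),
#'   `repeat_consensus` and strand = NA.
#' @export
detect_arrays <- function(genome, params = crispr_params()) {
  gchr <- genome$sequence
  n <- nchar(gchr)
  k <- params$k
  if (n < 3L * (params$repeat_len[1] + params$spacer_len[1])) return(list())
  period_min <- params$repeat_len[1] + params$spacer_len[1]
  period_max <- params$repeat_len[2] +
    floor(params$spacer_len[2] * params$spacer_soft_max_factor)

  kmers <- substring(gchr, 1:(n - k + 1L), k:n)
  pos_by_kmer <- split(seq_len(n - k + 1L), kmers)
  pos_by_kmer <- pos_by_kmer[lengths(pos_by_kmer) >= params$min_repeats]
  if (length(pos_by_kmer) == 0) return(list())
  # deterministic order: most frequent seeds first (a seed fully inside the
  # repeat sees every copy and claims the whole array before partial seeds
  # that straddle a repeat boundary can fragment it), then by position
  ord <- order(-lengths(pos_by_kmer),
               vapply(pos_by_kmer, min, numeric(1)))
  pos_by_kmer <- pos_by_kmer[ord]

  claimed <- logical(n)
  arrays <- list()

  for (p in pos_by_kmer) {
    p <- sort(p)
    if (any(claimed[p])) p <- p[!claimed[p]]
    if (length(p) < params$min_repeats) next
    gapping <- diff(p)
    ok <- gapping >= period_min & gapping <= period_max
    # maximal runs of in-range gaps
    runs <- rle(ok)
    idx_end <- cumsum(runs$lengths)
    idx_start <- idx_end - runs$lengths + 1L
    for (r in which(runs$values & runs$lengths >= params$min_repeats - 1L)) {
      anchors <- p[idx_start[r]:(idx_end[r] + 1L)]
      arr <- refine_array(gchr, anchors, k, params)
      if (is.null(arr)) next
      span <- (arr$repeats$start[1] + 1L):arr$repeats$end[nrow(arr$repeats)]
      if (any(claimed[span])) next
      claimed[span] <- TRUE
      arrays[[length(arrays) + 1L]] <- arr
    }
  }
  # coordinate order, assign ids
  if (length(arrays) > 0) {
    ordA <- order(vapply(arrays, function(a) a$repeats$start[1], numeric(1)))
    arrays <- arrays[ordA]
    for (i in seq_along(arrays)) {
      arrays[[i]]$array_id <- sprintf("CRISPR%d", i)
      arrays[[i]]$contig_id <- genome$contig_id
    }
  }
  arrays
}

# Extend a chain of anchor positions into full repeats and derive spacers.
refine_array <- function(gchr, anchors, k, params) {
  n <- nchar(gchr)
  m <- length(anchors)
  min_gap <- min(diff(anchors))
  # extend left of the anchor
  left <- 0L
  while (k + left < params$repeat_len[2] &&
         anchors[1] - left - 1L >= 1L &&
         left + 1L < min_gap - k) {
    cm <- column_majority(gchr, anchors - left - 1L)
    if (cm$frac >= 0.75) left <- left + 1L else break
  }
  right <- 0L
  while (k + left + right < params$repeat_len[2] &&
         anchors[m] + k + right <= n &&
         k + right < min_gap - left) {
    cm <- column_majority(gchr, anchors + k + right)
    if (cm$frac >= 0.75) right <- right + 1L else break
  }
  # shrink chance extensions: boundary columns must be near-identical
  while (left > 0L &&
         column_majority(gchr, anchors - left)$frac < 0.9) {
    left <- left - 1L
  }
  while (right > 0L &&
         column_majority(gchr, anchors + k + right - 1L)$frac < 0.9) {
    right <- right - 1L
  }
  rep_len <- k + left + right
  if (rep_len < params$repeat_len[1] || rep_len > params$repeat_len[2]) {
    return(NULL)
  }
  rstart <- anchors - left           # 1-based
  rend <- rstart + rep_len - 1L
  # consensus per column
  consensus <- paste(vapply(seq_len(rep_len), function(j) {
    column_majority(gchr, rstart + j - 1L)$base
  }, character(1)), collapse = "")
  # validate repeat identity; trim failing terminal repeats
  ident <- vapply(seq_len(m), function(i) {
    1 - hamming(substr(gchr, rstart[i], rend[i]), consensus) / rep_len
  }, numeric(1))
  keep <- ident >= params$min_identity
  first <- which(keep)[1]; last <- rev(which(keep))[1]
  if (is.na(first) || !all(keep[first:last])) return(NULL)
  rstart <- rstart[first:last]; rend <- rend[first:last]
  m <- length(rstart)
  if (m < params$min_repeats) return(NULL)
  # spacers between consecutive repeats
  sstart <- rend[-m] + 1L
  send <- rstart[-1] - 1L
  slen <- send - sstart + 1L
  soft_max <- floor(params$spacer_len[2] * params$spacer_soft_max_factor)
  if (any(slen < params$spacer_len[1] | slen > soft_max)) return(NULL)
  sseq <- substring(gchr, sstart, send)
  list(array_id = NA_character_, contig_id = NA_character_,
       strand = NA_character_,
       repeats = data.frame(start = rstart - 1L, end = rend),
       spacers = data.frame(start = sstart - 1L, end = send, seq = sseq,
                            flag_long = slen > params$spacer_len[2],
                            is_duplicate = duplicated(sseq) |
                              duplicated(sseq, fromLast = TRUE),
                            stringsAsFactors = FALSE),
       repeat_consensus = consensus, leader = NULL, orient_method = NULL)
}

# Oriented views -------------------------------------------------------------

# First repeat in transcription order (a list with start/end, 0-based
# half-open) for an oriented array.
first_repeat <- function(array) {
  stopifnot(!is.na(array$strand))
  i <- if (array$strand == "-") nrow(array$repeats) else 1L
  list(start = array$repeats$start[i], end = array$repeats$end[i])
}

# Spacer table in transcription order with oriented index.
oriented_spacers <- function(array) {
  sp <- array$spacers
  if (array$strand == "-") sp <- sp[rev(seq_len(nrow(sp))), , drop = FALSE]
  sp$spacer_index <- seq_len(nrow(sp))
  rownames(sp) <- NULL
  sp
}

# Oriented repeat consensus (transcript reading).
oriented_consensus <- function(array) {
  if (array$strand == "-") revcomp(array$repeat_consensus)
  else array$repeat_consensus
}

#' Orient a CRISPR array
#'
#' With a read pileup, the strand carrying >= 90% of array-overlapping read
#' depth wins (method "reads").  Without reads, the fallback compares the
#' A/T richness of the two 150-nt flanks: the AT-rich leader lies upstream
#' of the first repeat, so the strand placing the richer flank upstream is
#' chosen (method "sequence").  When both are available and conflict, the
#' read-based call wins with a warning.
#'
#' @param array a `crispr_array` from [detect_arrays()].
#' @param pileup optional [build_pileup()] result.
#' @param genome a [genome_record()] (needed for the sequence fallback and
#'   the leader interval).
#' @param leader_len leader interval length recorded on the array (nt).
#' @return the array with `strand`, `orient_method` and `leader` set.
#' @export
orient_array <- function(array, pileup = NULL, genome = NULL,
                         leader_len = 200L) {
  span <- c(array$repeats$start[1] + 1L,
            array$repeats$end[nrow(array$repeats)])
  read_strand <- NA_character_
  if (!is.null(pileup)) {
    dplus <- sum(pileup$plus$depth[span[1]:span[2]])
    dminus <- sum(pileup$minus$depth[span[1]:span[2]])
    if (dplus + dminus > 0) {
      frac_plus <- dplus / (dplus + dminus)
      read_strand <- if (frac_plus >= 0.5) "+" else "-"
      if (frac_plus < 0.9 && frac_plus > 0.1) {
        warn_fmt("array at %d: read strand bias only %.2f", span[1] - 1L,
                 max(frac_plus, 1 - frac_plus))
      }
    }
  }
  seq_strand <- NA_character_
  if (!is.null(genome)) {
    flank <- 150L
    lchr <- seq_extract(genome$sequence,
                        max(0L, array$repeats$start[1] - flank),
                        array$repeats$start[1], "+")
    rchr <- seq_extract(genome$sequence,
                        array$repeats$end[nrow(array$repeats)],
                        min(genome$length,
                            array$repeats$end[nrow(array$repeats)] + flank),
                        "+")
    at <- function(s) if (nchar(s) == 0) 0 else 1 - gc_fraction(s)
    seq_strand <- if (at(lchr) >= at(rchr)) "+" else "-"
  }
  if (!is.na(read_strand)) {
    if (!is.na(seq_strand) && seq_strand != read_strand) {
      warn_fmt("orientation conflict at %d: reads say %s, sequence says %s",
               span[1] - 1L, read_strand, seq_strand)
    }
    array$strand <- read_strand
    array$orient_method <- "reads"
  } else if (!is.na(seq_strand)) {
    array$strand <- seq_strand
    array$orient_method <- "sequence"
  } else {
    stop_fmt("orient_array needs a pileup or a genome")
  }
  fr <- first_repeat(array)
  if (array$strand == "+") {
    array$leader <- c(max(0L, fr$start - leader_len), fr$start)
  } else {
    L <- if (!is.null(genome)) genome$length else
      (if (!is.null(pileup)) pileup$length else fr$end + leader_len)
    array$leader <- c(fr$end, min(L, fr$end + leader_len))
  }
  array
}

#' Infer crRNA maturation from a read pileup
#'
#' Per spacer (in transcription order): read count and within-array relative
#' abundance; the 5' tag length as the modal upstream offset of read 5' ends
#' constrained to fall within the repeat, with the tag sequence read from
#' the repeat consensus suffix; the 3'-end offset distribution relative to
#' the last spacer base; and trimming hotspots via [call_termini()].
#'
#' @param array an oriented `crispr_array`.
#' @param pileup a [build_pileup()] result.
#' @param min_support,window,hotspot_fraction passed to [call_termini()].
#' @return data.frame, one row per spacer, plus attribute `three_end_dists`
#'   (list of offset -> count tables per spacer).
#' @export
infer_maturation <- function(array, pileup, min_support = 5L, window = 10L,
                             hotspot_fraction = 0.10) {
  stopifnot(!is.na(array$strand))
  sp <- oriented_spacers(array)
  strand <- array$strand
  sl <- if (strand == "-") pileup$minus else pileup$plus
  rep_len <- nchar(array$repeat_consensus)
  cons <- oriented_consensus(array)
  nsp <- nrow(sp)
  read_count <- integer(nsp); tag_len <- rep(NA_integer_, nsp)
  tag_seq <- rep(NA_character_, nsp); modal3 <- rep(NA_integer_, nsp)
  hotspots <- character(nsp); flags <- character(nsp)
  dists <- vector("list", nsp)
  for (i in seq_len(nsp)) {
    s0 <- sp$start[i]; e0 <- sp$end[i]
    # windows in forward coordinates, oriented by strand
    if (strand == "+") {
      w5 <- c(max(0L, s0 - rep_len), e0)      # 5' ends counted here
      tagwin <- c(max(0L, s0 - rep_len), s0)  # tag offsets measured here
      w3 <- c(s0, min(pileup$length, e0 + rep_len))
    } else {
      w5 <- c(s0, min(pileup$length, e0 + rep_len))
      tagwin <- c(e0, min(pileup$length, e0 + rep_len))
      w3 <- c(max(0L, s0 - rep_len), e0)
    }
    p5 <- sl$p5[(w5[1] + 1L):w5[2]]
    read_count[i] <- sum(p5)
    tp5 <- sl$p5[(tagwin[1] + 1L):tagwin[2]]
    if (sum(tp5) > 0) {
      posg <- (tagwin[1]:(tagwin[2] - 1L))[tp5 > 0]
      cnt <- tp5[tp5 > 0]
      off <- if (strand == "+") s0 - posg else posg - (e0 - 1L)
      agg <- tapply(cnt, off, sum)
      best <- max(agg)
      cand <- as.integer(names(agg)[agg == best])
      tag_len[i] <- min(cand)                 # tie: shortest tag
      tag_seq[i] <- substr(cons, rep_len - tag_len[i] + 1L, rep_len)
    } else {
      flags[i] <- "no_reads"
    }
    p3 <- sl$p3[(w3[1] + 1L):w3[2]]
    if (sum(p3) > 0) {
      posg <- (w3[1]:(w3[2] - 1L))[p3 > 0]
      cnt <- p3[p3 > 0]
      off3 <- if (strand == "+") posg - (e0 - 1L) else s0 - posg
      agg3 <- tapply(cnt, off3, sum)
      dists[[i]] <- agg3
      modal3[i] <- as.integer(names(agg3)[which.max(agg3)])
      tc <- call_termini(pileup, w3, strand, "3p", min_support, window,
                         hotspot_fraction)
      hs <- tc$position[tc$is_hotspot]
      if (length(hs) > 0) {
        hsoff <- if (strand == "+") hs - (e0 - 1L) else s0 - hs
        hotspots[i] <- paste(sort(hsoff), collapse = ",")
      }
    }
    extra <- c(if (sp$flag_long[i]) "long_spacer",
               if (sp$is_duplicate[i]) "duplicate_spacer")
    if (length(extra) > 0) {
      flags[i] <- paste(c(if (nzchar(flags[i])) flags[i], extra),
                        collapse = ",")
    }
  }
  total <- sum(read_count)
  out <- data.frame(
    array_id = array$array_id, spacer_index = sp$spacer_index,
    contig_id = array$contig_id, start = sp$start, end = sp$end,
    strand = strand, read_count = read_count,
    relative_abundance = if (total > 0) read_count / total else
      rep(NA_real_, nsp),
    five_tag_length = tag_len, five_tag_sequence = tag_seq,
    three_modal_offset = modal3, trimming_hotspots = hotspots,
    flags = flags, stringsAsFactors = FALSE)
  attr(out, "three_end_dists") <- dists
  out
}

#' Length of the identical leader shared by two arrays
#'
#' Walks upstream (strand-aware) from the first repeat of each array,
#' counting how long the two leader sequences stay identical.
#'
#' @param arrayA,arrayB oriented `crispr_array` objects.
#' @param genome a [genome_record()].
#' @param max_len maximum compared span (default 500 nt).
#' @return list with `identical_prefix_length` and `truncated`.
#' @export
compare_leaders <- function(arrayA, arrayB, genome, max_len = 500L) {
  up <- function(array) {
    fr <- first_repeat(array)
    if (array$strand == "+") {
      s <- max(0L, fr$start - max_len)
      chars <- seq_chars(seq_extract(genome$sequence, s, fr$start, "+"))
      rev(chars)                              # index 1 = closest to repeat
    } else {
      e <- min(genome$length, fr$end + max_len)
      chars <- seq_chars(seq_extract(genome$sequence, fr$end, e, "-"))
      rev(chars)
    }
  }
  a <- up(arrayA); b <- up(arrayB)
  nn <- min(length(a), length(b))
  same <- a[seq_len(nn)] == b[seq_len(nn)]
  len <- if (all(same)) nn else which(!same)[1] - 1L
  list(identical_prefix_length = as.integer(len),
       truncated = nn < max_len)
}

#' Call the transcription start site of a CRISPR array
#'
#' The TSS is the modal read 5'-end position within the leader interval
#' (strand-aware); ties go to the upstream-most position.  The offset to the
#' first repeat counts bases between the TSS and the repeat start on the
#' array strand (offset 33 = TSS 33 nt upstream).
#'
#' @param array an oriented `crispr_array` with a leader interval.
#' @param pileup a [build_pileup()] result.
#' @param genome a [genome_record()] for the TSS base identity.
#' @return list with `tss_position` (0-based), `tss_base`,
#'   `tss_offset_to_first_repeat`, `tie` flag; or `NULL` fields when the
#'   leader has no reads (flagged).
#' @export
call_tss <- function(array, pileup, genome) {
  stopifnot(!is.null(array$leader))
  strand <- array$strand
  sl <- if (strand == "-") pileup$minus else pileup$plus
  lo <- array$leader[1]; hi <- array$leader[2]
  p5 <- sl$p5[(lo + 1L):hi]
  if (sum(p5) == 0) {
    return(list(tss_position = NA_integer_, tss_base = NA_character_,
                tss_offset_to_first_repeat = NA_integer_, tie = FALSE,
                flag = "no_leader_reads"))
  }
  best <- max(p5)
  cand <- (lo:(hi - 1L))[p5 == best]
  tie <- length(cand) > 1L
  tss <- if (strand == "-") max(cand) else min(cand)  # upstream-most
  fr <- first_repeat(array)
  off <- if (strand == "+") fr$start - tss else tss - (fr$end - 1L)
  list(tss_position = as.integer(tss),
       tss_base = seq_extract(genome$sequence, tss, tss + 1L, strand),
       tss_offset_to_first_repeat = as.integer(off), tie = tie, flag = "")
}

#' Locate the box A promoter element upstream of a TSS
#'
#' Scans a window of distances upstream of the TSS for the best Hamming
#' match to the archaeal box A hexamer TTTAAA; matches worse than 1 mismatch
#' are reported as absent.  Distance is measured from the hexamer's 5'-most
#' base to the TSS; ties are broken towards distance 26, then upstream.
#'
#' @param genome a [genome_record()].
#' @param tss 0-based TSS position.
#' @param strand strand of the transcript.
#' @param scan_window c(min, max) distance in nt (default 20-35, i.e. the
#'   -35..-20 window).
#' @return list with `found`, `start`, `end` (forward interval), `seq`,
#'   `distance`, `mismatches`, `truncated`.
#' @export
find_boxA <- function(genome, tss, strand = "+", scan_window = c(20L, 35L)) {
  hex <- "TTTAAA"
  best <- NULL
  truncated <- FALSE
  for (d in scan_window[1]:scan_window[2]) {
    if (strand == "+") {
      s <- tss - d; e <- s + 6L
    } else {
      e <- tss + d + 1L; s <- e - 6L
    }
    if (s < 0 || e > genome$length) { truncated <- TRUE; next }
    cand <- seq_extract(genome$sequence, s, e, strand)
    mm <- hamming(cand, hex)
    key <- c(mm, abs(d - 26L), -d)
    if (is.null(best) ||
        (key[1] < best$key[1]) ||
        (key[1] == best$key[1] && key[2] < best$key[2]) ||
        (key[1] == best$key[1] && key[2] == best$key[2] &&
           key[3] < best$key[3])) {
      best <- list(start = s, end = e, seq = cand, distance = d,
                   mismatches = mm, key = key)
    }
  }
  if (is.null(best) || best$mismatches > 1L) {
    return(list(found = FALSE, start = NA_integer_, end = NA_integer_,
                seq = NA_character_, distance = NA_integer_,
                mismatches = NA_integer_, truncated = truncated))
  }
  list(found = TRUE, start = best$start, end = best$end, seq = best$seq,
       distance = best$distance, mismatches = best$mismatches,
       truncated = truncated)
}
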