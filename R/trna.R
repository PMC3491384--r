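# Split tRNA-half pairing: each half gene carries, on its intron-side end, a
# GC-rich clamp whose reverse complement is found only in the matching half.
# Pairing maximises the summed clamp duplex score over a one-to-one matching.

#' Extract clamp sequences flanking tRNA half genes
#'
#' The clamp is the flanking sequence on the intron-side end of the half
#' (downstream of a 5' half, upstream of a 3' half, in transcript
#' orientation), trimmed at the first downstream T-stretch (>= `t_stretch`
#' consecutive T, the polypyrimidine terminator) when present.  For a 3'
#' half, whose clamp precedes the body in the transcript, the portion after
#' the last upstream T-stretch is kept.
#'
#' @param halves feature table rows of kind `tRNA_half` with a `half_side`
#'   attribute (`five_prime` or `three_prime`).
#' @param genome a [genome_record()].
#' @param flank_len clamp search window (default 40 nt).
#' @param t_stretch minimum T-run length acting as terminator (default 5).
#' @return the input rows with `half_side`, `clamp_seq`, `clamp_start`,
#'   `clamp_end`, `low_gc` and `truncated` columns added.
#' @export
extract_clamps <- function(halves, genome, flank_len = 40L, t_stretch = 5L) {
  stopifnot(all(halves$kind == "tRNA_half"))
  side <- attr_get(halves$attrs, "half_side")
  if (anyNA(side)) stop_fmt("tRNA_half feature without half_side attribute")
  n <- nrow(halves)
  clamp_seq <- character(n); cs <- integer(n); ce <- integer(n)
  low_gc <- logical(n); trunc <- logical(n)
  trun <- sprintf("T{%d,}", t_stretch)
  for (i in seq_len(n)) {
    st <- halves$strand[i]
    if ((side[i] == "five_prime") == (st == "+")) {
      # flank to the right in forward coordinates
      a <- halves$end[i]; b <- min(genome$length, a + flank_len)
      trunc[i] <- (b - a) < flank_len
    } else {
      b <- halves$start[i]; a <- max(0L, b - flank_len)
      trunc[i] <- (b - a) < flank_len
    }
    s <- seq_extract(genome$sequence, a, b, st)   # transcript orientation
    if (side[i] == "five_prime") {
      hit <- regexpr(trun, s)
      keep_len <- if (hit > 0) hit - 1L else nchar(s)
      clamp <- substr(s, 1L, keep_len)
      if (st == "+") { cs[i] <- a; ce[i] <- a + keep_len }
      else { ce[i] <- b; cs[i] <- b - keep_len }
    } else {
      hits <- gregexpr(trun, s)[[1]]
      if (hits[1] > 0) {
        last <- length(hits)
        from <- hits[last] + attr(hits, "match.length")[last]
      } else from <- 1L
      clamp <- substr(s, from, nchar(s))
      if (st == "+") { ce[i] <- b; cs[i] <- b - nchar(clamp) }
      else { cs[i] <- a; ce[i] <- a + nchar(clamp) }
    }
    clamp_seq[i] <- clamp
    low_gc[i] <- !is.na(gc_fraction(clamp)) && gc_fraction(clamp) < 0.5
  }
  halves$half_side <- side
  halves$clamp_seq <- clamp_seq
  halves$clamp_start <- cs
  halves$clamp_end <- ce
  halves$low_gc <- low_gc
  halves$truncated <- trunc
  halves
}

# Best ungapped antiparallel duplex between two transcript-orientation
# sequences.  Returns the longest contiguous run of paired bases (G/U
# wobble admitted at gu_weight) maximising the summed weight over all
# offsets, as list(len, score, gc_fraction).
clamp_duplex <- function(a, b, gu_weight = 0.5) {
  if (nchar(a) == 0 || nchar(b) == 0) {
    return(list(len = 0L, score = 0, gc = NA_real_))
  }
  ac <- seq_chars(a)
  bc <- rev(seq_chars(b))      # antiparallel pairing: a[i] vs rev(b)[i]
  na <- length(ac); nb <- length(bc)
  best <- list(len = 0L, score = 0, gc = NA_real_)
  for (off in (-(nb - 1L)):(na - 1L)) {
    ia <- max(1L, 1L + off):min(na, nb + off)
    if (length(ia) == 0) next
    ib <- ia - off
    w <- pair_weight(ac[ia], bc[ib], gu_weight)
    # contiguous runs of non-zero weights
    r <- rle(w > 0)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (k in which(r$values)) {
      sc <- sum(w[starts[k]:ends[k]])
      len <- r$lengths[k]
      if (sc > best$score || (sc == best$score && len > best$len)) {
        seg <- ia[starts[k]:ends[k]]
        best <- list(len = as.integer(len), score = sc,
                     gc = mean(ac[seg] %in% c("G", "C")))
      }
    }
  }
  best
}

# Exact maximum-weight bipartite matching by bitmask dynamic programming
# (rows = 5' halves, columns = 3' halves; weights < 0 mean ineligible).
# Returns list(assign = column per row (NA = unmatched), score).
match_bipartite <- function(w) {
  nr <- nrow(w); nc <- ncol(w)
  if (nc > 20L) stop_fmt("bipartite instance too large (%d columns)", nc)
  nmask <- bitwShiftL(1L, nc)
  f <- matrix(-Inf, nr + 1L, nmask)
  f[1L, 1L] <- 0
  choice <- matrix(NA_integer_, nr + 1L, nmask)
  for (i in seq_len(nr)) {
    for (mask in 0:(nmask - 1L)) {
      base <- f[i, mask + 1L]
      if (!is.finite(base)) next
      # leave row i unmatched
      if (base > f[i + 1L, mask + 1L]) {
        f[i + 1L, mask + 1L] <- base
        choice[i + 1L, mask + 1L] <- 0L
      }
      for (j in seq_len(nc)) {
        bit <- bitwShiftL(1L, j - 1L)
        if (bitwAnd(mask, bit) != 0L || w[i, j] < 0) next
        v <- base + w[i, j]
        if (v > f[i + 1L, bitwOr(mask, bit) + 1L]) {
          f[i + 1L, bitwOr(mask, bit) + 1L] <- v
          choice[i + 1L, bitwOr(mask, bit) + 1L] <- j
        }
      }
    }
  }
  bestmask <- which.max(f[nr + 1L, ]) - 1L
  score <- f[nr + 1L, bestmask + 1L]
  assign <- rep(NA_integer_, nr)
  mask <- bestmask
  for (i in rev(seq_len(nr))) {
    j <- choice[i + 1L, mask + 1L]
    if (!is.na(j) && j > 0L) {
      assign[i] <- j
      mask <- bitwAnd(mask, bitwNot(bitwShiftL(1L, j - 1L)))
    }
  }
  list(assign = assign, score = score)
}

#' Pair split tRNA halves by clamp complementarity
#'
#' Scores all 5' x 3' half combinations by their best ungapped
#' reverse-complement clamp duplex (G/U wobble at `gu_weight`), rejects
#' pairs with a duplex shorter than `min_duplex_len`, and assigns halves
#' one-to-one by exact maximum-weight bipartite matching.  Pairs that could
#' be swapped without changing the optimal total score are flagged
#' ambiguous.
#'
#' @param halves output of [extract_clamps()].
#' @param genome a [genome_record()] (for mature-tRNA assembly).
#' @param min_duplex_len minimum accepted duplex length (default 8 nt).
#' @param gu_weight weight of a G/U pair in the duplex score (default 0.5).
#' @return data.frame of accepted pairs with duplex statistics, the
#'   assembled mature sequence and its junction index.
#' @export
pair_halves <- function(halves, genome = NULL, min_duplex_len = 8L,
                        gu_weight = 0.5) {
  fives <- halves[halves$half_side == "five_prime", , drop = FALSE]
  threes <- halves[halves$half_side == "three_prime", , drop = FALSE]
  if (nrow(fives) == 0 || nrow(threes) == 0) {
    stop_fmt("pair_halves needs at least one 5' and one 3' half")
  }
  nf <- nrow(fives); nt <- nrow(threes)
  W <- matrix(-1, nf, nt)
  L <- matrix(0L, nf, nt)
  G <- matrix(NA_real_, nf, nt)
  for (i in seq_len(nf)) {
    for (j in seq_len(nt)) {
      d <- clamp_duplex(fives$clamp_seq[i], threes$clamp_seq[j], gu_weight)
      if (d$len >= min_duplex_len) {
        W[i, j] <- d$score; L[i, j] <- d$len; G[i, j] <- d$gc
      }
    }
  }
  sol <- match_bipartite(W)
  rows <- list()
  for (i in seq_len(nf)) {
    j <- sol$assign[i]
    if (is.na(j)) next
    # ambiguity: does forbidding this pair still achieve the optimum?
    W2 <- W; W2[i, j] <- -1
    amb <- isTRUE(all.equal(match_bipartite(W2)$score, sol$score))
    asm <- if (!is.null(genome)) {
      assemble_mature(fives[i, ], threes[j, ], genome)
    } else list(mature_seq = NA_character_, junction = NA_integer_,
                length_flag = NA)
    rows[[length(rows) + 1L]] <- data.frame(
      five_id = fives$feature_id[i], three_id = threes$feature_id[j],
      duplex_len = L[i, j], duplex_score = W[i, j],
      gc_fraction_of_duplex = G[i, j], ambiguous = amb,
      junction = asm$junction, mature_len = nchar(asm$mature_seq),
      mature_seq = asm$mature_seq, length_flag = asm$length_flag,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(five_id = character(), three_id = character(),
                      duplex_len = integer(), duplex_score = numeric(),
                      gc_fraction_of_duplex = numeric(),
                      ambiguous = logical(), junction = integer(),
                      mature_len = integer(), mature_seq = character(),
                      length_flag = logical(), stringsAsFactors = FALSE)
  }
  attr(out, "matching_score") <- sol$score
  out
}

#' Assemble the mature trans-spliced tRNA from a half pair
#'
#' @param five_half,three_half single feature rows (with intervals and
#'   strand) whose bodies enter the mature tRNA.
#' @param genome a [genome_record()].
#' @return list with `mature_seq`, `junction` (index of the last 5'-body
#'   base) and `length_flag` (TRUE when outside the 70-100 nt sanity range).
#' @export
assemble_mature <- function(five_half, three_half, genome) {
  b5 <- seq_extract(genome$sequence, five_half$start, five_half$end,
                    five_half$strand)
  b3 <- seq_extract(genome$sequence, three_half$start, three_half$end,
                    three_half$strand)
  if (nchar(b5) == 0 || nchar(b3) == 0) {
    stop_fmt("empty tRNA half body (%s / %s)",
             five_half$feature_id, three_half$feature_id)
  }
  mature <- paste0(b5, b3)
  flag <- nchar(mature) < 70L || nchar(mature) > 100L
  if (flag) {
    warn_fmt("assembled tRNA %s+%s has unusual length %d nt",
             five_half$feature_id, three_half$feature_id, nchar(mature))
  }
  list(mature_seq = mature, junction = nchar(b5), length_flag = flag)
}

#' Annotate precursor termini of tRNA halves
#'
#' Per half: the modal 5' and 3' terminus from the pileup (via
#' [call_termini()]), reported as offsets from the expected precursor ends
#' (transcript start of the body for a 5' half / of the clamp for a 3' half;
#' clamp end / body end respectively for the 3' terminus; positive offsets
#' are extensions).  Also checks the purine start requirement and flags
#' read-through into flanking sequence, and reports the support-weighted
#' dispersion of each end.
#'
#' @param halves output of [extract_clamps()].
#' @param pileup a [build_pileup()] result.
#' @param genome a [genome_record()].
#' @param flank search window around the locus (default 20 nt).
#' @param min_support passed to [call_termini()] (default 5).
#' @return data.frame, one row per half.
#' @export
annotate_precursor_termini <- function(halves, pileup, genome, flank = 20L,
                                       min_support = 5L) {
  n <- nrow(halves)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    h <- halves[i, ]
    lo <- max(0L, min(h$start, h$clamp_start) - flank)
    hi <- min(pileup$length, max(h$end, h$clamp_end) + flank)
    # expected transcript ends in forward coordinates
    if (h$half_side == "five_prime") {
      exp5 <- if (h$strand == "+") h$start else h$end - 1L
      exp3 <- if (h$strand == "+") h$clamp_end - 1L else h$clamp_start
    } else {
      exp5 <- if (h$strand == "+") h$clamp_start else h$clamp_end - 1L
      exp3 <- if (h$strand == "+") h$end - 1L else h$start
    }
    t5 <- call_termini(pileup, c(lo, hi), h$strand, "5p", min_support)
    t3 <- call_termini(pileup, c(lo, hi), h$strand, "3p", min_support)
    m5 <- t5$position[t5$is_modal]
    m3 <- t3$position[t3$is_modal]
    sl <- if (h$strand == "-") pileup$minus else pileup$plus
    disp <- function(side_vec) {
      w <- side_vec[(lo + 1L):hi]
      if (sum(w) < 2) return(NA_real_)
      p <- (lo:(hi - 1L))[w > 0]; cnt <- w[w > 0]
      mu <- sum(p * cnt) / sum(cnt)
      sqrt(sum(cnt * (p - mu)^2) / (sum(cnt) - 1))
    }
    sgn <- if (h$strand == "+") 1L else -1L
    off5 <- if (length(m5) == 1) sgn * (exp5 - m5) else NA_integer_
    off3 <- if (length(m3) == 1) sgn * (m3 - exp3) else NA_integer_
    base5 <- if (length(m5) == 1) {
      seq_extract(genome$sequence, m5, m5 + 1L, h$strand)
    } else NA_character_
    # read-through: coverage persists well beyond the expected 3' end
    body_depth <- mean(sl$depth[(h$start + 1L):h$end])
    beyond <- if (h$strand == "+") {
      idx <- (exp3 + 6L):(exp3 + 15L)
      idx <- idx[idx >= 1L & idx <= pileup$length]
      if (length(idx) > 0) mean(sl$depth[idx + 1L]) else 0
    } else {
      idx <- (exp3 - 15L):(exp3 - 6L)
      idx <- idx[idx >= 0L & idx < pileup$length]
      if (length(idx) > 0) mean(sl$depth[idx + 1L]) else 0
    }
    rows[[i]] <- data.frame(
      feature_id = h$feature_id, half_side = h$half_side,
      strand = h$strand,
      modal5 = if (length(m5) == 1) m5 else NA_integer_,
      modal3 = if (length(m3) == 1) m3 else NA_integer_,
      offset5 = off5, offset3 = off3,
      start_base = base5,
      purine_start = !is.na(base5) & base5 %in% c("A", "G"),
      dispersion5 = disp(sl$p5), dispersion3 = disp(sl$p3),
      read_through = body_depth > 0 && beyond >= 0.5 * body_depth,
      absent = length(m5) == 0 && length(m3) == 0,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Leaderless transcription report for tRNA genes
#'
#' For each mature tRNA gene: the fraction of read 5' ends landing exactly
#' on the annotated gene start (denominator: 5' ends within +/- `window` nt
#' of the start), the start base and its purine status, and the -1
#' diagnostic: the fraction of reads starting exactly one templated base
#' upstream, with that base's identity (the G-1 test).
#'
#' @param trna_genes feature table rows of kind `tRNA`.
#' @param pileup a [build_pileup()] result.
#' @param genome a [genome_record()].
#' @param window denominator half-width (default 5 nt).
#' @return data.frame, one row per gene.
#' @export
leaderless_report <- function(trna_genes, pileup, genome, window = 5L) {
  n <- nrow(trna_genes)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    g <- trna_genes[i, ]
    s0 <- five_prime_pos(g$start, g$end, g$strand)
    sl <- if (g$strand == "-") pileup$minus else pileup$plus
    lo <- max(0L, s0 - window); hi <- min(pileup$length - 1L, s0 + window)
    denom <- sum(sl$p5[(lo + 1L):(hi + 1L)])
    at0 <- sl$p5[s0 + 1L]
    up1 <- if (g$strand == "+") s0 - 1L else s0 + 1L
    atm1 <- if (up1 >= 0L && up1 < pileup$length) sl$p5[up1 + 1L] else 0L
    rows[[i]] <- data.frame(
      feature_id = g$feature_id,
      mature_start_fraction = if (denom > 0) at0 / denom else NA_real_,
      start_base = seq_extract(genome$sequence, s0, s0 + 1L, g$strand),
      purine_start = seq_extract(genome$sequence, s0, s0 + 1L,
                                 g$strand) %in% c("A", "G"),
      minus1_fraction = if (denom > 0) atm1 / denom else NA_real_,
      minus1_base = if (up1 >= 0L && up1 < pileup$length) {
        seq_extract(genome$sequence, up1, up1 + 1L, g$strand)
      } else NA_character_,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
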