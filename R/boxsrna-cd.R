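# C/D box sRNA discovery.  Box patterns (DNA alphabet): box C = RTGATGA with
# the core GAT (positions 3-5) exact and at most boxC_mm mismatches at the
# remaining positions (R = A/G); box D = CTGA.  A canonical locus reads
# C .. guide1 .. D' .. C' .. guide2 .. D; a permuted locus carries box D
# genomically upstream of box C (linear order C' .. guide2 .. D .. C ..
# guide1 .. D'), which reads canonically only across a circular junction.

#' C/D box scan parameters
#'
#' @param boxC_mm,boxCp_mm,boxD_mm,boxDp_mm mismatch budgets for boxes C, C',
#'   D, D' (defaults 1/2/0/1; the box C core GAT is always exact).
#' @param sep_range allowed box C start to box D start separation for the
#'   canonical order (default 40-90 nt, the compact archaeal arrangement).
#' @param guide_range allowed guide length (gap from box C/C' end to box
#'   D'/D start; default 10-21 nt).
#' @param linker_range allowed box D' end to box C' start gap (default
#'   0-8 nt).
#' @param perm_gap allowed box D end to box C start gap in the permuted
#'   order (default 2-15 nt).
#' @param flank5,flank3 nt added outside the outermost boxes to form the
#'   sRNA interval (defaults 5 and 3).
#' @return a `cd_params` list.
#' @export
cd_params <- function(boxC_mm = 1L, boxCp_mm = 2L, boxD_mm = 0L,
                      boxDp_mm = 1L, sep_range = c(40L, 90L),
                      guide_range = c(10L, 21L), linker_range = c(0L, 8L),
                      perm_gap = c(2L, 15L), flank5 = 5L, flank3 = 3L) {
  structure(list(boxC_mm = boxC_mm, boxCp_mm = boxCp_mm, boxD_mm = boxD_mm,
                 boxDp_mm = boxDp_mm, sep_range = sep_range,
                 guide_range = guide_range, linker_range = linker_range,
                 perm_gap = perm_gap, flank5 = flank5, flank3 = flank3),
            class = "cd_params")
}

# Vectorised motif matchers over a character vector of bases.  Positions
# returned are 1-based starts; mm is the mismatch count at non-core
# positions.
boxC_matches <- function(ch, max_mm) {
  n <- length(ch)
  if (n < 7L) return(data.frame(pos = integer(), mm = integer()))
  idx <- seq_len(n - 6L)
  core <- ch[idx + 2L] == "G" & ch[idx + 3L] == "A" & ch[idx + 4L] == "T"
  mm <- (!(ch[idx] %in% c("A", "G"))) + (ch[idx + 1L] != "T") +
    (ch[idx + 5L] != "G") + (ch[idx + 6L] != "A")
  keep <- core & mm <= max_mm
  data.frame(pos = idx[keep], mm = as.integer(mm[keep]))
}

boxD_matches <- function(ch, max_mm) {
  n <- length(ch)
  if (n < 4L) return(data.frame(pos = integer(), mm = integer()))
  idx <- seq_len(n - 3L)
  mm <- (ch[idx] != "C") + (ch[idx + 1L] != "T") + (ch[idx + 2L] != "G") +
    (ch[idx + 3L] != "A")
  keep <- mm <= max_mm
  data.frame(pos = idx[keep], mm = as.integer(mm[keep]))
}

# Scan one strand-oriented sequence for canonical and permuted C/D loci.
# Coordinates returned are 1-based within the given sequence.
scan_cd_seq <- function(seqchr, params) {
  ch <- seq_chars(seqchr)
  C <- boxC_matches(ch, params$boxC_mm)
  D <- boxD_matches(ch, params$boxD_mm)
  Cp <- boxC_matches(ch, params$boxCp_mm)
  Dp <- boxD_matches(ch, params$boxDp_mm)
  g <- params$guide_range; lk <- params$linker_range
  out <- list()
  # canonical: C .. D' .. C' .. D
  for (ci in seq_len(nrow(C))) {
    p <- C$pos[ci]
    dcand <- D[D$pos - p >= params$sep_range[1] &
                 D$pos - p <= params$sep_range[2], , drop = FALSE]
    if (nrow(dcand) == 0) next
    dpc <- Dp[Dp$pos >= p + 7L + g[1] & Dp$pos <= p + 7L + g[2], ,
              drop = FALSE]
    if (nrow(dpc) == 0) next
    best <- NULL
    for (di in seq_len(nrow(dcand))) {
      q <- dcand$pos[di]
      for (ki in seq_len(nrow(dpc))) {
        d1 <- dpc$pos[ki]
        cpc <- Cp[Cp$pos >= d1 + 4L + lk[1] & Cp$pos <= d1 + 4L + lk[2] &
                    q - (Cp$pos + 7L) >= g[1] & q - (Cp$pos + 7L) <= g[2], ,
                  drop = FALSE]
        if (nrow(cpc) == 0) next
        for (li in seq_len(nrow(cpc))) {
          sc <- C$mm[ci] + dcand$mm[di] + dpc$mm[ki] + cpc$mm[li]
          cand <- list(arrangement = "canonical", score = sc,
                       boxC = p, boxD = q, boxDp = d1, boxCp = cpc$pos[li],
                       start = p - params$flank5, end = q + 3L + params$flank3)
          if (is.null(best) || sc < best$score) best <- cand
        }
      }
    }
    if (!is.null(best)) out[[length(out) + 1L]] <- best
  }
  # permuted: C' .. D .. C .. D'  (box D upstream of box C)
  for (di in seq_len(nrow(D))) {
    q <- D$pos[di]
    ccand <- C[C$pos - (q + 4L) >= params$perm_gap[1] &
                 C$pos - (q + 4L) <= params$perm_gap[2], , drop = FALSE]
    if (nrow(ccand) == 0) next
    best <- NULL
    for (ci in seq_len(nrow(ccand))) {
      p <- ccand$pos[ci]
      dpc <- Dp[Dp$pos >= p + 7L + g[1] & Dp$pos <= p + 7L + g[2], ,
                drop = FALSE]
      cpc <- Cp[q - (Cp$pos + 7L) >= g[1] & q - (Cp$pos + 7L) <= g[2], ,
                drop = FALSE]
      if (nrow(dpc) == 0 || nrow(cpc) == 0) next
      for (ki in seq_len(nrow(dpc))) {
        for (li in seq_len(nrow(cpc))) {
          sc <- D$mm[di] + ccand$mm[ci] + dpc$mm[ki] + cpc$mm[li]
          cand <- list(arrangement = "permuted", score = sc,
                       boxC = p, boxD = q, boxDp = dpc$pos[ki],
                       boxCp = cpc$pos[li],
                       start = cpc$pos[li] - params$flank5,
                       end = dpc$pos[ki] + 3L + params$flank3)
          if (is.null(best) || sc < best$score) best <- cand
        }
      }
    }
    if (!is.null(best)) out[[length(out) + 1L]] <- best
  }
  out
}

#' Scan a genome for C/D box sRNA candidates
#'
#' Both strands are scanned for the canonical box arrangement
#' (C-guide-D'-C'-guide-D) and for the permuted arrangement (box D
#' genomically upstream of box C); a permuted call is made only when no
#' canonical ordering scores at the locus.  Overlapping candidates on the
#' same strand are resolved by keeping the lowest total mismatch count
#' (then the longer span); losers are returned in the `shadowed` attribute.
#'
#' @param genome a [genome_record()].
#' @param params a [cd_params()].
#' @param regions optional data.frame with `start`, `end` (0-based
#'   half-open) restricting the scan, e.g. from [screen_intergenic()].
#' @return data.frame of candidates with box coordinates (0-based genomic),
#'   guide-region intervals and arrangement; attribute `shadowed` lists
#'   discarded overlaps.
#' @export
scan_cd <- function(genome, params = cd_params(), regions = NULL) {
  gchr <- genome$sequence
  L <- genome$length
  cands <- list()
  scan_one <- function(seqchr, to_fwd, strand) {
    for (h in scan_cd_seq(seqchr, params)) {
      s_local <- max(1L, h$start); e_local <- min(nchar(seqchr), h$end)
      iv <- to_fwd(s_local, e_local)
      box <- function(pos1, len) {
        b <- to_fwd(pos1, pos1 + len - 1L)
        c(b[1], b[2])
      }
      bc <- box(h$boxC, 7L); bd <- box(h$boxD, 4L)
      bdp <- box(h$boxDp, 4L); bcp <- box(h$boxCp, 7L)
      loc <- function(pos1, len) {
        substr(seqchr, pos1, pos1 + len - 1L)
      }
      # guide regions in local coordinates (1-based): upstream of D and D'
      guide_of <- function(upstream_box_end, d_start) {
        gs <- max(upstream_box_end + 1L, d_start - params$guide_range[2])
        c(gs, d_start - 1L)
      }
      g1 <- guide_of(h$boxC + 6L, h$boxDp)     # guide before D'
      g2 <- guide_of(h$boxCp + 6L, h$boxD)     # guide before D
      cands[[length(cands) + 1L]] <<- data.frame(
        contig_id = genome$contig_id, start = iv[1], end = iv[2],
        strand = strand, arrangement = h$arrangement, score = h$score,
        boxC_start = bc[1], boxC_end = bc[2], boxC_seq = loc(h$boxC, 7L),
        boxD_start = bd[1], boxD_end = bd[2], boxD_seq = loc(h$boxD, 4L),
        boxCp_start = bcp[1], boxCp_end = bcp[2],
        boxCp_seq = loc(h$boxCp, 7L),
        boxDp_start = bdp[1], boxDp_end = bdp[2],
        boxDp_seq = loc(h$boxDp, 4L),
        guideDp_seq = substr(seqchr, g1[1], g1[2]),
        guideD_seq = substr(seqchr, g2[1], g2[2]),
        stringsAsFactors = FALSE)
    }
  }
  run_window <- function(w_start, w_end) {
    fwd <- substr(gchr, w_start + 1L, w_end)
    scan_one(fwd,
             function(a, b) c(w_start + a - 1L, w_start + b),
             "+")
    rc <- revcomp(fwd)
    wlen <- w_end - w_start
    scan_one(rc,
             function(a, b) c(w_start + wlen - b, w_start + wlen - a + 1L),
             "-")
  }
  if (is.null(regions)) {
    run_window(0L, L)
  } else {
    pad <- 120L
    for (r in seq_len(nrow(regions))) {
      run_window(max(0L, regions$start[r] - pad),
                 min(L, regions$end[r] + pad))
    }
  }
  if (length(cands) == 0) {
    df <- empty_cd_candidates()
    attr(df, "shadowed") <- empty_cd_candidates()
    return(df)
  }
  df <- do.call(rbind, cands)
  df <- df[!duplicated(paste(df$start, df$end, df$strand, df$arrangement)), ,
           drop = FALSE]
  # a permuted call stands only where no equally good canonical ordering
  # does: overlap resolution prefers fewer mismatches, canonical on ties,
  # then the longer span
  arr_rank <- ifelse(df$arrangement == "canonical", 0L, 1L)
  df <- df[order(df$score, arr_rank, -(df$end - df$start), df$start), ,
           drop = FALSE]
  keep <- logical(nrow(df))
  taken <- list(`+` = IRanges::IRanges(), `-` = IRanges::IRanges())
  for (i in seq_len(nrow(df))) {
    ir <- IRanges::IRanges(df$start[i] + 1L, df$end[i])
    ov <- IRanges::countOverlaps(ir, taken[[df$strand[i]]]) > 0
    if (!ov) {
      keep[i] <- TRUE
      taken[[df$strand[i]]] <- c(taken[[df$strand[i]]], ir)
    }
  }
  shadowed <- df[!keep, , drop = FALSE]
  df <- df[keep, , drop = FALSE]
  df <- df[order(df$start), , drop = FALSE]
  if (nrow(df) > 0) df$srna_id <- sprintf("CD_%03d", seq_len(nrow(df)))
  rownames(df) <- NULL
  attr(df, "shadowed") <- shadowed
  df
}

empty_cd_candidates <- function() {
  data.frame(contig_id = character(), start = integer(), end = integer(),
             strand = character(), arrangement = character(),
             score = integer(), boxC_start = integer(), boxC_end = integer(),
             boxC_seq = character(), boxD_start = integer(),
             boxD_end = integer(), boxD_seq = character(),
             boxCp_start = integer(), boxCp_end = integer(),
             boxCp_seq = character(), boxDp_start = integer(),
             boxDp_end = integer(), boxDp_seq = character(),
             guideDp_seq = character(), guideD_seq = character(),
             stringsAsFactors = FALSE)
}

#' Count terminal base pairing of an sRNA
#'
#' Counts ungapped antiparallel complementary pairs (G/U admitted) between
#' the first and last `n_term` nt of the sRNA; a count of 0-1 qualifies as
#' "unpaired ends", the arrangement expected for C/D box sRNAs (a
#' k-turn-stem candidate pairs more).
#'
#' @param seq sRNA sequence (transcript orientation).
#' @param n_term terminal window (default 6 nt).
#' @return integer pair count.
#' @export
check_terminal_pairing <- function(seq, n_term = 6L) {
  n <- nchar(seq)
  n_term <- min(n_term, n %/% 2L)
  if (n_term == 0L) return(0L)
  a <- seq_chars(substr(seq, 1L, n_term))
  b <- seq_chars(substr(seq, n - n_term + 1L, n))
  sum(pair_weight(a, rev(b)) > 0)
}

#' Detect circular sRNAs from junction-spanning reads
#'
#' Counts reads whose sequence matches the doubled locus sequence across
#' the 3'end-to-5'start junction with at least `min_each` nt exactly
#' matching on each side (reads also matching the linear locus are not
#' junction evidence).  The circular flag requires `min_support` junction
#' reads.
#'
#' @param srna one row of the [scan_cd()] table (or any locus with
#'   `start`, `end`, `strand`).
#' @param reads data.frame with `seq` (raw reads; junction reads do not map
#'   linearly).
#' @param genome a [genome_record()].
#' @param min_each minimum exact match on each side of the junction
#'   (default 12 nt).
#' @param min_support junction reads needed for the circular call
#'   (default 5).
#' @return list with `junction_read_support`, `circular`, `circle_len`.
#' @export
detect_circular <- function(srna, reads, genome, min_each = 12L,
                            min_support = 5L) {
  S <- seq_extract(genome$sequence, srna$start, srna$end, srna$strand)
  Lc <- nchar(S)
  doubled <- paste0(S, S)
  support <- 0L
  useq <- table(reads$seq)
  for (s in names(useq)) {
    for (q in c(s, revcomp(s))) {
      len <- nchar(q)
      if (len < 2L * min_each || len > Lc) next
      hit <- regexpr(q, doubled, fixed = TRUE)[[1]]
      found <- FALSE
      while (hit > 0) {
        left <- Lc - hit + 1L
        right <- hit + len - 1L - Lc
        if (hit <= Lc && right >= 1L && left >= min_each &&
            right >= min_each) {
          found <- TRUE
          break
        }
        nxt <- regexpr(q, substr(doubled, hit + 1L, nchar(doubled)),
                       fixed = TRUE)[[1]]
        hit <- if (nxt > 0) hit + nxt else -1L
      }
      if (found) {
        support <- support + as.integer(useq[[s]])
        break
      }
    }
  }
  list(junction_read_support = support,
       circular = support >= min_support,
       circle_len = Lc)
}

#' Classify the genomic context of an sRNA
#'
#' Labels are tested in priority order: `tRNA_intronic` (inside an annotated
#' tRNA intron) > `tRNA_dicistronic` (at most `dicistronic_gap` nt
#' downstream of a tRNA gene on the same strand, the RNase Z co-processing
#' arrangement) > `split_gene_flank` (within `flank_dist` nt of a terminus
#' of a gene annotated with `split_part`) > `mRNA_overlap` (overlapping any
#' gene) > `standalone`.
#'
#' @param srnas data.frame with `start`, `end`, `strand` (0-based
#'   half-open).
#' @param features feature table; tRNA introns are rows of kind `other`
#'   with attribute `feature_class=tRNA_intron`; split genes carry the
#'   attribute `split_part` (`N_terminal` / `C_terminal`).
#' @param dicistronic_gap maximum tRNA-to-sRNA gap (default 5 nt).
#' @param flank_dist maximum distance to a split-gene terminus (default
#'   100 nt).
#' @return character vector of context labels, one per sRNA.
#' @export
classify_context <- function(srnas, features, dicistronic_gap = 5L,
                             flank_dist = 100L) {
  introns <- features[features$kind == "other" &
                        !is.na(attr_get(features$attrs, "feature_class")) &
                        attr_get(features$attrs, "feature_class") ==
                          "tRNA_intron", , drop = FALSE]
  trnas <- features[features$kind == "tRNA", , drop = FALSE]
  genes <- features[features$kind == "gene", , drop = FALSE]
  split_genes <- genes[!is.na(attr_get(genes$attrs, "split_part")), ,
                       drop = FALSE]
  vapply(seq_len(nrow(srnas)), function(i) {
    s <- srnas[i, ]
    inside <- introns$start <= s$start & introns$end >= s$end &
      (is.na(introns$strand) | introns$strand == s$strand)
    if (any(inside)) return("tRNA_intronic")
    if (nrow(trnas) > 0) {
      gap <- if (s$strand == "+") s$start - trnas$end else
        trnas$start - s$end
      if (any(trnas$strand == s$strand & gap >= 0 &
                gap <= dicistronic_gap)) {
        return("tRNA_dicistronic")
      }
    }
    if (nrow(split_genes) > 0) {
      dist_to <- function(pos) {
        pmax(0L, pmax(s$start - pos, pos - s$end))
      }
      d <- pmin(dist_to(split_genes$start), dist_to(split_genes$end))
      if (any(d <= flank_dist)) return("split_gene_flank")
    }
    if (nrow(genes) > 0 &&
        any(genes$start < s$end & genes$end > s$start)) {
      return("mRNA_overlap")
    }
    "standalone"
  }, character(1))
}

#' Predict 2'-O-methylation targets of C/D box sRNA guides
#'
#' For each guide region (10-21 nt immediately upstream of box D and box
#' D'), rRNAs are scanned for a contiguous antisense duplex of at least
#' `min_duplex` base pairs (G/U admitted) covering the guide base five
#' positions upstream of the box; the methylated target nucleotide is the
#' base paired to that guide position (the D+5 rule).  Qualifying sites are
#' ranked by duplex length, then fewest G/U pairs.
#'
#' @param srnas output of [scan_cd()] (needs `srna_id`, `guideD_seq`,
#'   `guideDp_seq`).
#' @param rrnas named character vector of rRNA sequences (DNA alphabet).
#' @param min_duplex minimum duplex length (default 10 nt).
#' @return data.frame of predictions (`target_position` is 1-based in the
#'   target RNA); guides shorter than 10 nt are skipped and listed in the
#'   `skipped` attribute.
#' @export
predict_2ome_targets <- function(srnas, rrnas, min_duplex = 10L) {
  preds <- list()
  skipped <- character(0)
  for (i in seq_len(nrow(srnas))) {
    for (src in c("D", "Dp")) {
      g <- if (src == "D") srnas$guideD_seq[i] else srnas$guideDp_seq[i]
      if (is.na(g) || nchar(g) < 10L) {
        skipped <- c(skipped, paste0(srnas$srna_id[i], ":", src))
        next
      }
      gch <- seq_chars(g)
      n <- length(gch)
      anchor <- n - 4L                       # 5th guide base upstream of box
      for (rn in names(rrnas)) {
        tch <- seq_chars(rrnas[[rn]])
        M <- length(tch)
        # guide i pairs target j0 + n - i, for j0 in 0..M-n
        for (j0 in 0:(M - n)) {
          v <- pair_weight(gch, tch[j0 + n - seq_len(n) + 1L]) > 0
          if (!v[anchor]) next
          r <- rle(v)
          ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
          k <- which(r$values & starts <= anchor & ends >= anchor)
          if (length(k) == 0 || r$lengths[k] < min_duplex) next
          seg <- starts[k]:ends[k]
          n_gu <- sum(pair_weight(gch[seg],
                                  tch[j0 + n - seg + 1L]) == 0.5)
          preds[[length(preds) + 1L]] <- data.frame(
            srna_id = srnas$srna_id[i], guide_source = src,
            target_rna = rn, target_position = j0 + n - anchor + 1L,
            duplex_len = r$lengths[k], n_gu = n_gu,
            modification = "2pOme", stringsAsFactors = FALSE)
        }
      }
    }
  }
  out <- do.call(rbind, preds)
  if (is.null(out)) {
    out <- empty_report_table("targets")
  } else {
    out <- out[order(-out$duplex_len, out$n_gu, out$srna_id,
                     out$target_rna, out$target_position), , drop = FALSE]
  }
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  out
}
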