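# H/ACA box sRNA discovery.  Secondary structure comes from a
# maximum-base-pairing (Nussinov) fold -- a deliberate desk-scale
# replacement for free-energy folding -- and the H/ACA architecture is then
# read off the pairing map: two non-overlapping hairpins separated by an
# ACA hinge, k-turn bulges flagged from tandem G/A runs at internal loops,
# and a pseudouridylation pocket per hairpin.

#' Maximum-base-pairing RNA fold (Nussinov)
#'
#' Maximises the number of nested base pairs (Watson-Crick, optionally G/U)
#' with a minimum hairpin loop of `min_loop` unpaired bases.
#'
#' @param seq sequence (DNA alphabet; T read as U).
#' @param min_loop minimum loop size (default 3).
#' @param gu admit G/U pairs (default TRUE).
#' @return list with `pairs` (integer vector, `pairs[i]` = partner of i or
#'   0) and `n_pairs`.
#' @export
nussinov_fold <- function(seq, min_loop = 3L, gu = TRUE) {
  ch <- seq_chars(seq)
  n <- length(ch)
  pairs <- integer(n)
  if (n < min_loop + 2L) return(list(pairs = pairs, n_pairs = 0L))
  P <- outer(ch, ch, function(a, b) can_pair(a, b, gu))
  N <- matrix(0L, n, n)
  for (span in (min_loop + 1L):(n - 1L)) {
    for (i in seq_len(n - span)) {
      j <- i + span
      best <- N[i, j - 1L]
      ks <- i:(j - min_loop - 1L)
      ks <- ks[P[ks, j]]
      if (length(ks) > 0) {
        left <- ifelse(ks > i, N[cbind(pmax(i, 1L), pmax(ks - 1L, 1L))], 0L)
        left[ks == i] <- 0L
        inner <- N[cbind(pmin(ks + 1L, n), rep(j - 1L, length(ks)))]
        inner[ks + 1L > j - 1L] <- 0L
        vals <- left + 1L + inner
        best <- max(best, max(vals))
      }
      N[i, j] <- best
    }
  }
  # traceback
  stack <- list(c(1L, n))
  while (length(stack) > 0) {
    ij <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    i <- ij[1]; j <- ij[2]
    if (j - i <= min_loop) next
    if (N[i, j] == N[i, j - 1L]) {
      stack[[length(stack) + 1L]] <- c(i, j - 1L)
      next
    }
    for (k in i:(j - min_loop - 1L)) {
      if (!P[k, j]) next
      left <- if (k > i) N[i, k - 1L] else 0L
      inner <- if (k + 1L <= j - 1L) N[k + 1L, j - 1L] else 0L
      if (left + 1L + inner == N[i, j]) {
        pairs[k] <- j; pairs[j] <- k
        if (k > i) stack[[length(stack) + 1L]] <- c(i, k - 1L)
        if (k + 1L <= j - 1L) stack[[length(stack) + 1L]] <- c(k + 1L, j - 1L)
        break
      }
    }
  }
  list(pairs = pairs, n_pairs = sum(pairs > 0) %/% 2L)
}

# Describe one folded hairpin: outermost pair, stem segments, internal
# loops.  `pairs` is a pairing vector over the local sequence.
hairpin_anatomy <- function(ch, pairs) {
  paired <- which(pairs > 0)
  if (length(paired) == 0) return(NULL)
  out_i <- min(paired); out_j <- pairs[out_i]
  if (out_j < out_i) return(NULL)
  # walk the stem path from the outer pair inwards, collecting internal
  # loops (unpaired runs on the 5' and/or 3' side between stem segments)
  loops <- list()
  i <- out_i; j <- out_j
  repeat {
    i2 <- i + 1L
    while (i2 < j && pairs[i2] == 0L) i2 <- i2 + 1L
    if (i2 >= j || pairs[i2] < i2) break      # reached the apical loop
    j2 <- pairs[i2]
    run5 <- if (i2 > i + 1L) c(i + 1L, i2 - 1L) else NULL
    run3 <- if (j2 < j - 1L) c(j2 + 1L, j - 1L) else NULL
    if (!is.null(run5) || !is.null(run3)) {
      loops[[length(loops) + 1L]] <- list(run5 = run5, run3 = run3)
    }
    i <- i2; j <- j2
  }
  list(outer = c(out_i, out_j), apical = c(i, j), loops = loops,
       n_pairs = sum(pairs[out_i:out_j] > 0) %/% 2L)
}

run_seq <- function(ch, run) {
  if (is.null(run)) "" else paste(ch[run[1]:run[2]], collapse = "")
}

# Unpaired runs on the 5' and 3' sides of a hairpin's stem path (local
# coordinates), excluding the apical loop.
side_runs <- function(anatomy) {
  r5 <- list(); r3 <- list()
  for (l in anatomy$loops) {
    if (!is.null(l$run5)) r5[[length(r5) + 1L]] <- l$run5
    if (!is.null(l$run3)) r3[[length(r3) + 1L]] <- l$run3
  }
  list(r5 = r5, r3 = r3)
}

# k-turn: short (<= max_len) unpaired runs on both sides of the stem whose
# +/- 2 nt sequence neighbourhood carries a G/A dinucleotide -- the tandem
# sheared G-A / A-G signature next to a bulge.  Tolerant to the exact
# register the maximum-pairing fold chooses around the bulge.
has_kturn <- function(ch, runs, max_len = 4L) {
  ga_near <- function(run) {
    a <- max(1L, run[1] - 2L); b <- min(length(ch), run[2] + 2L)
    grepl("GA", paste(ch[a:b], collapse = ""), fixed = TRUE)
  }
  short5 <- Filter(function(r) r[2] - r[1] + 1L <= max_len, runs$r5)
  short3 <- Filter(function(r) r[2] - r[1] + 1L <= max_len, runs$r3)
  any(vapply(short5, ga_near, logical(1))) &&
    any(vapply(short3, ga_near, logical(1)))
}

# pocket: the longest unpaired run (>= min_run) on each side of the stem
# (innermost wins ties) -- the bipartite pseudouridylation guide.
pocket_runs <- function(runs, min_run = 4L) {
  pick <- function(rs) {
    best <- NULL
    for (r in rs) {
      len <- r[2] - r[1] + 1L
      if (len >= min_run && (is.null(best) || len >= best[2] - best[1] + 1L)) {
        best <- r
      }
    }
    best
  }
  p5 <- pick(runs$r5); p3 <- pick(runs$r3)
  if (is.null(p5) || is.null(p3)) NULL else list(run5 = p5, run3 = p3)
}

#' Find H/ACA box sRNAs in candidate regions
#'
#' Each candidate region is folded around every ACA hinge candidate: the
#' sequence left and right of the hinge must each fold into a hairpin
#' spanning at least `min_hairpin` nt with at least `min_pairs` base pairs.
#' Requires an ACA exactly at the hinge and/or 3 nt from the 3' end.  The H
#' domain status is `canonical_ANANNA` when the hinge matches ANANNA,
#' otherwise `ACA_only`; k-turn bulges and pseudouridylation pockets are
#' annotated per hairpin.
#'
#' @param regions data.frame with `start`, `end`, `strand` (0-based
#'   half-open candidate expressed regions).
#' @param genome a [genome_record()].
#' @param min_hairpin minimum hairpin span (default 25 nt).
#' @param min_pairs minimum pairs per hairpin (default 8).
#' @param min_loop,gu passed to [nussinov_fold()].
#' @return list of `haca_srna` objects (possibly empty), each with the
#'   region, hinge, hairpin anatomy, k-turn flags, pockets (local 1-based
#'   coordinates) and `h_domain_status`.
#' @export
find_haca <- function(regions, genome, min_hairpin = 25L, min_pairs = 8L,
                      min_loop = 3L, gu = TRUE) {
  out <- list()
  for (r in seq_len(nrow(regions))) {
    strand <- regions$strand[r] %||% "+"
    s <- seq_extract(genome$sequence, regions$start[r], regions$end[r],
                     strand)
    ch <- seq_chars(s)
    n <- length(ch)
    if (n < 2L * min_hairpin + 3L) next
    hinges <- gregexpr("ACA", s, fixed = TRUE)[[1]]
    if (hinges[1] < 0) next
    hinges <- hinges[hinges > min_hairpin &
                       hinges + 2L <= n - min_hairpin]
    best <- NULL
    for (h in hinges) {
      left <- nussinov_fold(substr(s, 1L, h - 1L), min_loop, gu)
      right <- nussinov_fold(substr(s, h + 3L, n), min_loop, gu)
      a1 <- hairpin_anatomy(ch[1:(h - 1L)], left$pairs)
      a2 <- hairpin_anatomy(ch[(h + 3L):n], right$pairs)
      if (is.null(a1) || is.null(a2)) next
      span1 <- a1$outer[2] - a1$outer[1] + 1L
      span2 <- a2$outer[2] - a2$outer[1] + 1L
      if (span1 < min_hairpin || a1$n_pairs < min_pairs ||
          span2 < min_hairpin || a2$n_pairs < min_pairs) next
      total <- a1$n_pairs + a2$n_pairs
      if (is.null(best) || total > best$total) {
        best <- list(h = h, a1 = a1, a2 = a2, total = total,
                     off2 = h + 2L)   # local offset of hairpin-2 coordinates
      }
    }
    if (is.null(best)) next
    h <- best$h
    # terminal ACA: an ACA ending within a few nt of the 3' end (candidate
    # regions from coverage can be off by a base or two)
    tail_hits <- gregexpr("ACA", substr(s, max(1L, n - 8L), n),
                          fixed = TRUE)[[1]]
    terminal_aca <- tail_hits[1] > 0
    term_aca_local <- if (terminal_aca) {
      max(1L, n - 8L) + tail_hits[length(tail_hits)] - 1L
    } else NA_integer_
    hinge_seq <- substr(s, max(1L, h - 1L), min(n, h + 4L))
    h_status <- if (grepl("^A.A..A$", hinge_seq)) "canonical_ANANNA"
    else "ACA_only"
    describe <- function(a, off, ch_sub, aca_local) {
      runs <- side_runs(a)
      kturn <- has_kturn(ch_sub, runs)
      p <- pocket_runs(runs)
      # loop runs are indices into the sub-sequence; shift to locus-local
      shift <- function(run) if (is.null(run)) NULL else run + off
      pocket <- if (is.null(p)) NULL else {
        list(run5 = shift(p$run5), run3 = shift(p$run3))
      }
      pocket_dist <- if (is.null(pocket) || is.na(aca_local)) NA_integer_
      else as.integer(aca_local - pocket$run3[2] - 1L)
      list(outer = a$outer + off, n_pairs = a$n_pairs, kturn = kturn,
           pocket = pocket, pocket_to_aca = pocket_dist)
    }
    hp1 <- describe(best$a1, 0L, ch[1:(h - 1L)], h)
    hp2 <- describe(best$a2, best$off2, ch[(h + 3L):n], term_aca_local)
    out[[length(out) + 1L]] <- structure(list(
      contig_id = genome$contig_id,
      start = regions$start[r], end = regions$end[r], strand = strand,
      seq = s, hinge_local = h, hinge_seq = hinge_seq,
      terminal_ACA = terminal_aca, h_domain_status = h_status,
      hairpins = list(hp1, hp2),
      kturn_flags = c(hp1$kturn, hp2$kturn)), class = "haca_srna")
  }
  out
}

#' Predict pseudouridylation targets of an H/ACA sRNA
#'
#' Simplified bipartite pocket rule: for each hairpin with a pocket whose 3'
#' strand ends 14-16 nt upstream of its ACA motif (hinge for hairpin 1,
#' terminal ACA for hairpin 2), rRNAs are scanned for an unpaired U-N
#' dinucleotide whose 5' flank pairs antiparallel with the pocket 3' strand
#' and whose 3' flank pairs with the pocket 5' strand, each over 4-8
#' contiguous base pairs (G/U admitted).  The U of the dinucleotide is the
#' predicted pseudouridine.
#'
#' @param haca a `haca_srna` from [find_haca()].
#' @param rrnas named character vector of rRNA sequences.
#' @param flank_range c(min, max) pairing length per pocket strand
#'   (default 4-8).
#' @param aca_dist_range allowed pocket-to-ACA distance (default 14-16 nt).
#' @return data.frame of predictions (`target_position` 1-based).
#' @export
predict_psi_targets <- function(haca, rrnas, flank_range = c(4L, 8L),
                                aca_dist_range = c(14L, 16L)) {
  ch_s <- seq_chars(haca$seq)
  preds <- list()
  for (hpi in seq_along(haca$hairpins)) {
    hp <- haca$hairpins[[hpi]]
    if (is.null(hp$pocket)) next
    if (is.na(hp$pocket_to_aca) ||
        hp$pocket_to_aca < aca_dist_range[1] ||
        hp$pocket_to_aca > aca_dist_range[2]) next
    p5 <- ch_s[hp$pocket$run5[1]:hp$pocket$run5[2]]
    p3 <- ch_s[hp$pocket$run3[1]:hp$pocket$run3[2]]
    for (rn in names(rrnas)) {
      tch <- seq_chars(rrnas[[rn]])
      M <- length(tch)
      for (t in 2:(M - 1L)) {
        if (tch[t] != "T") next
        # 5' flank of the target pairs the pocket 3' strand: p3[i] ~ t - i
        k1 <- 0L
        while (k1 < min(flank_range[2], length(p3)) && t - k1 - 1L >= 1L &&
               can_pair(p3[k1 + 1L], tch[t - k1 - 1L])) k1 <- k1 + 1L
        if (k1 < flank_range[1]) next
        # 3' flank pairs the pocket 5' strand: p5[i] ~ t + 1 + k2 + 1 - i
        k2max <- min(flank_range[2], length(p5), M - t - 1L)
        k2 <- 0L
        for (kk in seq_len(k2max)) {
          ok <- all(vapply(seq_len(kk), function(i) {
            can_pair(p5[i], tch[t + 1L + kk + 1L - i])
          }, logical(1)))
          if (ok) k2 <- kk
        }
        if (k2 < flank_range[1]) next
        preds[[length(preds) + 1L]] <- data.frame(
          srna_id = sprintf("HACA:%d-%d", haca$start, haca$end),
          guide_source = paste0("pocket", hpi), target_rna = rn,
          target_position = t, duplex_len = k1 + k2, n_gu = NA_integer_,
          modification = "pseudouridine", stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, preds)
  if (is.null(out)) out <- empty_report_table("targets")
  rownames(out) <- NULL
  out
}
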