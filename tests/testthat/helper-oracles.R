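# Independent oracles used by unit and acceptance tests.  Each is written
# as directly as possible (plain loops, reference library calls) and stays
# independent of the implementation path it checks.

# Minimal glocal alignment cost of a read against a genome (both strands)
# via Biostrings::pairwiseAlignment with the pipeline's cost scheme encoded
# as negative scores.
oracle_min_cost <- function(read, gchr) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 0, mismatch = -2)
  best <- Inf
  for (q in c(read, revcomp(read))) {
    al <- Biostrings::pairwiseAlignment(
      pattern = q, subject = gchr, type = "global-local",
      substitutionMatrix = mat, gapOpening = 0, gapExtension = 3)
    best <- min(best, -Biostrings::score(al))
  }
  best
}

# Box matchers written as plain per-position loops.
oracle_box_matches <- function(seqchr, pattern, core, max_mm) {
  ch <- strsplit(seqchr, "")[[1]]
  pat <- strsplit(pattern, "")[[1]]
  n <- length(ch); k <- length(pat)
  out <- NULL
  for (p in seq_len(n - k + 1L)) {
    mm <- 0L; ok <- TRUE
    for (j in seq_len(k)) {
      b <- ch[p + j - 1L]
      match_j <- if (pat[j] == "R") b %in% c("A", "G") else b == pat[j]
      if (!match_j) {
        if (j %in% core) { ok <- FALSE; break }
        mm <- mm + 1L
      }
    }
    if (ok && mm <= max_mm) out <- rbind(out, c(p, mm))
  }
  if (is.null(out)) data.frame(pos = integer(), mm = integer())
  else data.frame(pos = out[, 1], mm = out[, 2])
}

# Full C/D structure enumeration by brute-force nested loops, mirroring the
# published arrangement definitions; returns the best candidate per anchor
# like the scanner does.
oracle_scan_cd_seq <- function(seqchr, params = cd_params()) {
  C <- oracle_box_matches(seqchr, "RTGATGA", 3:5, params$boxC_mm)
  Cp <- oracle_box_matches(seqchr, "RTGATGA", 3:5, params$boxCp_mm)
  D <- oracle_box_matches(seqchr, "CTGA", integer(0), params$boxD_mm)
  Dp <- oracle_box_matches(seqchr, "CTGA", integer(0), params$boxDp_mm)
  g <- params$guide_range; lk <- params$linker_range
  out <- list()
  for (ci in seq_len(nrow(C))) {
    p <- C$pos[ci]; best <- NULL
    for (di in seq_len(nrow(D))) {
      q <- D$pos[di]
      if (q - p < params$sep_range[1] || q - p > params$sep_range[2]) next
      for (ki in seq_len(nrow(Dp))) {
        d1 <- Dp$pos[ki]
        if (d1 < p + 7 + g[1] || d1 > p + 7 + g[2]) next
        for (li in seq_len(nrow(Cp))) {
          c1 <- Cp$pos[li]
          if (c1 < d1 + 4 + lk[1] || c1 > d1 + 4 + lk[2]) next
          if (q - (c1 + 7) < g[1] || q - (c1 + 7) > g[2]) next
          sc <- C$mm[ci] + D$mm[di] + Dp$mm[ki] + Cp$mm[li]
          if (is.null(best) || sc < best$score) {
            best <- list(arrangement = "canonical", score = sc, boxC = p,
                         boxD = q, boxDp = d1, boxCp = c1)
          }
        }
      }
    }
    if (!is.null(best)) out[[length(out) + 1L]] <- best
  }
  for (di in seq_len(nrow(D))) {
    q <- D$pos[di]; best <- NULL
    for (ci in seq_len(nrow(C))) {
      p <- C$pos[ci]
      if (p - (q + 4) < params$perm_gap[1] ||
          p - (q + 4) > params$perm_gap[2]) next
      for (ki in seq_len(nrow(Dp))) {
        d1 <- Dp$pos[ki]
        if (d1 < p + 7 + g[1] || d1 > p + 7 + g[2]) next
        for (li in seq_len(nrow(Cp))) {
          c1 <- Cp$pos[li]
          if (q - (c1 + 7) < g[1] || q - (c1 + 7) > g[2]) next
          sc <- D$mm[di] + C$mm[ci] + Dp$mm[ki] + Cp$mm[li]
          if (is.null(best) || sc < best$score) {
            best <- list(arrangement = "permuted", score = sc, boxC = p,
                         boxD = q, boxDp = d1, boxCp = c1)
          }
        }
      }
    }
    if (!is.null(best)) out[[length(out) + 1L]] <- best
  }
  out
}

cd_candidate_key <- function(x) {
  sprintf("%s:%d:%d:%d:%d:%d", x$arrangement, x$boxC, x$boxD, x$boxDp,
          x$boxCp, x$score)
}

# Maximum-base-pairing count by top-down memoised recursion (independent of
# the bottom-up implementation).
oracle_max_pairs <- function(seq, min_loop = 3L, gu = TRUE) {
  ch <- strsplit(seq, "")[[1]]
  n <- length(ch)
  memo <- new.env(hash = TRUE)
  pairable <- function(a, b) {
    p <- paste0(ch[a], ch[b])
    p %in% c("AT", "TA", "GC", "CG") || (gu && p %in% c("GT", "TG"))
  }
  rec <- function(i, j) {
    if (j - i <= min_loop) return(0L)
    key <- paste(i, j)
    if (!is.null(memo[[key]])) return(memo[[key]])
    best <- rec(i, j - 1L)
    for (k in i:(j - min_loop - 1L)) {
      if (pairable(k, j)) {
        left <- if (k > i) rec(i, k - 1L) else 0L
        best <- max(best, left + 1L + rec(k + 1L, j - 1L))
      }
    }
    memo[[key]] <- best
    best
  }
  if (n < 2L) return(0L)
  rec(1L, n)
}

# Maximum-weight bipartite matching by exhaustive enumeration (rows
# assigned to distinct columns or left unmatched); weights < 0 ineligible.
oracle_best_matching <- function(w) {
  nr <- nrow(w); nc <- ncol(w)
  best <- -Inf
  rec <- function(i, used, acc) {
    if (i > nr) { best <<- max(best, acc); return(invisible(NULL)) }
    rec(i + 1L, used, acc)                  # leave row i unmatched
    for (j in seq_len(nc)) {
      if (!used[j] && w[i, j] >= 0) {
        used[j] <- TRUE
        rec(i + 1L, used, acc + w[i, j])
        used[j] <- FALSE
      }
    }
  }
  rec(1L, logical(nc), 0)
  best
}
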