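#' Build a strand-aware read pileup
#'
#' Per strand, per position: read depth and counts of biological 5' and 3'
#' read termini.  The 3'-end coordinate of a mapped read is its last aligned
#' base (end - 1), not the half-open bound; on the minus strand the 5' end is
#' at end - 1 and the 3' end at start.
#'
#' @param mapped data.frame from [map_reads()].
#' @param genome a [genome_record()].
#' @return a `read_pileup` list with elements `plus` and `minus` (each with
#'   `depth`, `p5`, `p3` integer vectors of contig length), `total_mapped`,
#'   `contig_id` and `length`.  Position i of each vector is 0-based
#'   coordinate i - 1.
#' @export
build_pileup <- function(mapped, genome) {
  L <- genome$length
  if (nrow(mapped) > 0) {
    bad <- which(mapped$start < 0 | mapped$end > L | mapped$end <= mapped$start)
    if (length(bad) > 0) {
      stop_fmt("read '%s' maps outside contig [0,%d): [%d,%d)",
               mapped$read_id[bad[1]], L, mapped$start[bad[1]],
               mapped$end[bad[1]])
    }
  }
  one_strand <- function(df) {
    depth <- integer(L); p5 <- integer(L); p3 <- integer(L)
    if (nrow(df) > 0) {
      # depth by difference array
      d <- integer(L + 1L)
      starts1 <- df$start + 1L
      ends1 <- df$end + 1L
      d[sort(unique(starts1))] <- 0L  # ensure allocation
      for (i in seq_len(nrow(df))) {
        d[starts1[i]] <- d[starts1[i]] + 1L
        d[ends1[i]] <- d[ends1[i]] - 1L
      }
      depth <- cumsum(d[seq_len(L)])
      if (identical(df$strand[1], "-")) {
        p5 <- tabulate(df$end, nbins = L)        # end - 1, shifted to 1-based
        p3 <- tabulate(df$start + 1L, nbins = L)
      } else {
        p5 <- tabulate(df$start + 1L, nbins = L)
        p3 <- tabulate(df$end, nbins = L)
      }
    }
    list(depth = as.integer(depth), p5 = p5, p3 = p3, n = nrow(df))
  }
  plus <- one_strand(mapped[mapped$strand == "+", , drop = FALSE])
  minus <- one_strand(mapped[mapped$strand == "-", , drop = FALSE])
  stopifnot(sum(plus$p5) == plus$n, sum(plus$p3) == plus$n,
            sum(minus$p5) == minus$n, sum(minus$p3) == minus$n)
  structure(list(contig_id = genome$contig_id, length = L,
                 plus = plus, minus = minus,
                 total_mapped = plus$n + minus$n),
            class = "read_pileup")
}

#' @export
print.read_pileup <- function(x, ...) {
  cat(sprintf("<read_pileup> %s: %d nt, %d mapped reads (+%d / -%d)\n",
              x$contig_id, x$length, x$total_mapped, x$plus$n, x$minus$n))
  invisible(x)
}

empty_termini <- function() {
  data.frame(contig_id = character(), position = integer(),
             strand = character(), side = character(), support = integer(),
             local_fraction = numeric(), is_hotspot = logical(),
             is_modal = logical(), stringsAsFactors = FALSE)
}

#' Call read termini in a region
#'
#' Returns all local maxima of the strand/side end-count array inside the
#' region with support >= `min_support`.  The global maximum is the modal
#' terminus (ties broken towards the transcript-upstream side); non-modal
#' local maxima with local fraction >= `hotspot_fraction` are flagged as
#' trimming hotspots.  The local fraction is support divided by the total
#' end count of that side within a +/- `window` nt neighbourhood.
#'
#' @param pileup a [build_pileup()] result.
#' @param region c(start, end), 0-based half-open.
#' @param strand "+" or "-".
#' @param side "5p" or "3p".
#' @param min_support minimum read support (default 5).
#' @param window neighbourhood half-width W in nt (default 10).
#' @param hotspot_fraction minimum local fraction for a hotspot (default 0.10).
#' @return data.frame of terminus calls (possibly empty).
#' @export
call_termini <- function(pileup, region, strand, side = c("5p", "3p"),
                         min_support = 5L, window = 10L,
                         hotspot_fraction = 0.10) {
  side <- match.arg(side)
  stopifnot(region[1] >= 0, region[2] <= pileup$length, region[1] < region[2])
  sl <- if (strand == "-") pileup$minus else pileup$plus
  ends <- if (side == "5p") sl$p5 else sl$p3
  lo <- region[1] + 1L; hi <- region[2]          # 1-based indexing
  e <- ends[lo:hi]
  if (sum(e) == 0) return(empty_termini())
  n <- length(e)
  left <- c(-1L, e[-n]); right <- c(e[-1], -1L)
  is_max <- e >= min_support & e >= left & e > right  # plateaus keep leftmost
  pos_local <- which(is_max)
  if (length(pos_local) == 0) return(empty_termini())
  support <- e[pos_local]
  pos <- pos_local + lo - 2L                     # back to 0-based genomic
  locfrac <- vapply(pos, function(p) {
    w <- ends[max(1L, p + 1L - window):min(pileup$length, p + 1L + window)]
    ends[p + 1L] / sum(w)
  }, numeric(1))
  # modal call: max support; ties towards the transcript-upstream side
  best <- max(support)
  tied <- which(support == best)
  modal_i <- if (strand == "-") tied[which.max(pos[tied])] else tied[1]
  is_modal <- seq_along(pos) == modal_i
  df <- data.frame(contig_id = pileup$contig_id, position = pos,
                   strand = strand, side = side, support = support,
                   local_fraction = locfrac,
                   is_hotspot = !is_modal & locfrac >= hotspot_fraction,
                   is_modal = is_modal, stringsAsFactors = FALSE)
  df[order(df$position), , drop = FALSE]
}

#' Screen intergenic regions for expressed RNAs
#'
#' Maximal intergenic intervals with depth >= `min_coverage` on either
#' strand (>= semantics: a position at exactly the threshold is included),
#' merged when separated by gaps of at most `merge_gap` nt.
#'
#' @param pileup a [build_pileup()] result.
#' @param features feature table defining the genic complement.
#' @param min_coverage depth threshold (default 1000 reads).
#' @param merge_gap maximum gap for merging intervals (default 10 nt).
#' @return data.frame with `contig_id`, `start`, `end`, `strand`,
#'   `max_depth` (0-based half-open intervals).
#' @export
screen_intergenic <- function(pileup, features, min_coverage = 1000L,
                              merge_gap = 10L) {
  inter <- intergenic_intervals(features, pileup$length)
  mask <- logical(pileup$length)
  for (i in seq_len(nrow(inter))) {
    if (inter$end[i] > inter$start[i]) {
      mask[(inter$start[i] + 1L):inter$end[i]] <- TRUE
    }
  }
  out <- NULL
  for (strand in c("+", "-")) {
    sl <- if (strand == "-") pileup$minus else pileup$plus
    hit <- which(sl$depth >= min_coverage & mask)
    if (length(hit) == 0) next
    ir <- IRanges::reduce(IRanges::IRanges(hit, hit),
                          min.gapwidth = merge_gap + 1L)
    md <- vapply(seq_along(ir), function(k) {
      max(sl$depth[BiocGenerics::start(ir)[k]:BiocGenerics::end(ir)[k]])
    }, numeric(1))
    out <- rbind(out, data.frame(
      contig_id = pileup$contig_id,
      start = BiocGenerics::start(ir) - 1L, end = BiocGenerics::end(ir),
      strand = strand, max_depth = as.integer(md), stringsAsFactors = FALSE))
  }
  if (is.null(out)) {
    out <- data.frame(contig_id = character(), start = integer(),
                      end = integer(), strand = character(),
                      max_depth = integer(), stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}
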