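#' Mapping configuration for the micro-mapper
#'
#' Cost scheme and acceptance thresholds for the seed-and-extend aligner.
#'
#' @param mismatch_cost,insertion_cost,deletion_cost positive integer edit
#'   costs (defaults 2/3/3; insertions are read bases absent from the
#'   reference, deletions are reference bases absent from the read).
#' @param length_fraction minimum fraction of the read that must be aligned
#'   (the mapper aligns reads end-to-end, so this acts as an interface
#'   compatibility knob; default 0.5).
#' @param similarity minimum identity (matches / alignment columns) of an
#'   accepted placement (default 0.8).
#' @param multimap_policy how cost ties across placements are resolved:
#'   `random_best_seeded` (one placement drawn with the run seed),
#'   `report_all`, or `discard`.
#' @param seed_len exact-match seed length (default 12).
#' @return a `map_config` list.
#' @export
map_config <- function(mismatch_cost = 2L, insertion_cost = 3L,
                       deletion_cost = 3L, length_fraction = 0.5,
                       similarity = 0.8,
                       multimap_policy = c("random_best_seeded",
                                           "report_all", "discard"),
                       seed_len = 12L) {
  multimap_policy <- match.arg(multimap_policy)
  stopifnot(mismatch_cost > 0, insertion_cost > 0, deletion_cost > 0,
            length_fraction > 0, length_fraction <= 1,
            similarity > 0, similarity <= 1)
  structure(list(mismatch_cost = as.integer(mismatch_cost),
                 insertion_cost = as.integer(insertion_cost),
                 deletion_cost = as.integer(deletion_cost),
                 length_fraction = length_fraction, similarity = similarity,
                 multimap_policy = multimap_policy,
                 seed_len = as.integer(seed_len)),
            class = "map_config")
}

# Semi-global alignment: query aligned end-to-end, reference window with free
# ends, minimising edit cost (mismatch/insertion/deletion).  Returns cost,
# matches, alignment columns and the 0-based aligned reference interval
# within the window.
align_semiglobal <- function(q, ref, mismatch = 2L, insertion = 3L,
                             deletion = 3L) {
  qc <- seq_chars(q); rc <- seq_chars(ref)
  m <- length(qc); n <- length(rc)
  D <- matrix(0L, m + 1L, n + 1L)
  D[, 1L] <- (0:m) * insertion
  for (i in seq_len(m)) {
    sub <- ifelse(qc[i] == rc, 0L, mismatch)
    row <- pmin(D[i, 1:n] + sub, D[i, 2:(n + 1L)] + insertion)
    prev <- D[i + 1L, 1L]
    for (j in seq_len(n)) {
      v <- min(row[j], prev + deletion)
      D[i + 1L, j + 1L] <- v
      prev <- v
    }
  }
  jend <- which.min(D[m + 1L, ]) - 1L          # 0-based ref end (exclusive)
  cost <- D[m + 1L, jend + 1L]
  # traceback to count matches / columns and find ref start
  i <- m; j <- jend; matches <- 0L; cols <- 0L
  while (i > 0L) {
    cur <- D[i + 1L, j + 1L]
    if (j > 0L &&
        cur == D[i, j] + (if (qc[i] == rc[j]) 0L else mismatch)) {
      matches <- matches + (qc[i] == rc[j])
      i <- i - 1L; j <- j - 1L; cols <- cols + 1L
    } else if (cur == D[i, j + 1L] + insertion) {
      i <- i - 1L; cols <- cols + 1L
    } else if (j > 0L && cur == D[i + 1L, j] + deletion) {
      j <- j - 1L; cols <- cols + 1L
    } else {
      # free leading reference: only reachable at i == 0
      break
    }
  }
  list(cost = as.integer(cost), matches = as.integer(matches),
       cols = as.integer(cols), ref_start = as.integer(j),
       ref_end = as.integer(jend))
}

# All minimum-cost placements of one query on one contig (forward
# orientation of the query against the forward genome).
best_placements <- function(q, gdna, gchr, config) {
  m <- nchar(q)
  L <- nchar(gchr)
  hits <- Biostrings::matchPattern(q, gdna)
  if (length(hits) > 0) {
    st <- BiocGenerics::start(hits)
    return(data.frame(start = st - 1L, end = st - 1L + m, cost = 0L,
                      matches = m, cols = m))
  }
  k <- config$seed_len
  if (m < k) return(NULL)
  # half-k tiling: with one substitution and one indel, at least one seed
  # window stays error-free for reads >= ~2k nt
  offs <- unique(c(seq(1L, m - k + 1L, by = max(1L, k %/% 2L)), m - k + 1L))
  band <- max(3L, ceiling(0.2 * m))
  wins <- integer(0)
  for (o in offs) {
    sh <- Biostrings::matchPattern(substr(q, o, o + k - 1L), gdna)
    if (length(sh) == 0) next
    ws <- BiocGenerics::start(sh) - (o - 1L) - band
    wins <- c(wins, ws)
  }
  if (length(wins) == 0) return(NULL)
  wins <- unique(pmax(1L, wins))
  if (length(wins) > 16L) wins <- wins[seq_len(16L)]
  res <- NULL
  for (ws in wins) {
    we <- min(L, ws + m + 2L * band)
    al <- align_semiglobal(q, substr(gchr, ws, we),
                           config$mismatch_cost, config$insertion_cost,
                           config$deletion_cost)
    res <- rbind(res, data.frame(
      start = ws - 1L + al$ref_start, end = ws - 1L + al$ref_end,
      cost = al$cost, matches = al$matches, cols = al$cols))
  }
  res <- res[order(res$cost), , drop = FALSE]
  res <- res[!duplicated(res$start), , drop = FALSE]
  res[res$cost == min(res$cost), , drop = FALSE]
}

#' Map reads to a small genome
#'
#' Exact-seed (default k = 12) and extend by banded edit-cost alignment with
#' configurable costs; reads are aligned end-to-end (no soft clipping).  A
#' placement is accepted when identity (matches / alignment columns) is at
#' least `similarity`.  Cost ties across placements are resolved by the
#' configured multimap policy; `random_best_seeded` draws one placement per
#' read using the run seed, which keeps coverage inside exact repeat copies.
#'
#' @param reads data.frame with `read_id` and `seq`.
#' @param genome a [genome_record()] (single contig).
#' @param config a [map_config()].
#' @param seed integer run seed for multimap resolution.
#' @return data.frame of mapped reads (`read_id`, `contig_id`, `start`,
#'   `end`, `strand`, `edit_cost`, `is_unique`, `n_best`) with an attribute
#'   `log` counting unmapped and too-short reads.
#' @export
map_reads <- function(reads, genome, config = map_config(), seed = 1L) {
  stopifnot(inherits(genome, "genome_record"))
  set.seed(as.integer(seed))
  gdna <- Biostrings::DNAString(genome$sequence)
  gchr <- genome$sequence
  useq <- unique(reads$seq)
  cand <- vector("list", length(useq))
  names(cand) <- useq
  n_short <- 0L
  for (s in useq) {
    if (nchar(s) < config$seed_len) { n_short <- n_short + 1L; next }
    plus <- best_placements(s, gdna, gchr, config)
    minus <- best_placements(revcomp(s), gdna, gchr, config)
    if (!is.null(plus)) plus$strand <- "+"
    if (!is.null(minus)) minus$strand <- "-"
    pl <- rbind(plus, minus)
    if (is.null(pl) || nrow(pl) == 0) next
    pl <- pl[pl$cost == min(pl$cost), , drop = FALSE]
    pl <- pl[!duplicated(paste(pl$start, pl$strand)), , drop = FALSE]
    # reads are aligned end-to-end, so the aligned fraction is 1 and the
    # length_fraction threshold is always met; identity is the live filter
    pl <- pl[pl$matches / pl$cols >= config$similarity, , drop = FALSE]
    if (nrow(pl) == 0) next
    cand[[s]] <- pl
  }
  rows <- vector("list", nrow(reads))
  n_unmapped <- 0L
  for (i in seq_len(nrow(reads))) {
    pl <- cand[[reads$seq[i]]]
    if (is.null(pl)) { n_unmapped <- n_unmapped + 1L; next }
    nb <- nrow(pl)
    if (nb > 1L) {
      if (config$multimap_policy == "discard") { n_unmapped <- n_unmapped + 1L; next }
      if (config$multimap_policy == "random_best_seeded") {
        pl <- pl[sample.int(nb, 1L), , drop = FALSE]
      }
    }
    rows[[i]] <- data.frame(read_id = reads$read_id[i],
                            contig_id = genome$contig_id,
                            start = pl$start, end = pl$end,
                            strand = pl$strand, edit_cost = pl$cost,
                            is_unique = nb == 1L, n_best = nb,
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out)) {
    out <- data.frame(read_id = character(), contig_id = character(),
                      start = integer(), end = integer(),
                      strand = character(), edit_cost = integer(),
                      is_unique = logical(), n_best = integer(),
                      stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  attr(out, "log") <- list(input = nrow(reads), mapped = nrow(out),
                           unmapped = n_unmapped, too_short = n_short)
  out
}
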