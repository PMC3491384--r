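# Helper: plant a simple array (n repeats, n-1 distinct spacers) in random
# background and return the genome plus planted coordinates.
plant_array <- function(seed, n_rep = 5L, sp_len = 38L, pad = 3000L) {
  set.seed(seed)
  rep28 <- paste0(random_dna(20), "ATTGAAAG")
  spacers <- replicate(n_rep - 1L, random_dna(sp_len))
  body <- paste0(rep28, paste0(spacers, rep28, collapse = ""))
  g <- genome_record("c", paste0(random_dna(pad), body, random_dna(pad)))
  list(genome = g, repeat_seq = rep28, spacers = spacers,
       start = pad, rep_starts = pad + (seq_len(n_rep) - 1L) * (28L + sp_len))
}

test_that("a planted array is recovered with its consensus and spacers", {
  pl <- plant_array(3)
  arrs <- detect_arrays(pl$genome)
  expect_length(arrs, 1L)
  a <- arrs[[1]]
  expect_equal(nrow(a$repeats), 5L)
  expect_equal(nrow(a$spacers), 4L)
  expect_equal(a$repeat_consensus, pl$repeat_seq)
  expect_equal(a$spacers$seq, pl$spacers)
  expect_equal(a$repeats$start, pl$rep_starts)
  expect_true(is.na(a$strand))
})

test_that("uniform random sequence yields no arrays", {
  set.seed(17)
  g <- genome_record("c", random_dna(10000))
  expect_length(detect_arrays(g), 0L)
})

test_that("orientation uses reads when present and sequence as fallback", {
  pl <- plant_array(5)
  arrs <- detect_arrays(pl$genome)
  a <- arrs[[1]]
  span <- c(a$repeats$start[1], a$repeats$end[nrow(a$repeats)])
  # all reads on the minus strand over the array
  m <- mapped_df(rep(span[1] + 10, 30), rep(span[1] + 50, 30), rep("-", 30))
  p <- build_pileup(m, pl$genome)
  # the sequence fallback may disagree on this random flank; reads win
  am <- suppressWarnings(orient_array(a, pileup = p, genome = pl$genome))
  expect_equal(am$strand, "-")
  expect_equal(am$orient_method, "reads")
  # zero reads: sequence fallback path
  p0 <- build_pileup(mapped_df(integer(0), integer(0), character(0)),
                     pl$genome)
  a0 <- orient_array(a, pileup = p0, genome = pl$genome)
  expect_equal(a0$orient_method, "sequence")
  expect_true(a0$strand %in% c("+", "-"))
})

test_that("maturation recovers the planted 8-nt tag and abundances", {
  pl <- plant_array(7, n_rep = 5L)
  a <- detect_arrays(pl$genome)[[1]]
  a$strand <- "+"
  # crRNA reads: 5' end 8 nt upstream of each spacer start, counts 40/20/10/5
  counts <- c(40L, 20L, 10L, 5L)
  st <- integer(0); en <- integer(0)
  for (i in 1:4) {
    s0 <- a$spacers$start[i]
    st <- c(st, rep(s0 - 8L, counts[i]))
    en <- c(en, rep(a$spacers$end[i] + 12L, counts[i]))
  }
  p <- build_pileup(mapped_df(st, en, rep("+", sum(counts))), pl$genome)
  prof <- infer_maturation(a, p)
  expect_equal(prof$read_count, counts)
  expect_equal(sum(prof$relative_abundance), 1, tolerance = 1e-9)
  expect_equal(prof$five_tag_length, rep(8L, 4))
  expect_equal(unique(prof$five_tag_sequence), "ATTGAAAG")
  # tag sequence is always a suffix of the repeat consensus
  expect_true(all(vapply(prof$five_tag_sequence, function(t) {
    endsWith(a$repeat_consensus, t)
  }, logical(1))))
  expect_equal(prof$three_modal_offset, rep(12L, 4))
})

test_that("a zero-read spacer is reported with count 0 and flagged", {
  pl <- plant_array(13, n_rep = 4L)
  a <- detect_arrays(pl$genome)[[1]]
  a$strand <- "+"
  s0 <- a$spacers$start[1]
  p <- build_pileup(mapped_df(rep(s0 - 8L, 10), rep(s0 + 30L, 10),
                              rep("+", 10)), pl$genome)
  prof <- infer_maturation(a, p)
  expect_equal(prof$read_count[3], 0L)
  expect_match(prof$flags[3], "no_reads")
  expect_true(is.na(prof$five_tag_length[3]))
})

test_that("leader identity length equals the planted divergence point", {
  set.seed(23)
  # the base right before / after every repeat copy is forced to differ
  # across copies so repeat boundary refinement cannot absorb it
  shared <- paste0(random_dna(199), "T")
  rep28 <- paste0(random_dna(20), "ATTGAAAG")
  mk <- function(lead) {
    sp <- vapply(c("A", "C", "G"), function(b) {
      paste0(b, random_dna(36), b)
    }, character(1))
    paste0(lead, rep28, paste0(sp, rep28, collapse = ""), "T")
  }
  # arrays share exactly the last 130 leader nt; bases 131 upstream differ
  leadA <- paste0(random_dna(70), "G", substr(shared, 72, 200))
  leadB <- paste0(random_dna(70), "C", substr(shared, 72, 200))
  g <- genome_record("c", paste0(random_dna(500), mk(leadA),
                                 random_dna(400), mk(leadB),
                                 random_dna(500)))
  arrs <- detect_arrays(g)
  expect_length(arrs, 2L)
  arrs <- lapply(arrs, function(a) { a$strand <- "+"; a })
  cmp <- compare_leaders(arrs[[1]], arrs[[2]], g)
  expect_equal(cmp$identical_prefix_length, 129L)
  # fully identical 200-nt leaders compare to >= 200
  g2 <- genome_record("c", paste0(random_dna(500), mk(shared),
                                  random_dna(400), mk(shared),
                                  random_dna(500)))
  arrs2 <- lapply(detect_arrays(g2), function(a) { a$strand <- "+"; a })
  cmp2 <- compare_leaders(arrs2[[1]], arrs2[[2]], g2)
  # >= 199: boundary refinement may shift the detected repeat start by one
  expect_gte(cmp2$identical_prefix_length, 199L)
  # independent random leaders: matches the direct character-walk oracle
  up <- function(a) rev(strsplit(seq_extract(
    g$sequence, nanosmallrna:::first_repeat(a)$start - 500L,
    nanosmallrna:::first_repeat(a)$start, "+"), "")[[1]])
  wa <- up(arrs[[1]]); wb <- up(arrs[[2]])
  oracle <- which(wa != wb)[1] - 1L
  expect_equal(cmp$identical_prefix_length, oracle)
})

test_that("TSS calling is strand-aware with upstream tie-breaking", {
  pl <- plant_array(29)
  a <- detect_arrays(pl$genome)[[1]]
  a$strand <- "+"
  fr <- a$repeats$start[1]
  a$leader <- c(fr - 200L, fr)
  # equal modes at -40 and -33: upstream-most (-40) must win
  m <- mapped_df(c(rep(fr - 40L, 10), rep(fr - 33L, 10)),
                 rep(fr + 20L, 20), rep("+", 20))
  tss <- call_tss(a, build_pileup(m, pl$genome), pl$genome)
  expect_equal(tss$tss_position, fr - 40L)
  expect_true(tss$tie)
  expect_equal(tss$tss_offset_to_first_repeat, 40L)
})

test_that("box A search matches the planted hexamer and tie-break rule", {
  set.seed(31)
  bg <- strsplit(random_dna(400), "")[[1]]
  # clear the scan neighbourhood of near-matches, then plant TTTAAA at -27
  tss <- 200L
  bg[(tss - 40L):(tss + 1L)] <- rep(c("G", "C"), length.out = 42L)
  bg[(tss - 27L + 1L):(tss - 27L + 6L)] <- strsplit("TTTAAA", "")[[1]]
  g <- genome_record("c", paste(bg, collapse = ""))
  hit <- find_boxA(g, tss, "+")
  expect_true(hit$found)
  expect_equal(hit$distance, 27L)
  expect_equal(hit$mismatches, 0L)
  expect_equal(hit$seq, "TTTAAA")
  # two perfect hexamers at -27 and -20: -27 is closer to -26 and wins
  bg2 <- bg
  bg2[(tss - 20L + 1L):(tss - 20L + 6L)] <- strsplit("TTTAAA", "")[[1]]
  hit2 <- find_boxA(genome_record("c", paste(bg2, collapse = "")), tss, "+")
  expect_equal(hit2$distance, 27L)
  # no match within 1 mismatch -> reported absent, not an error
  bg3 <- bg
  bg3[(tss - 27L + 1L):(tss - 27L + 6L)] <- rep("G", 6L)
  hit3 <- find_boxA(genome_record("c", paste(bg3, collapse = "")), tss, "+")
  expect_false(hit3$found)
})
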