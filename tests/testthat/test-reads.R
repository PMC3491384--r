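test_that("trimming discards short reads and leaves clean reads alone", {
  q40 <- function(n) strrep("I", n)
  reads <- data.frame(
    read_id = c("short", "clean"),
    seq = c(strrep("A", 20), "ACGTACGTACGTACGTACGT"),
    qual = c(q40(20), q40(20)), stringsAsFactors = FALSE)
  # poly-A tail of the first read trims it to 0 nt -> discarded (< 15)
  tr <- trim_reads(reads, trim_config())
  expect_equal(tr$reads$read_id, "clean")
  expect_equal(tr$reads$seq, "ACGTACGTACGTACGTACGT")
  expect_equal(tr$log$discarded_short, 1L)
})

test_that("a 14-nt read after trimming is removed", {
  reads <- data.frame(read_id = "r", seq = strrep("C", 14),
                      qual = strrep("I", 14), stringsAsFactors = FALSE)
  tr <- trim_reads(reads, trim_config())
  expect_equal(nrow(tr$reads), 0L)
})

test_that("poly-A tails are stripped per direct suffix scan oracle", {
  set.seed(4)
  for (i in 1:20) {
    body <- paste0(random_dna(sample(20:40, 1)), "C")  # never ends in A
    tail_len <- sample(0:12, 1)
    s <- paste0(body, strrep("A", tail_len))
    oracle <- if (tail_len >= 6) body else s
    tr <- trim_reads(data.frame(read_id = "r", seq = s,
                                qual = strrep("I", nchar(s)),
                                stringsAsFactors = FALSE),
                     trim_config(polyA_min_run = 6L))
    got <- if (nrow(tr$reads) == 1) tr$reads$seq else ""
    expect_equal(got, if (nchar(oracle) >= 15) oracle else "")
  }
})

test_that("adapter suffixes are removed at >= 90% identity over >= 8 nt", {
  ad <- "AGATCGGAAGAGC"
  body <- "ACGTACGTACGTACGTCCGT"
  reads <- data.frame(
    read_id = c("full", "partial", "none"),
    seq = c(paste0(body, ad), paste0(body, substr(ad, 1, 9)), body),
    qual = strrep("I", c(33, 29, 20)), stringsAsFactors = FALSE)
  tr <- trim_reads(reads, trim_config())
  expect_equal(tr$reads$seq, rep(body, 3))
  expect_equal(tr$log$adapter_trimmed, 2L)
})

test_that("running-sum quality trimming clips low-quality tails", {
  # 20 good bases (Q40) then 10 bad (Q2, p ~ 0.63 > 0.05)
  s <- strrep("A", 30)
  # 'I' = Q40, '#' = Q2
  q <- paste0(strrep("I", 20), strrep("#", 10))
  reads <- data.frame(read_id = "r", seq = paste0(random_dna(0), s), qual = q,
                      stringsAsFactors = FALSE)
  reads$seq <- paste0(strrep("C", 30))
  tr <- trim_reads(reads, trim_config())
  expect_equal(nchar(tr$reads$seq), 20L)
})

test_that("exact reads map uniquely with cost 0 on both strands", {
  set.seed(8)
  g <- genome_record("c", random_dna(800))
  sub <- seq_extract(g$sequence, 300L, 330L, "+")
  m <- map_reads(data.frame(read_id = c("f", "r"),
                            seq = c(sub, revcomp(sub)),
                            stringsAsFactors = FALSE), g, seed = 1)
  expect_equal(nrow(m), 2L)
  expect_equal(m$start, c(300L, 300L))
  expect_equal(m$end, c(330L, 330L))
  expect_setequal(m$strand, c("-", "+"))
  expect_equal(m$edit_cost, c(0L, 0L))
  expect_true(all(m$is_unique))
})

test_that("a read with one mismatch and one deletion costs 2 + 3 = 5", {
  set.seed(9)
  g <- genome_record("c", random_dna(600))
  locus <- seq_extract(g$sequence, 200L, 230L, "+")
  ch <- strsplit(locus, "")[[1]]
  ch[5] <- setdiff(c("A", "C", "G", "T"), ch[5])[1]   # mismatch
  read <- paste(ch[-20], collapse = "")               # deletion
  m <- map_reads(data.frame(read_id = "r", seq = read,
                            stringsAsFactors = FALSE), g, seed = 1)
  expect_equal(m$edit_cost, 5L)
  # identity 28/30 = 0.93 >= 0.8 so the placement is accepted
  expect_equal(nrow(m), 1L)
})

test_that("mapper costs agree with the exhaustive alignment oracle", {
  set.seed(10)
  g <- genome_record("c", random_dna(2000))
  for (i in 1:15) {
    s0 <- sample(0:(2000 - 40), 1)
    len <- sample(25:40, 1)
    read <- seq_extract(g$sequence, s0, s0 + len,
                        sample(c("+", "-"), 1))
    ch <- strsplit(read, "")[[1]]
    nerr <- sample(0:2, 1)
    for (e in seq_len(nerr)) {
      p <- sample(seq_along(ch), 1)
      ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1)
    }
    read <- paste(ch, collapse = "")
    m <- map_reads(data.frame(read_id = "r", seq = read,
                              stringsAsFactors = FALSE), g, seed = 1)
    if (nrow(m) == 1) {
      expect_equal(m$edit_cost, oracle_min_cost(read, g$sequence))
    }
  }
})

test_that("pileups satisfy end-count conservation and linearity", {
  g <- genome_record("c", strrep("A", 200))
  m1 <- mapped_df(10, 40, "+")
  p1 <- build_pileup(m1, g)
  expect_equal(sum(p1$plus$depth), 30L)
  expect_equal(which(p1$plus$p5 > 0) - 1L, 10L)
  expect_equal(which(p1$plus$p3 > 0) - 1L, 39L)
  # N identical reads scale all arrays by N
  mN <- mapped_df(rep(10, 7), rep(40, 7), rep("+", 7))
  pN <- build_pileup(mN, g)
  expect_equal(pN$plus$depth, 7L * p1$plus$depth)
  expect_equal(pN$plus$p5, 7L * p1$plus$p5)
  # random read set: sum(depth) == sum of read lengths, ends conserved
  set.seed(2)
  st <- sample(0:150, 50, TRUE); en <- st + sample(15:45, 50, TRUE)
  en <- pmin(en, 200L)
  str <- sample(c("+", "-"), 50, TRUE)
  p <- build_pileup(mapped_df(st, en, str), g)
  expect_equal(sum(p$plus$depth) + sum(p$minus$depth), sum(en - st))
  expect_equal(sum(p$plus$p5), sum(str == "+"))
  expect_equal(sum(p$minus$p3), sum(str == "-"))
  # minus-strand biological 5' end is at end - 1
  pm <- build_pileup(mapped_df(10, 40, "-"), g)
  expect_equal(which(pm$minus$p5 > 0) - 1L, 39L)
})

test_that("reads outside the contig are a consistency error", {
  g <- genome_record("c", strrep("A", 100))
  expect_error(build_pileup(mapped_df(90, 120, "+"), g), "outside")
})

test_that("termini calling finds the modal end and trimming hotspots", {
  g <- genome_record("c", strrep("A", 300))
  # 60 5' ends at 100, 40 at 102
  m <- mapped_df(c(rep(100, 60), rep(102, 40)),
                 c(rep(140, 60), rep(142, 40)), rep("+", 100))
  p <- build_pileup(m, g)
  tc <- call_termini(p, c(80, 160), "+", "5p", min_support = 5, window = 10)
  expect_equal(nrow(tc), 2L)
  modal <- tc[tc$is_modal, ]
  expect_equal(modal$position, 100L)
  expect_equal(modal$support, 60L)
  expect_equal(modal$local_fraction, 0.6)
  hs <- tc[tc$is_hotspot, ]
  expect_equal(hs$position, 102L)
  expect_equal(hs$local_fraction, 0.4)
  # single shared end -> one call, local fraction 1
  p2 <- build_pileup(mapped_df(rep(50, 20), rep(90, 20), rep("+", 20)), g)
  tc2 <- call_termini(p2, c(0, 300), "+", "5p")
  expect_equal(nrow(tc2), 1L)
  expect_equal(tc2$local_fraction, 1)
  # permutation invariance in read order
  o <- sample(nrow(m))
  p3 <- build_pileup(m[o, ], g)
  expect_identical(call_termini(p3, c(80, 160), "+", "5p"), tc)
})

test_that("intergenic screening respects the >= threshold and merges gaps", {
  g <- genome_record("c", strrep("A", 500))
  feats <- feature_table("gene1", "c", 0L, 100L, "+", "gene", "")
  # expressed island at depth exactly 1000 in 200..250
  m <- mapped_df(rep(200, 1000), rep(250, 1000), rep("+", 1000))
  p <- build_pileup(m, g)
  hits <- screen_intergenic(p, feats, min_coverage = 1000)
  expect_equal(nrow(hits), 1L)
  expect_equal(c(hits$start, hits$end), c(200L, 250L))
  # just below threshold -> nothing
  expect_equal(nrow(screen_intergenic(p, feats, min_coverage = 1001)), 0L)
  # no reads -> empty
  p0 <- build_pileup(mapped_df(integer(0), integer(0), character(0)), g)
  expect_equal(nrow(screen_intergenic(p0, feats, min_coverage = 1)), 0L)
})
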