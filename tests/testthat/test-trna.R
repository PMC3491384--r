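test_that("clamp extraction trims at the T-stretch terminator", {
  set.seed(2)
  body5 <- paste0("G", random_dna(35))
  g <- genome_record("c", paste0(random_dna(100), body5, "GGGCGCCC",
                                 "TTTTT", random_dna(100)))
  h <- feature_table("h5", "c", 100L, 136L, "+", "tRNA_half",
                     "half_side=five_prime")
  hc <- extract_clamps(h, g)
  expect_equal(hc$clamp_seq, "GGGCGCCC")
  expect_false(hc$low_gc)
  expect_equal(hc$clamp_start, 136L)
  expect_equal(hc$clamp_end, 144L)
})

test_that("an A/T-rich clamp region is extracted but flagged low-GC", {
  g <- genome_record("c", paste0(strrep("C", 100), strrep("G", 36),
                                 "ATATATAA", "TTTTT", strrep("C", 100)))
  h <- feature_table("h5", "c", 100L, 136L, "+", "tRNA_half",
                     "half_side=five_prime")
  hc <- extract_clamps(h, g)
  expect_equal(hc$clamp_seq, "ATATATAA")
  expect_true(hc$low_gc)
})

test_that("3' half clamps come from upstream and respect strand", {
  clamp <- "GGCGCAGCCGCG"
  body3 <- paste0(random_dna(0), strrep("C", 40))
  tx <- paste0("TTTTT", revcomp(clamp), body3, "TTTTTT")
  set.seed(6)
  pad <- random_dna(80)
  # plus placement
  gp <- genome_record("c", paste0(pad, tx, pad))
  hp <- feature_table("h3", "c", 80L + 5L + 12L, 80L + 5L + 12L + 40L, "+",
                      "tRNA_half", "half_side=three_prime")
  expect_equal(extract_clamps(hp, gp)$clamp_seq, revcomp(clamp))
  # minus placement: same transcript, reverse-complemented genome segment
  gm <- genome_record("c", paste0(pad, revcomp(tx), pad))
  W <- nchar(tx)
  hm <- feature_table("h3", "c", 80L + W - (5L + 12L + 40L),
                      80L + W - (5L + 12L), "-",
                      "tRNA_half", "half_side=three_prime")
  expect_equal(extract_clamps(hm, gm)$clamp_seq, revcomp(clamp))
})

test_that("a perfect 12-mer complement scores duplex 12", {
  d <- nanosmallrna:::clamp_duplex("GGCGCAGCCGCA", revcomp("GGCGCAGCCGCA"))
  expect_equal(d$len, 12L)
  expect_equal(d$score, 12)
})

test_that("G/U pairs count at the configured wobble weight", {
  # clamp GGGGGG vs TTTTTT pairs only as G/U wobble
  d <- nanosmallrna:::clamp_duplex("GGGGGG", "GGGGGG", gu_weight = 0.5)
  # revcomp pairing view: G against reversed G cannot pair; use explicit T
  d2 <- nanosmallrna:::clamp_duplex("GGGGGG", "TTTTTT", gu_weight = 0.5)
  expect_equal(d2$len, 6L)
  expect_equal(d2$score, 3)
  expect_equal(d$score, 0)
})

test_that("bitmask matching equals brute-force enumeration on <= 6x6", {
  set.seed(12)
  for (i in 1:25) {
    nr <- sample(2:6, 1); nc <- sample(2:6, 1)
    w <- matrix(sample(c(-1, -1, 2:12), nr * nc, TRUE), nr, nc)
    got <- nanosmallrna:::match_bipartite(w)$score
    expect_equal(got, oracle_best_matching(w))
  }
})

test_that("planted pairs with distinct clamps are recovered exactly", {
  run <- flagship_run()
  pairs <- run$res$trna_pairs
  truth <- run$gen$truth$trna_pairs
  expect_equal(nrow(pairs), nrow(truth))
  got <- pairs[order(pairs$five_id), c("five_id", "three_id")]
  want <- truth[order(truth$five_id), c("five_id", "three_id")]
  expect_equal(got$three_id, want$three_id)
  expect_false(any(pairs$ambiguous))
  expect_true(all(pairs$duplex_len >= 8L))
  # each half used at most once
  expect_false(any(duplicated(pairs$five_id)))
  expect_false(any(duplicated(pairs$three_id)))
})

test_that("mature assembly concatenates bodies and records the junction", {
  run <- flagship_run()
  pairs <- run$res$trna_pairs
  truth <- run$gen$truth$trna_pairs
  m <- merge(pairs, truth, by = "five_id", suffixes = c("", ".t"))
  expect_equal(m$mature_seq, m$mature_seq.t)
  expect_equal(unique(m$junction), 36L)
  expect_true(all(m$mature_len >= 70 & m$mature_len <= 100))
  # mature sequence re-locates to the two planted body intervals
  g <- run$gen$genome$sequence
  feats <- run$gen$features
  for (i in seq_len(nrow(m))) {
    f5 <- feats[feats$feature_id == m$five_id[i], ]
    b5 <- seq_extract(g, f5$start, f5$end, f5$strand)
    expect_equal(substr(m$mature_seq[i], 1, m$junction[i]), b5)
  }
})

test_that("degenerate assembly inputs error", {
  g <- genome_record("c", strrep("A", 100))
  f5 <- feature_table("a", "c", 0L, 36L, "+", "tRNA_half", "")
  f3 <- f5; f3$start <- 50L; f3$end <- 50L + 40L
  f3bad <- f3; f3bad$end <- f3bad$start  # empty body
  expect_error(feature_table("b", "c", 50L, 50L, "+", "tRNA_half", ""),
               "invalid interval")
  expect_silent(assemble_mature(f5[1, ], f3[1, ], g))
})

test_that("precursor termini report the planted +2/+1/-1 offsets", {
  run <- flagship_run()
  tt <- run$res$trna_termini
  truth <- run$gen$truth$trna_pairs
  t3 <- tt[tt$half_side == "three_prime", ]
  t3 <- t3[order(t3$feature_id), ]
  want <- truth[order(truth$three_id), ]
  expect_equal(t3$offset3, want$offset3)
  # 5' precursor ends are exact and start on a purine (bodies start with G)
  t5 <- tt[tt$half_side == "five_prime", ]
  expect_true(all(t5$offset5 == 0L))
  expect_true(all(t5$purine_start))
  # 3' ends are less defined than 5' ends on the default simulation
  expect_true(mean(tt$dispersion3, na.rm = TRUE) >=
                mean(tt$dispersion5, na.rm = TRUE))
})

test_that("leaderless report flags purine starts and the G-1 extension", {
  g <- genome_record("c", paste0(strrep("C", 99), "G",
                                 "C", strrep("A", 75), strrep("C", 125)))
  trna <- feature_table("tyr", "c", 100L, 176L, "+", "tRNA", "")
  # 90 reads with the templated G-1, 10 exactly at the start
  m <- mapped_df(c(rep(99, 90), rep(100, 10)), rep(176, 100),
                 rep("+", 100))
  rep_ <- leaderless_report(trna, build_pileup(m, g), g)
  expect_equal(rep_$mature_start_fraction, 0.1)
  expect_equal(rep_$minus1_fraction, 0.9)
  expect_equal(rep_$minus1_base, "G")
  expect_equal(rep_$start_base, "C")
  expect_false(rep_$purine_start)
  # all reads at the start -> fraction 1, purine start
  g2 <- genome_record("c", paste0(strrep("C", 100), "A",
                                  strrep("G", 75), strrep("C", 124)))
  m2 <- mapped_df(rep(100, 50), rep(176, 50), rep("+", 50))
  rep2 <- leaderless_report(feature_table("t", "c", 100L, 176L, "+",
                                          "tRNA", ""),
                            build_pileup(m2, g2), g2)
  expect_equal(rep2$mature_start_fraction, 1)
  expect_true(rep2$purine_start)
})
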