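test_that("box matchers equal the per-position loop oracle", {
  set.seed(3)
  s <- random_dna(2000)
  ch <- strsplit(s, "")[[1]]
  for (mm in 0:2) {
    expect_equal(nanosmallrna:::boxC_matches(ch, mm),
                 oracle_box_matches(s, "RTGATGA", 3:5, mm))
  }
  for (mm in 0:1) {
    expect_equal(nanosmallrna:::boxD_matches(ch, mm),
                 oracle_box_matches(s, "CTGA", integer(0), mm))
  }
})

test_that("the structure scanner equals brute-force enumeration", {
  set.seed(14)
  for (i in 1:4) {
    s <- random_dna(5000)
    got <- sort(vapply(nanosmallrna:::scan_cd_seq(s, cd_params()),
                       cd_candidate_key, character(1)))
    want <- sort(vapply(oracle_scan_cd_seq(s, cd_params()),
                        cd_candidate_key, character(1)))
    expect_equal(got, want)
  }
})

test_that("planted canonical and permuted loci are found at their intervals", {
  run <- flagship_run()
  cds <- run$res$cd_srnas
  truth <- run$gen$truth$cd
  m <- merge(truth, cds, by = c("start", "end", "strand"),
             suffixes = c(".t", ".d"))
  expect_equal(nrow(m), nrow(truth))
  perm <- m$arrangement.t == "permuted"
  expect_equal(m$arrangement.d[!perm],
               m$arrangement.t[!perm])
  expect_true(all(m$arrangement.d[perm] %in%
                    c("permuted", "circular_permuted")))
})

test_that("terminal pairing distinguishes open ends from a stem", {
  # designed 5-bp terminal stem
  stem <- "GCGCA"
  s <- paste0(stem, random_dna(30), revcomp(stem))
  expect_gte(check_terminal_pairing(s), 5L)
  # planted sRNAs have unpaired ends (<= 1)
  run <- flagship_run()
  expect_true(all(run$res$cd_srnas$terminal_pairing <= 1L))
})

test_that("junction reads flag circular sRNAs; linear loci stay linear", {
  set.seed(33)
  g <- genome_record("c", random_dna(600))
  locus <- list(start = 200L, end = 260L, strand = "+")
  S <- seq_extract(g$sequence, 200L, 260L, "+")
  doubled <- paste0(S, S)
  jr <- vapply(1:50, function(i) {
    left <- sample(12:28, 1)
    substr(doubled, 60L - left + 1L, 60L - left + 40L)
  }, character(1))
  reads <- data.frame(read_id = sprintf("j%02d", 1:50), seq = jr,
                      stringsAsFactors = FALSE)
  circ <- detect_circular(locus, reads, g)
  expect_equal(circ$junction_read_support, 50L)
  expect_true(circ$circular)
  expect_equal(circ$circle_len, 60L)
  # linear reads from the same locus give no junction support
  lin <- data.frame(read_id = "l1", seq = substr(S, 5, 50),
                    stringsAsFactors = FALSE)
  expect_equal(detect_circular(locus, lin, g)$junction_read_support, 0L)
  expect_false(detect_circular(locus, lin, g)$circular)
})

test_that("circular permuted loci restore the C-before-D reading", {
  run <- flagship_run()
  cds <- run$res$cd_srnas
  cp <- cds[cds$arrangement == "circular_permuted", ]
  expect_equal(nrow(cp), 1L)
  expect_gte(cp$junction_read_support, 5L)
  # reading around the circle from box C reaches box D without wrapping
  # again: in the linear (permuted) locus C lies 3' of D, so the circular
  # reading C -> (wrap) -> D restores the canonical order
  expect_gt(cp$boxC_start, cp$boxD_start)
})

test_that("context classification follows the priority rules", {
  feats <- feature_table(
    feature_id = c("tval", "intron", "split1", "geneX"),
    contig_id = "c",
    start = c(1000L, 2000L, 3000L, 5000L),
    end = c(1072L, 2066L, 3600L, 5700L),
    strand = c("+", "+", "+", "+"),
    kind = c("tRNA", "other", "gene", "gene"),
    attrs = c("", "feature_class=tRNA_intron", "split_part=N_terminal", ""))
  srnas <- data.frame(
    start = c(1074L, 2005L, 3650L, 5100L, 8000L),
    end = c(1130L, 2060L, 3706L, 5156L, 8056L),
    strand = "+", stringsAsFactors = FALSE)
  expect_equal(classify_context(srnas, feats),
               c("tRNA_dicistronic", "tRNA_intronic", "split_gene_flank",
                 "mRNA_overlap", "standalone"))
  # flagship planted contexts all recovered
  run <- flagship_run()
  m <- merge(run$gen$truth$cd, run$res$cd_srnas,
             by = c("start", "end", "strand"), suffixes = c(".t", ".d"))
  expect_equal(m$context.d, m$context.t)
})

test_that("the D+5 rule gives the hand-computed methylation target", {
  guide <- "TACGGATCCGTA"                 # 12 nt, guide for box D
  target <- paste0(strrep("A", 99), revcomp(guide), strrep("A", 100))
  srnas <- data.frame(srna_id = "s1", guideD_seq = guide,
                      guideDp_seq = strrep("A", 3),
                      stringsAsFactors = FALSE)
  pred <- predict_2ome_targets(srnas, c(r = target))
  pred <- pred[pred$duplex_len == 12L, ]
  # guide aligned antisense over target 100..111; the D+5 base (guide
  # position 8 of 12) pairs target position 99 + (12 - 8) + 1 = 104
  expect_equal(pred$target_position, 104L)
  expect_equal(pred$guide_source, "D")
  # short guide region is skipped and flagged
  expect_true("s1:Dp" %in% attr(pred, "skipped") ||
                "s1:Dp" %in% attr(predict_2ome_targets(srnas,
                                                       c(r = target)),
                                  "skipped"))
  # no duplex >= 10 anywhere -> empty
  none <- predict_2ome_targets(
    data.frame(srna_id = "s", guideD_seq = strrep("A", 12),
               guideDp_seq = strrep("A", 12), stringsAsFactors = FALSE),
    c(r = strrep("A", 200)))
  expect_equal(nrow(none), 0L)
})

test_that("guide extraction and target prediction are strand-symmetric", {
  run <- flagship_run()
  gen <- run$gen
  cds <- run$res$cd_srnas
  truth <- gen$truth$cd
  # guides of a minus-strand locus are read in transcript orientation and
  # equal the planted guides exactly
  m <- merge(truth, cds, by = c("start", "end", "strand"),
             suffixes = c(".t", ".d"))
  minus <- m[m$strand == "-", ]
  expect_gte(nrow(minus), 1L)
  expect_equal(minus$guideD_seq, minus$guideD)
  expect_equal(minus$guideDp_seq, minus$guideDp)
  # re-planting the same locus on the plus strand predicts the same targets
  plus_locus <- truth[truth$id == "cd_standalone2", ]
  g2 <- genome_record("flip", paste0(
    strrep("A", 100),
    seq_extract(gen$genome$sequence, plus_locus$start, plus_locus$end, "-"),
    strrep("A", 100)))
  cd2 <- scan_cd(g2)
  expect_equal(nrow(cd2), 1L)
  expect_equal(cd2$strand, "+")
  orig <- cds[cds$start == plus_locus$start &
                cds$strand == plus_locus$strand, ]
  p_orig <- predict_2ome_targets(orig, gen$rrnas)
  p_flip <- predict_2ome_targets(cd2, gen$rrnas)
  cols <- c("guide_source", "target_rna", "target_position", "duplex_len")
  expect_equal(p_flip[, cols], p_orig[, cols], ignore_attr = TRUE)
})

test_that("the Nussinov folder matches independent maximisation", {
  set.seed(41)
  for (i in 1:12) {
    s <- random_dna(sample(20:40, 1))
    expect_equal(nussinov_fold(s)$n_pairs, oracle_max_pairs(s),
                 info = s)
  }
  # a simple designed hairpin pairs its full stem
  expect_equal(nussinov_fold("GGGGAAAACCCC")$n_pairs, 4L)
})

test_that("H/ACA discovery requires two hairpins and reads the hinge", {
  run <- flagship_run()
  hs <- run$res$hacas
  expect_length(hs, 1L)
  h <- hs[[1]]
  expect_equal(h$h_domain_status, "ACA_only")
  expect_true(all(h$kturn_flags))
  expect_true(h$terminal_ACA)
  expect_length(h$hairpins, 2L)
  # planted locus recovered to within the coverage-trimmed bounds
  expect_lte(abs(h$start - run$gen$truth$haca$start), 3L)
  expect_lte(abs(h$end - run$gen$truth$haca$end), 3L)
  # a single-hairpin RNA is rejected
  set.seed(44)
  stem <- strrep("G", 10)
  single <- paste0("AAA", stem, strrep("A", 6), revcomp(stem), "ACA",
                   strrep("A", 30))
  g <- genome_record("c", paste0(random_dna(100), single, random_dna(100)))
  none <- find_haca(data.frame(start = 100L, end = 100L + nchar(single),
                               strand = "+"), g)
  expect_length(none, 0L)
})

test_that("pseudouridine predictions obey the pocket distance rule", {
  run <- flagship_run()
  psi <- run$res$targets[run$res$targets$modification == "pseudouridine", ]
  expect_gte(nrow(psi), 1L)
  expect_true(all(psi$target_position ==
                    run$gen$truth$rrna_targets$target_position[2]))
  h <- run$res$hacas[[1]]
  # hairpin with a pocket too far from its ACA yields nothing
  h2 <- h
  h2$hairpins <- lapply(h$hairpins, function(hp) {
    hp$pocket_to_aca <- 25L
    hp
  })
  expect_equal(nrow(predict_psi_targets(h2, run$gen$rrnas)), 0L)
  # empty rRNA set -> empty
  expect_equal(nrow(predict_psi_targets(h, character(0))), 0L)
})
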