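test_that("genome generation is deterministic and plants 41 spacers", {
  sc <- scenario(seed = 5L)
  g1 <- generate_genome(sc)
  g2 <- generate_genome(sc)
  expect_identical(g1$genome$sequence, g2$genome$sequence)
  expect_identical(g1$features, g2$features)
  expect_equal(sum(vapply(g1$truth$arrays,
                          function(a) nrow(a$spacers), integer(1))), 41L)
  # FASTA bytes identical across runs of write_scenario
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  s1 <- write_scenario(scenario(seed = 6L, read_depth = 5L,
                                srna_depth_factor = 0.2,
                                haca_depth_factor = 0.2), d1)
  s2 <- write_scenario(scenario(seed = 6L, read_depth = 5L,
                                srna_depth_factor = 0.2,
                                haca_depth_factor = 0.2), d2)
  expect_identical(readLines(s1$paths$genome), readLines(s2$paths$genome))
  expect_identical(readLines(s1$paths$reads), readLines(s2$paths$reads))
})

test_that("planted truth intervals lie within the genome", {
  gen <- generate_genome(scenario(seed = 5L))
  f <- gen$features
  expect_true(all(f$start >= 0 & f$end <= gen$genome$length))
  expect_true(all(f$start < f$end))
  expect_true(all(gen$truth$cd$end <= gen$genome$length))
  # repeat carries the tag, leaders identical for exactly 130 nt
  expect_true(endsWith(gen$truth$repeat_seq, "ATTGAAAG"))
})

test_that("without trimming or errors all crRNA 5' ends sit at the tag", {
  sc <- scenario(seed = 9L, error_rate = 0, trim_geometric_p = 0.999,
                 trim_hotspot_prob = 0, read_depth = 20L,
                 srna_depth_factor = 0, haca_depth_factor = 0,
                 trna_depth_factor = 0)
  gen <- generate_genome(sc)
  sim <- simulate_reads(gen$genome, gen$truth, sc)
  cr <- sim$reads[grepl("^crRNA", sim$reads$read_id), ]
  expect_gt(nrow(cr), 100L)
  expect_true(all(startsWith(cr$seq, "ATTGAAAG")))
})

test_that("crRNA counts follow the planted geometric abundance decay", {
  sc <- reduced_scenario(21L)
  gen <- generate_genome(sc)
  sim <- simulate_reads(gen$genome, gen$truth, sc)
  cr <- sim$counts[sim$counts$class == "crRNA", ]
  ord <- cr[grepl("^crRNA_a1", cr$transcript_id), ]
  lam <- sc$read_depth * sc$abundance_decay^(seq_len(nrow(ord)) - 1L)
  z <- abs(ord$n_reads - lam) / sqrt(lam)
  expect_true(mean(z <= 3) >= 0.95)
})

test_that("RT drop-off leaves mature tRNAs under-represented", {
  sc <- scenario(seed = 13L, read_depth = 50L, rt_dropoff = 0.01)
  gen <- generate_genome(sc)
  sim <- simulate_reads(gen$genome, gen$truth, sc)
  cnt <- sim$counts
  mean_trna <- mean(cnt$n_reads[cnt$class == "tRNA"])
  mean_srna <- mean(cnt$n_reads[cnt$class == "CD_sRNA"])
  expect_lt(mean_trna, mean_srna)
})

test_that("zero-depth scenarios yield an empty but valid library", {
  sc <- scenario(seed = 3L, read_depth = 0L, srna_depth_factor = 0,
                 haca_depth_factor = 0, trna_depth_factor = 0)
  gen <- generate_genome(sc)
  sim <- simulate_reads(gen$genome, gen$truth, sc)
  # only background mRNA fragments remain; crRNA counts are all zero
  expect_true(all(sim$counts$n_reads[sim$counts$class == "crRNA"] == 0L))
})
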