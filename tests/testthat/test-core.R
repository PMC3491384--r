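test_that("FASTA reading normalises case and U/T and preserves order", {
  tf <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">x", "acgt", ">y desc", "ACGU", ">z", "GGGG"), tf)
  recs <- read_fasta(tf)
  expect_equal(vapply(recs, `[[`, "", "contig_id"), c("x", "y", "z"))
  expect_equal(recs[[1]]$sequence, "ACGT")
  expect_equal(recs[[2]]$sequence, "ACGT")   # U transliterated
  expect_equal(recs[[1]]$length, 4L)
})

test_that("FASTA errors name the problem", {
  tf <- withr::local_tempfile(fileext = ".fa")
  writeLines(character(0), tf)
  expect_error(read_fasta(tf), "empty")
  writeLines(c(">x", "ACGT", ">y", "ACXT"), tf)
  expect_error(read_fasta(tf), "line 4")
})

test_that("FASTA round trip preserves sequences", {
  g <- genome_record("contig1", "ACGTACGTAA")
  tf <- withr::local_tempfile(fileext = ".fa")
  write_fasta(g, tf)
  back <- read_fasta(tf)[[1]]
  expect_equal(back$sequence, g$sequence)
  expect_equal(back$contig_id, g$contig_id)
})

test_that("GFF3 import shifts to 0-based half-open and maps kinds", {
  tf <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "c\tsrc\ttRNA\t1\t10\t.\t+\t.\tID=t1",
               "c\tsrc\tsnoRNA\t21\t40\t.\t-\t.\tID=s1"), tf)
  f <- read_gff3(tf)
  expect_equal(f$start, c(0L, 20L))
  expect_equal(f$end, c(10L, 40L))
  expect_equal(f$kind, c("tRNA", "other"))
  expect_equal(attr_get(f$attrs[2], "gff_type"), "snoRNA")
})

test_that("GFF3 write -> read round trip preserves all fields", {
  set.seed(1)
  n <- 12L
  starts <- sort(sample(0:5000, n))
  f <- feature_table(
    feature_id = sprintf("f%02d", 1:n), contig_id = "c",
    start = starts, end = starts + sample(20:400, n, TRUE),
    strand = sample(c("+", "-"), n, TRUE),
    kind = sample(c("gene", "tRNA", "tRNA_half", "CD_sRNA", "HACA_sRNA",
                    "rRNA", "leader"), n, TRUE),
    attrs = ifelse(seq_len(n) %% 2 == 0,
                   "half_side=five_prime;note=x", ""))
  tf <- withr::local_tempfile(fileext = ".gff3")
  write_gff3(f, tf, contigs = genome_record("c", strrep("A", 6000)))
  back <- read_gff3(tf)
  expect_equal(back$feature_id, f$feature_id)
  expect_equal(back$start, f$start)
  expect_equal(back$end, f$end)
  expect_equal(back$strand, f$strand)
  expect_equal(back$kind, f$kind)
  expect_equal(nanosmallrna:::attrs_canonical(back$attrs),
               nanosmallrna:::attrs_canonical(f$attrs))
})

test_that("report writing is deterministic and cross-checks row counts", {
  run <- reduced_run()
  out1 <- withr::local_tempdir()
  out2 <- withr::local_tempdir()
  tabs <- nanosmallrna:::run_report_tables(run$res)
  write_reports(tabs, out1)
  write_reports(tabs, out2)
  for (fn in list.files(out1)) {
    expect_identical(readLines(file.path(out1, fn)),
                     readLines(file.path(out2, fn)), info = fn)
  }
  sp <- utils::read.delim(file.path(out1, "spacers.tsv"))
  expect_equal(nrow(sp),
               sum(vapply(run$res$arrays,
                          function(a) nrow(a$spacers), integer(1))))
})

test_that("empty results still give valid headers-only reports", {
  out <- withr::local_tempdir()
  write_reports(list(), out)
  sp <- utils::read.delim(file.path(out, "spacers.tsv"))
  expect_equal(nrow(sp), 0L)
  expect_true("relative_abundance" %in% colnames(sp))
  gff <- readLines(file.path(out, "features.gff3"))
  expect_equal(gff, "##gff-version 3")
})

test_that("intergenic complement covers the contig minus features", {
  f <- feature_table(c("a", "b"), "c", c(100L, 400L), c(200L, 600L),
                     c("+", "-"), c("gene", "gene"), c("", ""))
  iv <- intergenic_intervals(f, 1000L)
  expect_equal(iv$start, c(0L, 200L, 600L))
  expect_equal(iv$end, c(100L, 400L, 1000L))
})
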