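# Shared fixtures.  The flagship run (default scenario, seed 42) is built
# once and cached for the session; reduced runs keep the cheaper tests fast.

.fixture_cache <- new.env(parent = emptyenv())

flagship_run <- function() {
  if (is.null(.fixture_cache$flagship)) {
    sc <- scenario(seed = 42L)
    gen <- generate_genome(sc)
    sim <- simulate_reads(gen$genome, gen$truth, sc)
    res <- run_all(list(seed = 42L), genome = gen$genome,
                   features = gen$features, reads = sim$reads,
                   rrnas = gen$rrnas)
    .fixture_cache$flagship <- list(sc = sc, gen = gen, sim = sim, res = res)
  }
  .fixture_cache$flagship
}

# small scenario for pipeline-level tests: crRNA decay plus a skeleton of
# the other feature classes, error-free reads so mapping stays exact
reduced_scenario <- function(seed) {
  scenario(seed = seed, genome_length = 1000L, read_depth = 50L,
           n_trna_pairs = 3L, srna_depth_factor = 0.3,
           haca_depth_factor = 0, trna_depth_factor = 0,
           error_rate = 0)
}

reduced_run <- function() {
  if (is.null(.fixture_cache$reduced)) {
    sc <- reduced_scenario(11L)
    gen <- generate_genome(sc)
    sim <- simulate_reads(gen$genome, gen$truth, sc)
    res <- run_all(list(seed = 11L,
                        intergenic = list(min_coverage = 40L)),
                   genome = gen$genome, features = gen$features,
                   reads = sim$reads, rrnas = gen$rrnas)
    .fixture_cache$reduced <- list(sc = sc, gen = gen, sim = sim, res = res)
  }
  .fixture_cache$reduced
}

# hand-made mapped-read table (bypasses the mapper) for pileup-level tests
mapped_df <- function(start, end, strand, contig = "c") {
  n <- length(start)
  data.frame(read_id = sprintf("r%04d", seq_len(n)),
             contig_id = rep(contig, n), start = as.integer(start),
             end = as.integer(end), strand = as.character(strand),
             edit_cost = rep(0L, n), is_unique = rep(TRUE, n),
             n_best = rep(1L, n), stringsAsFactors = FALSE)
}
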