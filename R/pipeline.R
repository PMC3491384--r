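#' Default pipeline configuration
#'
#' Nested list of paths, stage toggles and per-module parameter blocks.
#' All parameters are range-checked by [validate_config()].
#'
#' @return a `run_config` list.
#' @export
default_config <- function() {
  structure(list(
    paths = list(genome = NULL, gff = NULL, reads = NULL, rrna = NULL,
                 out_dir = NULL),
    seed = 1L,
    stages = list(trim = TRUE, map = TRUE, crispr = TRUE, trna = TRUE,
                  srna = TRUE),
    trim = list(quality_error_limit = 0.05, min_length = 15L,
                polyA_min_run = 6L),
    map = list(mismatch_cost = 2L, insertion_cost = 3L, deletion_cost = 3L,
               length_fraction = 0.5, similarity = 0.8,
               multimap_policy = "random_best_seeded", seed_len = 12L),
    termini = list(min_support = 5L, window = 10L, hotspot_fraction = 0.10),
    intergenic = list(min_coverage = 1000L, merge_gap = 10L),
    crispr = list(leader_max_len = 500L),
    trna = list(flank_len = 40L, min_duplex_len = 8L, gu_weight = 0.5),
    cd = list(min_junction_each = 12L, min_junction_support = 5L),
    haca = list(min_hairpin = 25L, min_pairs = 8L)
  ), class = "run_config")
}

#' Validate and normalise a pipeline configuration
#'
#' Missing entries are filled from [default_config()]; every parameter is
#' range-checked.  Normalisation is idempotent.
#'
#' @param config partial or full configuration list.
#' @return the normalised `run_config`, or an error listing each violated
#'   parameter with its bound.
#' @export
validate_config <- function(config = list()) {
  cfg <- utils::modifyList(default_config(), config, keep.null = TRUE)
  errs <- character(0)
  chk <- function(val, ok, what, bound) {
    if (!isTRUE(ok)) errs <<- c(errs, sprintf("%s=%s violates %s",
                                              what, format(val), bound))
  }
  chk(cfg$trim$quality_error_limit,
      cfg$trim$quality_error_limit > 0 && cfg$trim$quality_error_limit < 1,
      "trim.quality_error_limit", "(0,1)")
  chk(cfg$trim$min_length, cfg$trim$min_length >= 1,
      "trim.min_length", ">=1")
  chk(cfg$map$similarity,
      cfg$map$similarity > 0 && cfg$map$similarity <= 1,
      "map.similarity", "(0,1]")
  chk(cfg$map$length_fraction,
      cfg$map$length_fraction > 0 && cfg$map$length_fraction <= 1,
      "map.length_fraction", "(0,1]")
  for (p in c("mismatch_cost", "insertion_cost", "deletion_cost")) {
    chk(cfg$map[[p]], cfg$map[[p]] > 0, paste0("map.", p), ">0")
  }
  chk(cfg$termini$hotspot_fraction,
      cfg$termini$hotspot_fraction >= 0 && cfg$termini$hotspot_fraction <= 1,
      "termini.hotspot_fraction", "[0,1]")
  chk(cfg$intergenic$min_coverage, cfg$intergenic$min_coverage >= 1,
      "intergenic.min_coverage", ">=1")
  chk(cfg$trna$gu_weight,
      cfg$trna$gu_weight >= 0 && cfg$trna$gu_weight <= 1,
      "trna.gu_weight", "[0,1]")
  chk(cfg$seed, is.numeric(cfg$seed) && cfg$seed == round(cfg$seed),
      "seed", "integer")
  if (length(errs) > 0) {
    stop_fmt("invalid configuration:\n  %s", paste(errs, collapse = "\n  "))
  }
  cfg
}

#' Run the full small-RNA analysis pipeline
#'
#' Stages run in dependency order: trim, map, pileup, then CRISPR / tRNA /
#' sRNA inference, then reports.  Coverage-dependent stages are skipped
#' (with explicit `NULL` summary fields) when no reads are given; the tRNA
#' stage is skipped with a warning when the annotation carries no tRNA half
#' genes.
#'
#' @param config a (partial) configuration for [validate_config()]; paths
#'   may also be passed directly via the arguments below, which override
#'   the config.
#' @param genome,features,reads,rrnas optional in-memory inputs (a
#'   [genome_record()], feature table, reads data.frame, named rRNA
#'   vector), used instead of reading from the configured paths.
#' @return a `nanosmallrna_run` list of stage results and a `summary` list
#'   (the machine-readable account of the run); reports are written when
#'   `paths$out_dir` is configured.
#' @export
run_all <- function(config = list(), genome = NULL, features = NULL,
                    reads = NULL, rrnas = NULL) {
  cfg <- validate_config(config)
  res <- list(config = cfg)
  summary <- list(seed = cfg$seed)

  if (is.null(genome)) {
    if (is.null(cfg$paths$genome)) stop_fmt("no genome given")
    genome <- read_fasta(cfg$paths$genome)[[1]]
  }
  if (is.null(features) && !is.null(cfg$paths$gff)) {
    features <- read_gff3(cfg$paths$gff)
  }
  if (is.null(reads) && !is.null(cfg$paths$reads)) {
    reads <- read_fastq(cfg$paths$reads)
  }
  if (is.null(rrnas) && !is.null(cfg$paths$rrna)) {
    rr <- read_fasta(cfg$paths$rrna)
    rrnas <- stats::setNames(vapply(rr, `[[`, character(1), "sequence"),
                             vapply(rr, `[[`, character(1), "contig_id"))
  }
  res$genome <- genome
  res$features <- features

  # --- reads: trim, map, pileup ------------------------------------------
  pileup <- NULL
  mapped <- NULL
  if (!is.null(reads)) {
    summary$reads_input <- nrow(reads)
    if (cfg$stages$trim) {
      tr <- trim_reads(reads, trim_config(
        quality_error_limit = cfg$trim$quality_error_limit,
        min_length = cfg$trim$min_length,
        polyA_min_run = cfg$trim$polyA_min_run))
      reads <- tr$reads
      summary$reads_discarded_short <- tr$log$discarded_short
    }
    mc <- map_config(mismatch_cost = cfg$map$mismatch_cost,
                     insertion_cost = cfg$map$insertion_cost,
                     deletion_cost = cfg$map$deletion_cost,
                     length_fraction = cfg$map$length_fraction,
                     similarity = cfg$map$similarity,
                     multimap_policy = cfg$map$multimap_policy,
                     seed_len = cfg$map$seed_len)
    mapped <- map_reads(reads, genome, mc, seed = cfg$seed)
    summary$reads_mapped <- nrow(mapped)
    pileup <- build_pileup(mapped, genome)
    res$mapped <- mapped
    res$pileup <- pileup
  } else {
    summary$reads_input <- NULL
    summary$reads_mapped <- NULL
  }

  tp <- cfg$termini

  # --- CRISPR stage -------------------------------------------------------
  if (cfg$stages$crispr) {
    arrays <- detect_arrays(genome)
    arrays <- lapply(arrays, orient_array, pileup = pileup, genome = genome)
    res$arrays <- arrays
    summary$n_arrays <- length(arrays)
    spacers <- NULL
    leader <- NULL
    tss_boxa <- list()
    if (length(arrays) > 0 && !is.null(pileup)) {
      spacers <- do.call(rbind, lapply(arrays, infer_maturation,
                                       pileup = pileup,
                                       min_support = tp$min_support,
                                       window = tp$window,
                                       hotspot_fraction = tp$hotspot_fraction))
      for (a in arrays) {
        tss <- call_tss(a, pileup, genome)
        boxa <- if (!is.na(tss$tss_position)) {
          find_boxA(genome, tss$tss_position, a$strand)
        } else list(found = FALSE)
        tss_boxa[[a$array_id]] <- list(tss = tss, boxA = boxa)
      }
    }
    if (length(arrays) >= 2) {
      leader <- compare_leaders(arrays[[1]], arrays[[2]], genome,
                                max_len = cfg$crispr$leader_max_len)
    }
    res$spacers <- spacers
    res$leader <- leader
    res$tss_boxa <- tss_boxa
    summary$n_spacers <- if (is.null(spacers)) {
      sum(vapply(arrays, function(a) nrow(a$spacers), integer(1)))
    } else nrow(spacers)
    summary$leader_identity <- if (is.null(leader)) NULL else
      leader$identical_prefix_length
    summary$tss <- if (length(tss_boxa) == 0) NULL else
      lapply(tss_boxa, function(x) list(
        position = x$tss$tss_position, base = x$tss$tss_base,
        offset = x$tss$tss_offset_to_first_repeat,
        boxA_found = isTRUE(x$boxA$found),
        boxA_distance = if (isTRUE(x$boxA$found)) x$boxA$distance else NULL))
  } else {
    summary$n_arrays <- NULL
  }

  # --- tRNA stage ---------------------------------------------------------
  halves_ok <- !is.null(features) && any(features$kind == "tRNA_half")
  if (cfg$stages$trna && halves_ok) {
    halves <- extract_clamps(
      features[features$kind == "tRNA_half", , drop = FALSE], genome,
      flank_len = cfg$trna$flank_len)
    pairs <- pair_halves(halves, genome,
                         min_duplex_len = cfg$trna$min_duplex_len,
                         gu_weight = cfg$trna$gu_weight)
    res$trna_halves <- halves
    res$trna_pairs <- pairs
    summary$n_trna_pairs <- nrow(pairs)
    if (!is.null(pileup)) {
      res$trna_termini <- annotate_precursor_termini(
        halves, pileup, genome, min_support = tp$min_support)
      trna_genes <- features[features$kind == "tRNA", , drop = FALSE]
      if (nrow(trna_genes) > 0) {
        res$leaderless <- leaderless_report(trna_genes, pileup, genome)
      }
    }
  } else {
    if (cfg$stages$trna && !halves_ok) {
      warn_fmt("tRNA stage skipped: no tRNA_half annotations")
    }
    summary$n_trna_pairs <- NULL
  }

  # --- sRNA stage ---------------------------------------------------------
  if (cfg$stages$srna) {
    cds <- scan_cd(genome)
    if (nrow(cds) > 0) {
      if (!is.null(features)) {
        cds$context <- classify_context(cds, features)
      }
      cds$terminal_pairing <- vapply(seq_len(nrow(cds)), function(i) {
        check_terminal_pairing(seq_extract(genome$sequence, cds$start[i],
                                           cds$end[i], cds$strand[i]))
      }, integer(1))
      cds$junction_read_support <- NA_integer_
      cds$circular <- NA
      if (!is.null(reads)) {
        for (i in seq_len(nrow(cds))) {
          circ <- detect_circular(cds[i, ], reads, genome,
                                  min_each = cfg$cd$min_junction_each,
                                  min_support = cfg$cd$min_junction_support)
          cds$junction_read_support[i] <- circ$junction_read_support
          cds$circular[i] <- circ$circular
        }
        cds$arrangement[cds$arrangement == "permuted" &
                          cds$circular %in% TRUE] <- "circular_permuted"
      }
    }
    res$cd_srnas <- cds
    summary$n_cd_srnas <- nrow(cds)
    summary$n_cd_circular <- if (is.null(reads)) NULL else
      sum(cds$circular %in% TRUE)

    hacas <- list()
    if (!is.null(pileup) && !is.null(features)) {
      genic <- features[features$kind %in%
                          c("gene", "tRNA", "tRNA_half", "rRNA",
                            "CRISPR_array"), , drop = FALSE]
      cand <- screen_intergenic(pileup, genic,
                                min_coverage = cfg$intergenic$min_coverage,
                                merge_gap = cfg$intergenic$merge_gap)
      # regions already claimed by C/D calls are not H/ACA candidates
      if (nrow(cand) > 0 && nrow(cds) > 0) {
        keep <- vapply(seq_len(nrow(cand)), function(i) {
          !any(cds$strand == cand$strand[i] & cds$start < cand$end[i] &
                 cds$end > cand$start[i])
        }, logical(1))
        cand <- cand[keep, , drop = FALSE]
      }
      res$intergenic_candidates <- cand
      if (nrow(cand) > 0) {
        hacas <- find_haca(cand, genome,
                           min_hairpin = cfg$haca$min_hairpin,
                           min_pairs = cfg$haca$min_pairs)
      }
    }
    res$hacas <- hacas
    summary$n_haca <- if (is.null(pileup)) NULL else length(hacas)

    targets <- NULL
    if (!is.null(rrnas)) {
      if (nrow(cds) > 0) targets <- predict_2ome_targets(cds, rrnas)
      for (h in hacas) {
        targets <- rbind(targets, predict_psi_targets(h, rrnas))
      }
    }
    res$targets <- targets
    summary$n_target_predictions <- if (is.null(targets)) NULL else
      nrow(targets)
  } else {
    summary$n_cd_srnas <- NULL
    summary$n_haca <- NULL
  }

  res$summary <- summary
  class(res) <- "nanosmallrna_run"

  if (!is.null(cfg$paths$out_dir)) {
    write_reports(run_report_tables(res), cfg$paths$out_dir)
  }
  res
}

# Assemble the write_reports() input from a run result.
run_report_tables <- function(res) {
  haca_df <- NULL
  if (length(res$hacas %||% list()) > 0) {
    haca_df <- do.call(rbind, lapply(seq_along(res$hacas), function(i) {
      h <- res$hacas[[i]]
      data.frame(srna_id = sprintf("HACA_%03d", i), contig_id = h$contig_id,
                 start = h$start, end = h$end, strand = h$strand,
                 n_hairpins = length(h$hairpins),
                 hinge_pos = h$start + h$hinge_local - 1L,
                 terminal_ACA = h$terminal_ACA,
                 h_domain_status = h$h_domain_status,
                 kturn_flags = paste(h$kturn_flags, collapse = ","),
                 stringsAsFactors = FALSE)
    }))
  }
  list(genome = res$genome, features = res$features,
       spacers = res$spacers, trna_pairs = res$trna_pairs,
       leaderless = res$leaderless, cd_srnas = res$cd_srnas,
       haca_srnas = haca_df, targets = res$targets,
       summary = res$summary)
}

#' @export
print.nanosmallrna_run <- function(x, ...) {
  s <- x$summary
  cat("<nanosmallrna_run>\n")
  cat(sprintf("  reads: %s input, %s mapped\n",
              s$reads_input %||% "none", s$reads_mapped %||% "-"))
  cat(sprintf("  CRISPR arrays: %s (%s spacers)\n",
              s$n_arrays %||% "-", s$n_spacers %||% "-"))
  cat(sprintf("  tRNA pairs: %s\n", s$n_trna_pairs %||% "-"))
  cat(sprintf("  C/D sRNAs: %s, H/ACA: %s\n",
              s$n_cd_srnas %||% "-", s$n_haca %||% "-"))
  invisible(x)
}
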