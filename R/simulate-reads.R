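#' Simulate a processed small-RNA-seq read library
#'
#' Per planted transcript, read counts are drawn Poisson around the
#' scenario's abundance model (geometric decay along each CRISPR array;
#' high constant abundance for C/D sRNAs; reduced counts for mature tRNAs).
#' crRNA reads carry the Cas6 5' tag and geometrically 3'-trimmed ends with
#' a secondary fixed trimming mode (the hotspot); tRNA reads suffer
#' 3'-anchored RT drop-off truncation; circular sRNAs emit
#' junction-spanning reads; substitution errors are applied at
#' `error_rate`; qualities are constant Q30.
#'
#' @param genome a [genome_record()] from [generate_genome()].
#' @param truth the matching truth list.
#' @param sc the [scenario()] used for generation.
#' @return list with `reads` (data.frame: `read_id`, `seq`, `qual`) and
#'   `counts` (data.frame of reads emitted per transcript).
#' @export
simulate_reads <- function(genome, truth, sc = scenario()) {
  set.seed(as.integer((sc$seed + 7919) %% .Machine$integer.max))
  gseq <- genome$sequence
  L <- genome$length
  reads <- list()
  counts <- list()

  apply_errors <- function(s) {
    if (sc$error_rate <= 0) return(s)
    ch <- seq_chars(s)
    hit <- which(stats::runif(length(ch)) < sc$error_rate)
    if (length(hit) > 0) {
      for (h in hit) {
        ch[h] <- sample(setdiff(c("A", "C", "G", "T"), ch[h]), 1L)
      }
      s <- paste(ch, collapse = "")
    }
    s
  }
  emit <- function(class_id, fwd_start, fwd_end, strand) {
    fwd_start <- max(0L, fwd_start); fwd_end <- min(L, fwd_end)
    if (fwd_end - fwd_start < 15L) return(invisible(NULL))
    s <- apply_errors(seq_extract(gseq, fwd_start, fwd_end, strand))
    reads[[length(reads) + 1L]] <<- c(class_id, s)
    invisible(NULL)
  }
  emit_seq <- function(class_id, s) {
    if (nchar(s) < 15L) return(invisible(NULL))
    reads[[length(reads) + 1L]] <<- c(class_id, apply_errors(s))
    invisible(NULL)
  }
  note_count <- function(id, class, n) {
    counts[[length(counts) + 1L]] <<- data.frame(
      transcript_id = id, class = class, n_reads = n,
      stringsAsFactors = FALSE)
  }

  # --- crRNAs -------------------------------------------------------------
  tag3_max <- 28L - sc$tag_len                  # 3' repeat remnant length
  for (ai in seq_along(truth$arrays)) {
    arr <- truth$arrays[[ai]]
    sp <- arr$spacers                           # rows in transcription order
    for (k in seq_len(nrow(sp))) {
      lambda <- sc$read_depth * sc$abundance_decay^(k - 1L)
      n <- stats::rpois(1L, lambda)
      id <- sprintf("crRNA_a%d_s%02d", ai, k)
      note_count(id, "crRNA", n)
      if (n == 0) next
      for (r in seq_len(n)) {
        trim <- if (stats::runif(1) < sc$trim_hotspot_prob) {
          sc$trim_hotspot_offset
        } else {
          min(stats::rgeom(1L, sc$trim_geometric_p),
              tag3_max + sp$len[k] %/% 2L)
        }
        ext3 <- tag3_max - trim                 # relative to spacer 3' end
        if (arr$strand == "+") {
          emit(id, sp$start[k] - sc$tag_len, sp$end[k] + ext3, "+")
        } else {
          emit(id, sp$start[k] - ext3, sp$end[k] + sc$tag_len, "-")
        }
      }
    }
    # pre-crRNA leader reads pin the TSS
    n <- stats::rpois(1L, 0.6 * sc$read_depth)
    note_count(sprintf("leader_a%d", ai), "pre_crRNA", n)
    for (r in seq_len(n)) {
      len <- sample(40:60, 1L)
      if (arr$strand == "+") {
        emit(sprintf("leader_a%d", ai), arr$tss_pos, arr$tss_pos + len, "+")
      } else {
        emit(sprintf("leader_a%d", ai), arr$tss_pos - len + 1L,
             arr$tss_pos + 1L, "-")
      }
    }
  }

  # --- tRNA half precursors ----------------------------------------------
  jitter3 <- function() sample(c(-1L, 0L, 1L), 1L, prob = c(0.1, 0.8, 0.1))
  for (i in seq_len(nrow(truth$trna_pairs))) {
    p <- truth$trna_pairs[i, ]
    n5 <- stats::rpois(1L, sc$read_depth)
    note_count(p$five_id, "tRNA_half", n5)
    for (r in seq_len(n5)) {
      j <- jitter3()
      if (p$strand5 == "+") emit(p$five_id, p$tx5_start, p$tx5_end + j, "+")
      else emit(p$five_id, p$tx5_start - j, p$tx5_end, "-")
    }
    n3 <- stats::rpois(1L, sc$read_depth)
    note_count(p$three_id, "tRNA_half", n3)
    for (r in seq_len(n3)) {
      # planted 3' offset dominates; minor jitter around it
      off <- p$offset3 + (if (stats::runif(1) < 0.2) jitter3() else 0L)
      if (p$strand3 == "+") emit(p$three_id, p$tx3_start, p$tx3_end + off, "+")
      else emit(p$three_id, p$tx3_start - off, p$tx3_end, "-")
    }
  }

  # --- mature tRNA genes (RT drop-off; leaderless starts; G-1 on Tyr) -----
  for (tg in truth$trna_genes) {
    n <- stats::rpois(1L, sc$trna_depth_factor * sc$read_depth)
    note_count(tg$id, "tRNA", n)
    glen <- tg$end - tg$start
    for (r in seq_len(n)) {
      minus1 <- stats::runif(1) < tg$minus1_frac
      full <- glen + as.integer(minus1)
      len <- min(full, 15L + stats::rgeom(1L, sc$rt_dropoff))
      if (tg$strand == "+") {
        emit(tg$id, tg$end - len, tg$end, "+")
      } else {
        emit(tg$id, tg$start, tg$start + len, "-")
      }
    }
  }

  # --- C/D box sRNAs ------------------------------------------------------
  for (i in seq_len(nrow(truth$cd))) {
    x <- truth$cd[i, ]
    n <- stats::rpois(1L, sc$srna_depth_factor * sc$read_depth)
    note_count(x$id, "CD_sRNA", n)
    slen <- x$end - x$start
    circ_seq <- seq_extract(gseq, x$start, x$end, x$strand)
    doubled <- paste0(circ_seq, circ_seq)
    for (r in seq_len(n)) {
      if (x$circular && stats::runif(1) < sc$circular_junction_fraction) {
        rl <- sample(40:min(50L, slen), 1L)
        left <- sample(12:(rl - 12L), 1L)       # nt before the junction
        emit_seq(x$id, substr(doubled, slen - left + 1L,
                              slen - left + rl))
      } else {
        j5 <- sample(0:1, 1L); j3 <- sample(0:2, 1L)
        if (x$strand == "+") emit(x$id, x$start + j5, x$end - j3, "+")
        else emit(x$id, x$start + j3, x$end - j5, "-")
      }
    }
  }

  # --- H/ACA sRNA ---------------------------------------------------------
  n <- stats::rpois(1L, sc$haca_depth_factor * sc$read_depth)
  note_count(truth$haca$id, "HACA_sRNA", n)
  for (r in seq_len(n)) {
    j5 <- sample(0:1, 1L); j3 <- sample(0:1, 1L)
    emit(truth$haca$id, truth$haca$start + j5, truth$haca$end - j3,
         truth$haca$strand)
  }

  # --- background mRNA fragments -----------------------------------------
  for (i in seq_len(nrow(truth$genes))) {
    g <- truth$genes[i, ]
    n <- stats::rpois(1L, 20)
    note_count(g$feature_id, "mRNA", n)
    for (r in seq_len(n)) {
      flen <- sample(35:60, 1L)
      fs <- g$start + sample.int(max(1L, g$end - g$start - flen), 1L) - 1L
      emit(g$feature_id, fs, fs + flen, g$strand)
    }
  }

  out <- do.call(rbind, reads)
  df <- data.frame(read_id = sprintf("%s_%06d", out[, 1],
                                     seq_len(nrow(out))),
                   seq = out[, 2], stringsAsFactors = FALSE)
  df <- df[sample.int(nrow(df)), , drop = FALSE]
  rownames(df) <- NULL
  df$qual <- strrep("?", nchar(df$seq))
  list(reads = df, counts = do.call(rbind, counts))
}

#' Write a complete synthetic scenario to disk
#'
#' Emits the genome FASTA, annotation GFF3, read FASTQ, rRNA FASTA and a
#' JSON truth summary into `out_dir`.
#'
#' @param sc a [scenario()].
#' @param out_dir output directory.
#' @return invisibly, a list with the generated objects and file paths.
#' @export
write_scenario <- function(sc = scenario(), out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  gen <- generate_genome(sc)
  sim <- simulate_reads(gen$genome, gen$truth, sc)
  paths <- list(
    genome = file.path(out_dir, "genome.fa"),
    gff = file.path(out_dir, "features.gff3"),
    reads = file.path(out_dir, "reads.fastq"),
    rrna = file.path(out_dir, "rrna.fa"),
    truth = file.path(out_dir, "truth.json"))
  write_fasta(gen$genome, paths$genome)
  write_gff3(gen$features, paths$gff, contigs = gen$genome)
  write_fastq(sim$reads, paths$reads)
  write_fasta(gen$rrnas, paths$rrna)
  jsonlite::write_json(
    list(seed = sc$seed,
         n_spacers = sum(sc$spacers_per_array),
         tag_seq = gen$truth$tag_seq,
         leader_identity_len = gen$truth$leader_identity_len,
         tss_offset = gen$truth$tss_offset,
         boxA_offset = gen$truth$boxA_offset,
         cd = gen$truth$cd, haca_len = gen$truth$haca$len),
    paths$truth, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(genome = gen$genome, features = gen$features,
                 rrnas = gen$rrnas, truth = gen$truth,
                 reads = sim$reads, counts = sim$counts, paths = paths))
}
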