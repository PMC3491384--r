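# Synthetic-data generator: plants every feature class the pipeline infers
# -- two CRISPR arrays with identical leaders, split tRNA-half genes with
# reverse-complement GC-rich clamps, canonical / permuted / dicistronic /
# intronic / split-gene-flanking C/D box sRNAs (two of them circular), one
# two-hairpin H/ACA sRNA -- and a read library reflecting the processing
# model: Cas6 cleavage leaving a fixed 5' tag, geometric 3' exo-trimming,
# abundance decay along the array, leaderless tRNA starts and RT drop-off
# on structured tRNAs.

#' Synthetic scenario parameters
#'
#' Defaults mirror the study conditions of the real system: 41 spacers on
#' two arrays, a 28-nt repeat ending ATTGAAAG, leaders identical for 130 nt,
#' TSS on an A 33 nt upstream of the first repeat, box A (TTTAAA) 27 nt
#' upstream of the TSS, an 8-nt crRNA 5' tag, six trans-spliced tRNA pairs
#' and a 159-nt H/ACA sRNA.
#'
#' @param seed integer RNG seed; the whole scenario is deterministic in it.
#' @param genome_length minimum genome length (padded with random sequence).
#' @param spacers_per_array spacer counts of the two arrays (default 21, 20).
#' @param repeat_seq 28-nt repeat; default random 20-mer + ATTGAAAG.
#' @param leader_identity_len identical leader length (default 130 nt).
#' @param tss_offset TSS to first-repeat offset (default 33 nt).
#' @param boxA_offset box A to TSS distance (default 27 nt).
#' @param tag_len crRNA 5' tag length (default 8 nt).
#' @param trim_geometric_p geometric 3'-trimming parameter (default 0.25).
#' @param trim_hotspot_offset,trim_hotspot_prob secondary fixed trimming
#'   mode producing a discrete hotspot (default 12 nt at probability 0.15).
#' @param abundance_decay per-spacer abundance factor (default 0.8).
#' @param n_trna_pairs trans-spliced tRNA pairs (default 6).
#' @param clamp_len clamp length (default 12 nt).
#' @param read_depth mean reads per crRNA spacer at the array head / per
#'   tRNA half (default 100).
#' @param srna_depth_factor C/D sRNA abundance multiple of `read_depth`
#'   (default 3).
#' @param haca_depth_factor H/ACA abundance multiple (default 15; the
#'   H/ACA sRNA is a highly expressed intergenic RNA).
#' @param trna_depth_factor mature tRNA multiple (default 0.3; reverse
#'   transcription of modified, structured tRNAs yields few reads).
#' @param error_rate per-base substitution rate (default 0.001).
#' @param rt_dropoff per-nt RT drop-off probability on tRNAs (default
#'   0.005).
#' @param circular_junction_fraction fraction of circular-sRNA reads that
#'   span the circularization junction (default 0.4).
#' @return a `scenario` list.
#' @export
scenario <- function(seed = 42L, genome_length = 50000L,
                     spacers_per_array = c(21L, 20L), repeat_seq = NULL,
                     leader_identity_len = 130L, tss_offset = 33L,
                     boxA_offset = 27L, tag_len = 8L,
                     trim_geometric_p = 0.25, trim_hotspot_offset = 12L,
                     trim_hotspot_prob = 0.15, abundance_decay = 0.8,
                     n_trna_pairs = 6L, clamp_len = 12L, read_depth = 100L,
                     srna_depth_factor = 3, haca_depth_factor = 15,
                     trna_depth_factor = 0.3, error_rate = 0.001,
                     rt_dropoff = 0.005,
                     circular_junction_fraction = 0.4) {
  stopifnot(trim_geometric_p > 0, trim_geometric_p < 1,
            error_rate >= 0, error_rate < 1,
            rt_dropoff >= 0, rt_dropoff < 1, abundance_decay > 0)
  structure(as.list(environment()), class = "scenario")
}

# sample a random DNA string avoiding given substrings
random_dna_avoiding <- function(n, avoid = character(0), max_try = 200L) {
  for (i in seq_len(max_try)) {
    s <- random_dna(n)
    if (!any(vapply(avoid, grepl, logical(1), x = s, fixed = TRUE))) return(s)
  }
  stop_fmt("could not generate %d-nt sequence avoiding motifs", n)
}

# C/D sRNA locus builder (local 0-based offsets; includes 5'/3' flanks so
# the planted interval equals what the scanner calls).
make_cd_locus <- function(arrangement = c("canonical", "permuted"),
                          guideD = NULL, guideDp = NULL, boxC = "ATGATGA",
                          linker = "AGTC", perm_gap_seq = NULL) {
  arrangement <- match.arg(arrangement)
  avoid <- c("CTGA", "TGATGA")
  if (is.null(guideD)) guideD <- random_dna_avoiding(12L, avoid)
  if (is.null(guideDp)) guideDp <- random_dna_avoiding(12L, avoid)
  flank5 <- "AACCA"; flank3 <- "CAA"
  boxCp <- "GTGATGA"; boxD <- "CTGA"; boxDp <- "CTGA"
  if (arrangement == "canonical") {
    seqs <- c(flank5, boxC, guideDp, boxDp, linker, boxCp, guideD, boxD,
              flank3)
  } else {
    # linear order C' guide2 D | gap | C guide1 D'; the 10-nt gap keeps the
    # canonical reading from fitting the linker window and is a fixed
    # sequence free of GAT cores and of anything within one mismatch of
    # CTGA, so no spurious internal boxes can support a canonical reading
    if (is.null(perm_gap_seq)) perm_gap_seq <- "CCACCACCAC"
    seqs <- c(flank5, boxCp, guideD, boxD, perm_gap_seq, boxC, guideDp,
              boxDp, flank3)
  }
  seq <- paste(seqs, collapse = "")
  offs <- cumsum(c(0L, nchar(seqs)))
  names(offs) <- c("flank5", if (arrangement == "canonical") {
    c("boxC", "guideDp", "boxDp", "linker", "boxCp", "guideD", "boxD")
  } else {
    c("boxCp", "guideD", "boxD", "gap", "boxC", "guideDp", "boxDp")
  }, "flank3")
  list(seq = seq, len = nchar(seq), arrangement = arrangement,
       guideD = guideD, guideDp = guideDp, offsets = offs)
}

# H/ACA hairpin builder: pure G/C stems, A-only pockets and loops, AA bulge
# with the tandem G/A k-turn signature.  pocket-to-ACA distance is
# stemB + 2 + stemA = 15 nt by construction.
make_haca_hairpin <- function(stemA = 7L, stemB = 6L, stemC = 9L,
                              pocket = 7L, loop = 10L) {
  sA <- strrep("G", stemA); sB <- strrep("G", stemB); sC <- strrep("G", stemC)
  paste0(sA, "AA", "GA", sB, strrep("A", pocket), sC, strrep("A", loop),
         revcomp(sC), strrep("A", pocket), revcomp(sB), "GA", revcomp(sA))
}

#' Generate a synthetic genome with planted features and ground truth
#'
#' Background sequence is uniform random; planted features are laid out
#' sequentially with random intergenic gaps and do not overlap except where
#' the scenario demands it (an mRNA-overlapping C/D sRNA inside a gene, an
#' intronic C/D sRNA inside a tRNA intron).  Deterministic given the
#' scenario seed.
#'
#' @param sc a [scenario()].
#' @return list with `genome` ([genome_record()]), `features` (feature
#'   table), `rrnas` (named character vector, the 16S/23S stand-ins) and
#'   `truth` (planted coordinates, sequences and processing parameters).
#' @export
generate_genome <- function(sc = scenario()) {
  set.seed(as.integer(sc$seed))
  segs <- character(0)
  cur <- 0L
  feats <- list()
  truth <- list(seed = sc$seed)

  add_seq <- function(s) {
    segs[[length(segs) + 1L]] <<- s
    start <- cur
    cur <<- cur + nchar(s)
    start
  }
  add_gap <- function(n = sample(150:300, 1L)) add_seq(random_dna(n))
  add_feat <- function(id, start, end, strand, kind, attrs = "") {
    feats[[length(feats) + 1L]] <<- list(id = id, start = start, end = end,
                                         strand = strand, kind = kind,
                                         attrs = attrs)
  }
  add_gene <- function(id, len, strand = "+", attrs = "", seq = NULL) {
    s <- add_seq(seq %||% random_dna(len))
    add_feat(id, s, s + (if (is.null(seq)) len else nchar(seq)), strand,
             "gene", attrs)
    s
  }

  # --- identical CRISPR leader core --------------------------------------
  L_id <- sc$leader_identity_len
  # leaders are AT-rich, as expected upstream of archaeal promoters
  core <- sample(c("A", "T", "C", "G"), L_id, replace = TRUE,
                 prob = c(0.35, 0.35, 0.15, 0.15))
  tss_i <- L_id - sc$tss_offset                # 0-based index within core
  boxA_i <- tss_i - sc$boxA_offset
  scrub <- c((tss_i - 35L):(boxA_i - 1L), (boxA_i + 6L):(tss_i - 20L + 5L))
  scrub <- scrub[scrub >= 0L & scrub < L_id]
  core[scrub + 1L] <- rep(c("G", "C"), length.out = length(scrub))
  core[(boxA_i + 1L):(boxA_i + 6L)] <- seq_chars("TTTAAA")
  core[tss_i + 1L] <- "A"
  leader_core <- paste(core, collapse = "")

  repeat_seq <- sc$repeat_seq %||%
    paste0(random_dna_avoiding(20L, c("CTGA", "TGATGA", "TTTTT")),
           "ATTGAAAG")
  stopifnot(nchar(repeat_seq) == 28L,
            endsWith(repeat_seq, substr("ATTGAAAG", 9L - sc$tag_len, 8L)))

  n_sp_total <- sum(sc$spacers_per_array)
  sp_lens <- rep(38L, n_sp_total)
  sp_lens[4L] <- 60L                            # one long spacer, array 1
  spacer_seqs <- character(n_sp_total)
  for (i in seq_len(n_sp_total)) {
    repeat {
      s <- random_dna_avoiding(sp_lens[i], c("CTGA", "TGATGA", "TTTTT"))
      if (!s %in% spacer_seqs) break
    }
    spacer_seqs[i] <- s
  }
  sp_split <- split(seq_len(n_sp_total),
                    rep(seq_along(sc$spacers_per_array),
                        sc$spacers_per_array))

  build_array <- function(which_array, strand, divpad_last) {
    idx <- sp_split[[which_array]]
    nrep <- length(idx) + 1L
    divpad <- paste0(paste(sample(c("A", "T", "C", "G"), 69L, replace = TRUE,
                                  prob = c(0.35, 0.35, 0.15, 0.15)),
                           collapse = ""), divpad_last)
    body <- paste0(repeat_seq,
                   paste0(spacer_seqs[idx], repeat_seq, collapse = ""))
    tx <- paste0(divpad, leader_core, body)     # transcript-strand layout
    gseq <- if (strand == "-") revcomp(tx) else tx
    S <- add_seq(gseq)
    W <- nchar(tx)
    # transcript-local 0-based [a, b) -> forward interval
    tofwd <- function(a, b) {
      if (strand == "-") c(S + W - b, S + W - a) else c(S + a, S + b)
    }
    lead0 <- nchar(divpad)
    body0 <- lead0 + L_id
    rep_local <- body0 + cumsum(c(0L, nchar(repeat_seq) +
                                    sp_lens[idx]))[seq_len(nrep)]
    reps <- t(vapply(rep_local, function(a) tofwd(a, a + 28L), numeric(2)))
    sp_local <- rep_local[-nrep] + 28L
    sps <- t(vapply(seq_along(idx), function(i) {
      tofwd(sp_local[i], sp_local[i] + sp_lens[idx][i])
    }, numeric(2)))
    tss_fwd <- tofwd(lead0 + tss_i, lead0 + tss_i + 1L)  # single base
    boxA_fwd <- tofwd(lead0 + boxA_i, lead0 + boxA_i + 6L)
    span <- tofwd(body0, W)
    add_feat(sprintf("array%d", which_array), span[1], span[2], NA,
             "CRISPR_array", "")
    lead_fwd <- tofwd(lead0, body0)
    add_feat(sprintf("leader%d", which_array), lead_fwd[1], lead_fwd[2],
             strand, "leader", "")
    list(strand = strand, span = span,
         repeats = data.frame(start = reps[, 1], end = reps[, 2]),
         spacers = data.frame(index = seq_along(idx),
                              start = sps[, 1], end = sps[, 2],
                              seq = spacer_seqs[idx], len = sp_lens[idx],
                              stringsAsFactors = FALSE),
         tss_pos = tss_fwd[1],
         boxA = boxA_fwd, repeat_seq = repeat_seq,
         tag_seq = substr(repeat_seq, 29L - sc$tag_len, 28L))
  }

  add_gap(300L)
  add_gene("NEQ_A", 800L)
  add_gap()
  arr1 <- build_array(1L, "+", "G")
  add_gap()
  arr2 <- build_array(2L, "-", "C")
  truth$arrays <- list(arr1, arr2)
  truth$repeat_seq <- repeat_seq
  truth$tag_len <- sc$tag_len
  truth$tag_seq <- substr(repeat_seq, 29L - sc$tag_len, 28L)
  truth$leader_identity_len <- L_id
  truth$tss_offset <- sc$tss_offset
  truth$boxA_offset <- sc$boxA_offset

  # --- trans-spliced tRNA halves -----------------------------------------
  np <- sc$n_trna_pairs
  clamps <- character(0)
  while (length(clamps) < np) {
    cand <- paste(sample(c(rep(c("G", "C"), 5L), sample(c("A", "C", "G"),
                                                        2L, TRUE))),
                  collapse = "")
    if (nchar(cand) != sc$clamp_len) cand <- substr(cand, 1L, sc$clamp_len)
    ok <- !grepl("TTTTT", cand) &&
      all(vapply(clamps, function(old) {
        clamp_duplex(cand, revcomp(old))$len < 6 &&
          clamp_duplex(old, revcomp(cand))$len < 6
      }, logical(1)))
    if (ok) clamps <- c(clamps, cand)
  }
  off3_planted <- utils::head(c(2L, 1L, -1L, integer(max(0L, np - 3L))), np)
  ext_bases <- utils::head(c("GC", "A", "", character(max(0L, np - 3L))), np)
  half_rows <- list()
  for (i in seq_len(np)) {
    st5 <- if (i %% 2L == 0L) "-" else "+"
    st3 <- if (i %% 3L == 0L) "-" else "+"
    body5 <- paste0("G", random_dna_avoiding(35L, "TTTTT"))
    body3 <- random_dna_avoiding(40L, "TTTTT")
    # 5' half: body + clamp + terminator
    tx5 <- paste0(body5, clamps[i], "TTTTTT")
    g5 <- if (st5 == "-") revcomp(tx5) else tx5
    add_gap()
    S5 <- add_seq(g5); W5 <- nchar(tx5)
    tofwd5 <- function(a, b) if (st5 == "-") c(S5 + W5 - b, S5 + W5 - a)
      else c(S5 + a, S5 + b)
    b5 <- tofwd5(0L, 36L)
    id5 <- sprintf("trna_half_%d_5p", i)
    add_feat(id5, b5[1], b5[2], st5, "tRNA_half",
             attrs_build(half_side = "five_prime"))
    tx5_span <- tofwd5(0L, 36L + sc$clamp_len)
    # 3' half: terminator-bounded clamp + body + planted extension
    tx3 <- paste0("TTTTT", revcomp(clamps[i]), body3, ext_bases[i],
                  "TTTTTT")
    g3 <- if (st3 == "-") revcomp(tx3) else tx3
    add_gap()
    S3 <- add_seq(g3); W3 <- nchar(tx3)
    tofwd3 <- function(a, b) if (st3 == "-") c(S3 + W3 - b, S3 + W3 - a)
      else c(S3 + a, S3 + b)
    b3 <- tofwd3(5L + sc$clamp_len, 5L + sc$clamp_len + 40L)
    id3 <- sprintf("trna_half_%d_3p", i)
    add_feat(id3, b3[1], b3[2], st3, "tRNA_half",
             attrs_build(half_side = "three_prime"))
    tx3_span <- tofwd3(5L, 5L + sc$clamp_len + 40L)
    half_rows[[i]] <- data.frame(
      pair_id = i, five_id = id5, three_id = id3,
      clamp = clamps[i], strand5 = st5, strand3 = st3,
      tx5_start = tx5_span[1], tx5_end = tx5_span[2],
      tx3_start = tx3_span[1], tx3_end = tx3_span[2],
      offset3 = off3_planted[i],
      mature_seq = paste0(body5, body3), stringsAsFactors = FALSE)
  }
  truth$trna_pairs <- do.call(rbind, half_rows)

  # --- tRNA genes ---------------------------------------------------------
  trna_rows <- list()
  add_trna <- function(id, seq, strand = "+", lead_base = NULL,
                       attrs = "", kind = "tRNA") {
    if (!is.null(lead_base)) add_seq(lead_base)
    s <- add_seq(seq)
    add_feat(id, s, s + nchar(seq), strand, kind, attrs)
    s
  }
  add_gap()
  tyr_seq <- paste0("C", random_dna_avoiding(75L, "TTTTT"))
  tyr_s <- add_trna("tRNA_Tyr", tyr_seq, "+", lead_base = "G")
  trna_rows$tyr <- list(id = "tRNA_Tyr", start = tyr_s,
                        end = tyr_s + 76L, strand = "+",
                        minus1_base = "G", minus1_frac = 0.9)
  add_gap()
  val_seq <- paste0("G", random_dna_avoiding(71L, "TTTTT"))
  val_s <- add_trna("tRNA_Val", val_seq, "+",
                    attrs = attrs_build(anticodon = "TAC"))
  # dicistronic C/D sRNA 2 nt downstream of the tRNA 3' end
  cd_dici <- make_cd_locus("canonical")
  add_seq("AT")
  cd_dici$start <- add_seq(cd_dici$seq); cd_dici$strand <- "+"
  cd_dici$context <- "tRNA_dicistronic"; cd_dici$circular <- FALSE
  cd_dici$id <- "cd_dicistronic"
  trna_rows$val <- list(id = "tRNA_Val", start = val_s, end = val_s + 72L,
                        strand = "+", minus1_base = NA, minus1_frac = 0)
  add_gap()
  # intron-containing elongator tRNA-Met; the 66-nt intron carries a C/D
  # sRNA whose box C has one mutation, plus a 6-GC-pair hairpin
  cd_intr <- make_cd_locus("canonical",
                           guideD = random_dna_avoiding(10L,
                                                        c("CTGA", "TGATGA")),
                           guideDp = random_dna_avoiding(10L,
                                                         c("CTGA", "TGATGA")),
                           boxC = "AAGATGA", linker = "AG")
  hairpin_gc <- paste0("GGCGGC", "AT", revcomp("GGCGGC"))
  intron <- paste0(cd_intr$seq, hairpin_gc)
  stopifnot(nchar(intron) == 66L)
  exon1 <- paste0("A", random_dna_avoiding(36L, "TTTTT"))
  exon2 <- random_dna_avoiding(39L, "TTTTT")
  met_s <- add_trna("tRNA_Met", paste0(exon1, intron, exon2), "+",
                    attrs = attrs_build(anticodon = "CAT"))
  intron_s <- met_s + 37L
  add_feat("tRNA_Met_intron", intron_s, intron_s + 66L, "+", "other",
           attrs_build(feature_class = "tRNA_intron"))
  cd_intr$start <- intron_s; cd_intr$strand <- "+"
  cd_intr$context <- "tRNA_intronic"; cd_intr$circular <- FALSE
  cd_intr$id <- "cd_intronic"
  trna_rows$met <- list(id = "tRNA_Met", start = met_s,
                        end = met_s + 37L + 66L + 39L, strand = "+",
                        minus1_base = NA, minus1_frac = 0)
  add_gap()
  gly_seq <- paste0("A", random_dna_avoiding(73L, "TTTTT"))
  gly_s <- add_trna("tRNA_Gly", gly_seq, "+",
                    attrs = attrs_build(anticodon = "TCC"))
  trna_rows$gly <- list(id = "tRNA_Gly", start = gly_s, end = gly_s + 74L,
                        strand = "+", minus1_base = NA, minus1_frac = 0)
  truth$trna_genes <- trna_rows

  # --- standalone and mRNA-overlapping C/D sRNAs --------------------------
  add_gap()
  cd_sa1 <- make_cd_locus("canonical")
  cd_sa1$start <- add_seq(cd_sa1$seq); cd_sa1$strand <- "+"
  cd_sa1$context <- "standalone"; cd_sa1$circular <- FALSE
  cd_sa1$id <- "cd_standalone1"
  add_gap()
  cd_sa2 <- make_cd_locus("canonical")
  cd_sa2$start <- add_seq(revcomp(cd_sa2$seq)); cd_sa2$strand <- "-"
  cd_sa2$context <- "standalone"; cd_sa2$circular <- FALSE
  cd_sa2$id <- "cd_standalone2"
  add_gap()
  cd_ov <- make_cd_locus("canonical")
  geneB <- paste0(random_dna(150L), cd_ov$seq, random_dna(300L))
  gB <- add_gene("NEQ_B", seq = geneB, len = nchar(geneB))
  cd_ov$start <- gB + 150L; cd_ov$strand <- "+"
  cd_ov$context <- "mRNA_overlap"; cd_ov$circular <- FALSE
  cd_ov$id <- "cd_overlap"

  # --- split gene flanked by two C/D sRNAs (one permuted, both circular) --
  add_gap()
  cd_c23 <- make_cd_locus("canonical")
  cd_c23$start <- add_seq(cd_c23$seq); cd_c23$strand <- "+"
  cd_c23$context <- "split_gene_flank"; cd_c23$circular <- TRUE
  cd_c23$id <- "cd_circular23"
  add_seq(random_dna(30L))
  add_gene("NEQ_R1", 600L, attrs = attrs_build(split_part = "N_terminal"))
  add_seq(random_dna(20L))
  cd_p24 <- make_cd_locus("permuted")
  cd_p24$start <- add_seq(cd_p24$seq); cd_p24$strand <- "+"
  cd_p24$context <- "split_gene_flank"; cd_p24$circular <- TRUE
  cd_p24$id <- "cd_permuted24"
  # controlled tail: keeps chance boxes downstream of the permuted locus
  # from completing a spurious canonical reading
  add_seq("CCACCACCACCACCACCA")
  add_gap()
  add_gene("NEQ_R2", 500L, strand = "-",
           attrs = attrs_build(split_part = "C_terminal"))

  truth$cd <- do.call(rbind, lapply(
    list(cd_sa1, cd_sa2, cd_ov, cd_dici, cd_intr, cd_c23, cd_p24),
    function(x) data.frame(
      id = x$id, start = x$start, end = x$start + x$len, strand = x$strand,
      arrangement = x$arrangement, context = x$context,
      circular = x$circular, guideD = x$guideD, guideDp = x$guideDp,
      stringsAsFactors = FALSE)))
  for (i in seq_len(nrow(truth$cd))) {
    add_feat(truth$cd$id[i], truth$cd$start[i], truth$cd$end[i],
             truth$cd$strand[i], "CD_sRNA",
             attrs_build(arrangement = truth$cd$arrangement[i]))
  }

  # --- H/ACA sRNA ---------------------------------------------------------
  add_gap()
  add_gene("NEQ_C", 600L)
  add_gap(200L)
  h1 <- make_haca_hairpin(loop = 10L)
  h2 <- make_haca_hairpin(stemC = 8L, loop = 9L)
  haca_seq <- paste0("AAAAA", h1, "ACA", h2, "ACA", "AAA")
  haca_s <- add_seq(haca_seq)
  add_feat("haca1", haca_s, haca_s + nchar(haca_seq), "+", "HACA_sRNA", "")
  truth$haca <- list(id = "haca1", start = haca_s,
                     end = haca_s + nchar(haca_seq), strand = "+",
                     len = nchar(haca_seq),
                     pocket5 = strrep("A", 7L), pocket3 = strrep("A", 7L))
  add_gap(200L)
  add_gene("NEQ_D", 600L)
  add_gap(300L)

  if (cur < sc$genome_length) add_seq(random_dna(sc$genome_length - cur))
  genome <- genome_record("synth_contig", paste(segs, collapse = ""))

  fdf <- feature_table(
    feature_id = vapply(feats, `[[`, character(1), "id"),
    contig_id = genome$contig_id,
    start = vapply(feats, function(f) as.integer(f$start), integer(1)),
    end = vapply(feats, function(f) as.integer(f$end), integer(1)),
    strand = vapply(feats, function(f) as.character(f$strand), character(1)),
    kind = vapply(feats, `[[`, character(1), "kind"),
    attrs = vapply(feats, `[[`, character(1), "attrs"))

  truth$genes <- fdf[fdf$kind == "gene",
                     c("feature_id", "start", "end", "strand")]

  # --- rRNA stand-ins with implanted guide targets ------------------------
  r16 <- paste0(random_dna(140L), revcomp(cd_sa1$guideD), random_dna(148L))
  psi_site <- paste0(revcomp(substr(truth$haca$pocket3, 1L, 6L)), "T", "G",
                     revcomp(substr(truth$haca$pocket5, 1L, 6L)))
  r23 <- paste0(random_dna(180L), psi_site, random_dna(206L))
  rrnas <- c(rRNA_16S = r16, rRNA_23S = r23)
  truth$rrna_targets <- data.frame(
    srna_id = c("cd_standalone1", "haca1"),
    target_rna = c("rRNA_16S", "rRNA_23S"),
    target_position = c(140L + 12L - 8L + 1L, 181L + 6L),
    modification = c("2pOme", "pseudouridine"), stringsAsFactors = FALSE)

  list(genome = genome, features = fdf, rrnas = rrnas, truth = truth)
}
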