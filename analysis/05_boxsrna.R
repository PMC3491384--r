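#!/usr/bin/env Rscript
# C/D box and H/ACA box sRNA discovery: motif scanning, arrangement and
# context classification, circularity from junction reads, and simplified
# guide-target prediction against the rRNA set.

library(nanosmallrna)

genome <- read_fasta("results/scenario/genome.fa")[[1]]
features <- read_gff3("results/scenario/features.gff3")
reads <- read_fastq("results/scenario/reads.fastq")
rr <- read_fasta("results/scenario/rrna.fa")
rrnas <- stats::setNames(vapply(rr, `[[`, character(1), "sequence"),
                         vapply(rr, `[[`, character(1), "contig_id"))
mapped <- utils::read.delim("results/mapped_reads.tsv",
                            stringsAsFactors = FALSE)
pileup <- build_pileup(mapped, genome)

cds <- scan_cd(genome)
cds$context <- classify_context(cds, features)
for (i in seq_len(nrow(cds))) {
  circ <- detect_circular(cds[i, ], reads, genome)
  cds$junction_read_support[i] <- circ$junction_read_support
  cds$circular[i] <- circ$circular
}
cds$arrangement[cds$arrangement == "permuted" & cds$circular] <-
  "circular_permuted"
cat(sprintf("C/D box sRNAs: %d (%s)\n", nrow(cds),
            paste(sprintf("%d %s", table(cds$arrangement),
                          names(table(cds$arrangement))), collapse = ", ")))
cat(sprintf("contexts: %s\n",
            paste(sprintf("%d %s", table(cds$context),
                          names(table(cds$context))), collapse = ", ")))
cat(sprintf("circular sRNAs: %d (junction support %s)\n",
            sum(cds$circular),
            paste(cds$junction_read_support[cds$circular], collapse = ", ")))
utils::write.table(cds, "results/cd_srnas.tsv", sep = "\t", quote = FALSE,
                   row.names = FALSE)

genic <- features[features$kind %in% c("gene", "tRNA", "tRNA_half", "rRNA",
                                       "CRISPR_array"), ]
cand <- screen_intergenic(pileup, genic)
hacas <- find_haca(cand, genome)
cat(sprintf("H/ACA sRNAs: %d\n", length(hacas)))
for (h in hacas) {
  cat(sprintf("  %d-%d (%s): hinge %s, terminal ACA %s, k-turns %s/%s\n",
              h$start, h$end, h$h_domain_status, h$hinge_seq,
              h$terminal_ACA, h$kturn_flags[1], h$kturn_flags[2]))
}

targets <- predict_2ome_targets(cds, rrnas)
for (h in hacas) targets <- rbind(targets, predict_psi_targets(h, rrnas))
utils::write.table(targets, "results/guide_targets.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
cat(sprintf("guide-target predictions: %d (top: %s %s -> %s:%d, %d bp)\n",
            nrow(targets), targets$srna_id[1], targets$guide_source[1],
            targets$target_rna[1], targets$target_position[1],
            targets$duplex_len[1]))
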