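#!/usr/bin/env Rscript
# Trans-spliced tRNA analysis: clamp extraction, half pairing by maximum-
# weight clamp-duplex matching, mature tRNA assembly, precursor termini and
# the leaderless-start / G-1 diagnostics.

library(nanosmallrna)

genome <- read_fasta("results/scenario/genome.fa")[[1]]
features <- read_gff3("results/scenario/features.gff3")
mapped <- utils::read.delim("results/mapped_reads.tsv",
                            stringsAsFactors = FALSE)
pileup <- build_pileup(mapped, genome)

halves <- extract_clamps(features[features$kind == "tRNA_half", ], genome)
pairs <- pair_halves(halves, genome)
cat(sprintf("%d half genes paired into %d mature tRNAs (duplex %d-%d nt)\n",
            nrow(halves), nrow(pairs), min(pairs$duplex_len),
            max(pairs$duplex_len)))
utils::write.table(pairs[, setdiff(colnames(pairs), "mature_seq")],
                   "results/trna_pairs.tsv", sep = "\t", quote = FALSE,
                   row.names = FALSE)

termini <- annotate_precursor_termini(halves, pileup, genome)
utils::write.table(termini, "results/trna_termini.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
t3 <- termini[termini$half_side == "three_prime", ]
cat(sprintf("3' precursor offsets: %s (5' ends all exact: %s)\n",
            paste(t3$offset3, collapse = ", "),
            all(termini$offset5[termini$half_side == "five_prime"] == 0)))

ll <- leaderless_report(features[features$kind == "tRNA", ], pileup, genome)
utils::write.table(ll, "results/trna_leaderless.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
for (i in seq_len(nrow(ll))) {
  cat(sprintf("%s: start %s (purine %s), -1 fraction %.2f (%s)\n",
              ll$feature_id[i], ll$start_base[i], ll$purine_start[i],
              ll$minus1_fraction[i], ll$minus1_base[i]))
}
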