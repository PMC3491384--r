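#!/usr/bin/env Rscript
# Generate the synthetic study system: a 50-kb archaeal-style genome with
# two CRISPR arrays (41 spacers, identical 130-nt leaders), six split tRNA
# pairs, seven C/D box sRNAs across all genomic contexts, one H/ACA sRNA,
# and a processed small-RNA-seq library with known truth.

library(nanosmallrna)

seed <- 42L
out <- "results/scenario"
sc <- scenario(seed = seed)
s <- write_scenario(sc, out)

cat(sprintf("genome: %d nt, %d annotated features\n",
            s$genome$length, nrow(s$features)))
cat(sprintf("reads simulated: %d (%.1f nt mean length)\n",
            nrow(s$reads), mean(nchar(s$reads$seq))))
cat(sprintf("planted: %d spacers on 2 arrays, %d tRNA pairs, %d C/D sRNAs, 1 H/ACA\n",
            sum(sc$spacers_per_array), sc$n_trna_pairs,
            nrow(s$truth$cd)))
cat(sprintf("files under %s: genome.fa, features.gff3, reads.fastq, rrna.fa, truth.json\n",
            out))
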