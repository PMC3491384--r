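#!/usr/bin/env Rscript
# Trim and map the simulated library with the study's mapping costs
# (mismatch 2, insertion 3, deletion 3; accept at >= 80% identity), build
# the strand-aware pileup and report read accounting.

library(nanosmallrna)

dir.create("results", showWarnings = FALSE)
genome <- read_fasta("results/scenario/genome.fa")[[1]]
reads <- read_fastq("results/scenario/reads.fastq")

tr <- trim_reads(reads, trim_config())
cat(sprintf("input reads: %d; discarded < 15 nt: %d\n",
            tr$log$input, tr$log$discarded_short))

mapped <- map_reads(tr$reads, genome, map_config(), seed = 42L)
log <- attr(mapped, "log")
cat(sprintf("mapped: %d of %d (%.1f%%); unmapped: %d\n",
            log$mapped, log$input, 100 * log$mapped / log$input,
            log$unmapped))

pileup <- build_pileup(mapped, genome)
cat(sprintf("pileup: +%d / -%d reads, max depth %d\n",
            pileup$plus$n, pileup$minus$n,
            max(pileup$plus$depth, pileup$minus$depth)))

# mapped reads go to a plain TSV; downstream scripts rebuild the pileup
# from it, which is cheap
utils::write.table(mapped, "results/mapped_reads.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
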