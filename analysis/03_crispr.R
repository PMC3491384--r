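#!/usr/bin/env Rscript
# De novo CRISPR array detection and crRNA maturation profiling: per-spacer
# abundance, Cas6 5' tag, 3' trimming offsets, leader identity, TSS and
# box A promoter element.

library(nanosmallrna)

genome <- read_fasta("results/scenario/genome.fa")[[1]]
mapped <- utils::read.delim("results/mapped_reads.tsv",
                            stringsAsFactors = FALSE)
pileup <- build_pileup(mapped, genome)

arrays <- detect_arrays(genome)
arrays <- lapply(arrays, orient_array, pileup = pileup, genome = genome)
cat(sprintf("detected %d arrays, %d spacers total\n", length(arrays),
            sum(vapply(arrays, function(a) nrow(a$spacers), integer(1)))))

spacers <- do.call(rbind, lapply(arrays, infer_maturation, pileup = pileup))
utils::write.table(spacers, "results/crispr_spacers.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)

for (a in arrays) {
  tss <- call_tss(a, pileup, genome)
  boxa <- find_boxA(genome, tss$tss_position, a$strand)
  boxa_txt <- if (boxa$found) {
    sprintf("%s at -%d (%d mismatches)", boxa$seq, boxa$distance,
            boxa$mismatches)
  } else "absent"
  cat(sprintf("%s (%s): TSS on %s at offset %d; box A %s\n",
              a$array_id, a$strand, tss$tss_base,
              tss$tss_offset_to_first_repeat, boxa_txt))
}
leader <- compare_leaders(arrays[[1]], arrays[[2]], genome)
cat(sprintf("leaders identical for %d nt upstream of the first repeats\n",
            leader$identical_prefix_length))
top <- spacers[order(-spacers$read_count), ][1:2, ]
cat(sprintf("most abundant crRNAs: %s spacer %d (%d reads), %s spacer %d (%d reads)\n",
            top$array_id[1], top$spacer_index[1], top$read_count[1],
            top$array_id[2], top$spacer_index[2], top$read_count[2]))
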