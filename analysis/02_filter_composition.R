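#!/usr/bin/env Rscript
# Quality-filter the simulated CDS set and summarise base and dinucleotide
# composition by codon position. Expects the bundles written by
# analysis/01_simulate.R; writes tables under results/composition/.

library(cricketcub)

recs <- read_cds_fasta("results/data/mutation_only/cds.fasta")
recs <- attach_expression(recs, "results/data/mutation_only/expression.tsv")

filt <- filter_cds(recs)
message("filter: ", filt$report$n_input, " in, ",
        filt$report$n_pass, " pass (",
        filt$report$n_too_short, " short / ",
        filt$report$n_too_many_n, " N-rich / ",
        filt$report$n_internal_stops, " multi-stop removed)")

dir.create("results/composition", recursive = TRUE, showWarnings = FALSE)
write.table(filt$report, "results/composition/filter_report.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
write_cds_fasta(filt$records, "results/composition/cds_filtered.fasta")

pooled <- pooled_composition(filt$records)
comp <- data.frame(position = rownames(pooled$by_position),
                   pooled$by_position,
                   gc = rowSums(pooled$by_position[, c("G", "C")]))
write.table(comp, "results/composition/base_composition.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
message("pooled GC by position: gc1 = ", round(pooled$gc1, 3),
        ", gc2 = ", round(pooled$gc2, 3), ", gc3 = ", round(pooled$gc3, 3))

dinuc <- dinucleotide_table(filt$records)
write.table(dinuc, "results/composition/dinucleotide_ratios.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
worst <- dinuc[which.max(abs(dinuc$ratio - 1)), ]
message("largest observed/expected dinucleotide departure: ",
        worst$dinucleotide, " at junction ", worst$junction,
        " (ratio ", round(worst$ratio, 3), ")")

write.table(gc_by_position(filt$records),
            "results/composition/gene_gc.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
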