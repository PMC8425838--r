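#!/usr/bin/env Rscript
# miRNA-target consolidation (predicted score > 0.9 AND validated) and GO
# over-representation of the consolidated targets, with the shared-gene
# term graph and Jaccard dendrogram over the significant terms.

suppressPackageStartupMessages(library(sevmir))

de <- read.table("results/de_table.tsv", header = TRUE, sep = "\t")
query <- de$probe_id[de$de_call & de$direction == "up"]
pred <- read_target_table("results/inputs/targets_predicted.tsv")
val <- read_target_table("results/inputs/targets_validated.tsv")
gsc <- read_gmt("results/inputs/gene_sets.gmt")

sel <- consolidate_targets(query, pred, val, threshold = 0.9)
cat(sprintf("%d consolidated target genes from %d DE miRNAs\n",
            length(sel$genes), length(query)))

enr <- hypergeom_enrich(sel$genes, gsc, fdr_cutoff = 0.05)
write.table(enr, "results/enrichment.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
sig <- enr[enr$significant, ]
cat(sprintf("%d/%d terms significant at FDR < 0.05\n", nrow(sig), nrow(enr)))
print(head(sig[, c("term_id", "k", "K", "p_hyper", "fdr")], 10))

tg <- term_graph(top_terms(sig, 30))
write.table(tg$edges, "results/term_graph_edges.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
writeLines(tg$newick, "results/term_dendrogram.newick")
cat(sprintf("term graph: %d nodes, %d edges; dendrogram written\n",
            nrow(tg$nodes), nrow(tg$edges)))
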