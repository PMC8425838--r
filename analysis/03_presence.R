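#!/usr/bin/env Rscript
# Presence-absence partition of the probed miRNA universe: a miRNA is
# present in a group only if every retained replicate has TPM >= 1.

suppressPackageStartupMessages(library(sevmir))

cm <- read_count_matrix("results/inputs/counts.tsv", "results/inputs/annotation.tsv")
design <- read_sample_sheet("results/inputs/samples.tsv")
kept <- drop_failed_samples(cm, sample_qc(cm), design)
tpm <- tpm_normalize(kept)

part <- presence_sets(tpm, design)
print(part)
vc <- venn_counts(part)
write.table(part$pattern, "results/presence.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
jsonlite::write_json(as.list(vc), "results/presence_counts.json", auto_unbox = TRUE)
cat(sprintf("Venn: %d common | %d control-only | %d case-only\n",
            vc["n_common"], vc["n_unique_control"], vc["n_unique_case"]))
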