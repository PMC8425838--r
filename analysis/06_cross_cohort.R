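#!/usr/bin/env Rscript
# Cross-cohort signature overlap: the published TFM DE miRNA list against
# the four prior CRPS patient study signatures, and the synthetic DE calls
# against the generator's reference signatures.

suppressPackageStartupMessages(library(sevmir))

## published lists
om <- overlap_matrix(tfm_de_table()$mirna, crps_signatures(), policy = "strict")
print(om)
write_overlap_table(om, "results/published_overlap.tsv")
jsonlite::write_json(c(as.list(om$column_counts),
                       list(any_reference = om$any_reference_count)),
                     "results/published_overlap_counts.json", auto_unbox = TRUE)

## synthetic DE calls against the simulated references
de <- read.table("results/de_table.tsv", header = TRUE, sep = "\t")
refs <- read_signatures("results/inputs/signatures.tsv")
om_syn <- overlap_matrix(de$probe_id[de$de_call], refs, policy = "strict")
cat("synthetic overlap counts (planted 8 exosome / 23 whole blood among all planted DE):\n")
print(om_syn$column_counts)
write_overlap_table(om_syn, "results/synthetic_overlap.tsv")
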