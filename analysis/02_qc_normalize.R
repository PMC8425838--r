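#!/usr/bin/env Rscript
# Sample QC (total reads >= 1e6, spike fraction < 10%, housekeeping CV
# < 15%) followed by TPM normalization of the retained samples.

suppressPackageStartupMessages(library(sevmir))

cm <- read_count_matrix("results/inputs/counts.tsv", "results/inputs/annotation.tsv")
design <- read_sample_sheet("results/inputs/samples.tsv")

qc <- sample_qc(cm)
print(qc[, c("sample_id", "total_reads", "spike_fraction", "cv", "pass", "reasons")])
write.table(qc, "results/qc_report.tsv", sep = "\t", quote = FALSE, row.names = FALSE)

kept <- drop_failed_samples(cm, qc, design)
cat(sprintf("dropped %d sample(s): %s\n", sum(!qc$pass),
            paste(qc$sample_id[!qc$pass], collapse = ", ")))

tpm <- tpm_normalize(kept)
stopifnot(all(abs(colSums(tpm$values) - 1e6) < 1e-3))
write.table(data.frame(probe_id = rownames(tpm$values), tpm$values,
                       check.names = FALSE),
            "results/tpm.tsv", sep = "\t", quote = FALSE, row.names = FALSE)
cat(sprintf("TPM matrix: %d probes x %d samples (columns sum to 1e6)\n",
            nrow(tpm$values), ncol(tpm$values)))
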