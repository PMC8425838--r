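#!/usr/bin/env Rscript
# Materialize one synthetic study with the default design: 5 control vs 4
# case (TFM) mice on a ~2,000-probe miRNA panel, 57 planted up-regulated
# miRNAs (FC 2-6), control_1 planted to fail spike QC, plus the cytokine
# panel (6 vs 8) and the annotation resources (targets, GMT, reference
# signatures).  All downstream drivers read from results/inputs/.

suppressPackageStartupMessages(library(sevmir))

cfg <- synthetic_config(seed = 1L)
run_cfg <- write_synthetic_inputs(cfg, "results/inputs")
yaml::write_yaml(run_cfg, "results/run_config.yaml")

truth <- jsonlite::read_json("results/inputs/truth.json", simplifyVector = TRUE)
cat(sprintf("simulated %d+%d samples, %d planted DE miRNAs (FC %.2f-%.2f)\n",
            cfg$n_control, cfg$n_case, nrow(truth$de),
            min(truth$de$true_fc), max(truth$de$true_fc)))
qf <- as.data.frame(truth$qc_failures)
cat(sprintf("planted QC failure: %s (%s)\n", qf$sample[1], qf$mode[1]))
cat("inputs written under results/inputs/\n")
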