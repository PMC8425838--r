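#' Count-to-DE workflow
#'
#' Chains the expression stages in their canonical order: sample QC, drop
#' of failed samples, TPM normalization, presence-absence partition (on
#' the full probed universe), low-expression filtering,
#' housekeeping-aggregate normalization, log2 transform, permutation
#' t-test, fold change, DE calls, and the sample clustergram.
#'
#' @param cm a [count_matrix()].
#' @param design a [sample_sheet()].
#' @param thresholds a [qc_thresholds()].
#' @param filter_mode low-expression rule, see [low_expression_filter()].
#' @param alpha,fc_min DE thresholds (defaults 0.01 and 2).
#' @param scheme,B,seed permutation scheme, see [permutation_t_test()].
#' @param pseudocount offset used by housekeeping normalization.
#' @param presence_threshold TPM presence threshold.
#' @return list with `qc`, `counts` (QC-passed), `tpm`, `presence`,
#'   `removed_probes`, `de_table`, `clustergram`, `design` (retained
#'   samples).
#' @export
diffexp_workflow <- function(cm, design,
                             thresholds = qc_thresholds(),
                             filter_mode = "all_samples_below",
                             alpha = 0.01, fc_min = 2.0,
                             scheme = "pooled", B = 9999, seed = 1,
                             pseudocount = 1.0,
                             presence_threshold = 1.0) {
  qc <- sample_qc(cm, thresholds)
  kept <- drop_failed_samples(cm, qc, design)
  design_kept <- design[design$sample_id %in% colnames(kept$counts), , drop = FALSE]
  tpm <- tpm_normalize(kept)
  presence <- presence_sets(tpm, design_kept, threshold = presence_threshold)
  filt <- low_expression_filter(tpm, design_kept, mode = filter_mode)
  norm <- housekeeping_normalize(filt$expr, pseudocount = pseudocount)
  norm_log <- log_transform(norm, pseudocount = 0)
  p <- permutation_t_test(norm_log, design_kept, scheme = scheme, B = B, seed = seed)
  fc <- fold_change(norm, design_kept, pseudocount = 0)
  de <- call_differential(fc, p, annotation = filt$expr$annotation,
                          alpha = alpha, fc_min = fc_min)
  clust <- sample_clustergram(norm_log)
  list(qc = qc, counts = kept, tpm = tpm, presence = presence,
       removed_probes = filt$removed, de_table = de, clustergram = clust,
       design = design_kept)
}

#' Validate a pipeline run configuration
#'
#' A run configuration is a named list (typically read from YAML via
#' [read_run_config()]) with an `inputs` block of file paths (`counts`,
#' `annotation`, `sample_sheet`, and optionally `cytokines` - a named list
#' per fraction - `signatures`, `targets_predicted`, `targets_validated`,
#' `gmt`), a `params` block (`qc`, `alpha`, `fc_min`, `scheme`, `B`,
#' `filter_mode`, `policy`, `score_threshold`, `fdr_cutoff`), an
#' `output_dir`, and a `seed`.  All referenced paths must exist.
#'
#' @param config named list.
#' @return the validated config (with defaults filled in).
#' @export
validate_run_config <- function(config) {
  inputs <- config$inputs %||% stop("config needs an 'inputs' block")
  req <- c("counts", "annotation", "sample_sheet")
  for (f in req) {
    if (is.null(inputs[[f]])) stop(sprintf("config inputs must name '%s'", f))
  }
  paths <- c(unlist(inputs[setdiff(names(inputs), "cytokines")]),
             unlist(inputs$cytokines))
  missing <- paths[!file.exists(paths)]
  if (length(missing)) {
    stop(sprintf("input path does not exist: %s", missing[1]))
  }
  p <- config$params %||% list()
  p$alpha <- p$alpha %||% 0.01
  p$fc_min <- p$fc_min %||% 2.0
  p$scheme <- p$scheme %||% "pooled"
  p$B <- p$B %||% 9999
  p$filter_mode <- p$filter_mode %||% "all_samples_below"
  p$policy <- p$policy %||% "strict"
  p$score_threshold <- p$score_threshold %||% 0.9
  p$fdr_cutoff <- p$fdr_cutoff %||% 0.05
  if (p$alpha <= 0 || p$alpha > 1) stop("alpha must lie in (0, 1]")
  if (p$fc_min < 1) stop("fc_min must be >= 1")
  config$params <- p
  config$seed <- config$seed %||% 1L
  config$output_dir <- config$output_dir %||% "results"
  config
}

#' @rdname validate_run_config
#' @param path path to a YAML run configuration.
#' @export
read_run_config <- function(path) {
  validate_run_config(yaml::read_yaml(path))
}

#' Run the full analysis pipeline from a configuration
#'
#' Executes QC, normalization, presence-absence, differential expression,
#' and - when the corresponding inputs are configured - cytokine panel
#' statistics, cross-cohort overlap of the up-regulated DE miRNAs, and
#' target GO over-representation.  Every stage's table is written under
#' `output_dir` and a machine-readable run report (JSON) summarizes the
#' decisions and counts.
#'
#' @param config a run configuration, see [validate_run_config()].
#' @return the run report, invisibly also written to
#'   `output_dir/run_report.json`.
#' @export
run_pipeline <- function(config) {
  config <- validate_run_config(config)
  out <- config$output_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  p <- config$params
  inputs <- config$inputs

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)), call. = FALSE)
    })
  }

  cm <- stage("read", read_count_matrix(inputs$counts, inputs$annotation))
  design <- stage("read", read_sample_sheet(inputs$sample_sheet))
  qc_thr <- do.call(qc_thresholds, p$qc %||% list())

  wf <- stage("diffexp", diffexp_workflow(
    cm, design, thresholds = qc_thr, filter_mode = p$filter_mode,
    alpha = p$alpha, fc_min = p$fc_min, scheme = p$scheme, B = p$B,
    seed = config$seed))

  utils::write.table(wf$qc, file.path(out, "qc_report.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(probe_id = rownames(wf$tpm$values), wf$tpm$values,
                                check.names = FALSE),
                     file.path(out, "tpm.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(wf$presence$pattern, file.path(out, "presence.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(as.list(wf$presence$counts),
                       file.path(out, "presence_counts.json"), auto_unbox = TRUE)
  utils::write.table(wf$de_table, file.path(out, "de_table.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(wf$clustergram$newick, file.path(out, "clustergram.newick"))
  utils::write.table(as.data.frame(wf$clustergram$dist),
                     file.path(out, "sample_distances.tsv"), sep = "\t", quote = FALSE)

  report <- list(
    seed = config$seed,
    version = as.character(utils::packageVersion("sevmir")),
    decisions = list(
      cv_metric = sprintf("CV of per-sample %s-probe counts", qc_thr$cv_probe_class),
      spike_comparator = ">= max_spike_fraction fails",
      tpm_denominator = "positive_control probes excluded",
      permutation_scheme = p$scheme,
      bh_family = "per fraction (cytokines); mirna probes only (DE)",
      harmonization_policy = p$policy),
    qc = list(n_samples = nrow(wf$qc),
              dropped = wf$qc$sample_id[!wf$qc$pass]),
    presence = as.list(wf$presence$counts),
    n_probes_filtered = length(wf$removed_probes),
    n_de_calls = sum(wf$de_table$de_call))

  de_up <- wf$de_table$probe_id[wf$de_table$de_call & wf$de_table$direction == "up"]

  if (!is.null(inputs$cytokines)) {
    tables <- lapply(inputs$cytokines, read_cytokine_table)
    cyt <- stage("cytokines", analyze_cytokine_panel(tables, design = stage(
      "cytokines", read_sample_sheet(inputs$cytokine_sample_sheet %||% inputs$sample_sheet))))
    utils::write.table(cyt, file.path(out, "cytokine_stats.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    report$cytokines <- list(n_significant = sum(cyt$significant))
  }

  if (!is.null(inputs$signatures)) {
    refs <- stage("overlap", read_signatures(inputs$signatures))
    om <- stage("overlap", overlap_matrix(de_up, refs, policy = p$policy))
    write_overlap_table(om, file.path(out, "overlap.tsv"))
    jsonlite::write_json(c(as.list(om$column_counts),
                           list(any_reference = om$any_reference_count)),
                         file.path(out, "overlap_counts.json"), auto_unbox = TRUE)
    report$overlap <- as.list(om$column_counts)
  }

  if (!is.null(inputs$targets_predicted) && !is.null(inputs$targets_validated) &&
      !is.null(inputs$gmt)) {
    pred <- stage("enrichment", read_target_table(inputs$targets_predicted))
    val <- stage("enrichment", read_target_table(inputs$targets_validated))
    gsc <- stage("enrichment", read_gmt(inputs$gmt))
    sel <- stage("enrichment",
                 consolidate_targets(de_up, pred, val, threshold = p$score_threshold))
    enr <- stage("enrichment",
                 hypergeom_enrich(sel$genes, gsc, fdr_cutoff = p$fdr_cutoff))
    utils::write.table(enr, file.path(out, "enrichment.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    sig <- enr[enr$significant, , drop = FALSE]
    tg <- term_graph(top_terms(sig, 30))
    utils::write.table(tg$edges, file.path(out, "term_graph_edges.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    writeLines(tg$newick, file.path(out, "term_dendrogram.newick"))
    report$enrichment <- list(n_targets = length(sel$genes),
                              n_significant_terms = sum(enr$significant))
  }

  jsonlite::write_json(report, file.path(out, "run_report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(report)
}

#' Write a complete synthetic input bundle to disk
#'
#' Materializes one synthetic study (counts, annotation, sample sheet,
#' cytokine tables, reference signatures, target tables, GMT) plus
#' `truth.json` under a directory, and returns a run configuration pointing
#' at it.  This is the file-level entry point the pipeline can be exercised
#' against end to end.
#'
#' @param config a [synthetic_config()].
#' @param dir output directory.
#' @return a run configuration list (see [validate_run_config()]).
#' @export
write_synthetic_inputs <- function(config = synthetic_config(), dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sim <- simulate_counts(config)
  cyt <- simulate_cytokines(config)
  ann <- simulate_annotation(config, sim$truth)
  path <- function(f) file.path(dir, f)
  write_count_matrix(sim$counts, path("counts.tsv"), path("annotation.tsv"))
  write_sample_sheet(sim$samples, path("samples.tsv"))
  write_sample_sheet(cyt$samples, path("cytokine_samples.tsv"))
  write_cytokine_table(cyt$sev_plus, path("cytokines_sev_plus.tsv"))
  write_cytokine_table(cyt$sev_minus, path("cytokines_sev_minus.tsv"))
  write_signatures(ann$signatures, path("signatures.tsv"))
  utils::write.table(ann$predicted, path("targets_predicted.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(ann$validated, path("targets_validated.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_gmt(ann$gene_sets, path("gene_sets.gmt"))
  jsonlite::write_json(list(de = sim$truth$de,
                            qc_failures = sim$truth$qc_failures,
                            cytokine_shift_sev_plus = as.list(cyt$truth$shift_sev_plus),
                            cytokine_shift_sev_minus = as.list(cyt$truth$shift_sev_minus)),
                       path("truth.json"), auto_unbox = TRUE, digits = NA)
  list(inputs = list(counts = path("counts.tsv"),
                     annotation = path("annotation.tsv"),
                     sample_sheet = path("samples.tsv"),
                     cytokine_sample_sheet = path("cytokine_samples.tsv"),
                     cytokines = list(sev_plus = path("cytokines_sev_plus.tsv"),
                                      sev_minus = path("cytokines_sev_minus.tsv")),
                     signatures = path("signatures.tsv"),
                     targets_predicted = path("targets_predicted.tsv"),
                     targets_validated = path("targets_validated.tsv"),
                     gmt = path("gene_sets.gmt")),
       params = list(),
       output_dir = file.path(dir, "results"),
       seed = config$seed)
}
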