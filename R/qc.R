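#' Sample QC thresholds
#'
#' Defaults follow the panel's published acceptance rules: at least 10^6
#' total reads, less than 10% of reads from the positive-control spike, and
#' a coefficient of variation below 15%.  The CV is computed across the
#' sample's housekeeping-probe counts by default (the intended invariant
#' signal of the panel); set `cv_probe_class = "positive_control"` to
#' compute it over the spike probes instead.  The spike comparator fails at
#' `>= max_spike_fraction` (the conservative reading of the rule).
#'
#' @param min_total_reads minimum acceptable column sum.
#' @param max_spike_fraction spike-read fraction at or above which a sample
#'   fails.
#' @param max_cv CV at or above which a sample fails.
#' @param cv_probe_class probe class over which the within-sample CV is
#'   taken.
#' @return list of class `qc_thresholds`.
#' @export
qc_thresholds <- function(min_total_reads = 1e6, max_spike_fraction = 0.10,
                          max_cv = 0.15,
                          cv_probe_class = c("housekeeping", "positive_control")) {
  assert_scalar_number(min_total_reads, "min_total_reads", positive = TRUE)
  if (max_spike_fraction <= 0 || max_spike_fraction >= 1) stop("max_spike_fraction must be in (0,1)")
  if (max_cv <= 0 || max_cv >= 1) stop("max_cv must be in (0,1)")
  structure(list(min_total_reads = min_total_reads,
                 max_spike_fraction = max_spike_fraction,
                 max_cv = max_cv,
                 cv_probe_class = match.arg(cv_probe_class)),
            class = "qc_thresholds")
}

#' Per-sample quality control
#'
#' Computes, for every sample: total reads (column sum), the fraction of
#' reads from positive-control spike probes, and the coefficient of
#' variation (sd/mean) of the sample's counts over the CV probe class.  A
#' sample fails if total reads fall below `min_total_reads`, the spike
#' fraction reaches `max_spike_fraction`, or the CV reaches `max_cv`.
#'
#' @param cm a [count_matrix()] with annotated probe classes.
#' @param thresholds a [qc_thresholds()].
#' @return `data.frame` of class `sev_qc` with columns `sample_id`,
#'   `total_reads`, `spike_fraction`, `cv`, `pass`, `reasons`
#'   (semicolon-separated failure reasons, empty when passing).  The
#'   thresholds used are attached as attribute `"thresholds"`.
#' @export
sample_qc <- function(cm, thresholds = qc_thresholds()) {
  stopifnot(inherits(cm, "sev_counts"), inherits(thresholds, "qc_thresholds"))
  spike <- cm$annotation$probe_class == "positive_control"
  if (!any(spike)) {
    stop(paste("no positive_control probes found: the spike-fraction check cannot run.",
               "Annotate spike probes or use thresholds with max_spike_fraction",
               "effectively disabled (e.g. 0.999...) after reviewing the panel."))
  }
  cv_rows <- cm$annotation$probe_class == thresholds$cv_probe_class
  if (!any(cv_rows)) {
    stop(sprintf("no probes of class '%s' for the CV check", thresholds$cv_probe_class))
  }
  total <- colSums(cm$counts)
  spike_frac <- colSums(cm$counts[spike, , drop = FALSE]) / total
  cvm <- cm$counts[cv_rows, , drop = FALSE]
  cv <- apply(cvm, 2, stats::sd) / colMeans(cvm)
  reasons <- vapply(seq_along(total), function(j) {
    r <- character()
    if (total[j] < thresholds$min_total_reads) r <- c(r, "low_total_reads")
    if (spike_frac[j] >= thresholds$max_spike_fraction) r <- c(r, "high_spike")
    if (cv[j] >= thresholds$max_cv) r <- c(r, "high_cv")
    paste(r, collapse = ";")
  }, "")
  out <- data.frame(sample_id = colnames(cm$counts), total_reads = unname(total),
                    spike_fraction = unname(spike_frac), cv = unname(cv),
                    pass = !nzchar(reasons), reasons = reasons,
                    stringsAsFactors = FALSE)
  attr(out, "thresholds") <- thresholds
  class(out) <- c("sev_qc", class(out))
  out
}

#' Drop QC-failed samples from a count matrix
#'
#' @param cm the [count_matrix()] the report was computed on.
#' @param report a [sample_qc()] report.
#' @param design optional [sample_sheet()]; when given, errors if dropping
#'   failures would leave fewer than two samples in either group.
#' @return a `sev_counts` with failing columns removed.
#' @export
drop_failed_samples <- function(cm, report, design = NULL) {
  stopifnot(inherits(cm, "sev_counts"), inherits(report, "sev_qc"))
  if (!setequal(report$sample_id, colnames(cm$counts))) {
    stop("QC report does not cover the samples of this count matrix")
  }
  keep <- report$sample_id[report$pass]
  out <- count_matrix(cm$counts[, keep, drop = FALSE], cm$annotation)
  if (!is.null(design)) check_design(out, design, min_per_group = 2L)
  out
}

#' TPM normalization
#'
#' Scales each sample's length-normalized counts to transcripts per
#' kilobase million: `rate = count / length_kb` per probe, then each sample
#' column is scaled to sum to 10^6.  Positive-control spike probes are
#' excluded from both the output and the scaling denominator: their
#' abundance is a property of the assay, not of the sample, and would
#' otherwise distort the biological proportions.  Housekeeping probes stay
#' in.  With all probe lengths equal (the default 1 kb), TPM coincides with
#' counts-per-million.
#'
#' @param cm a [count_matrix()].
#' @return an expression matrix of class `sev_expr` in unit `"tpm"`.
#' @export
tpm_normalize <- function(cm) {
  stopifnot(inherits(cm, "sev_counts"))
  keep <- cm$annotation$probe_class != "positive_control"
  counts <- cm$counts[keep, , drop = FALSE]
  ann <- cm$annotation[keep, , drop = FALSE]
  rate <- counts / ann$length_kb
  denom <- colSums(rate)
  if (any(denom == 0)) {
    stop(sprintf("sample '%s' has no reads outside positive controls; cannot TPM-normalize",
                 colnames(counts)[denom == 0][1]))
  }
  tpm <- sweep(rate, 2, denom, `/`) * 1e6
  expression_matrix(tpm, ann, unit = "tpm",
                    provenance = "tpm_normalize: positive_control probes excluded from denominator")
}

#' @noRd
expression_matrix <- function(values, annotation, unit, pseudocount = NA_real_,
                              provenance = character(), dropped_samples = character()) {
  structure(list(values = values, annotation = annotation, unit = unit,
                 pseudocount = pseudocount, provenance = provenance,
                 dropped_samples = dropped_samples),
            class = "sev_expr")
}

#' @export
print.sev_expr <- function(x, ...) {
  cat(sprintf("sev_expr [%s]: %d probes x %d samples\n", x$unit,
              nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Log2 transform of a TPM matrix
#'
#' @param em a `sev_expr` in unit `"tpm"` (or `"hk_relative"`).
#' @param pseudocount non-negative offset added before taking log2;
#'   default 1.  A pseudocount of 0 is allowed only when the matrix has no
#'   zeros.
#' @return a `sev_expr` in unit `"log2tpm"` (or `"log2_hk_relative"`).
#' @export
log_transform <- function(em, pseudocount = 1.0) {
  stopifnot(inherits(em, "sev_expr"))
  if (!em$unit %in% c("tpm", "hk_relative")) {
    stop(sprintf("log_transform expects a linear-scale matrix, got unit '%s'", em$unit))
  }
  if (!is.numeric(pseudocount) || pseudocount < 0) stop("pseudocount must be >= 0")
  if (pseudocount == 0 && any(em$values == 0)) {
    stop("pseudocount 0 with zero values present; choose a positive pseudocount")
  }
  out <- em
  out$values <- log2(em$values + pseudocount)
  out$unit <- if (em$unit == "tpm") "log2tpm" else "log2_hk_relative"
  out$pseudocount <- pseudocount
  out$provenance <- c(em$provenance, sprintf("log2 transform, pseudocount %g", pseudocount))
  out
}

#' Low-expression filter
#'
#' In the default `all_samples_below` mode a probe is removed only if every
#' retained sample in both groups has TPM below the threshold.  The
#' `any_sample_below` variant removes a probe whenever any sample falls
#' below the threshold (the stricter rule some panel reports apply before
#' testing).  Housekeeping probes are never removed: they are needed for
#' normalization downstream.
#'
#' @param em a `sev_expr` in unit `"tpm"`.
#' @param design optional [sample_sheet()] (kept for interface symmetry;
#'   both modes quantify over all retained samples).
#' @param mode `"all_samples_below"` (default) or `"any_sample_below"`.
#' @param threshold TPM threshold, default 1.
#' @return list with `expr` (filtered `sev_expr`) and `removed` (character
#'   vector of removed probe ids).
#' @export
low_expression_filter <- function(em, design = NULL,
                                  mode = c("all_samples_below", "any_sample_below"),
                                  threshold = 1.0) {
  stopifnot(inherits(em, "sev_expr"))
  if (em$unit != "tpm") stop("low_expression_filter operates on TPM values")
  mode <- match.arg(mode)
  below <- em$values < threshold
  drop <- if (mode == "all_samples_below") {
    rowSums(below) == ncol(em$values)
  } else {
    rowSums(below) > 0
  }
  drop <- drop & em$annotation$probe_class != "housekeeping"
  removed <- rownames(em$values)[drop]
  out <- em
  out$values <- em$values[!drop, , drop = FALSE]
  out$annotation <- em$annotation[!drop, , drop = FALSE]
  out$provenance <- c(em$provenance,
                      sprintf("low_expression_filter (%s, TPM < %g): removed %d probes",
                              mode, threshold, length(removed)))
  list(expr = out, removed = removed)
}
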