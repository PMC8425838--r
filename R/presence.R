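#' Group-wise presence calls and Venn partition
#'
#' A miRNA is called present in a group if every retained replicate of that
#' group has TPM at or above the threshold.  The analysis runs on the full
#' probed universe (before low-expression filtering), as the published
#' partition does; housekeeping and positive-control probes are excluded
#' from the Venn counts and reported separately via the per-probe pattern
#' table.
#'
#' @param em a `sev_expr` in unit `"tpm"`, restricted to QC-passed samples.
#' @param design a [sample_sheet()] covering the samples of `em`.
#' @param threshold presence threshold in TPM, default 1 (comparator `>=`).
#' @return object of class `presence_partition`: a list with `pattern`
#'   (per-probe `data.frame`: probe_id, probe_class, present_control,
#'   present_case, pattern), `counts` (named integer vector over miRNA
#'   probes: `common`, `unique_control`, `unique_case`,
#'   `present_in_neither`), `threshold`, `n_samples` per group.
#' @export
presence_sets <- function(em, design, threshold = 1.0) {
  stopifnot(inherits(em, "sev_expr"))
  if (em$unit != "tpm") stop("presence_sets operates on TPM values")
  grp <- design$group[match(colnames(em$values), design$sample_id)]
  if (anyNA(grp)) {
    stop(sprintf("sample '%s' missing from the sample sheet",
                 colnames(em$values)[is.na(grp)][1]))
  }
  for (g in c("control", "case")) {
    if (!any(grp == g)) stop(sprintf("empty group '%s' in presence analysis", g))
  }
  min_by_group <- function(g) {
    apply(em$values[, grp == g, drop = FALSE], 1, min)
  }
  pres_ctrl <- min_by_group("control") >= threshold
  pres_case <- min_by_group("case") >= threshold
  pattern <- ifelse(pres_ctrl & pres_case, "common",
             ifelse(pres_ctrl, "unique_control",
             ifelse(pres_case, "unique_case", "present_in_neither")))
  tab <- data.frame(probe_id = rownames(em$values),
                    probe_class = em$annotation$probe_class,
                    present_control = pres_ctrl, present_case = pres_case,
                    pattern = pattern, stringsAsFactors = FALSE,
                    row.names = NULL)
  mir <- tab[tab$probe_class == "mirna", ]
  counts <- c(common = sum(mir$pattern == "common"),
              unique_control = sum(mir$pattern == "unique_control"),
              unique_case = sum(mir$pattern == "unique_case"),
              present_in_neither = sum(mir$pattern == "present_in_neither"))
  structure(list(pattern = tab, counts = counts, threshold = threshold,
                 n_samples = table(grp)),
            class = "presence_partition")
}

#' @export
print.presence_partition <- function(x, ...) {
  cat(sprintf("presence_partition (TPM >= %g): %d common, %d unique to control, %d unique to case, %d in neither\n",
              x$threshold, x$counts[["common"]], x$counts[["unique_control"]],
              x$counts[["unique_case"]], x$counts[["present_in_neither"]]))
  invisible(x)
}

#' Two-group Venn counts of a presence partition
#'
#' @param partition a [presence_sets()] result.
#' @return named integer vector `(n_common, n_unique_control,
#'   n_unique_case)` over miRNA probes.
#' @export
venn_counts <- function(partition) {
  stopifnot(inherits(partition, "presence_partition"))
  if (length(dim(partition$n_samples)) > 1 || length(partition$n_samples) > 2) {
    stop("venn_counts supports two-group designs only")
  }
  c(n_common = unname(partition$counts[["common"]]),
    n_unique_control = unname(partition$counts[["unique_control"]]),
    n_unique_case = unname(partition$counts[["unique_case"]]))
}
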