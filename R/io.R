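#' Probe annotation table
#'
#' Builds and validates the probe annotation used throughout the pipeline.
#' Probes fall into one of four classes: `mirna` (the biological targets of
#' the nuclease-protection panel), `housekeeping` (the stable aggregate used
#' for fold-change normalization), `positive_control` (spiked-in probes used
#' for sample QC), and `other`.  `length_kb` is the probe target length in
#' kilobases used by TPM normalization; nuclease-protection probes are of
#' uniform length, so it defaults to 1.0 (TPM then reduces to
#' counts-per-million).
#'
#' @param probe_id character vector of unique probe identifiers.
#' @param probe_class character vector in
#'   `c("mirna", "housekeeping", "positive_control", "other")`; recycled if
#'   length 1.
#' @param length_kb positive numeric vector of probe lengths in kilobases;
#'   recycled if length 1.
#' @return a `data.frame` with columns `probe_id`, `probe_class`,
#'   `length_kb`.
#' @export
probe_annotation <- function(probe_id, probe_class = "mirna", length_kb = 1.0) {
  probe_id <- as.character(probe_id)
  if (anyDuplicated(probe_id)) {
    dup <- unique(probe_id[duplicated(probe_id)])
    stop(sprintf("duplicate probe_id(s): %s", paste(utils::head(dup, 5), collapse = ", ")))
  }
  probe_class <- rep_len(as.character(probe_class), length(probe_id))
  valid <- c("mirna", "housekeeping", "positive_control", "other")
  bad <- setdiff(unique(probe_class), valid)
  if (length(bad)) stop(sprintf("unknown probe_class: %s", paste(bad, collapse = ", ")))
  length_kb <- rep_len(as.numeric(length_kb), length(probe_id))
  if (any(!is.finite(length_kb) | length_kb <= 0)) {
    stop("length_kb must be positive and finite for every probe")
  }
  data.frame(probe_id = probe_id, probe_class = probe_class,
             length_kb = length_kb, stringsAsFactors = FALSE)
}

#' Count matrix container
#'
#' Couples a non-negative integer probe-by-sample count matrix with its probe
#' annotation.  This is the raw input of the pipeline.
#'
#' @param counts integer matrix, probes in rows (rownames = probe ids),
#'   samples in columns (colnames = sample ids).
#' @param annotation probe annotation `data.frame` as from
#'   [probe_annotation()]; probes present in `counts` but not annotated are
#'   assigned class `mirna` and length 1.0 kb with a warning.
#' @return an object of class `sev_counts` with elements `counts` and
#'   `annotation` (row-aligned with `counts`).
#' @export
count_matrix <- function(counts, annotation = NULL) {
  if (!is.matrix(counts)) counts <- as.matrix(counts)
  if (is.null(rownames(counts))) stop("counts must have probe ids as rownames")
  if (is.null(colnames(counts))) stop("counts must have sample ids as colnames")
  if (anyDuplicated(colnames(counts))) stop("sample names must be unique")
  bad <- which(!is.finite(counts) | counts < 0 | counts != round(counts), arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf("counts must be non-negative integers; offending cell: probe '%s', sample '%s' (value %s)",
                 rownames(counts)[bad[1, 1]], colnames(counts)[bad[1, 2]],
                 format(counts[bad[1, 1], bad[1, 2]])))
  }
  storage.mode(counts) <- "double"  # counts can exceed .Machine$integer.max in total
  if (is.null(annotation)) {
    annotation <- probe_annotation(rownames(counts))
  } else {
    missing <- setdiff(rownames(counts), annotation$probe_id)
    if (length(missing)) {
      warning(sprintf("%d probe(s) missing from annotation; defaulting to class 'mirna', length 1.0 kb (e.g. %s)",
                      length(missing), paste(utils::head(missing, 3), collapse = ", ")))
      annotation <- rbind(annotation, probe_annotation(missing))
    }
    extra <- setdiff(annotation$probe_id, rownames(counts))
    if (length(extra)) annotation <- annotation[!annotation$probe_id %in% extra, , drop = FALSE]
    annotation <- annotation[match(rownames(counts), annotation$probe_id), , drop = FALSE]
    rownames(annotation) <- NULL
  }
  if (!any(annotation$probe_class == "mirna")) {
    stop("a usable panel must contain at least one probe of class 'mirna'")
  }
  structure(list(counts = counts, annotation = annotation), class = "sev_counts")
}

#' @export
print.sev_counts <- function(x, ...) {
  cat(sprintf("sev_counts: %d probes x %d samples (%s)\n",
              nrow(x$counts), ncol(x$counts),
              paste(sprintf("%d %s", table(x$annotation$probe_class),
                            names(table(x$annotation$probe_class))), collapse = ", ")))
  invisible(x)
}

#' @export
dim.sev_counts <- function(x) dim(x$counts)

#' Read a probe count matrix (and annotation) from TSV
#'
#' The counts file is a delimited table whose first column holds probe ids
#' and whose remaining columns (named in the header) hold per-sample integer
#' counts.  The annotation file has columns `probe_id`, `probe_class` and
#' optionally `length_kb`.
#'
#' @param path path to the counts table.
#' @param annotation_path optional path to the probe annotation table.
#' @param sep field delimiter, tab by default.
#' @return a [count_matrix()] object.
#' @export
read_count_matrix <- function(path, annotation_path = NULL, sep = "\t") {
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          stringsAsFactors = FALSE, quote = "", comment.char = "")
  if (ncol(df) < 2) stop(sprintf("%s: expected a probe id column plus >=1 sample column", path))
  probe_id <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) {
    bad <- which(is.na(suppressWarnings(apply(df[, -1, drop = FALSE], 2, as.numeric))), arr.ind = TRUE)
    stop(sprintf("%s: non-numeric count at probe '%s', sample '%s'",
                 path, probe_id[bad[1, 1]], colnames(df)[-1][bad[1, 2]]))
  }
  rownames(m) <- probe_id
  ann <- if (!is.null(annotation_path)) read_probe_annotation(annotation_path, sep = sep) else NULL
  count_matrix(m, ann)
}

#' @rdname read_count_matrix
#' @param cm a `sev_counts` object.
#' @export
write_count_matrix <- function(cm, path, annotation_path = NULL, sep = "\t") {
  stopifnot(inherits(cm, "sev_counts"))
  df <- data.frame(probe_id = rownames(cm$counts), cm$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  if (!is.null(annotation_path)) {
    utils::write.table(cm$annotation, annotation_path, sep = sep, quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' @rdname probe_annotation
#' @param path path to an annotation table with columns `probe_id`,
#'   `probe_class`, and optionally `length_kb`.
#' @param sep field delimiter.
#' @export
read_probe_annotation <- function(path, sep = "\t") {
  df <- utils::read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE,
                          quote = "", comment.char = "")
  req <- c("probe_id", "probe_class")
  if (!all(req %in% names(df))) {
    stop(sprintf("%s: annotation needs columns %s", path, paste(req, collapse = ", ")))
  }
  probe_annotation(df$probe_id, df$probe_class,
                   if ("length_kb" %in% names(df)) df$length_kb else 1.0)
}

#' Read / write the sample sheet
#'
#' The sample sheet carries the group design (`control` vs `case`) and the
#' optional total protein content used for cytokine normalization.  Missing
#' protein content is allowed at parse time; it only errors when protein
#' normalization is actually requested.
#'
#' @param path path to a delimited table with columns `sample_id`, `group`
#'   and optionally `protein_mg_per_ml`.
#' @param sep field delimiter.
#' @return `data.frame` with columns `sample_id`, `group`,
#'   `protein_mg_per_ml`.
#' @export
read_sample_sheet <- function(path, sep = "\t") {
  df <- utils::read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE,
                          quote = "", comment.char = "")
  sample_sheet(df$sample_id, df$group,
               if ("protein_mg_per_ml" %in% names(df)) df$protein_mg_per_ml else NA_real_)
}

#' @rdname read_sample_sheet
#' @param sample_id character vector of sample ids.
#' @param group character vector, one of `"control"`/`"case"` per sample.
#' @param protein_mg_per_ml numeric vector of total protein (mg/mL) or `NA`.
#' @export
sample_sheet <- function(sample_id, group, protein_mg_per_ml = NA_real_) {
  sample_id <- as.character(sample_id)
  if (anyDuplicated(sample_id)) stop("sample_id values must be unique")
  group <- as.character(group)
  bad <- setdiff(unique(group), c("control", "case"))
  if (length(bad)) stop(sprintf("group must be 'control' or 'case'; got: %s", paste(bad, collapse = ", ")))
  protein_mg_per_ml <- rep_len(as.numeric(protein_mg_per_ml), length(sample_id))
  if (any(!is.na(protein_mg_per_ml) & protein_mg_per_ml <= 0)) {
    stop("protein_mg_per_ml must be positive where present")
  }
  data.frame(sample_id = sample_id, group = group,
             protein_mg_per_ml = protein_mg_per_ml, stringsAsFactors = FALSE)
}

#' @rdname read_sample_sheet
#' @param sheet a sample sheet `data.frame`.
#' @export
write_sample_sheet <- function(sheet, path, sep = "\t") {
  utils::write.table(sheet, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Check that a count matrix and sample sheet agree
#' @noRd
check_design <- function(cm, sheet, min_per_group = 2L) {
  missing <- setdiff(colnames(cm$counts), sheet$sample_id)
  if (length(missing)) {
    stop(sprintf("sample(s) absent from sample sheet: %s", paste(missing, collapse = ", ")))
  }
  grp <- sheet$group[match(colnames(cm$counts), sheet$sample_id)]
  tab <- table(factor(grp, levels = c("control", "case")))
  if (any(tab < min_per_group)) {
    stop(sprintf("each group needs >= %d samples for inference (have control=%d, case=%d)",
                 min_per_group, tab[["control"]], tab[["case"]]))
  }
  invisible(grp)
}

#' Read / write gene-set collections in GMT format
#'
#' Standard GMT dialect: one set per line, tab-separated fields
#' `term_id`, `description`, then gene symbols.  Duplicate genes within one
#' term are collapsed.
#'
#' @param path path to the GMT file.
#' @return an object of class `gene_set_collection`: a list with `sets`
#'   (named list of character vectors), `descriptions` (named character) and
#'   `background` (`NULL` unless set explicitly).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) {
    warning(sprintf("%s: empty GMT file", path))
    return(gene_set_collection(stats::setNames(list(), character())))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf < 3)) {
    stop(sprintf("%s: line %d has %d field(s); GMT requires term, description, >=1 gene",
                 path, which(nf < 3)[1], nf[which(nf < 3)[1]]))
  }
  ids <- vapply(parts, `[[`, "", 1L)
  if (anyDuplicated(ids)) stop(sprintf("%s: duplicate term id '%s'", path, ids[duplicated(ids)][1]))
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(sets) <- ids
  desc <- stats::setNames(vapply(parts, `[[`, "", 2L), ids)
  gene_set_collection(sets, desc)
}

#' @rdname read_gmt
#' @param sets named list of character gene vectors.
#' @param descriptions optional named character of term descriptions.
#' @param background optional explicit gene universe; must contain every
#'   gene of every set.
#' @export
gene_set_collection <- function(sets, descriptions = NULL, background = NULL) {
  if (is.null(names(sets)) && length(sets)) stop("sets must be a named list")
  sets <- lapply(sets, function(g) unique(as.character(g)))
  if (any(lengths(sets) == 0)) {
    stop(sprintf("empty gene set: %s", names(sets)[lengths(sets) == 0][1]))
  }
  if (is.null(descriptions)) descriptions <- stats::setNames(names(sets), names(sets))
  if (!is.null(background)) {
    background <- unique(as.character(background))
    stray <- setdiff(unique(unlist(sets)), background)
    if (length(stray)) {
      stop(sprintf("background must contain every annotated gene; missing e.g. %s",
                   paste(utils::head(stray, 3), collapse = ", ")))
    }
  }
  structure(list(sets = sets, descriptions = descriptions, background = background),
            class = "gene_set_collection")
}

#' @rdname read_gmt
#' @param gsc a `gene_set_collection`.
#' @export
write_gmt <- function(gsc, path) {
  stopifnot(inherits(gsc, "gene_set_collection"))
  lines <- vapply(names(gsc$sets), function(id) {
    paste(c(id, gsc$descriptions[[id]] %||% id, gsc$sets[[id]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Read / write reference miRNA signature tables
#'
#' Each row of the signature file describes one prior study: `study_id`,
#' `sample_type` (e.g. exosome, whole_blood), `comparison`, `treatment`, and
#' a comma-separated list of miRNA names reported as significantly altered
#' in that study.  Names are stored verbatim (surrounding whitespace
#' stripped); cross-study harmonization is deferred to [harmonize_mirna()].
#'
#' @param path path to the signature TSV.
#' @param sep field delimiter.
#' @return a named list (by `study_id`) of signature entries, each a list
#'   with `study_id`, `sample_type`, `comparison`, `treatment`, `mirnas`.
#' @export
read_signatures <- function(path, sep = "\t") {
  df <- utils::read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE,
                          quote = "", comment.char = "")
  req <- c("study_id", "sample_type", "comparison", "treatment", "mirnas")
  if (!all(req %in% names(df))) {
    stop(sprintf("%s: signature table needs columns %s", path, paste(req, collapse = ", ")))
  }
  if (anyDuplicated(df$study_id)) {
    stop(sprintf("%s: duplicate study_id '%s'", path, df$study_id[duplicated(df$study_id)][1]))
  }
  df$mirnas <- as.character(df$mirnas)
  df$mirnas[is.na(df$mirnas)] <- ""
  sigs <- lapply(seq_len(nrow(df)), function(i) {
    mirnas <- trimws(strsplit(df$mirnas[i], ",", fixed = TRUE)[[1]])
    mirnas <- mirnas[nzchar(mirnas)]
    if (!length(mirnas)) warning(sprintf("%s: study '%s' has an empty miRNA list", path, df$study_id[i]))
    if (anyDuplicated(mirnas)) {
      stop(sprintf("%s: duplicate miRNA name within study '%s'", path, df$study_id[i]))
    }
    list(study_id = df$study_id[i], sample_type = df$sample_type[i],
         comparison = df$comparison[i], treatment = df$treatment[i], mirnas = mirnas)
  })
  stats::setNames(sigs, df$study_id)
}

#' @rdname read_signatures
#' @param signatures a list of signature entries as returned by
#'   [read_signatures()].
#' @export
write_signatures <- function(signatures, path, sep = "\t") {
  df <- data.frame(
    study_id = vapply(signatures, `[[`, "", "study_id"),
    sample_type = vapply(signatures, `[[`, "", "sample_type"),
    comparison = vapply(signatures, `[[`, "", "comparison"),
    treatment = vapply(signatures, `[[`, "", "treatment"),
    mirnas = vapply(signatures, function(s) paste(s$mirnas, collapse = ","), ""),
    stringsAsFactors = FALSE
  )
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a miRNA-target table
#'
#' Columns: `mirna`, `gene`, `score` (real or empty; e.g. a TargetScan
#' aggregate P_CT for predicted records), `evidence`
#' (`predicted` or `validated`).  The (`mirna`, `gene`) pair must be unique
#' within each evidence class.
#'
#' @param path path to the target TSV.
#' @param sep field delimiter.
#' @return `data.frame` with columns `mirna`, `gene`, `score`, `evidence`.
#' @export
read_target_table <- function(path, sep = "\t") {
  df <- utils::read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE,
                          quote = "", comment.char = "")
  req <- c("mirna", "gene", "evidence")
  if (!all(req %in% names(df))) {
    stop(sprintf("%s: target table needs columns %s", path, paste(req, collapse = ", ")))
  }
  if (!"score" %in% names(df)) df$score <- NA_real_
  target_table(df$mirna, df$gene, df$score, df$evidence)
}

#' @rdname read_target_table
#' @param mirna,gene,score,evidence vectors defining the records.
#' @export
target_table <- function(mirna, gene, score = NA_real_, evidence = "predicted") {
  df <- data.frame(mirna = as.character(mirna), gene = as.character(gene),
                   score = as.numeric(score),
                   evidence = as.character(evidence), stringsAsFactors = FALSE)
  bad <- setdiff(unique(df$evidence), c("predicted", "validated"))
  if (length(bad)) stop(sprintf("evidence must be 'predicted' or 'validated'; got %s", paste(bad, collapse = ", ")))
  key <- paste(df$mirna, df$gene, df$evidence, sep = "\r")
  if (anyDuplicated(key)) {
    d <- df[duplicated(key), ][1, ]
    stop(sprintf("duplicate (%s, %s) record in evidence class '%s'", d$mirna, d$gene, d$evidence))
  }
  df
}

#' Cytokine concentration table
#'
#' Holds per-analyte, per-sample concentrations from a multiplex immunoassay
#' panel together with below-LLOQ censoring flags and the per-analyte lower
#' limit of quantitation.  Censored entries carry `NA` concentration until
#' [impute_lloq()] assigns them the LLOQ.
#'
#' @param conc numeric matrix, analytes in rows, samples in columns
#'   (concentrations, pg/mL); censored cells may be `NA`.
#' @param censored logical matrix of the same shape flagging below-LLOQ
#'   cells; defaults to `is.na(conc)`.
#' @param lloq named numeric vector of per-analyte LLOQs (pg/mL).
#' @param unit concentration unit, `"pg_per_ml"` (raw) or `"pg_per_mg"`
#'   (protein-normalized).
#' @return object of class `cytokine_table`.
#' @export
cytokine_table <- function(conc, censored = NULL, lloq = NULL, unit = "pg_per_ml") {
  if (!is.matrix(conc)) conc <- as.matrix(conc)
  if (is.null(rownames(conc))) stop("conc must have analyte names as rownames")
  if (is.null(colnames(conc))) stop("conc must have sample ids as colnames")
  if (is.null(censored)) censored <- is.na(conc)
  censored <- censored | is.na(conc)
  if (!identical(dim(censored), dim(conc))) stop("censored must match conc in shape")
  if (any(conc[!censored] < 0, na.rm = TRUE)) stop("concentrations must be >= 0 unless censored")
  if (!is.null(lloq)) {
    lloq <- lloq[rownames(conc)]
    if (any(is.na(lloq) & rowSums(censored) > 0)) {
      stop(sprintf("censored entries present for analyte '%s' but no LLOQ given",
                   rownames(conc)[is.na(lloq) & rowSums(censored) > 0][1]))
    }
    if (any(!is.na(lloq) & lloq <= 0)) stop("lloq must be positive")
  } else {
    lloq <- stats::setNames(rep(NA_real_, nrow(conc)), rownames(conc))
  }
  unit <- match.arg(unit, c("pg_per_ml", "pg_per_mg"))
  structure(list(conc = conc, censored = censored, lloq = lloq, unit = unit),
            class = "cytokine_table")
}

#' @rdname cytokine_table
#' @param path path to a long-format TSV with columns `analyte`, `sample_id`,
#'   `concentration`, `censored`, `lloq`.
#' @param sep field delimiter.
#' @export
read_cytokine_table <- function(path, sep = "\t") {
  df <- utils::read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE,
                          quote = "", comment.char = "")
  req <- c("analyte", "sample_id", "concentration", "censored", "lloq")
  if (!all(req %in% names(df))) {
    stop(sprintf("%s: cytokine table needs columns %s", path, paste(req, collapse = ", ")))
  }
  analytes <- unique(df$analyte)
  samples <- unique(df$sample_id)
  conc <- matrix(NA_real_, length(analytes), length(samples),
                 dimnames = list(analytes, samples))
  cens <- matrix(FALSE, length(analytes), length(samples),
                 dimnames = list(analytes, samples))
  conc[cbind(match(df$analyte, analytes), match(df$sample_id, samples))] <- df$concentration
  cens[cbind(match(df$analyte, analytes), match(df$sample_id, samples))] <- as.logical(df$censored)
  lloq <- stats::setNames(df$lloq[!duplicated(df$analyte)], df$analyte[!duplicated(df$analyte)])
  conc[cens] <- NA_real_
  cytokine_table(conc, cens, lloq)
}

#' @rdname cytokine_table
#' @param ct a `cytokine_table`.
#' @export
write_cytokine_table <- function(ct, path, sep = "\t") {
  stopifnot(inherits(ct, "cytokine_table"))
  idx <- expand.grid(analyte = rownames(ct$conc), sample_id = colnames(ct$conc),
                     stringsAsFactors = FALSE)
  df <- data.frame(idx,
                   concentration = as.vector(ct$conc),
                   censored = as.vector(ct$censored),
                   lloq = ct$lloq[idx$analyte],
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}
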