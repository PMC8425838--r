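#' miRNA name harmonization
#'
#' Maps miRNA names from different studies and species onto a canonical
#' form so membership can be compared by name: lowercase, species prefix
#' (`hsa-`, `mmu-`, `rno-`, ...) stripped, arm suffix (`-5p`/`-3p`)
#' retained.  Under the `strict` policy two names match only if their
#' canonical forms (including arm) are equal; under `relaxed`, an arm-less
#' name additionally matches either arm of the same stem (for legacy lists
#' that predate arm-resolved naming).
#'
#' @param names character vector of miRNA names.
#' @return `data.frame` with columns `original`, `canonical`, `stem`
#'   (canonical without arm suffix), `arm` (`"5p"`, `"3p"`, or
#'   `"unspecified"`), `species_prefix_removed`.
#' @export
harmonize_mirna <- function(names) {
  names <- as.character(names)
  if (any(!nzchar(trimws(names)))) stop("empty miRNA name")
  canon <- tolower(trimws(names))
  prefixes <- c("hsa", "mmu", "rno", "ptr", "mml", "bta", "ssc", "cfa", "oar",
                "gga", "dre", "xtr", "dme", "cel")
  pat <- sprintf("^(%s)-", paste(prefixes, collapse = "|"))
  stripped <- grepl(pat, canon)
  canon <- sub(pat, "", canon)
  arm <- ifelse(grepl("-5p$", canon), "5p",
         ifelse(grepl("-3p$", canon), "3p", "unspecified"))
  stem <- sub("-(5p|3p)$", "", canon)
  data.frame(original = names, canonical = canon, stem = stem, arm = arm,
             species_prefix_removed = stripped, stringsAsFactors = FALSE)
}

#' Match harmonized query names against a harmonized reference
#' @noRd
mirna_membership <- function(query_h, ref_h, policy) {
  if (policy == "strict") {
    query_h$canonical %in% ref_h$canonical
  } else {
    exact <- query_h$canonical %in% ref_h$canonical
    # arm-less on either side matches the other side's stem
    q_armless_hit <- query_h$arm == "unspecified" & query_h$stem %in% ref_h$stem
    r_armless_stems <- ref_h$stem[ref_h$arm == "unspecified"]
    r_armless_hit <- query_h$stem %in% r_armless_stems
    exact | q_armless_hit | r_armless_hit
  }
}

#' Cross-cohort overlap membership matrix
#'
#' Builds the membership matrix of a query DE miRNA list against reference
#' study signatures: rows are query miRNAs found in at least one reference,
#' columns are studies, cells indicate harmonized-name membership.
#'
#' @param query character vector of miRNA names (e.g. the DE list).
#' @param references signature list as from [read_signatures()].
#' @param policy `"strict"` (default) or `"relaxed"` arm matching.
#' @return object of class `sev_overlap`: list with `membership` (logical
#'   matrix), `column_counts` (hits per study), `any_reference_count`
#'   (query miRNAs found in >= 1 study), `row_counts`, `policy`.
#'   Duplicate names (after harmonization) are counted once.
#' @export
overlap_matrix <- function(query, references, policy = c("strict", "relaxed")) {
  policy <- match.arg(policy)
  query <- as.character(query)
  qh <- harmonize_mirna(query)
  qh <- qh[!duplicated(qh$canonical), , drop = FALSE]
  studies <- vapply(references, `[[`, "", "study_id")
  mem <- matrix(FALSE, nrow(qh), length(references),
                dimnames = list(qh$original, studies))
  for (j in seq_along(references)) {
    mirnas <- references[[j]]$mirnas
    if (!length(mirnas)) next
    rh <- harmonize_mirna(mirnas)
    rh <- rh[!duplicated(rh$canonical), , drop = FALSE]
    mem[, j] <- mirna_membership(qh, rh, policy)
  }
  keep <- rowSums(mem) > 0
  mem <- mem[keep, , drop = FALSE]
  structure(list(membership = mem,
                 column_counts = colSums(mem),
                 any_reference_count = nrow(mem),
                 row_counts = rowSums(mem),
                 references = references,
                 policy = policy),
            class = "sev_overlap")
}

#' @export
print.sev_overlap <- function(x, ...) {
  cat(sprintf("sev_overlap (%s policy): %d query miRNAs in >= 1 of %d reference studies\n",
              x$policy, x$any_reference_count, ncol(x$membership)))
  print(x$column_counts)
  invisible(x)
}

#' Write / read the overlap membership table
#'
#' Serializes the membership matrix in the familiar cross-study layout: a
#' header block of study attributes (`study`, `treatment`, `comparison`,
#' `sample_type`) followed by one row per miRNA with `X` marking
#' membership.  Rows with no membership are omitted by construction.
#'
#' @param om a [overlap_matrix()] result.
#' @param path output path.
#' @param sep field delimiter.
#' @export
write_overlap_table <- function(om, path, sep = "\t") {
  stopifnot(inherits(om, "sev_overlap"))
  refs <- om$references
  hdr <- function(field, label) {
    paste(c(label, vapply(refs, `[[`, "", field)), collapse = sep)
  }
  lines <- c(hdr("study_id", "study"),
             hdr("treatment", "treatment"),
             hdr("comparison", "comparison"),
             hdr("sample_type", "sample_type"))
  for (i in seq_len(nrow(om$membership))) {
    lines <- c(lines, paste(c(rownames(om$membership)[i],
                              ifelse(om$membership[i, ], "X", "")), collapse = sep))
  }
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_overlap_table
#' @return `read_overlap_table` returns a logical membership matrix with
#'   study ids as columns.
#' @export
read_overlap_table <- function(path, sep = "\t") {
  lines <- readLines(path)
  if (length(lines) < 4) stop(sprintf("%s: expected 4 header rows", path))
  split1 <- strsplit(lines, sep, fixed = TRUE)
  studies <- split1[[1]][-1]
  body <- split1[-(1:4)]
  mem <- matrix(FALSE, length(body), length(studies),
                dimnames = list(vapply(body, `[[`, "", 1), studies))
  for (i in seq_along(body)) {
    cells <- body[[i]][-1]
    mem[i, seq_along(cells)] <- cells == "X"
  }
  mem
}
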