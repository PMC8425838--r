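#' Consolidate predicted and validated miRNA targets
#'
#' A gene enters the consolidated target list only when some query miRNA
#' predicts it with score strictly above the threshold (e.g. a TargetScan
#' aggregate P_CT > 0.9) *and* some query miRNA targets it with
#' experimental evidence (miRTarBase-style).  The intersection rule keeps
#' only genes supported by both evidence classes.
#'
#' @param mirnas character vector of query miRNA names.
#' @param predicted a [target_table()] with scores (evidence `predicted`).
#' @param validated a [target_table()] (evidence `validated`).
#' @param threshold predicted-score cutoff in \[0, 1\], strict `>`;
#'   default 0.9.
#' @return list of class `target_selection`: `genes` (character),
#'   `support` (named list: per gene, the supporting miRNAs), `threshold`,
#'   `mirnas`.
#' @export
consolidate_targets <- function(mirnas, predicted, validated, threshold = 0.9) {
  if (threshold < 0 || threshold > 1) stop("threshold must lie in [0, 1]")
  mirnas <- unique(as.character(mirnas))
  pred <- predicted[predicted$mirna %in% mirnas &
                      !is.na(predicted$score) & predicted$score > threshold, , drop = FALSE]
  val <- validated[validated$mirna %in% mirnas, , drop = FALSE]
  genes <- sort(intersect(unique(pred$gene), unique(val$gene)))
  support <- lapply(genes, function(g) {
    sort(unique(c(pred$mirna[pred$gene == g], val$mirna[val$gene == g])))
  })
  structure(list(genes = genes, support = stats::setNames(support, genes),
                 threshold = threshold, mirnas = mirnas),
            class = "target_selection")
}

#' Hypergeometric over-representation test
#'
#' One-sided upper-tail hypergeometric test per gene-set term: with a
#' background universe of size N containing K term genes, drawing the n
#' query genes gives overlap k; p = P(X >= k).  P-values are BH-adjusted
#' across tested terms and terms are flagged significant at `fdr_cutoff`.
#' Background defaults to the collection's explicit universe, else the
#' union of all annotated genes; query genes outside the background are
#' dropped with a warning.
#'
#' @param query character vector of genes (e.g. consolidated targets).
#' @param gsc a [gene_set_collection()].
#' @param background optional explicit gene universe.
#' @param fdr_cutoff significance threshold on the BH-adjusted p.
#' @return `data.frame` of class `sev_enrichment`, FDR-sorted:
#'   `term_id`, `term_name`, `k`, `K`, `n`, `N`, `p_hyper`, `fdr`,
#'   `significant`, `genes` (comma-joined member genes).
#' @export
hypergeom_enrich <- function(query, gsc, background = NULL, fdr_cutoff = 0.05) {
  stopifnot(inherits(gsc, "gene_set_collection"))
  background <- unique(as.character(
    background %||% gsc$background %||% unlist(gsc$sets)))
  if (!length(background)) stop("empty background universe")
  query <- unique(as.character(query))
  outside <- setdiff(query, background)
  if (length(outside)) {
    warning(sprintf("%d query gene(s) outside the background dropped (e.g. %s)",
                    length(outside), outside[1]))
    query <- intersect(query, background)
  }
  N <- length(background)
  n <- length(query)
  recs <- lapply(names(gsc$sets), function(id) {
    set <- intersect(gsc$sets[[id]], background)
    K <- length(set)
    members <- intersect(query, set)
    k <- length(members)
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(term_id = id, term_name = gsc$descriptions[[id]] %||% id,
               k = k, K = K, n = n, N = N, p_hyper = p,
               genes = paste(sort(members), collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, recs)
  out$fdr <- bh_adjust(out$p_hyper)
  out$significant <- out$fdr < fdr_cutoff
  out <- out[order(out$fdr, out$p_hyper, out$term_id),
             c("term_id", "term_name", "k", "K", "n", "N", "p_hyper", "fdr",
               "significant", "genes")]
  rownames(out) <- NULL
  class(out) <- c("sev_enrichment", class(out))
  out
}

#' Keep the most significant terms
#'
#' @param records a [hypergeom_enrich()] table.
#' @param n number of terms to keep (default 30), ordered by ascending
#'   FDR, ties broken by raw p then term id.
#' @return the first `n` records.
#' @export
top_terms <- function(records, n = 30) {
  o <- order(records$fdr, records$p_hyper, records$term_id)
  records[o[seq_len(min(n, nrow(records)))], , drop = FALSE]
}

#' Term-similarity graph and dendrogram of enriched terms
#'
#' Builds, over the supplied (typically significant) terms, the shared-gene
#' graph - an undirected edge wherever two terms share at least
#' `min_shared` member genes, weighted by that count - and a hierarchical
#' dendrogram on `1 - Jaccard` distance of the member-gene sets with
#' average linkage (deterministic leaf order, Newick serialization).
#'
#' @param records a [hypergeom_enrich()] table (filter to significant
#'   terms first).
#' @param min_shared minimum shared-gene count for an edge, default 1.
#' @return list of class `sev_term_graph`: `nodes` (`data.frame`:
#'   term_id, n_genes, fdr), `edges` (`data.frame`: term1, term2, weight),
#'   `dendrogram` (hclust or `NULL` when < 2 terms), `newick`.
#' @export
term_graph <- function(records, min_shared = 1) {
  members <- strsplit(records$genes, ",", fixed = TRUE)
  members <- lapply(members, function(g) g[nzchar(g)])
  names(members) <- records$term_id
  nodes <- data.frame(term_id = records$term_id,
                      n_genes = lengths(members),
                      fdr = records$fdr, stringsAsFactors = FALSE)
  m <- length(members)
  edges <- data.frame(term1 = character(), term2 = character(),
                      weight = integer(), stringsAsFactors = FALSE)
  if (m >= 2) {
    for (i in seq_len(m - 1)) {
      for (j in (i + 1):m) {
        w <- length(intersect(members[[i]], members[[j]]))
        if (w >= min_shared) {
          edges <- rbind(edges, data.frame(term1 = names(members)[i],
                                           term2 = names(members)[j],
                                           weight = w, stringsAsFactors = FALSE))
        }
      }
    }
  }
  if (m >= 2) {
    jac <- matrix(0, m, m, dimnames = list(names(members), names(members)))
    for (i in seq_len(m)) {
      for (j in seq_len(m)) {
        u <- length(union(members[[i]], members[[j]]))
        jac[i, j] <- if (u == 0) 1 else 1 - length(intersect(members[[i]], members[[j]])) / u
      }
    }
    hc <- stats::hclust(stats::as.dist(jac), method = "average")
    hc$labels <- names(members)
    nk <- hclust_to_newick(hc)
    dend <- hc; newick <- nk$newick
  } else {
    dend <- NULL
    newick <- if (m == 1) paste0(names(members), ";") else ""
  }
  structure(list(nodes = nodes, edges = edges, dendrogram = dend, newick = newick),
            class = "sev_term_graph")
}
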