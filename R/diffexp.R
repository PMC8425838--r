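#' Housekeeping-aggregate normalization
#'
#' Divides every probe's TPM in a sample by the geometric mean of the
#' sample's housekeeping-probe TPMs (the "aggregate" of the panel's 13
#' housekeeping genes).  After normalization the housekeeping aggregate
#' equals exactly 1 in every sample, so downstream fold changes are
#' expressed relative to that aggregate.
#'
#' @param em a `sev_expr` in unit `"tpm"`.
#' @param pseudocount optional non-negative offset added to every TPM value
#'   (housekeeping probes included) before the aggregate is formed and the
#'   division applied, so the normalized matrix is strictly positive.
#'   Without it, a sample with any zero housekeeping TPM is an error.
#' @return a `sev_expr` in unit `"hk_relative"`.
#' @export
housekeeping_normalize <- function(em, pseudocount = NULL) {
  stopifnot(inherits(em, "sev_expr"))
  if (em$unit != "tpm") stop("housekeeping_normalize expects a TPM matrix")
  hk <- em$annotation$probe_class == "housekeeping"
  if (!any(hk)) stop("no housekeeping probes present")
  vals <- em$values
  if (is.null(pseudocount)) {
    zero <- colSums(vals[hk, , drop = FALSE] == 0) > 0
    if (any(zero)) {
      stop(sprintf("sample '%s' has a zero housekeeping TPM; supply a pseudocount",
                   colnames(vals)[zero][1]))
    }
  } else {
    if (pseudocount < 0) stop("pseudocount must be >= 0")
    vals <- vals + pseudocount
  }
  aggregate <- apply(vals[hk, , drop = FALSE], 2, geomean)
  out <- em
  out$values <- sweep(vals, 2, aggregate, `/`)
  out$unit <- "hk_relative"
  out$provenance <- c(em$provenance,
                      sprintf("housekeeping_normalize over %d probes (geometric mean aggregate)",
                              sum(hk)))
  attr(out, "hk_aggregate") <- aggregate
  out
}

#' Group fold change of geometric means
#'
#' Fold change is the ratio of the case-group geometric mean to the
#' control-group geometric mean, computed as
#' `2^(mean(log2 case) - mean(log2 control))` on the (housekeeping-relative)
#' linear values.
#'
#' @param em a `sev_expr` on a linear scale (`"hk_relative"` or `"tpm"`).
#' @param design a [sample_sheet()] covering the samples.
#' @param pseudocount non-negative offset added before log2; default 0,
#'   which errors if zeros are present.
#' @return named numeric vector of fold changes (case / control).
#' @export
fold_change <- function(em, design, pseudocount = 0) {
  stopifnot(inherits(em, "sev_expr"))
  if (!em$unit %in% c("tpm", "hk_relative")) {
    stop("fold_change expects linear-scale values")
  }
  if (pseudocount < 0) stop("pseudocount must be >= 0")
  if (pseudocount == 0 && any(em$values == 0)) {
    stop("zero values present; supply a positive pseudocount for fold_change")
  }
  grp <- design$group[match(colnames(em$values), design$sample_id)]
  lg <- log2(em$values + pseudocount)
  m_case <- rowMeans(lg[, grp == "case", drop = FALSE])
  m_ctrl <- rowMeans(lg[, grp == "control", drop = FALSE])
  stats::setNames(2^(m_case - m_ctrl), rownames(em$values))
}

#' Welch t statistics for all probe rows given a column labeling
#' @noRd
welch_t_rows <- function(x, idx_ctrl, idx_case) {
  n1 <- length(idx_ctrl); n2 <- length(idx_case)
  x1 <- x[, idx_ctrl, drop = FALSE]; x2 <- x[, idx_case, drop = FALSE]
  m1 <- rowMeans(x1); m2 <- rowMeans(x2)
  v1 <- rowSums((x1 - m1)^2) / (n1 - 1)
  v2 <- rowSums((x2 - m2)^2) / (n2 - 1)
  se <- sqrt(v1 / n1 + v2 / n2)
  d <- m2 - m1
  t <- d / se
  # degenerate rows: zero variance in both groups under this labeling
  deg <- se == 0
  t[deg & d == 0] <- 0
  t[deg & d != 0] <- sign(d[deg & d != 0]) * Inf
  t
}

#' Permutation t-test for two-group differential expression
#'
#' The observed statistic per probe is the Welch t on log2-scale values
#' (case minus control).  Its significance is assessed against the
#' group-label permutation distribution; all `choose(n, n1)` relabelings
#' are enumerated whenever that count is at most `max_exhaustive`.
#'
#' Three p-value schemes are offered:
#' \describe{
#'   \item{`pooled` (default)}{the null statistics of all relabelings of
#'     *all* probes are pooled into one reference distribution and each
#'     probe's p is its upper-tail share of that pool.  With small groups
#'     (4 vs 4 gives only 70 relabelings) a per-probe permutation p can
#'     never go below 1/70, so pooling across probes is what makes p-values
#'     on the panel-report scale (down to ~1e-5) attainable at this design;
#'     it assumes probes share a common null shape after log2 scaling.}
#'   \item{`exhaustive`}{the classical per-probe permutation p:
#'     `#\{|T*| >= |T_obs|\} / n_labelings`, identity labeling included, so
#'     p is always positive and takes values `k/n_labelings`.}
#'   \item{`monte_carlo`}{B random relabelings with the add-one correction
#'     `p = (1 + #\{|T*| >= |T_obs|\}) / (B + 1)`.}
#' }
#' Probes that are constant across all samples get p = 1 with a warning.
#'
#' @param em a `sev_expr` on the log2 scale.
#' @param design a [sample_sheet()] covering the samples.
#' @param scheme `"pooled"`, `"exhaustive"`, or `"monte_carlo"`.
#' @param B number of Monte-Carlo draws (monte_carlo scheme only).
#' @param seed RNG seed for the Monte-Carlo scheme.
#' @param max_exhaustive largest number of labelings enumerated before the
#'   exhaustive/pooled schemes refuse (guards against factorial blow-up).
#' @return named numeric vector of p-values with attribute `"scheme"`
#'   (list: scheme, n_labelings or B, seed).
#' @export
permutation_t_test <- function(em, design,
                               scheme = c("pooled", "exhaustive", "monte_carlo"),
                               B = 9999, seed = 1,
                               max_exhaustive = 20000) {
  stopifnot(inherits(em, "sev_expr"))
  if (!startsWith(em$unit, "log2")) {
    stop("permutation_t_test expects log2-scale values")
  }
  scheme <- match.arg(scheme)
  x <- em$values
  grp <- design$group[match(colnames(x), design$sample_id)]
  if (anyNA(grp)) stop("all samples must appear in the sample sheet")
  n1 <- sum(grp == "control"); n2 <- sum(grp == "case")
  if (n1 < 2 || n2 < 2) stop("each group needs >= 2 samples")
  idx_ctrl_obs <- which(grp == "control")
  t_obs <- welch_t_rows(x, idx_ctrl_obs, setdiff(seq_along(grp), idx_ctrl_obs))
  const <- apply(x, 1, function(r) all(r == r[1]))
  if (any(const)) {
    warning(sprintf("%d probe(s) constant across samples; p set to 1", sum(const)))
  }
  tol <- 1e-12 * (1 + abs(t_obs))
  tol[!is.finite(tol)] <- 0

  if (scheme %in% c("pooled", "exhaustive")) {
    n_lab <- choose(n1 + n2, n1)
    if (n_lab > max_exhaustive) {
      stop(sprintf("%d labelings exceed max_exhaustive=%d; use scheme='monte_carlo'",
                   n_lab, max_exhaustive))
    }
    labelings <- utils::combn(n1 + n2, n1)
    tmat <- apply(labelings, 2, function(i1) {
      abs(welch_t_rows(x, i1, setdiff(seq_len(n1 + n2), i1)))
    })  # probes x labelings
    if (!is.matrix(tmat)) tmat <- matrix(tmat, nrow = nrow(x))
    if (scheme == "exhaustive") {
      p <- rowMeans(tmat >= (abs(t_obs) - tol))
      meta <- list(scheme = "exhaustive", n_labelings = n_lab)
    } else {
      pool <- sort(as.vector(tmat))          # finite + Inf sort fine
      total <- length(pool)
      ge <- total - findInterval(abs(t_obs) - tol, pool, left.open = TRUE)
      # findInterval can't place Inf-tol = NaN; handle infinite t_obs directly
      inf_obs <- is.infinite(t_obs)
      if (any(inf_obs)) ge[inf_obs] <- sum(is.infinite(pool))
      p <- ge / total
      meta <- list(scheme = "pooled", n_labelings = n_lab, pool_size = total)
    }
  } else {
    p <- with_seed(seed, {
      hits <- numeric(nrow(x))
      for (b in seq_len(B)) {
        i1 <- sample.int(n1 + n2, n1)
        tb <- abs(welch_t_rows(x, i1, setdiff(seq_len(n1 + n2), i1)))
        hits <- hits + (tb >= abs(t_obs) - tol)
      }
      (1 + hits) / (B + 1)
    })
    meta <- list(scheme = "monte_carlo", B = B, seed = seed)
  }
  p[const] <- 1
  p <- stats::setNames(pmin(p, 1), rownames(x))
  attr(p, "scheme") <- meta
  attr(p, "t_obs") <- stats::setNames(t_obs, rownames(x))
  p
}

#' Call differentially expressed probes
#'
#' A probe is called differentially expressed when its permutation p falls
#' below `alpha` and its fold change is at least `fc_min` (or at most
#' `1/fc_min` for down-regulation).  Benjamini-Hochberg adjusted p-values
#' are reported alongside; by default the call is made on the raw
#' permutation p (the operational rule of the panel analysis), with
#' `call_on = "p_adj"` available.  When a probe annotation is supplied,
#' only `mirna`-class probes enter the BH multiplicity count; housekeeping
#' probes remain testable and reportable but get `NA` adjusted p.
#'
#' @param fc named fold-change vector from [fold_change()].
#' @param p named p-value vector from [permutation_t_test()].
#' @param annotation optional probe annotation `data.frame`.
#' @param alpha p-value threshold, default 0.01.
#' @param fc_min fold-change threshold, default 2.
#' @param call_on `"p"` (default) or `"p_adj"`.
#' @return `data.frame` of class `sev_de_table`, sorted by `p_perm`:
#'   `probe_id`, `fold_change`, `p_perm`, `p_adj`, `de_call`, `direction`.
#'   Thresholds and the permutation scheme are attached as attributes.
#' @export
call_differential <- function(fc, p, annotation = NULL,
                              alpha = 0.01, fc_min = 2.0,
                              call_on = c("p", "p_adj")) {
  call_on <- match.arg(call_on)
  probes <- names(p)
  if (!setequal(probes, names(fc))) stop("fc and p must cover the same probes")
  fc <- fc[probes]
  p_adj <- rep(NA_real_, length(p))
  if (!is.null(annotation)) {
    cls <- annotation$probe_class[match(probes, annotation$probe_id)]
    mir <- !is.na(cls) & cls == "mirna"
  } else {
    mir <- rep(TRUE, length(p))
  }
  p_adj[mir] <- bh_adjust(p[mir])
  crit_p <- if (call_on == "p") p else p_adj
  de <- !is.na(crit_p) & crit_p < alpha & (fc >= fc_min | fc <= 1 / fc_min)
  out <- data.frame(probe_id = probes, fold_change = unname(fc),
                    p_perm = unname(p), p_adj = unname(p_adj),
                    de_call = unname(de),
                    direction = ifelse(fc >= 1, "up", "down"),
                    stringsAsFactors = FALSE)
  out <- out[order(out$p_perm, out$probe_id), ]
  rownames(out) <- NULL
  attr(out, "thresholds") <- list(alpha = alpha, fc_min = fc_min, call_on = call_on)
  attr(out, "scheme") <- attr(p, "scheme")
  class(out) <- c("sev_de_table", class(out))
  out
}

#' Hierarchical sample clustergram on correlation distance
#'
#' Pairwise sample distance is `1 - Pearson r` between log2 expression
#' columns (range \[0, 2\]); the tree is built with average linkage.  Leaf
#' order is made deterministic by placing, at every merge, the subtree
#' containing the smaller original sample index first; the tree is also
#' serialized as a Newick string with ultrametric branch lengths.
#'
#' @param em a `sev_expr` on the log2 scale with >= 2 samples.
#' @return object of class `sev_clustergram`: list with `dist` (matrix),
#'   `hclust`, `leaf_order` (character), `newick` (string).
#' @export
sample_clustergram <- function(em) {
  stopifnot(inherits(em, "sev_expr"))
  x <- em$values
  if (ncol(x) < 2) stop("need >= 2 samples to cluster")
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0)) {
    stop(sprintf("sample '%s' has constant expression; correlation undefined",
                 colnames(x)[sds == 0][1]))
  }
  d <- 1 - stats::cor(x)
  hc <- stats::hclust(stats::as.dist(d), method = "average")
  nk <- hclust_to_newick(hc)
  structure(list(dist = d, hclust = hc, leaf_order = nk$leaves, newick = nk$newick),
            class = "sev_clustergram")
}

#' Serialize an hclust tree as Newick with deterministic child order
#'
#' At every internal node the child subtree containing the smallest
#' original leaf index is written first.  Branch lengths are differences of
#' merge heights (leaves sit at height 0).
#'
#' @param hc an `stats::hclust` object with labels.
#' @param digits branch-length digits.
#' @return list with `newick` (string, semicolon-terminated) and `leaves`
#'   (labels in serialized order).
#' @export
hclust_to_newick <- function(hc, digits = 6) {
  labels <- hc$labels %||% as.character(seq_len(nrow(hc$merge) + 1))
  fmt <- function(v) format(round(v, digits), trim = TRUE, scientific = FALSE)
  build <- function(k) {
    parts <- lapply(hc$merge[k, ], function(ch) {
      if (ch < 0) {
        list(str = labels[-ch], h = 0, min_idx = -ch, leaves = labels[-ch])
      } else {
        build(ch)
      }
    })
    if (parts[[2]]$min_idx < parts[[1]]$min_idx) parts <- parts[c(2, 1)]
    h <- hc$height[k]
    strs <- vapply(parts, function(p) paste0(p$str, ":", fmt(h - p$h)), "")
    list(str = sprintf("(%s)", paste(strs, collapse = ",")),
         h = h,
         min_idx = min(parts[[1]]$min_idx, parts[[2]]$min_idx),
         leaves = c(parts[[1]]$leaves, parts[[2]]$leaves))
  }
  if (nrow(hc$merge) == 0) {
    return(list(newick = paste0(labels[1], ";"), leaves = labels[1]))
  }
  root <- build(nrow(hc$merge))
  list(newick = paste0(root$str, ";"), leaves = root$leaves)
}
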