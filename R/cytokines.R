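#' Impute censored cytokine values at the LLOQ
#'
#' Entries flagged below the lower limit of quantitation are assigned the
#' analyte's LLOQ, the convention used when undetected analytes must enter
#' quantitative comparison.  Uncensored entries are never altered.
#'
#' @param ct a [cytokine_table()].
#' @return the table with censored cells set to the analyte LLOQ; the
#'   per-analyte imputation count is attached as attribute
#'   `"n_imputed"`.
#' @export
impute_lloq <- function(ct) {
  stopifnot(inherits(ct, "cytokine_table"))
  need <- rowSums(ct$censored) > 0
  if (any(need & is.na(ct$lloq))) {
    stop(sprintf("analyte '%s' has censored entries but no LLOQ",
                 rownames(ct$conc)[need & is.na(ct$lloq)][1]))
  }
  out <- ct
  for (a in rownames(ct$conc)[need]) {
    out$conc[a, ct$censored[a, ]] <- ct$lloq[[a]]
  }
  attr(out, "n_imputed") <- rowSums(ct$censored)
  out
}

#' Normalize cytokine concentrations by total protein
#'
#' Converts pg/mL concentrations to pg per mg of total protein by dividing
#' each sample's values by its protein content (mg/mL), adjusting for
#' sample-to-sample variation in processing.
#'
#' @param ct a [cytokine_table()] in `pg_per_ml`.
#' @param design a [sample_sheet()] with `protein_mg_per_ml` for every
#'   sample of the table.
#' @return a `cytokine_table` in `pg_per_mg`.
#' @export
protein_normalize <- function(ct, design) {
  stopifnot(inherits(ct, "cytokine_table"))
  if (ct$unit != "pg_per_ml") stop("table already protein-normalized")
  prot <- design$protein_mg_per_ml[match(colnames(ct$conc), design$sample_id)]
  bad <- is.na(prot) | prot <= 0
  if (any(bad)) {
    stop(sprintf("missing or non-positive protein content for sample '%s'",
                 colnames(ct$conc)[bad][1]))
  }
  out <- ct
  out$conc <- sweep(ct$conc, 2, prot, `/`)
  out$lloq <- stats::setNames(rep(NA_real_, nrow(ct$conc)), rownames(ct$conc))
  out$unit <- "pg_per_mg"
  out
}

#' Welch's t-test from group summary statistics
#'
#' Two-tailed Welch test computed from means, standard deviations and group
#' sizes alone, enabling verification against published summary tables:
#' `t = (m2 - m1) / sqrt(s1^2/n1 + s2^2/n2)` with Welch-Satterthwaite
#' degrees of freedom.  When both SDs are zero the convention is p = 1 for
#' equal means and p = 0 otherwise.  All arguments are vectorized.
#'
#' @param m1,s1,n1 control mean, SD, size.
#' @param m2,s2,n2 case mean, SD, size.
#' @return `data.frame` with columns `t`, `df`, `p`.
#' @export
welch_from_summary <- function(m1, s1, n1, m2, s2, n2) {
  if (any(n1 < 2 | n2 < 2)) stop("each group needs n >= 2")
  if (any(s1 < 0 | s2 < 0)) stop("standard deviations must be >= 0")
  a <- s1^2 / n1
  b <- s2^2 / n2
  se <- sqrt(a + b)
  t <- (m2 - m1) / se
  df <- (a + b)^2 / (a^2 / (n1 - 1) + b^2 / (n2 - 1))
  deg <- se == 0
  t[deg & m1 == m2] <- 0
  t[deg & m1 != m2] <- sign((m2 - m1)[deg & m1 != m2]) * Inf
  df[deg] <- n1 + n2 - 2
  p <- 2 * stats::pt(-abs(t), df)
  p[deg & m1 == m2] <- 1
  data.frame(t = t, df = df, p = p)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Classic step-up FDR adjustment: with p-values sorted ascending,
#' `adj(i) = min_(j >= i) ( p(j) * m / j )`, capped at 1, returned in the
#' original order.  `m` defaults to the number of p-values but can be set
#' larger when the tested family is bigger than the list supplied.
#'
#' @param p numeric vector of p-values in (0, 1].
#' @param m family size, default `length(p)`.
#' @return adjusted p-values in the input order.
#' @export
bh_adjust <- function(p, m = length(p)) {
  if (any(!is.finite(p) | p <= 0 | p > 1)) stop("p-values must lie in (0, 1]")
  if (m < length(p)) stop("family size m cannot be smaller than length(p)")
  o <- order(p)
  ranked <- p[o] * m / seq_along(p)
  adj <- rev(cummin(rev(ranked)))
  adj <- pmin(adj, 1)
  out <- numeric(length(p))
  out[o] <- adj
  out
}

#' Pooled-variance two-sample Student t-test
#'
#' Two-tailed Student t with pooled variance, used for the scalar
#' characterization comparisons (vesicle size, protein content, behavioral
#' readouts).  Zero pooled variance with equal means gives p = 1 by
#' convention.
#'
#' @param x,y numeric vectors (each n >= 2).
#' @return list with `t`, `df`, `p`.
#' @export
students_t <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  if (n1 < 2 || n2 < 2) stop("each group needs n >= 2")
  sp2 <- ((n1 - 1) * stats::var(x) + (n2 - 1) * stats::var(y)) / (n1 + n2 - 2)
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  df <- n1 + n2 - 2
  if (se == 0) {
    if (mean(x) == mean(y)) return(list(t = 0, df = df, p = 1))
    return(list(t = sign(mean(y) - mean(x)) * Inf, df = df, p = 0))
  }
  t <- (mean(y) - mean(x)) / se
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

#' Hind paw weight-bearing ratio
#'
#' The incapacitance readout `2R / (R + L) * 100` in percent: 100 means
#' symmetric weight bearing, below 100 means unweighting of the right
#' (injured) hind paw.
#'
#' @param right_g,left_g weight borne on the right / left hind paw (grams).
#' @return percent weight distribution.
#' @export
hindpaw_weight_ratio <- function(right_g, left_g) {
  s <- right_g + left_g
  if (any(s <= 0)) stop("right_g + left_g must be positive")
  2 * right_g / s * 100
}

#' Cytokine panel analysis
#'
#' Runs the full panel pipeline per fraction: LLOQ imputation, protein
#' normalization, a per-analyte two-tailed Welch t-test (computed from the
#' raw per-sample values), and Benjamini-Hochberg adjustment.  By default
#' each fraction's analytes form their own BH family (matching how
#' per-fraction panel tables are reported); `bh_family = "pooled"` adjusts
#' across all fractions jointly.
#'
#' @param tables named list of [cytokine_table()]s (e.g. `sev_plus`,
#'   `sev_minus`).
#' @param design a [sample_sheet()] covering the samples with protein
#'   content.
#' @param bh_family `"per_fraction"` (default) or `"pooled"`.
#' @param normalize_protein logical; set `FALSE` to compare raw pg/mL.
#' @param fdr significance threshold on adjusted p, default 0.05.
#' @return `data.frame` with one row per fraction and analyte: group
#'   summaries (n, mean, sd), `difference` (case - control), `t`, `df`,
#'   `p`, `p_adj`, `significant`.
#' @export
analyze_cytokine_panel <- function(tables, design,
                                   bh_family = c("per_fraction", "pooled"),
                                   normalize_protein = TRUE, fdr = 0.05) {
  bh_family <- match.arg(bh_family)
  if (is.null(names(tables))) names(tables) <- sprintf("fraction_%d", seq_along(tables))
  res <- do.call(rbind, lapply(names(tables), function(fr) {
    ct <- impute_lloq(tables[[fr]])
    if (normalize_protein) ct <- protein_normalize(ct, design)
    grp <- design$group[match(colnames(ct$conc), design$sample_id)]
    if (anyNA(grp)) stop("all cytokine samples must appear in the sample sheet")
    ctrl <- ct$conc[, grp == "control", drop = FALSE]
    case <- ct$conc[, grp == "case", drop = FALSE]
    wt <- welch_from_summary(rowMeans(ctrl), apply(ctrl, 1, stats::sd), ncol(ctrl),
                             rowMeans(case), apply(case, 1, stats::sd), ncol(case))
    data.frame(fraction = fr, analyte = rownames(ct$conc),
               control_n = ncol(ctrl), control_mean = rowMeans(ctrl),
               control_sd = apply(ctrl, 1, stats::sd),
               case_n = ncol(case), case_mean = rowMeans(case),
               case_sd = apply(case, 1, stats::sd),
               difference = rowMeans(case) - rowMeans(ctrl),
               t = wt$t, df = wt$df, p = wt$p,
               stringsAsFactors = FALSE, row.names = NULL)
  }))
  if (bh_family == "per_fraction") {
    res$p_adj <- stats::ave(res$p, res$fraction, FUN = bh_adjust)
  } else {
    res$p_adj <- bh_adjust(res$p)
  }
  res$significant <- res$p_adj < fdr
  res[order(res$fraction, res$p), ]
}
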