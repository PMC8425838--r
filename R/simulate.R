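#' Configuration for the synthetic study generator
#'
#' Describes the synthetic cohort the generators emit.  Defaults mirror the
#' TFM serum sEV study design: 5 control and 4 case (TFM) mice profiled on a
#' ~2,000-probe nuclease-protection miRNA panel with 13 housekeeping probes
#' and positive-control spikes, 57 planted up-regulated miRNAs with fold
#' changes between 2 and 6, and one control sample planted to fail QC on
#' spike content (so the post-QC design is 4 vs 4).  The cytokine arm
#' mirrors the 23-plex panel measured on 6 control vs 8 case animals.
#'
#' @param n_control,n_case pre-QC group sizes for the miRNA panel.
#' @param n_mirna,n_housekeeping,n_spike probe counts per class.
#' @param n_de number of planted up-regulated miRNAs.
#' @param de_fc_range range (low, high) of planted fold changes, low >= 1.
#' @param library_size_mean mean per-sample total read count.
#' @param nb_dispersion negative-binomial dispersion of miRNA probes
#'   (variance = mu + dispersion * mu^2).
#' @param hk_dispersion dispersion of housekeeping and spike probes (kept
#'   low: these probes are the stable signal QC and normalization rely on).
#' @param base_sdlog log-sd of the across-probe abundance distribution.
#' @param spike_fraction_normal expected fraction of a healthy sample's
#'   reads coming from positive-control spike probes.
#' @param hk_fraction expected fraction of reads from housekeeping probes.
#' @param planted_qc_failures list of `list(sample=, mode=)` entries with
#'   mode one of `"low_reads"`, `"high_spike"`, `"high_cv"`.
#' @param cyt_n_control,cyt_n_case cytokine-panel group sizes.
#' @param cytokine_shifts list with per-fraction true case/control
#'   concentration ratios (scalar or named per analyte) for the `sev_plus`
#'   and `sev_minus` fractions.
#' @param signature_overlaps named integer vector: per reference study, the
#'   number of planted DE miRNAs its signature must contain.
#' @param n_genes size of the simulated gene universe for target tables.
#' @param seed integer RNG seed; every generator is deterministic given it.
#' @return a validated list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_control = 5L, n_case = 4L,
                             n_mirna = 2000L, n_housekeeping = 13L, n_spike = 5L,
                             n_de = 57L, de_fc_range = c(2, 6),
                             library_size_mean = 3e6,
                             nb_dispersion = 0.1, hk_dispersion = 0.005,
                             base_sdlog = 2.0,
                             spike_fraction_normal = 0.02, hk_fraction = 0.05,
                             planted_qc_failures = list(list(sample = "control_1",
                                                             mode = "high_spike")),
                             cyt_n_control = 6L, cyt_n_case = 8L,
                             cytokine_shifts = list(
                               sev_plus = 1.0,
                               sev_minus = c("IL-6" = 4.0, "TNFa" = 4.0, "MCP-1" = 4.0)),
                             signature_overlaps = c(exosome = 8L, whole_blood = 23L),
                             n_genes = 800L,
                             seed = 1L) {
  cfg <- list(n_control = as.integer(n_control), n_case = as.integer(n_case),
              n_mirna = as.integer(n_mirna), n_housekeeping = as.integer(n_housekeeping),
              n_spike = as.integer(n_spike), n_de = as.integer(n_de),
              de_fc_range = as.numeric(de_fc_range),
              library_size_mean = library_size_mean,
              nb_dispersion = nb_dispersion, hk_dispersion = hk_dispersion,
              base_sdlog = base_sdlog,
              spike_fraction_normal = spike_fraction_normal, hk_fraction = hk_fraction,
              planted_qc_failures = planted_qc_failures,
              cyt_n_control = as.integer(cyt_n_control), cyt_n_case = as.integer(cyt_n_case),
              cytokine_shifts = cytokine_shifts,
              signature_overlaps = signature_overlaps,
              n_genes = as.integer(n_genes),
              seed = as.integer(seed))
  if (cfg$n_de > cfg$n_mirna) stop("n_de must not exceed n_mirna")
  if (length(cfg$de_fc_range) != 2 || cfg$de_fc_range[1] < 1 || diff(cfg$de_fc_range) < 0) {
    stop("de_fc_range must be (low, high) with low >= 1 and high >= low")
  }
  for (f in c("n_control", "n_case", "n_mirna", "n_housekeeping", "n_spike")) {
    if (cfg[[f]] < 1) stop(sprintf("'%s' must be positive", f))
  }
  assert_scalar_number(cfg$nb_dispersion, "nb_dispersion", positive = TRUE)
  assert_scalar_number(cfg$library_size_mean, "library_size_mean", positive = TRUE)
  if (cfg$spike_fraction_normal <= 0 || cfg$spike_fraction_normal >= 1) {
    stop("spike_fraction_normal must lie in (0, 1)")
  }
  if (cfg$spike_fraction_normal + cfg$hk_fraction >= 1) {
    stop("spike and housekeeping fractions must leave room for miRNA reads")
  }
  for (pf in cfg$planted_qc_failures) {
    if (!all(c("sample", "mode") %in% names(pf)) ||
        !pf$mode %in% c("low_reads", "high_spike", "high_cv")) {
      stop("planted_qc_failures entries need sample and mode in {low_reads, high_spike, high_cv}")
    }
  }
  structure(cfg, class = "synthetic_config")
}

#' Simulate a probe-level count matrix with planted ground truth
#'
#' Counts are negative-binomial around probe-specific base abundances scaled
#' by a per-sample library size.  Planted differentially expressed miRNAs
#' have their case-group mean multiplied by the planted fold change; they
#' are drawn from the moderately-to-highly expressed probes so that, like
#' the reported miRNAs of the study this emulates, they survive the
#' low-expression filter.  Housekeeping and spike probes share a common
#' within-class mean and low dispersion, which is what the CV and
#' spike-fraction QC metrics assume.  Planted QC failures force a sample
#' below 10^6 total reads (`low_reads`), above 10% spike reads
#' (`high_spike`), or above 15% housekeeping CV (`high_cv`).
#'
#' @param config a [synthetic_config()].
#' @return list with `counts` (a [count_matrix()]), `samples` (a
#'   [sample_sheet()]), and `truth` (planted DE probes with true fold
#'   change, planted QC failures, and the base abundance vector).
#' @export
simulate_counts <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  with_seed(config$seed, {
    arms <- rep(c("5p", "3p", ""), length.out = config$n_mirna)
    mirna_ids <- ifelse(arms == "",
                        sprintf("miR-%04d", seq_len(config$n_mirna)),
                        sprintf("miR-%04d-%s", seq_len(config$n_mirna), arms))
    hk_ids <- sprintf("HK_%02d", seq_len(config$n_housekeeping))
    spike_ids <- sprintf("POS_%d", seq_len(config$n_spike))
    ann <- probe_annotation(
      c(mirna_ids, hk_ids, spike_ids),
      c(rep("mirna", config$n_mirna),
        rep("housekeeping", config$n_housekeeping),
        rep("positive_control", config$n_spike)))

    mirna_total <- 1 - config$spike_fraction_normal - config$hk_fraction
    base <- stats::rlnorm(config$n_mirna, meanlog = 0, sdlog = config$base_sdlog)
    frac <- c(base / sum(base) * mirna_total,
              rep(config$hk_fraction / config$n_housekeeping, config$n_housekeeping),
              rep(config$spike_fraction_normal / config$n_spike, config$n_spike))
    names(frac) <- ann$probe_id

    # DE probes drawn from the upper 60% of base abundance so planted truth
    # is observable after the TPM<1 filter
    eligible <- mirna_ids[base >= stats::quantile(base, 0.4)]
    de_ids <- sort(sample(eligible, config$n_de))
    true_fc <- stats::setNames(
      stats::runif(config$n_de, config$de_fc_range[1], config$de_fc_range[2]), de_ids)

    samples <- sample_sheet(
      c(sprintf("control_%d", seq_len(config$n_control)),
        sprintf("case_%d", seq_len(config$n_case))),
      c(rep("control", config$n_control), rep("case", config$n_case)),
      protein_mg_per_ml = round(stats::rlnorm(config$n_control + config$n_case,
                                              log(2), 0.2), 3))
    n_samp <- nrow(samples)
    lib <- stats::rlnorm(n_samp, log(config$library_size_mean), 0.15)
    names(lib) <- samples$sample_id

    planted <- config$planted_qc_failures
    planted_modes <- stats::setNames(vapply(planted, `[[`, "", "mode"),
                                     vapply(planted, `[[`, "", "sample"))
    unknown <- setdiff(names(planted_modes), samples$sample_id)
    if (length(unknown)) stop(sprintf("planted QC failure names unknown sample '%s'", unknown[1]))
    lib[names(planted_modes)[planted_modes == "low_reads"]] <- 6e5

    fc_col <- matrix(1, nrow(ann), n_samp, dimnames = list(ann$probe_id, samples$sample_id))
    fc_col[de_ids, samples$sample_id[samples$group == "case"]] <- true_fc

    mu <- frac * fc_col  # recycles frac down columns
    spike_rows <- ann$probe_class == "positive_control"
    hk_rows <- ann$probe_class == "housekeeping"
    for (s in names(planted_modes)[planted_modes == "high_spike"]) {
      mu[spike_rows, s] <- mu[spike_rows, s] * (0.15 / config$spike_fraction_normal)
      mu[!spike_rows, s] <- mu[!spike_rows, s] *
        ((1 - 0.15) / (1 - config$spike_fraction_normal))
    }
    for (s in names(planted_modes)[planted_modes == "high_cv"]) {
      mu[hk_rows, s] <- mu[hk_rows, s] * stats::rlnorm(sum(hk_rows), 0, 0.4)
    }
    mu <- sweep(mu, 2, lib / colSums(mu), `*`)

    size <- ifelse(ann$probe_class == "mirna",
                   1 / config$nb_dispersion, 1 / config$hk_dispersion)
    counts <- matrix(stats::rnbinom(length(mu), mu = as.vector(mu),
                                    size = rep(size, times = n_samp)),
                     nrow(ann), n_samp, dimnames = dimnames(mu))
    list(counts = count_matrix(counts, ann),
         samples = samples,
         truth = list(de = data.frame(probe_id = de_ids, true_fc = unname(true_fc),
                                      stringsAsFactors = FALSE),
                      qc_failures = planted,
                      library_sizes = lib,
                      base_fraction = frac))
  })
}

#' The 23 analytes of the simulated cytokine panel
#' @noRd
panel_analytes <- function() {
  c("IL-1b", "IL-1a", "IL-2", "IL-3", "IL-4", "IL-5", "IL-6", "IL-9", "IL-10",
    "IL-12p40", "IL-12p70", "IL-13", "IL-17", "Eotaxin", "G-CSF", "GM-CSF",
    "IFNg", "KC", "MCP-1", "MIP-1a", "MIP-1b", "RANTES", "TNFa")
}

#' Simulate a censored multiplex cytokine panel
#'
#' Emulates a 23-plex bead immunoassay on serum sEV (`sev_plus`) and
#' sEV-deplete (`sev_minus`) fractions: per-analyte log-normal
#' concentrations, a configurable true case/control ratio per analyte and
#' fraction, and left-censoring at a per-analyte LLOQ (set at the 5th
#' percentile of the control concentration distribution, so a few percent
#' of healthy values fall below it).  Censored cells carry `NA` until
#' [impute_lloq()].
#'
#' @param config a [synthetic_config()].
#' @return list with `sev_plus` and `sev_minus` ([cytokine_table()]s),
#'   `samples` (a [sample_sheet()] with protein content), and `truth`
#'   (per-analyte true ratios).
#' @export
simulate_cytokines <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  with_seed(config$seed + 1000003L, {
    analytes <- panel_analytes()
    n1 <- config$cyt_n_control; n2 <- config$cyt_n_case
    samples <- sample_sheet(
      c(sprintf("cyt_control_%d", seq_len(n1)), sprintf("cyt_case_%d", seq_len(n2))),
      c(rep("control", n1), rep("case", n2)),
      protein_mg_per_ml = round(stats::rlnorm(n1 + n2, log(2), 0.2), 3))
    meanlog <- stats::setNames(stats::runif(length(analytes), log(50), log(5000)), analytes)
    sdlog <- 0.5

    expand_shift <- function(shift) {
      out <- stats::setNames(rep(1, length(analytes)), analytes)
      if (is.null(names(shift))) out[] <- shift else out[names(shift)] <- shift
      out
    }
    one_fraction <- function(shift) {
      ratio <- expand_shift(shift)
      conc <- matrix(NA_real_, length(analytes), n1 + n2,
                     dimnames = list(analytes, samples$sample_id))
      for (a in analytes) {
        ml <- meanlog[[a]] + ifelse(samples$group == "case", log(ratio[[a]]), 0)
        conc[a, ] <- stats::rlnorm(n1 + n2, ml, sdlog)
      }
      lloq <- stats::setNames(stats::qlnorm(0.05, meanlog, sdlog), analytes)
      censored <- sweep(conc, 1, lloq, `<`)
      conc[censored] <- NA_real_
      list(table = cytokine_table(conc, censored, lloq), ratio = ratio)
    }
    plus <- one_fraction(config$cytokine_shifts$sev_plus %||% 1)
    minus <- one_fraction(config$cytokine_shifts$sev_minus %||% 1)
    list(sev_plus = plus$table, sev_minus = minus$table, samples = samples,
         truth = list(shift_sev_plus = plus$ratio, shift_sev_minus = minus$ratio))
  })
}

#' Simulate target tables, gene sets, and reference signatures
#'
#' Emits the annotation resources downstream of differential expression: a
#' predicted miRNA-target table with scores in \[0, 1\] (a synthetic stand-in
#' for TargetScan-style aggregate P_CT scores), a validated subset
#' (miRTarBase-style), a GMT gene-set collection in which a few terms are
#' deliberately enriched for targets of the planted DE miRNAs, and
#' reference signature lists that overlap the planted DE set by the
#' configured counts (decoy names and species prefixes are added so that
#' name harmonization is exercised).
#'
#' @param config a [synthetic_config()].
#' @param truth the `truth` element of [simulate_counts()] run under the
#'   same config (supplies the planted DE probe ids).
#' @return list with `predicted`, `validated` (target tables), `gene_sets`
#'   (a [gene_set_collection()]), and `signatures` (as [read_signatures()]).
#' @export
simulate_annotation <- function(config = synthetic_config(),
                                truth = simulate_counts(config)$truth) {
  stopifnot(inherits(config, "synthetic_config"))
  if (any(config$signature_overlaps > nrow(truth$de))) {
    stop("signature_overlaps cannot exceed the number of planted DE miRNAs")
  }
  with_seed(config$seed + 2000003L, {
    genes <- sprintf("GENE%04d", seq_len(config$n_genes))
    de_ids <- truth$de$probe_id
    other <- sprintf("miR-%04d-5p", config$n_mirna + seq_len(200))
    query_mirnas <- c(de_ids, sample(other, 100))

    pred <- do.call(rbind, lapply(query_mirnas, function(m) {
      tg <- sample(genes, 15)
      data.frame(mirna = m, gene = tg, score = stats::runif(15),
                 evidence = "predicted", stringsAsFactors = FALSE)
    }))
    val_idx <- pred$score > 0.5 & stats::runif(nrow(pred)) < 0.6
    val <- pred[val_idx, c("mirna", "gene")]
    val$score <- NA_real_
    val$evidence <- "validated"
    rownames(val) <- NULL

    # gene pool actually selected at the default 0.9 threshold for DE miRNAs
    sel <- consolidate_targets(de_ids, pred, val, threshold = 0.9)
    pool <- sel$genes
    if (length(pool) < 5) pool <- unique(pred$gene[pred$mirna %in% de_ids])

    sets <- list()
    for (i in 1:5) {
      k <- sample(20:40, 1)
      n_hit <- min(length(pool), ceiling(0.6 * k))
      sets[[sprintf("TERM_ENRICHED_%02d", i)]] <-
        unique(c(sample(pool, n_hit), sample(genes, k - n_hit)))
    }
    for (i in 1:20) {
      sets[[sprintf("TERM_RANDOM_%02d", i)]] <- sample(genes, sample(20:60, 1))
    }
    gsc <- gene_set_collection(sets, background = genes)

    overlaps <- config$signature_overlaps
    decoys <- sprintf("miR-9%03d-3p", seq_len(500))
    signatures <- stats::setNames(lapply(seq_along(overlaps), function(i) {
      hits <- sample(de_ids, overlaps[[i]])
      noise <- sample(decoys, 12)
      list(study_id = names(overlaps)[i],
           sample_type = names(overlaps)[i],
           comparison = "case_vs_control", treatment = "untreated",
           mirnas = paste0("hsa-", sample(c(hits, noise))))
    }), names(overlaps))
    list(predicted = pred, validated = val, gene_sets = gsc, signatures = signatures)
  })
}
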