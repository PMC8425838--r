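#' Bundled TFM cohort reference tables
#'
#' The package ships small transcriptions of the TFM serum sEV cohort's
#' published result tables so that its statistical machinery can be
#' verified directly against them:
#'
#' * `tfm_cytokine_summary()` - the 23-plex sEV-fraction cytokine panel
#'   summary (protein-normalized pg/mg): per analyte the control (n = 6)
#'   and TFM (n = 8) mean and SD, plus the printed Welch p and BH-adjusted
#'   p for comparison.
#' * `tfm_de_table()` - the 57 probes reported as significantly
#'   up-regulated in TFM sEVs (housekeeping-relative fold change and
#'   permutation p).  One housekeeping probe (HK_RPL27) appears among the
#'   reported rows and is kept verbatim.
#' * `crps_signatures()` - the four prior CRPS patient study signatures
#'   (exosome and whole-blood; untreated case-control and pre/post
#'   treatment comparisons) used for cross-cohort overlap.
#'
#' @return a `data.frame` (or, for `crps_signatures()`, a signature list as
#'   from [read_signatures()]).
#' @export
tfm_cytokine_summary <- function() {
  utils::read.table(system.file("extdata", "tfm_cytokine_sev_summary.tsv",
                                package = "sevmir"),
                    header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}

#' @rdname tfm_cytokine_summary
#' @export
tfm_de_table <- function() {
  utils::read.table(system.file("extdata", "tfm_de_mirnas.tsv", package = "sevmir"),
                    header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}

#' @rdname tfm_cytokine_summary
#' @export
crps_signatures <- function() {
  read_signatures(system.file("extdata", "crps_reference_signatures.tsv",
                              package = "sevmir"))
}
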