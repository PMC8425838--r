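# In-code fixtures shared across test files.

# Wrap a plain matrix as an expression object without running the upstream
# stages (used to feed specific values into single operations).
make_expr <- function(values, annotation = NULL, unit = "tpm", pseudocount = NA_real_) {
  if (is.null(annotation)) annotation <- probe_annotation(rownames(values))
  structure(list(values = values, annotation = annotation, unit = unit,
                 pseudocount = pseudocount, provenance = character(),
                 dropped_samples = character()),
            class = "sev_expr")
}

# A tiny fully annotated count matrix: 3 miRNA + 2 housekeeping + 1 spike
# probes over 2 control + 2 case samples.
tiny_counts <- function(counts = NULL) {
  probes <- c("miR-a-5p", "miR-b-3p", "miR-c", "HK_1", "HK_2", "POS_1")
  if (is.null(counts)) {
    counts <- matrix(c(100, 200, 50, 1000, 1000, 40,
                       110, 190, 60, 1100, 1050, 45,
                       300, 100, 55, 950, 1000, 38,
                       320, 120, 55, 1020, 980, 42),
                     nrow = 6,
                     dimnames = list(probes, c("control_1", "control_2",
                                               "case_1", "case_2")))
  }
  count_matrix(counts, probe_annotation(
    probes, c("mirna", "mirna", "mirna", "housekeeping", "housekeeping",
              "positive_control")))
}

tiny_design <- function() {
  sample_sheet(c("control_1", "control_2", "case_1", "case_2"),
               c("control", "control", "case", "case"),
               protein_mg_per_ml = c(2, 2.2, 1.8, 2.1))
}

# Down-scaled synthetic study for fast property loops.
small_config <- function(seed = 1L, ...) {
  args <- list(n_mirna = 300L, n_de = 20L, n_genes = 300L,
               signature_overlaps = c(exosome = 8L, whole_blood = 15L),
               seed = seed)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(synthetic_config, args)
}

# Brute-force hypergeometric upper tail by enumerating all draws (N <= 12).
enum_hyper_p <- function(k, K, n, N) {
  pop <- c(rep(1, K), rep(0, N - K))
  draws <- utils::combn(N, n)
  hits <- apply(draws, 2, function(i) sum(pop[i]))
  mean(hits >= k)
}
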