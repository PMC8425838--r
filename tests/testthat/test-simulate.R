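test_that("count simulation is deterministic under a fixed seed", {
  cfg <- small_config(seed = 11L)
  a <- simulate_counts(cfg)
  b <- simulate_counts(cfg)
  expect_identical(a$counts$counts, b$counts$counts)
  expect_identical(a$truth$de, b$truth$de)
  c <- simulate_counts(small_config(seed = 12L))
  expect_false(identical(a$counts$counts, c$counts$counts))
})

test_that("planted QC failures are expressed in the emitted matrix", {
  cfg <- small_config(seed = 3L, planted_qc_failures = list(
    list(sample = "control_1", mode = "low_reads"),
    list(sample = "control_2", mode = "high_spike"),
    list(sample = "case_1", mode = "high_cv")))
  sim <- simulate_counts(cfg)
  cnt <- sim$counts$counts
  spike <- sim$counts$annotation$probe_class == "positive_control"
  hk <- sim$counts$annotation$probe_class == "housekeeping"
  expect_lt(sum(cnt[, "control_1"]), 1e6)
  expect_gt(sum(cnt[spike, "control_2"]) / sum(cnt[, "control_2"]), 0.10)
  cv <- sd(cnt[hk, "case_1"]) / mean(cnt[hk, "case_1"])
  expect_gte(cv, 0.15)
})

test_that("spike reads sit near their nominal share in healthy samples", {
  sim <- simulate_counts(synthetic_config(seed = 5L))
  cnt <- sim$counts$counts
  spike <- sim$counts$annotation$probe_class == "positive_control"
  planted <- vapply(sim$truth$qc_failures, `[[`, "", "sample")
  healthy <- setdiff(colnames(cnt), planted)
  frac <- colSums(cnt[spike, healthy]) / colSums(cnt[, healthy])
  expect_true(all(frac > 0.005 & frac < 0.08))
})

test_that("null cytokine panels give calibrated Welch type-I error", {
  # all shift ratios 1: the fraction of analytes with p < 0.05 should match
  # the nominal level over repeated simulation
  hits <- 0L; total <- 0L
  for (s in 1:40) {
    cfg <- small_config(seed = 100L + s,
                        cytokine_shifts = list(sev_plus = 1, sev_minus = 1))
    cyt <- simulate_cytokines(cfg)
    res <- analyze_cytokine_panel(list(sev_plus = cyt$sev_plus), cyt$samples,
                                  normalize_protein = FALSE)
    hits <- hits + sum(res$p < 0.05)
    total <- total + nrow(res)
  }
  rate <- hits / total
  # LLOQ imputation truncates the lower tail, so the test is slightly
  # conservative; allow generous binomial slack around 0.05
  se <- sqrt(0.05 * 0.95 / total)
  expect_lt(rate, 0.05 + 4 * se)
  expect_gt(rate, 0.05 - 6 * se)
})

test_that("an LLOQ above all values censors every entry of that analyte", {
  cfg <- small_config(seed = 9L)
  cyt <- simulate_cytokines(cfg)
  ct <- cyt$sev_plus
  a <- rownames(ct$conc)[1]
  ct$lloq[a] <- 1e9
  ct$censored[a, ] <- TRUE
  ct$conc[a, ] <- NA_real_
  imp <- impute_lloq(ct)
  expect_true(all(imp$conc[a, ] == 1e9))
  expect_equal(unname(sd(imp$conc[a, ])), 0)
})

test_that("simulated annotation honours configured signature overlaps", {
  cfg <- small_config(seed = 21L, signature_overlaps = c(exosome = 8L, whole_blood = 15L))
  sim <- simulate_counts(cfg)
  ann <- simulate_annotation(cfg, sim$truth)
  om <- overlap_matrix(sim$truth$de$probe_id, ann$signatures, policy = "strict")
  expect_equal(unname(om$column_counts["exosome"]), 8)
  expect_equal(unname(om$column_counts["whole_blood"]), 15)
  # emitted predicted scores live in [0,1] and strict thresholding works
  expect_true(all(ann$predicted$score >= 0 & ann$predicted$score <= 1))
  keep <- ann$predicted[ann$predicted$score > 0.9, ]
  expect_true(all(keep$score > 0.9))
  # determinism
  ann2 <- simulate_annotation(cfg, sim$truth)
  expect_identical(ann$gene_sets, ann2$gene_sets)
  expect_identical(ann$signatures, ann2$signatures)
})

test_that("infeasible configurations are rejected", {
  expect_error(synthetic_config(spike_fraction_normal = 1.2), "spike_fraction")
  expect_error(synthetic_config(n_de = 5000, n_mirna = 100), "n_de")
  expect_error(synthetic_config(de_fc_range = c(0.5, 2)), "de_fc_range")
  expect_error(synthetic_config(planted_qc_failures = list(list(sample = "x", mode = "bad"))),
               "mode")
})
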