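test_that("QC applies the published thresholds on reads, spike and CV", {
  # three samples engineered to fail exactly one rule each, one to pass
  probes <- c(paste0("m", 1:3), paste0("hk", 1:4), "pos")
  mk_col <- function(total, spike_frac, hk_cv_high = FALSE) {
    hk <- if (hk_cv_high) c(4000, 1000, 500, 2500) else c(2000, 2000, 2000, 2000)
    spike <- round(total * spike_frac)
    mir_total <- total - spike - sum(hk)
    v <- c(round(mir_total * c(0.5, 0.3, 0.2)), hk, spike)
    v[1] <- v[1] + (total - sum(v))   # pin the column total exactly
    v
  }
  m <- cbind(fail_reads = mk_col(999999, 0.02),
             fail_spike = mk_col(2e6, 0.12),
             fail_cv = mk_col(2e6, 0.02, hk_cv_high = TRUE),
             ok = mk_col(2e6, 0.02))
  rownames(m) <- probes
  cm <- count_matrix(m, probe_annotation(probes, c(rep("mirna", 3),
                                                   rep("housekeeping", 4),
                                                   "positive_control")))
  qc <- sample_qc(cm)
  expect_equal(qc$reasons[qc$sample_id == "fail_reads"], "low_total_reads")
  expect_equal(qc$reasons[qc$sample_id == "fail_spike"], "high_spike")
  expect_equal(qc$reasons[qc$sample_id == "fail_cv"], "high_cv")
  expect_true(qc$pass[qc$sample_id == "ok"])
  expect_equal(qc$reasons[qc$sample_id == "ok"], "")

  # spike comparator fails at exactly the threshold (>= 0.10)
  m2 <- cbind(border = mk_col(2e6, 0.10))
  rownames(m2) <- probes
  cm2 <- count_matrix(m2, cm$annotation)
  expect_false(sample_qc(cm2)$pass)
})

test_that("QC pass/fail is monotone in thresholds", {
  sim <- simulate_counts(small_config(seed = 31L))
  base <- sample_qc(sim$counts)
  loose <- sample_qc(sim$counts,
                     qc_thresholds(min_total_reads = 5e5,
                                   max_spike_fraction = 0.3, max_cv = 0.5))
  expect_true(all(loose$pass[base$pass]))
})

test_that("dropping failed samples enforces the minimum group size", {
  sim <- simulate_counts(synthetic_config(seed = 2L))
  qc <- sample_qc(sim$counts)
  kept <- drop_failed_samples(sim$counts, qc, sim$samples)
  expect_equal(ncol(kept$counts), 8)      # 5 + 4 with control_1 planted out
  expect_false("control_1" %in% colnames(kept$counts))

  cm <- tiny_counts()
  ok <- sample_qc(cm, qc_thresholds(min_total_reads = 10))
  expect_identical(drop_failed_samples(cm, ok, tiny_design())$counts, cm$counts)
  fail_one <- ok
  fail_one$pass[fail_one$sample_id == "case_1"] <- FALSE
  expect_error(drop_failed_samples(cm, fail_one, tiny_design()), ">= 2 samples")
})

test_that("TPM columns are proportions scaled to 1e6 and honour lengths", {
  # proportions forced with unit lengths
  m <- matrix(c(100, 300, 600), 3, 1, dimnames = list(paste0("p", 1:3), "s1"))
  em <- tpm_normalize(count_matrix(m))
  expect_equal(unname(em$values[, 1]), c(1e5, 3e5, 6e5))

  # one-probe matrix pegs at 1e6
  m1 <- matrix(5, 1, 1, dimnames = list("p1", "s1"))
  expect_equal(unname(tpm_normalize(count_matrix(m1))$values[1, 1]), 1e6)

  # direct evaluation of the length correction
  m2 <- matrix(c(10, 10), 2, 1, dimnames = list(c("p1", "p2"), "s1"))
  ann <- probe_annotation(c("p1", "p2"), "mirna", c(0.5, 1.0))
  em2 <- tpm_normalize(count_matrix(m2, ann))
  expect_equal(unname(em2$values[, 1]), c(666666.67, 333333.33), tolerance = 1e-6)

  # spike probes excluded from output and denominator
  cm <- tiny_counts()
  em3 <- tpm_normalize(cm)
  expect_false("POS_1" %in% rownames(em3$values))
  expect_equal(unname(colSums(em3$values)), rep(1e6, 4), tolerance = 1e-9)

  # scale invariance: multiplying a sample's counts leaves TPM unchanged
  cm2 <- cm
  cm2$counts[, "case_1"] <- cm$counts[, "case_1"] * 7
  expect_equal(tpm_normalize(cm2)$values, em3$values, tolerance = 1e-12)

  # equal lengths reduce TPM to counts-per-million (oracle)
  keep <- cm$annotation$probe_class != "positive_control"
  cpm <- sweep(cm$counts[keep, ], 2, colSums(cm$counts[keep, ]), `/`) * 1e6
  expect_equal(em3$values, cpm, tolerance = 1e-12)

  # all-zero column errors with the sample named
  bad <- cm
  bad$counts[, "case_2"] <- 0
  expect_error(tpm_normalize(bad), "case_2")
})

test_that("log transform applies log2 with the requested pseudocount", {
  m <- matrix(c(0, 1, 7), 3, 1, dimnames = list(paste0("p", 1:3), "s1"))
  em <- make_expr(m)
  lt <- log_transform(em, pseudocount = 1)
  expect_equal(unname(lt$values[, 1]), c(0, 1, 3))
  expect_equal(lt$unit, "log2tpm")
  m2 <- matrix(1, 1, 1, dimnames = list("p1", "s1"))
  expect_equal(unname(log_transform(make_expr(m2), pseudocount = 0)$values[1, 1]), 0)
  expect_error(log_transform(em, pseudocount = -1), "pseudocount")
  expect_error(log_transform(em, pseudocount = 0), "zero values")
})

test_that("low-expression filter applies the group-wise and any-sample rules", {
  vals <- rbind(all_low   = c(0.2, 0.5, 0.9, 0.1),
                one_above = c(0.2, 1.5, 0.9, 0.1),
                all_above = c(2, 3, 4, 5),
                hk_low    = c(0.1, 0.1, 0.1, 0.1))
  colnames(vals) <- c("control_1", "control_2", "case_1", "case_2")
  ann <- probe_annotation(rownames(vals),
                          c("mirna", "mirna", "mirna", "housekeeping"))
  em <- make_expr(vals, ann)
  def <- low_expression_filter(em, tiny_design())
  expect_equal(def$removed, "all_low")
  any_mode <- low_expression_filter(em, tiny_design(), mode = "any_sample_below")
  expect_setequal(any_mode$removed, c("all_low", "one_above"))
  # housekeeping probes survive both modes
  expect_true("hk_low" %in% rownames(any_mode$expr$values))
})
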