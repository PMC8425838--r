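test_that("LLOQ imputation fills censored cells and touches nothing else", {
  conc <- matrix(c(10, NA, NA, 7), 2, dimnames = list(c("A", "B"), c("s1", "s2")))
  ct <- cytokine_table(conc, lloq = c(A = 3.2, B = 2))
  imp <- impute_lloq(ct)
  expect_equal(unname(imp$conc["A", "s2"]), 3.2)
  expect_equal(unname(imp$conc["B", "s1"]), 2)
  expect_equal(unname(imp$conc["A", "s1"]), 10)
  expect_equal(unname(imp$conc["B", "s2"]), 7)
  expect_true(all(imp$conc >= ct$conc, na.rm = TRUE))
  expect_equal(unname(attr(imp, "n_imputed")), c(1, 1))

  # censored value without an LLOQ is an error
  ct2 <- cytokine_table(conc)
  expect_error(impute_lloq(ct2), "no LLOQ")
  # nothing censored: table unchanged
  full <- cytokine_table(matrix(c(1, 2), 1, 2, dimnames = list("A", c("s1", "s2"))))
  expect_equal(impute_lloq(full)$conc, full$conc)
})

test_that("protein normalization divides by per-sample protein content", {
  conc <- matrix(c(500, 300), 1, 2, dimnames = list("A", c("s1", "s2")))
  ct <- cytokine_table(conc)
  des <- sample_sheet(c("s1", "s2"), c("control", "case"), c(2, 1))
  norm <- protein_normalize(ct, des)
  expect_equal(unname(norm$conc["A", ]), c(250, 300))
  expect_equal(norm$unit, "pg_per_mg")
  des0 <- sample_sheet(c("s1", "s2"), c("control", "case"), c(2, NA))
  expect_error(protein_normalize(ct, des0), "s2")
})

test_that("Welch from summary matches t.test on raw data to 1e-12", {
  set.seed(3)
  for (i in 1:10) {
    x <- rnorm(sample(3:9, 1), mean = runif(1, -2, 2), sd = runif(1, 0.5, 3))
    y <- rnorm(sample(3:9, 1), mean = runif(1, -2, 2), sd = runif(1, 0.5, 3))
    ref <- t.test(y, x)   # Welch by default
    w <- welch_from_summary(mean(x), sd(x), length(x), mean(y), sd(y), length(y))
    expect_equal(w$t, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(w$df, unname(ref$parameter), tolerance = 1e-12)
    expect_equal(w$p, ref$p.value, tolerance = 1e-12)
  }
  # conventions at zero variance
  expect_equal(welch_from_summary(5, 0, 4, 5, 0, 4)$p, 1)
  expect_equal(welch_from_summary(2, 1, 4, 2, 1, 4)$t, 0)
})

test_that("BH step-up matches the hand-computed example and p.adjust", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.3), 0.3)
  set.seed(4)
  p <- runif(50)
  expect_equal(bh_adjust(p), p.adjust(p, "BH"), tolerance = 1e-15)
  # monotone along sorted raw p, never below raw p
  adj <- bh_adjust(p)
  expect_true(all(diff(adj[order(p)]) >= -1e-15))
  expect_true(all(adj >= p))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\(0, 1\\]")
  expect_error(bh_adjust(c(0.5, 0)), "\\(0, 1\\]")
  # enlarged family size
  expect_equal(bh_adjust(c(0.01, 0.04), m = 4), c(0.04, 0.08))
})

test_that("Student t matches the hand-computed pooled case and t.test", {
  r <- students_t(c(1, 2, 3), c(4, 5, 6))
  expect_lt(abs(abs(r$t) - 3.674), 1e-3)
  expect_equal(r$df, 4)
  expect_lt(abs(r$p - 0.0214), 1e-3)
  ref <- t.test(c(4, 5, 6), c(1, 2, 3), var.equal = TRUE)
  expect_equal(r$t, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(r$p, ref$p.value, tolerance = 1e-12)
  # scale invariance and degenerate conventions
  r10 <- students_t(10 * c(1, 2, 3), 10 * c(4, 5, 6))
  expect_equal(r10$t, r$t, tolerance = 1e-12)
  expect_equal(students_t(c(2, 2), c(2, 2))$p, 1)
})

test_that("hind paw weight ratio follows 2R/(R+L) x 100", {
  expect_equal(hindpaw_weight_ratio(5, 5), 100)
  expect_equal(hindpaw_weight_ratio(1, 3), 50)
  expect_equal(hindpaw_weight_ratio(2, 0), 200)
  expect_error(hindpaw_weight_ratio(0, 0), "positive")
})

test_that("panel analysis flags a strongly shifted analyte and not its peers", {
  set.seed(8)
  n1 <- 6; n2 <- 8
  samples <- sample_sheet(c(paste0("c", 1:n1), paste0("t", 1:n2)),
                          rep(c("control", "case"), c(n1, n2)),
                          protein_mg_per_ml = rep(2, n1 + n2))
  conc <- rbind(shifted = c(rlnorm(n1, log(100), 0.1), rlnorm(n2, log(500), 0.1)),
                flat1 = rlnorm(n1 + n2, log(200), 0.1),
                flat2 = rlnorm(n1 + n2, log(50), 0.1))
  colnames(conc) <- samples$sample_id
  ct <- cytokine_table(conc)
  res <- analyze_cytokine_panel(list(f = ct), samples)
  expect_equal(res$analyte[which.min(res$p)], "shifted")
  expect_true(res$significant[res$analyte == "shifted"])

  # identical group distributions: same data duplicated as both groups
  dup <- cbind(conc[, 1:n1], conc[, 1:n1])
  colnames(dup) <- paste0("s", seq_len(2 * n1))
  des <- sample_sheet(colnames(dup), rep(c("control", "case"), each = n1),
                      protein_mg_per_ml = rep(1, 2 * n1))
  res2 <- analyze_cytokine_panel(list(f = cytokine_table(dup)), des)
  expect_true(all(res2$p == 1))
})
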