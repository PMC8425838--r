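test_that("housekeeping aggregate is a per-sample geometric mean divisor", {
  vals <- rbind(m1 = c(500, 80), HK_a = c(10, 100), HK_b = c(1000, 100))
  colnames(vals) <- c("s1", "s2")
  ann <- probe_annotation(rownames(vals), c("mirna", "housekeeping", "housekeeping"))
  em <- make_expr(vals, ann)
  norm <- housekeeping_normalize(em)
  # geometric mean of 10 and 1000 is 100
  expect_equal(unname(norm$values["m1", ]), c(5, 0.8))
  # after normalization the housekeeping aggregate equals 1 in every sample
  hk <- norm$values[c("HK_a", "HK_b"), ]
  expect_equal(unname(apply(hk, 2, function(x) exp(mean(log(x))))), c(1, 1))

  # a zero housekeeping TPM errors unless a pseudocount is supplied
  vals0 <- vals; vals0["HK_a", 1] <- 0
  em0 <- make_expr(vals0, ann)
  expect_error(housekeeping_normalize(em0), "zero housekeeping")
  expect_error(housekeeping_normalize(em0, pseudocount = 1), NA)
})

test_that("fold change is the ratio of group geometric means", {
  des <- tiny_design()
  vals <- rbind(same = c(3, 5, 3, 5),
                quad = c(2, 2, 8, 8),
                geo  = c(1, 1, 2, 4))
  colnames(vals) <- des$sample_id
  em <- make_expr(vals, unit = "hk_relative")
  fc <- fold_change(em, des)
  expect_equal(unname(fc["same"]), 1.0)
  expect_equal(unname(fc["quad"]), 4.0)
  expect_equal(unname(fc["geo"]), sqrt(8), tolerance = 1e-12)
  # reciprocity under group swap
  des_sw <- des; des_sw$group <- rev(des$group)
  expect_equal(unname(fc * fold_change(em, des_sw)), rep(1, 3), tolerance = 1e-12)
  # zeros demand a pseudocount
  vals0 <- vals; vals0[1, 1] <- 0
  expect_error(fold_change(make_expr(vals0, unit = "hk_relative"), des), "pseudocount")
})

test_that("exhaustive permutation p-values match enumeration identities", {
  des <- sample_sheet(paste0("s", 1:8), rep(c("control", "case"), each = 4))
  sep <- matrix(1:8, 1, dimnames = list("p1", paste0("s", 1:8)))
  em <- make_expr(sep, unit = "log2tpm")
  p <- permutation_t_test(em, des, scheme = "exhaustive")
  # complete separation: only the observed split and its mirror reach max |T|
  expect_equal(unname(p["p1"]), 2 / 70, tolerance = 1e-12)

  # identical groups: every relabeling ties
  same <- matrix(rep(c(1, 2, 3, 4), 2), 1, dimnames = list("p1", paste0("s", 1:8)))
  p1 <- permutation_t_test(make_expr(same, unit = "log2tpm"), des, scheme = "exhaustive")
  expect_equal(unname(p1["p1"]), 1.0)

  # p-values live on the k/70 grid
  sim <- simulate_counts(small_config(seed = 41L))
  wfp <- suppressWarnings(permutation_t_test(
    log_transform(tpm_normalize(drop_failed_samples(sim$counts, sample_qc(sim$counts),
                                                    sim$samples))),
    sim$samples, scheme = "exhaustive"))
  ks <- wfp * 70
  expect_equal(ks, round(ks), tolerance = 1e-9)
  expect_true(all(wfp >= 1 / 70))
})

test_that("monte-carlo p agrees with the exhaustive value within sampling error", {
  des <- sample_sheet(paste0("s", 1:8), rep(c("control", "case"), each = 4))
  sep <- matrix(1:8, 1, dimnames = list("p1", paste0("s", 1:8)))
  em <- make_expr(sep, unit = "log2tpm")
  B <- 9999
  p_mc <- permutation_t_test(em, des, scheme = "monte_carlo", B = B, seed = 7)
  p_true <- 2 / 70
  se <- sqrt(p_true * (1 - p_true) / B)
  expect_lt(abs(p_mc - p_true), 3 * se + 2 / B)
})

test_that("permutation p is invariant to affine transforms of a probe", {
  des <- sample_sheet(paste0("s", 1:8), rep(c("control", "case"), each = 4))
  set.seed(5)
  x <- matrix(rnorm(8 * 10), 10, 8,
              dimnames = list(paste0("p", 1:10), paste0("s", 1:8)))
  p0 <- permutation_t_test(make_expr(x, unit = "log2tpm"), des, scheme = "exhaustive")
  p1 <- permutation_t_test(make_expr(3 * x + 7, unit = "log2tpm"), des,
                           scheme = "exhaustive")
  expect_equal(p0, p1, tolerance = 1e-12)
})

test_that("constant probes get p = 1 with a warning, not an error", {
  des <- tiny_design()
  x <- rbind(flat = rep(2, 4), var = c(1, 2, 5, 6))
  colnames(x) <- des$sample_id
  expect_warning(p <- permutation_t_test(make_expr(x, unit = "log2tpm"), des,
                                         scheme = "exhaustive"),
                 "constant")
  expect_equal(unname(p["flat"]), 1.0)
})

test_that("pooled p-values rank probes like |t| and reach below 1/70", {
  sim <- simulate_counts(synthetic_config(seed = 8L))
  kept <- drop_failed_samples(sim$counts, sample_qc(sim$counts), sim$samples)
  norm <- housekeeping_normalize(low_expression_filter(tpm_normalize(kept))$expr,
                                 pseudocount = 1)
  lg <- log_transform(norm, pseudocount = 0)
  p <- suppressWarnings(permutation_t_test(lg, sim$samples, scheme = "pooled"))
  t_obs <- attr(p, "t_obs")
  expect_lt(min(p), 1 / 70)
  expect_gt(min(p), 0)
  # p decreases with |t|
  o <- order(abs(t_obs))
  expect_true(all(diff(p[o]) <= 1e-12))
})

test_that("DE calls require both the p and fold-change thresholds", {
  fc <- c(a = 2.5, b = 1.8, c = 0.3, d = 3.0)
  p <- c(a = 0.005, b = 0.005, c = 0.002, d = 0.5)
  tab <- call_differential(fc, p)
  calls <- setNames(tab$de_call, tab$probe_id)
  expect_true(calls[["a"]])    # both thresholds met, up
  expect_false(calls[["b"]])   # FC fails
  expect_true(calls[["c"]])    # down-regulation: FC <= 1/2
  expect_false(calls[["d"]])   # p fails
  expect_equal(tab$direction[tab$probe_id == "c"], "down")
  expect_equal(tab$p_perm, sort(tab$p_perm))

  # housekeeping probes are excluded from the BH family but still reported
  ann <- probe_annotation(c("a", "b", "c", "d"),
                          c("mirna", "mirna", "mirna", "housekeeping"))
  tab2 <- call_differential(fc, p, annotation = ann)
  expect_true(is.na(tab2$p_adj[tab2$probe_id == "d"]))
  expect_equal(sort(tab2$p_adj[tab2$probe_id != "d"]),
               sort(bh_adjust(p[c("a", "b", "c")])))
})

test_that("clustergram distances and deterministic tree behave as expected", {
  des <- tiny_design()
  set.seed(2)
  base <- rnorm(30)
  x <- cbind(control_1 = base,
             control_2 = base,                       # identical to control_1
             case_1 = -base,                         # anticorrelated
             case_2 = rnorm(30))                     # unrelated
  rownames(x) <- paste0("p", 1:30)
  cg <- sample_clustergram(make_expr(x, unit = "log2tpm"))
  expect_equal(cg$dist["control_1", "control_2"], 0, tolerance = 1e-12)
  expect_equal(cg$dist["control_1", "case_1"], 2, tolerance = 1e-12)
  expect_true(all(cg$dist >= 0 & cg$dist <= 2 + 1e-12))
  expect_equal(unname(diag(cg$dist)), rep(0, 4))
  # identical samples merge first, at height 0
  expect_equal(min(cg$hclust$height), 0, tolerance = 1e-12)
  expect_equal(sort(cg$leaf_order), sort(colnames(x)))
  expect_equal(cg$leaf_order[1:2], c("control_1", "control_2"))
  expect_match(cg$newick, "^\\(.*\\);$")

  # a constant sample column is an error naming the sample
  x2 <- x; x2[, "case_2"] <- 5
  expect_error(sample_clustergram(make_expr(x2, unit = "log2tpm")), "case_2")
})

test_that("newick serialization is parseable and preserves the tree", {
  skip_if_not_installed("ape")
  sim <- simulate_counts(small_config(seed = 19L))
  lg <- log_transform(tpm_normalize(sim$counts))
  cg <- sample_clustergram(lg)
  tr <- ape::read.tree(text = cg$newick)
  expect_equal(sort(tr$tip.label), sort(colnames(lg$values)))
  # ultrametric: all root-to-tip path lengths equal the root height
  depths <- ape::node.depth.edgelength(tr)
  tip_depths <- depths[seq_along(tr$tip.label)]
  expect_equal(max(tip_depths) - min(tip_depths), 0, tolerance = 1e-4)
})
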