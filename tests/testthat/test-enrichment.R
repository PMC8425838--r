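test_that("target consolidation intersects evidence with a strict score cut", {
  pred <- target_table(c("m1", "m1", "m1", "m2"),
                       c("gA", "gB", "gC", "gD"),
                       c(0.95, 0.90, 0.99, 0.92), "predicted")
  val <- target_table(c("m1", "m2", "m2"), c("gA", "gC", "gE"),
                      evidence = "validated")
  sel <- consolidate_targets(c("m1", "m2"), pred, val, threshold = 0.9)
  # gA: predicted 0.95 + validated -> in; gB: 0.90 is not > 0.9 -> out;
  # gC: predicted by m1, validated by m2 -> in; gD: predicted only; gE: validated only
  expect_equal(sel$genes, c("gA", "gC"))
  expect_equal(sel$support$gA, "m1")
  expect_setequal(sel$support$gC, c("m1", "m2"))
  # non-query miRNAs contribute nothing
  sel2 <- consolidate_targets("m1", pred, val, threshold = 0.9)
  expect_equal(sel2$genes, "gA")
})

test_that("hypergeometric p matches brute-force enumeration for N <= 12", {
  # the canonical 4-of-4 case: N=10, K=5, n=4 -> 5/210
  gsc <- gene_set_collection(list(T1 = paste0("g", 1:5)),
                             background = paste0("g", 1:10))
  rec <- hypergeom_enrich(paste0("g", c(1:3, 5)), gsc)
  expect_equal(rec$k, 4)
  expect_equal(rec$p_hyper, 5 / 210, tolerance = 1e-12)
  expect_equal(rec$p_hyper, enum_hyper_p(4, 5, 4, 10), tolerance = 1e-12)

  # randomized small cases against the enumeration oracle
  set.seed(6)
  for (i in 1:12) {
    N <- sample(5:12, 1)
    K <- sample(1:(N - 1), 1)
    n <- sample(1:(N - 1), 1)
    bg <- paste0("g", seq_len(N))
    set <- paste0("g", seq_len(K))
    query <- sample(bg, n)
    k <- length(intersect(query, set))
    rec <- hypergeom_enrich(query, gene_set_collection(list(T = set), background = bg))
    expect_equal(rec$p_hyper, enum_hyper_p(k, K, n, N), tolerance = 1e-12)
  }
})

test_that("hypergeometric p is monotone decreasing in the overlap k", {
  p_at_k <- vapply(0:4, function(k) {
    phyper(k - 1, 5, 5, 4, lower.tail = FALSE)
  }, 0)
  expect_true(all(diff(p_at_k) < 0))
  # degenerate corners through the module
  gsc <- gene_set_collection(list(T = paste0("g", 1:5)), background = paste0("g", 1:10))
  all_in <- hypergeom_enrich(paste0("g", 1:10), gsc)  # query = background
  expect_equal(all_in$p_hyper, 1)
  expect_equal(all_in$k, all_in$K)
  none <- suppressWarnings(hypergeom_enrich("g999", gsc))
  expect_equal(none$k, 0)
  expect_equal(none$p_hyper, 1)
})

test_that("background genes outside every term only act through N", {
  gsc1 <- gene_set_collection(list(T = c("a", "b")), background = c("a", "b", "c", "d"))
  gsc2 <- gene_set_collection(list(T = c("a", "b")),
                              background = c("a", "b", "c", "d", "e", "f"))
  r1 <- hypergeom_enrich(c("a", "b"), gsc1)
  r2 <- hypergeom_enrich(c("a", "b"), gsc2)
  expect_equal(r1$N, 4); expect_equal(r2$N, 6)
  expect_lt(r2$p_hyper, r1$p_hyper)  # same overlap, rarer under a bigger universe
})

test_that("top_terms orders by fdr, then p, then term id", {
  rec <- data.frame(term_id = c("T3", "T1", "T2", "T4"),
                    p_hyper = c(0.02, 0.01, 0.01, 0.001),
                    fdr = c(0.05, 0.02, 0.02, 0.02),
                    stringsAsFactors = FALSE)
  expect_equal(top_terms(rec, 3)$term_id, c("T4", "T1", "T2"))
  expect_equal(nrow(top_terms(rec, 30)), 4)
})

test_that("the term graph links terms by shared genes and clusters by Jaccard", {
  rec <- data.frame(term_id = c("A", "B", "C"),
                    fdr = c(0.01, 0.01, 0.02),
                    genes = c("g1,g2,g3", "g2,g3,g4", "g9,g10"),
                    stringsAsFactors = FALSE)
  tg <- term_graph(rec)
  expect_equal(nrow(tg$edges), 1)
  expect_equal(tg$edges$weight, 2)
  expect_setequal(c(tg$edges$term1, tg$edges$term2), c("A", "B"))
  # identical gene sets merge at height 0
  rec2 <- rec; rec2$genes[2] <- rec2$genes[1]
  tg2 <- term_graph(rec2)
  expect_equal(min(tg2$dendrogram$height), 0, tolerance = 1e-12)
  # fewer than two terms: no dendrogram
  tg1 <- term_graph(rec[1, , drop = FALSE])
  expect_null(tg1$dendrogram)
  expect_equal(tg1$newick, "A;")
})

test_that("planted enriched terms surface in synthetic enrichment", {
  cfg <- small_config(seed = 23L)
  sim <- simulate_counts(cfg)
  ann <- simulate_annotation(cfg, sim$truth)
  sel <- consolidate_targets(sim$truth$de$probe_id, ann$predicted, ann$validated)
  enr <- hypergeom_enrich(sel$genes, ann$gene_sets)
  sig <- enr$term_id[enr$significant]
  expect_gt(length(sel$genes), 0)
  expect_true(any(grepl("ENRICHED", sig)))
  top5 <- top_terms(enr, 5)$term_id
  expect_true(mean(grepl("ENRICHED", top5)) >= 0.6)
})
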