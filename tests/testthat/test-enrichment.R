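test_that("normalization scales challenged counts to the paired control total", {
  ctrl <- toy_table(c(10L, 20L), c(999990L, 10L), sample_id = "c")
  chal <- toy_table(c(10L, 30L), c(199992L, 8L), sample_id = "p",
                    condition = "phage")
  norm <- normalize_counts(chal, ctrl)
  expect_equal(attr(norm, "scale"), 5)
  expect_equal(norm$counts$count[norm$counts$position == 30L], 40)
  expect_equal(norm$total_reads, ctrl$total_reads, tolerance = 1e-9)
  # identity when totals already match
  same <- normalize_counts(toy_table(5L, 7L, condition = "phage"),
                           toy_table(9L, 7L))
  expect_equal(same$counts$count, 7)
  expect_error(normalize_counts(toy_table(integer(0), integer(0),
                                          condition = "phage"), ctrl),
               "zero total")
})

test_that("normalization conservation and fold-change antisymmetry hold on random tables", {
  set.seed(77)
  for (i in 1:1000) {
    n1 <- sample(1:12, 1)
    n2 <- sample(1:12, 1)
    a <- toy_table(sample.int(1000L, n1), sample.int(500L, n1, replace = TRUE),
                   sample_id = "a", condition = "phage")
    b <- toy_table(sample.int(1000L, n2), sample.int(500L, n2, replace = TRUE),
                   sample_id = "b")
    norm <- normalize_counts(a, b)
    expect_equal(norm$total_reads, b$total_reads, tolerance = 1e-9)
    # antisymmetry of log2fc under role swap, shared pseudocount
    fc_ab <- gene_log2_fold_change(a$total_reads, b$total_reads)
    fc_ba <- gene_log2_fold_change(b$total_reads, a$total_reads)
    expect_equal(fc_ab, -fc_ba, tolerance = 1e-12)
  }
})

test_that("log2 fold change follows the pseudocount formula", {
  expect_equal(gene_log2_fold_change(63, 1, 1), 5)
  expect_equal(gene_log2_fold_change(10, 10), 0)
  expect_equal(gene_log2_fold_change(0, 0), 0)
  expect_true(is.finite(gene_log2_fold_change(0, 1e9)))
  expect_error(gene_log2_fold_change(1, 1, pseudocount = 0))
})

test_that("Mann-Whitney exact p matches hand-enumerated labelings", {
  r <- mann_whitney_gene(c(3, 4), c(1, 2))
  expect_equal(r$U, 4)
  expect_equal(r$p.value, 2 / 6)
  expect_equal(r$method, "exact")
  r2 <- mann_whitney_gene(c(10, 11, 12), c(1, 2, 3))
  expect_equal(r2$p.value, 2 / 20)
  # identical multisets carry no separation
  expect_equal(mann_whitney_gene(c(5, 6, 7), c(5, 6, 7))$p.value, 1)
  # all-zero groups are degenerate with p = 1
  d <- mann_whitney_gene(c(0, 0), c(0, 0))
  expect_true(d$degenerate)
  expect_equal(d$p.value, 1)
})

test_that("exact Mann-Whitney agrees with the brute-force oracle under heavy ties", {
  set.seed(42)
  for (i in 1:200) {
    n <- sample(2:6, 1)
    m <- sample(2:6, 1)
    x <- sample(0:5, n, replace = TRUE)
    y <- sample(0:5, m, replace = TRUE)
    got <- mann_whitney_gene(x, y)
    want <- brute_force_mw(x, y)
    expect_equal(got$U, want$U)
    expect_equal(got$p.value, want$p.value, tolerance = 1e-12)
  }
})

test_that("tie-free exact p matches wilcox.test's doubled one-tail p", {
  set.seed(8)
  for (i in 1:50) {
    x <- sample(1:1000, 5)
    y <- sample(1001:2000, 6) - sample(0:900, 6, replace = TRUE)
    if (any(duplicated(c(x, y)))) next
    got <- mann_whitney_gene(x, y)
    ref <- suppressWarnings(wilcox.test(x, y, exact = TRUE))
    expect_equal(got$U, unname(ref$statistic))
    expect_equal(got$p.value, ref$p.value, tolerance = 1e-12)
  }
})

test_that("large-sample path uses a tie-corrected normal approximation", {
  set.seed(15)
  x <- rpois(40, 5)
  y <- rpois(35, 9)
  got <- mann_whitney_gene(x, y)
  expect_equal(got$method, "normal")
  ref <- suppressWarnings(wilcox.test(x, y, correct = TRUE))
  expect_equal(got$p.value, ref$p.value, tolerance = 1e-10)
})

test_that("U-test p is invariant to common positive scaling of both samples", {
  set.seed(3)
  for (i in 1:25) {
    x <- sample(0:20, 5, replace = TRUE)
    y <- sample(0:20, 5, replace = TRUE)
    p1 <- mann_whitney_gene(x, y)$p.value
    p2 <- mann_whitney_gene(x * 37.5, y * 37.5)$p.value
    expect_identical(p1, p2)
  }
})

test_that("BH adjustment matches the canonical step-up definition", {
  expect_equal(adjust_pvalues(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(adjust_pvalues(0.2), 0.2)
  expect_equal(adjust_pvalues(rep(1, 5)), rep(1, 5))
  expect_error(adjust_pvalues(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(5)
  for (i in 1:50) {
    p <- runif(sample(1:10, 1))
    expect_equal(adjust_pvalues(p), brute_force_bh(p), tolerance = 1e-12)
  }
})

test_that("hit calling applies both criteria in both replicates", {
  rec <- data.frame(
    gene_id = c("g1", "g2", "g3"),
    gene_length = c(900L, 900L, 900L),
    log2fc_A = c(2.5, 2.5, 6.0), log2fc_B = c(2.2, 2.5, 1.0),
    unique_insertions_challenged_A = c(3L, 1L, 10L),
    unique_insertions_challenged_B = c(2L, 5L, 10L))
  out <- call_hits(rec)
  expect_equal(out$hit, c(TRUE, FALSE, FALSE))
  expect_equal(out$strong_hit, c(FALSE, FALSE, FALSE))
  # strong tier needs > 5 in every replicate
  rec2 <- rec[1, ]
  rec2$log2fc_A <- 6.2
  rec2$log2fc_B <- 5.4
  expect_true(call_hits(rec2)$strong_hit)
})

test_that("small genes failing only the unique-insertion criterion are review-flagged, not promoted", {
  rec <- data.frame(
    gene_id = c("porA_like", "big", "weak_small"),
    gene_length = c(250L, 900L, 250L),
    log2fc_A = c(4, 4, 1), log2fc_B = c(3, 3, 1),
    unique_insertions_challenged_A = c(1L, 1L, 1L),
    unique_insertions_challenged_B = c(1L, 1L, 1L))
  out <- call_hits(rec)
  expect_equal(out$hit, c(FALSE, FALSE, FALSE))
  expect_equal(out$small_gene_flag, c(TRUE, FALSE, FALSE))
})

test_that("depleted genes are reported but never called", {
  rec <- data.frame(
    gene_id = "dep", gene_length = 900L,
    log2fc_A = -4, log2fc_B = -5,
    unique_insertions_challenged_A = 10L,
    unique_insertions_challenged_B = 10L)
  out <- call_hits(rec)
  expect_true(out$depleted)
  expect_false(out$hit)
})

test_that("raising thresholds never adds a hit (monotonicity on constructed records)", {
  set.seed(19)
  rec <- data.frame(
    gene_id = sprintf("g%03d", 1:200),
    gene_length = sample(200:2000, 200, replace = TRUE),
    log2fc_A = runif(200, -2, 8), log2fc_B = runif(200, -2, 8),
    unique_insertions_challenged_A = sample(0:10, 200, replace = TRUE),
    unique_insertions_challenged_B = sample(0:10, 200, replace = TRUE))
  prev <- call_hits(rec, fc_threshold = 1)$hit
  for (th in c(2, 3, 5)) {
    cur <- call_hits(rec, fc_threshold = th)$hit
    expect_true(all(!cur | prev))
    prev <- cur
  }
  h1 <- call_hits(rec, min_unique = 1)$hit
  h3 <- call_hits(rec, min_unique = 3)$hit
  expect_true(all(!h3 | h1))
})

test_that("replicate reproducibility is Pearson over finite pairs", {
  rec <- data.frame(log2fc_A = c(0, 1, 2, 4), log2fc_B = c(0, 1, 2, 4))
  expect_equal(replicate_reproducibility(rec), 1)
  rec2 <- data.frame(log2fc_A = 1:3, log2fc_B = 3:1)
  expect_equal(replicate_reproducibility(rec2), -1)
  # hand Pearson: cross 11.25, ssA 8.75, ssB 14.75
  rec3 <- data.frame(log2fc_A = c(0, 1, 2, 4), log2fc_B = c(0, 1, 3, 5))
  expect_equal(replicate_reproducibility(rec3),
               11.25 / sqrt(8.75 * 14.75), tolerance = 1e-12)
  expect_error(replicate_reproducibility(
    data.frame(log2fc_A = c(1, 1, 1), log2fc_B = 1:3)), "zero variance")
})

test_that("enrich_pair produces the per-gene record fields on a toy pair", {
  ann <- toy_annotation()
  # geneA harbours the resistance signal in the challenged sample
  chal <- toy_table(c(150L, 160L, 400L), c(40L, 23L, 1L), sample_id = "p",
                    condition = "phage")
  ctrl <- toy_table(c(150L, 155L, 400L, 700L), c(2L, 2L, 60L, 64L),
                    sample_id = "c")
  res <- enrich_pair(chal, ctrl, ann)
  a <- res[res$gene_id == "geneA", ]
  expect_equal(a$control_total, 4)
  expect_equal(a$challenged_total, 63)
  expect_equal(a$unique_insertions_challenged, 2L)
  # scale = 128/64 = 2 -> normalized 126; log2((126+1)/(4+1)) by hand
  expect_equal(a$challenged_norm, 126)
  expect_equal(a$log2fc, log2(127 / 5), tolerance = 1e-12)
  expect_true(a$p <= 1 && a$p >= 0)
  # genes with no sites anywhere are degenerate with p = 1
  b <- res[res$gene_id == "geneC", ]
  expect_equal(b$challenged_norm, 0)
  expect_equal(b$p[1], 1)
})

test_that("end-to-end enrichment recovers planted genes on the small simulation", {
  sim <- small_sim()
  rec <- enrich_experiment(sim$samples, sim$sample_sheet, sim$annotation)
  expect_equal(nrow(rec), 300L)          # no gene silently dropped
  expect_equal(rec$gene_id, sim$annotation$genes$gene_id)
  sc <- score_against_truth(rec[rec$hit, ], sim$truth)
  expect_gte(sc$sensitivity, 2 / 3)
  expect_lte(sc$false_positives, 2L)
  planted <- sim$truth$gene_id[sim$truth$planted]
  expect_gt(min(rec$mean_log2fc[rec$gene_id %in% planted]), 2)
  expect_true(all(rec$q >= rec$p_combined - 1e-12))
})

test_that("replicate correlation is near-perfect without escape and degrades with clonal escapees", {
  base <- function(eps, seed) {
    m <- selection_model(library_size = 2e4, read_depth = 2e5,
                         survivor_plate_capacity = 5e3,
                         escape_baseline = eps, seed = seed)
    sim <- simulate_experiment(model = m, n_genes = 300)
    rec <- enrich_experiment(sim$samples, sim$sample_sheet, sim$annotation)
    replicate_reproducibility(rec)
  }
  # with no phenotypic escape, the two challenges of one library agree
  expect_gt(base(0, 11L), 0.95)
  # clonal (per-mutant) escape plants one-replicate jackpot genes that
  # depress the all-gene correlation well below the escape-free value
  expect_lt(base(1e-3, 11L), base(0, 11L))
})
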