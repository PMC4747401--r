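test_that("fold change and average difference match their definitions", {
  em <- two_group_em(cbind(c(200, 150, 80), c(200, 150, 80)),
                     cbind(c(100, 150, 160), c(100, 150, 160)))
  fc <- compute_fc(em, group_A_cols(em), group_B_cols(em))
  expect_equal(fc$stat[fc$gene_id == "g1"], 2)
  expect_identical(fc$direction[fc$gene_id == "g1"], "up")
  expect_equal(fc$stat[fc$gene_id == "g2"], 1)
  expect_identical(fc$direction[fc$gene_id == "g2"], "none")
  expect_identical(fc$direction[fc$gene_id == "g3"], "down")

  ad <- compute_ad(em, group_A_cols(em), group_B_cols(em))
  expect_equal(ad$stat[ad$gene_id == "g1"], 100)
  expect_identical(ad$direction[ad$gene_id == "g2"], "none")
  # means quoted in the expression-bias discussion: 2322.72 vs 1992.72
  em2 <- two_group_em(matrix(2322.72, 1), matrix(1992.72, 1))
  ad2 <- compute_ad(em2, 1, 2)
  expect_equal(ad2$stat, 330, tolerance = 1e-9)
  expect_identical(ad2$direction, "up")
})

test_that("statistics agree with a per-gene loop oracle on random data", {
  set.seed(21)
  m <- matrix(rexp(50 * 6, 1 / 150), 50, 6)
  rownames(m) <- sprintf("g%02d", 1:50)
  em <- expression_matrix(m, "linear")
  fc <- compute_fc(em, 1:3, 4:6)
  ad <- compute_ad(em, 1:3, 4:6)
  for (g in rownames(m)) {
    ma <- mean(m[g, 1:3]); mb <- mean(m[g, 4:6])
    expect_equal(fc$stat[fc$gene_id == g], ma / mb)
    expect_equal(ad$stat[ad$gene_id == g], ma - mb)
    # direction concordance of the two statistics for positive means
    expect_identical(fc$stat[fc$gene_id == g] > 1,
                     ad$stat[ad$gene_id == g] > 0)
  }
})

test_that("swapping groups inverts statistics and directions", {
  set.seed(22)
  m <- matrix(rexp(40 * 4, 1 / 100), 40, 4)
  rownames(m) <- sprintf("g%02d", 1:40)
  em <- expression_matrix(m, "linear")
  fc <- compute_fc(em, 1:2, 3:4); fc_rev <- compute_fc(em, 3:4, 1:2)
  ad <- compute_ad(em, 1:2, 3:4); ad_rev <- compute_ad(em, 3:4, 1:2)
  i <- match(fc$gene_id, fc_rev$gene_id)
  expect_equal(fc$stat, 1 / fc_rev$stat[i])
  expect_equal(fc$magnitude, fc_rev$magnitude[i])
  j <- match(ad$gene_id, ad_rev$gene_id)
  expect_equal(ad$stat, -ad_rev$stat[j])
  flip <- c(up = "down", down = "up", none = "none")
  expect_identical(unname(flip[fc$direction]), fc_rev$direction[i])
})

test_that("top_n selects by magnitude with deterministic tie-breaks", {
  em <- two_group_em(matrix(c(9, 7, 5, 3, 2), 5), matrix(rep(1, 5), 5))
  ad <- compute_ad(em, 1, 2)
  top <- top_n(ad, 3)
  expect_setequal(names(top), c("g1", "g2", "g3"))
  expect_true(all(top == "up"))
  expect_error(top_n(ad, 6), "exceeds")
  expect_identical(length(top_n(ad, 5)), 5L)
  # idempotence of the selected set
  expect_setequal(names(top_n(ad, 5)), ad$gene_id)
  # invariance to input row order
  set.seed(30)
  m <- matrix(rexp(60 * 2, 1 / 50), 60, 2)
  rownames(m) <- sprintf("g%02d", 1:60)
  sh <- sample.int(60)
  em1 <- expression_matrix(m, "linear")
  em2 <- expression_matrix(m[sh, ], "linear")
  t1 <- top_n(compute_fc(em1, 1, 2), 20)
  t2 <- top_n(compute_fc(em2, 1, 2), 20)
  expect_identical(sort(names(t1)), sort(names(t2)))
})

test_that("genes with no direction are excluded from top lists", {
  em <- two_group_em(matrix(c(5, 5, 9), 3), matrix(c(5, 5, 3), 3))
  fc <- compute_fc(em, 1, 2)
  expect_error(top_n(fc, 3), "exceeds")
  expect_identical(names(top_n(fc, 1)), "g3")
})

test_that("two_drug_intersection keeps equal-direction shared genes", {
  s1 <- dgs(A = "up", B = "down", C = "up")
  s2 <- dgs(A = "up", B = "up", D = "down")
  out <- two_drug_intersection(s1, s2)
  expect_identical(names(out), "A")
  expect_identical(as.vector(unclass(out)), "up")
  expect_identical(length(two_drug_intersection(s1, s1)), 3L)
  expect_identical(length(two_drug_intersection(s1, dgs(Z = "up"))), 0L)
})

test_that("BD/IP/ID designs pick the prescribed sample groups", {
  cfg <- small_config(seed = 7)
  ex <- generate_cellline_experiment(cfg, "5-FU")
  em <- ex$matrix; truth <- ex$truth
  # ID at the last time point is dominated by planted signal genes
  id24 <- define_gene_class(em, "ID", drug = "5-FU", time_h = 24,
                            method = "FC", n = 100)
  planted <- truth$gene_id[truth$class != "null"]
  expect_gt(mean(names(id24) %in% planted), 0.85)
  # planted directions are recovered for non-stratum resistance genes
  res <- truth[truth$class == "resistance" & !truth$stratum, ]
  hit <- intersect(res$gene_id, names(id24))
  expect_gt(length(hit), 10)
  expect_identical(unname(unclass(id24)[hit]),
                   res$direction[match(hit, res$gene_id)])
  # BD contrast contains no treated samples: planted basal signal leads
  bd <- define_gene_class(em, "BD", method = "FC", n = 50)
  basal_like <- truth$gene_id[truth$class %in%
                                c("basal_difference", "drug_response")]
  expect_gt(mean(names(bd) %in% basal_like), 0.9)
  expect_error(define_gene_class(em, "ID", drug = "5-FU", time_h = 48,
                                 method = "FC", n = 10), "ID design needs")
  expect_error(define_gene_class(em, "IP", method = "FC"), "requires")
})

test_that("null data yield balanced directions in top lists", {
  cfg <- null_config(seed = 13)
  ex <- generate_cellline_experiment(cfg, "drugX")
  bd <- define_gene_class(ex$matrix, "BD", method = "FC", n = 300)
  frac_up <- mean(bd == "up")
  expect_gt(frac_up, 0.40)
  expect_lt(frac_up, 0.60)
})

test_that("expression bias report isolates method-exclusive genes", {
  cfg <- small_config(seed = 8)
  ex <- generate_cellline_experiment(cfg, "5-FU")
  em <- ex$matrix
  gA <- list(resistance_status = "resistant", drug = "5-FU",
             treatment_time_h = 24)
  gB <- list(resistance_status = "parental", drug = "5-FU",
             treatment_time_h = 24)
  fc <- define_gene_class(em, "ID", drug = "5-FU", time_h = 24,
                          method = "FC", n = 120)
  ad <- define_gene_class(em, "ID", drug = "5-FU", time_h = 24,
                          method = "AD", n = 120)
  rep <- expression_bias_report(fc, ad, em, gA, gB, labels = c("FC", "AD"))
  expect_setequal(rep$only_X, setdiff(names(fc), names(ad)))
  # report means equal an independent per-gene computation
  ia <- do.call(samples_where, c(list(em), gA))
  manual <- mean(rowMeans(em$values[rep$only_X, ia, drop = FALSE]))
  expect_equal(rep$report$mean_A[1], manual)
  # identical sets leave both exclusive lists empty
  same <- expression_bias_report(fc, fc, em, gA, gB)
  expect_identical(length(same$only_X), 0L)
  expect_identical(same$report$n, c(0L, 0L))
})
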