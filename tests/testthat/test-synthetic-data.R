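test_that("generator output is bit-identical for identical config and seed", {
  cfg <- small_config(seed = 51)
  a <- generate_cellline_experiment(cfg, "5-FU")
  b <- generate_cellline_experiment(cfg, "5-FU")
  expect_identical(a$matrix$values, b$matrix$values)
  expect_identical(a$truth, b$truth)
  c2 <- generate_cellline_experiment(cfg, "5-FU", seed = 52)
  expect_false(identical(a$matrix$values, c2$matrix$values))
  pre1 <- generate_clinical_cohort(cfg, a$truth)
  pre2 <- generate_clinical_cohort(cfg, a$truth)
  expect_identical(pre1$values, pre2$values)
})

test_that("experiment layout covers the full design factorial", {
  cfg <- small_config(seed = 53)
  ex <- generate_cellline_experiment(cfg, "L-OHP")
  em <- ex$matrix
  expect_identical(em$scale, "linear")
  expect_identical(ncol(em$values), 2L * 4L * 3L)
  for (st in c("parental", "resistant")) {
    expect_length(samples_where(em, resistance_status = st, drug = "none"),
                  3L)
    for (t in c(6, 12, 24))
      expect_length(samples_where(em, resistance_status = st,
                                  drug = "L-OHP", treatment_time_h = t), 3L)
  }
  # truth is consistent with configured class sizes
  expect_identical(sum(ex$truth$class == "resistance"), 30L)
  expect_identical(sum(ex$truth$stratum), 6L)
  expect_true(all(ex$truth$direction[ex$truth$class == "null"] == "none"))
})

test_that("ground truth round-trips losslessly through TSV", {
  cfg <- small_config(seed = 54)
  ex <- generate_cellline_experiment(cfg, "5-FU")
  f <- tempfile(fileext = ".tsv")
  utils::write.table(ex$truth, f, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  back <- utils::read.delim(f, stringsAsFactors = FALSE)
  expect_identical(back$gene_id, ex$truth$gene_id)
  expect_identical(back$class, ex$truth$class)
  expect_identical(back$stratum, ex$truth$stratum)
  expect_equal(back$baseline, ex$truth$baseline, tolerance = 1e-12)
})

test_that("null-gene baselines follow the configured log-normal", {
  cfg <- generator_config(seed = 55, n_genes = 5000, n_resistance = 50,
                          n_stratum = 5, n_drug_response = 50, n_basal = 50)
  ex <- generate_cellline_experiment(cfg, "5-FU")
  nulls <- ex$truth$baseline[ex$truth$class == "null"]
  ks <- suppressWarnings(stats::ks.test(nulls, "pnorm", 8, 1.5))
  expect_gt(ks$p.value, 0.01)
})

test_that("planted kinetics: resistance effects grow, induction is transient", {
  cfg <- small_config(seed = 56, noise_sd = 0.05)
  ex <- generate_cellline_experiment(cfg, "5-FU")
  em <- ex$matrix; truth <- ex$truth
  res <- truth$gene_id[truth$class == "resistance" & !truth$stratum]
  traj <- trajectory_table(em, res, "5-FU", c(6, 12, 24))
  m6 <- mean(abs(traj$log2_fc[traj$time_h == 6]))
  m24 <- mean(abs(traj$log2_fc[traj$time_h == 24]))
  expect_gt(m24, m6)
  # drug-response genes: parental induction peaks at 12 h, decays by 24 h
  dr <- truth[truth$class == "drug_response", ]
  ip_lfc <- function(t) {
    ia <- samples_where(em, resistance_status = "parental", drug = "5-FU",
                        treatment_time_h = t)
    ib <- samples_where(em, resistance_status = "parental", drug = "none")
    sgn <- ifelse(dr$direction == "up", 1, -1)
    mean(sgn * (rowMeans(log2(em$values[dr$gene_id, ia, drop = FALSE])) -
                  rowMeans(log2(em$values[dr$gene_id, ib, drop = FALSE]))))
  }
  expect_gt(ip_lfc(12), ip_lfc(6))
  expect_gt(ip_lfc(12), ip_lfc(24))
  expect_gt(ip_lfc(24), 0)
})

test_that("clinical cohorts carry attenuated effects and batch structure", {
  cfg <- small_config(seed = 57, n_responders = 8, n_nonresponders = 8)
  ex <- generate_cellline_experiment(cfg, "5-FU")
  pre <- generate_clinical_cohort(cfg, ex$truth)
  expect_identical(pre$scale, "linear")
  expect_identical(ncol(pre$values), 16L)
  expect_setequal(unique(pre$samples$dataset_id), c("D1", "D2"))
  expect_identical(sum(pre$samples$response == "responder"), 8L)
  # non-responders are shifted along the planted resistance directions
  truth <- ex$truth
  res <- truth[truth$class == "resistance" & !truth$stratum, ]
  nr <- samples_where(pre, response = "non_responder")
  rr <- samples_where(pre, response = "responder")
  lfc <- rowMeans(log2(pre$values[res$gene_id, nr, drop = FALSE])) -
    rowMeans(log2(pre$values[res$gene_id, rr, drop = FALSE]))
  sgn <- ifelse(res$direction == "up", 1, -1)
  expect_gt(mean(sgn * lfc), 0.3)
  # with zero attenuation the shift disappears
  cfg0 <- small_config(seed = 57, n_responders = 8, n_nonresponders = 8,
                       attenuation = 0)
  pre0 <- generate_clinical_cohort(cfg0, ex$truth)
  lfc0 <- rowMeans(log2(pre0$values[res$gene_id,
                                    samples_where(pre0, response = "non_responder"),
                                    drop = FALSE])) -
    rowMeans(log2(pre0$values[res$gene_id,
                              samples_where(pre0, response = "responder"),
                              drop = FALSE]))
  expect_lt(abs(mean(sgn * lfc0)), 0.25)
})

test_that("post-chemotherapy cohorts add the treated state to all samples", {
  cfg <- small_config(seed = 58, clinical_noise_sd = 0.2,
                      n_responders_post = 6, n_nonresponders_post = 6)
  ex <- generate_cellline_experiment(cfg, "5-FU")
  both <- generate_clinical_cohorts(cfg, ex$truth)
  expect_named(both, c("pre_chemo", "post_chemo"))
  truth <- ex$truth
  dr <- truth[truth$class == "drug_response", ]
  sgn <- ifelse(dr$direction == "up", 1, -1)
  # responders show the sustained induction only post chemo
  r_pre <- samples_where(both$pre_chemo, response = "responder")
  r_post <- samples_where(both$post_chemo, response = "responder")
  delta <- rowMeans(log2(both$post_chemo$values[dr$gene_id, r_post,
                                                drop = FALSE])) -
    rowMeans(log2(both$pre_chemo$values[dr$gene_id, r_pre, drop = FALSE]))
  expect_gt(mean(sgn * delta), 0.5)
})

test_that("invalid generator configurations are rejected", {
  expect_error(generator_config(n_genes = 100, n_resistance = 80,
                                n_drug_response = 30, seed = 1),
               "exceed")
  expect_error(generator_config(n_resistance = 5, n_stratum = 10, seed = 1),
               "n_stratum")
  expect_error(generator_config(noise_sd = 0, seed = 1), "positive")
  expect_error(generator_config(), "required")
})
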