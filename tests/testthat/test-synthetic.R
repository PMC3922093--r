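test_that("default cohort reproduces the study structure", {
  co <- generate_cohort(cohort_config(n_probes = 500, seed = 1))
  expect_equal(ncol(co$expression), 45)
  expect_equal(sum(co$metadata$label == "non_recurrent"), 33)
  expect_equal(sum(co$metadata$label == "metastatic"), 12)
  expect_setequal(co$metadata$sample_id, colnames(co$expression))
  expect_true(all(co$truth %in% rownames(co$expression)))
  expect_length(co$truth, 14)

  mm <- co$metadata[co$metadata$label == "metastatic", ]
  nr <- co$metadata[co$metadata$label == "non_recurrent", ]
  expect_true(all(mm$event == 1) && all(nr$event == 0))
  expect_gte(median(mm$dfs_months), 8)
  expect_lte(median(mm$dfs_months), 20)
  expect_true(all(nr$dfs_months >= 41 & nr$dfs_months <= 115))
})

test_that("generation is reproducible from the seed and sensitive to it", {
  cfg <- cohort_config(n_probes = 80, seed = 42)
  a <- generate_cohort(cfg); b <- generate_cohort(cfg)
  expect_identical(a$expression, b$expression)
  expect_identical(a$metadata, b$metadata)
  expect_identical(a$genesets, b$genesets)
  c <- generate_cohort(cohort_config(n_probes = 80, seed = 43))
  expect_false(identical(a$expression, c$expression))
})

test_that("planted down-shift behaves as configured", {
  # full penetrance, clear effect: every planted probe lower in metastatic
  co <- generate_cohort(cohort_config(n_probes = 100, effect_size = 2,
                                      penetrance = 1, noise_sd = 0.5, seed = 7))
  met <- co$metadata$sample_id[co$metadata$label == "metastatic"]
  nr <- co$metadata$sample_id[co$metadata$label == "non_recurrent"]
  diffs <- rowMeans(co$expression[co$truth, met]) -
    rowMeans(co$expression[co$truth, nr])
  expect_true(all(diffs < 0))

  # no effect: group differences centered at zero, downstream AUC near chance
  co0 <- generate_cohort(cohort_config(n_probes = 400, effect_size = 0, seed = 1))
  met <- co0$metadata$sample_id[co0$metadata$label == "metastatic"]
  nr <- co0$metadata$sample_id[co0$metadata$label == "non_recurrent"]
  d0 <- rowMeans(co0$expression[, met]) - rowMeans(co0$expression[, nr])
  expect_lt(abs(mean(d0)), 0.1)
  auc <- roc_analysis(below_median_counts(co0$expression, co0$truth),
                      co0$metadata$label)$auc
  expect_gt(auc, 0.3); expect_lt(auc, 0.7)
})

test_that("classifier AUC is non-decreasing in the planted effect size", {
  aucs <- vapply(c(0.5, 1.5, 3), function(d) {
    co <- generate_cohort(cohort_config(n_probes = 200, effect_size = d, seed = 11))
    roc_analysis(below_median_counts(co$expression, co$truth),
                 co$metadata$label)$auc
  }, numeric(1))
  expect_true(all(diff(aucs) >= 0))
})

test_that("permuting labels destroys the planted association", {
  co <- generate_cohort(cohort_config(n_probes = 150, effect_size = 2, seed = 3))
  set.seed(5)
  mean_t <- mean(replicate(40, {
    perm <- sample(co$metadata$label)
    de <- differential_screen(co$expression[co$truth, ], perm)
    mean(de$t)
  }))
  expect_lt(abs(mean_t), 0.25)
})

test_that("invalid configurations are rejected with the violated field named", {
  expect_error(cohort_config(n_nonrecurrent = 0), "n_nonrecurrent")
  expect_error(cohort_config(n_nonrecurrent = 2, n_metastatic = 1), "n_nonrecurrent")
  expect_error(cohort_config(penetrance = 1.2), "penetrance")
  expect_error(cohort_config(noise_sd = 0), "noise_sd")
  expect_error(cohort_config(n_probes = 5), "n_probes")
  expect_error(cohort_config(followup_range = c(10, 5)), "followup_range")
})

test_that("duplicate-probe mode plants two probes per signature gene", {
  co <- generate_cohort(cohort_config(n_probes = 100,
                                      duplicate_signature_probes = TRUE, seed = 1))
  expect_length(co$truth, 28)
  ann <- co$probe_annotation
  sig_counts <- table(ann$gene_symbol[ann$gene_symbol %in% immune_signature_genes()])
  expect_true(all(sig_counts == 2))
  # collapsing recovers the 14 unique symbols
  expect_length(map_probes_to_genes(co$truth, ann), 14)
})

test_that("qPCR generator is deterministic and shifts the metastatic group", {
  a <- generate_qpcr(n_per_group = 5, genes = c("CD74", "CXCL9"), effect = 2, seed = 9)
  b <- generate_qpcr(n_per_group = 5, genes = c("CD74", "CXCL9"), effect = 2, seed = 9)
  expect_identical(a, b)

  # reference present for every sample, calibrator covers every gene
  expect_true(all(table(a$sample_id[a$gene == "ACTB"]) == 1))
  cal <- a[a$sample_id == "HT29", ]
  expect_setequal(cal$gene, c("CD74", "CXCL9", "ACTB"))

  # effect = 2 cycles -> about four-fold lower relative expression
  big <- generate_qpcr(n_per_group = 200, genes = "CD74", effect = 2, seed = 3)
  rq <- delta_delta_ct(big, "CD74")
  med <- tapply(rq$rq, rq$group, median)
  ratio <- med[["non_recurrent"]] / med[["metastatic"]]
  expect_gt(ratio, 2.8); expect_lt(ratio, 5.6)

  # no effect: group centers agree within noise
  null <- generate_qpcr(n_per_group = 200, genes = "CD74", effect = 0, seed = 3)
  rq0 <- delta_delta_ct(null, "CD74")
  med0 <- tapply(rq0$rq, rq0$group, median)
  expect_lt(abs(log2(med0[["non_recurrent"]] / med0[["metastatic"]])), 0.35)

  expect_error(generate_qpcr(n_per_group = 1), "n_per_group")
  expect_error(generate_qpcr(genes = character(0)), "genes")
})
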