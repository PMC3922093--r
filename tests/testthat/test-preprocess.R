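test_that("glog is the arsinh transform with a positive scale", {
  expect_equal(glog(0, c = 5), 0)
  expect_equal(glog(10, c = 2), asinh(5))
  expect_error(glog(1, c = 0), "positive")
  expect_error(glog(1, c = -1), "positive")
})

test_that("calibration maps identical arrays to identical columns and preserves ranks", {
  set.seed(1)
  col <- rexp(100, 1 / 50)
  raw <- cbind(a = col, b = col, c = col)
  rownames(raw) <- paste0("p", 1:100)
  norm <- normalize_glog(raw)
  expect_equal(norm[, "a"], norm[, "b"], ignore_attr = TRUE)
  expect_equal(norm[, "a"], norm[, "c"], ignore_attr = TRUE)

  raw2 <- cbind(a = col, b = col * 3 + 10)   # affine-distorted replicate
  rownames(raw2) <- paste0("p", 1:100)
  norm2 <- normalize_glog(raw2)
  expect_equal(order(norm2[, "b"]), order(raw2[, "b"]))

  expect_error(normalize_glog(raw - 100), "negative")
  expect_error(normalize_glog(raw[, 1, drop = FALSE]), "2 arrays")
})

test_that("glog stabilizes replicate spread across the intensity range", {
  set.seed(11)
  n <- 4000
  mu <- exp(runif(n, log(10), log(1e5)))
  make_arr <- function() mu * exp(rnorm(n, 0, 0.15)) + rnorm(n, 0, 50) + 60
  raw <- cbind(a = make_arr(), b = make_arr())
  raw[raw < 0] <- 0
  rownames(raw) <- paste0("p", 1:n)
  deciles <- cut(rank(mu), 10)
  spread <- function(d) tapply(d, deciles, sd)
  before <- spread(raw[, 1] - raw[, 2])
  norm <- normalize_glog(raw)
  after <- spread(norm[, 1] - norm[, 2])
  expect_gt(max(before) / min(before), 10)
  expect_lt(max(after) / min(after), 3)
})

test_that("bh_adjust matches hand-evaluated and brute-force step-up values", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.37), 0.37)
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  expect_error(bh_adjust(c(0.5, NA)), "\\[0, 1\\]")

  set.seed(8)
  for (i in 1:25) {
    p <- runif(sample(1:20, 1))
    expect_equal(bh_adjust(p), bh_brute(p))
  }
  # order-preserving in the p ranking
  p <- runif(50)
  q <- bh_adjust(p)
  expect_true(all(diff(q[order(p)]) >= -1e-12))
})

test_that("the differential screen flags a constructed strong effect and degenerate probes behave", {
  co <- generate_cohort(cohort_config(n_probes = 500, effect_size = 0, seed = 2))
  x <- co$expression
  lab <- co$metadata$label
  x["P000020", lab == "metastatic"] <- x["P000020", lab == "metastatic"] - 8
  de <- differential_screen(x, lab)
  expect_true(de$flagged[de$probe_id == "P000020"])

  x["P000030", ] <- 5  # zero variance in both groups
  expect_warning(de2 <- differential_screen(x, lab), "zero variance")
  expect_equal(de2$pvalue[de2$probe_id == "P000030"], 1)
})

test_that("the screen is invariant to column order and label encoding", {
  co <- generate_cohort(cohort_config(n_probes = 60, seed = 6))
  de <- differential_screen(co$expression, co$metadata$label)
  perm <- sample(ncol(co$expression))
  de_perm <- differential_screen(co$expression[, perm],
                                 co$metadata$label[perm])
  expect_equal(de$pvalue, de_perm$pvalue)
  expect_equal(de$flagged, de_perm$flagged)

  relab <- ifelse(co$metadata$label == "metastatic", "1", "0")
  de_rl <- differential_screen(co$expression, relab)
  expect_equal(de$pvalue, de_rl$pvalue)
  expect_equal(abs(de$t), abs(de_rl$t))
  expect_equal(de$flagged, de_rl$flagged)
})

test_that("pure-noise cohorts rarely produce flagged probes", {
  flags <- vapply(1:30, function(s) {
    co <- generate_cohort(cohort_config(n_probes = 500, effect_size = 0,
                                        seed = 100 + s))
    sum(differential_screen(co$expression, co$metadata$label)$flagged)
  }, numeric(1))
  expect_gte(mean(flags == 0), 0.8)
  expect_lt(mean(flags), 0.5)
})

test_that("heterogeneous planting defeats the univariate screen while staying multivariately real", {
  # moderate effect, partial penetrance: the planted probes need not reach
  # the double threshold even though every one of them is truly shifted
  co <- generate_cohort(cohort_config(n_probes = 2000, seed = 1))
  de <- differential_screen(co$expression, co$metadata$label)
  expect_lte(sum(de$flagged[de$probe_id %in% co$truth]), length(co$truth))
  expect_true(all(de$qvalue >= 0 & de$qvalue <= 1))
})

test_that("projection and clustering center rows and separate a planted two-block cohort", {
  co <- generate_cohort(cohort_config(n_probes = 200, effect_size = 4,
                                      penetrance = 1, seed = 3))
  pr <- project_and_cluster(co$expression, co$truth)
  # every retained row scaled to mean 0, variance 1 (checked via the PCA input)
  x <- co$expression[pr$probes_used, ]
  xs <- t(scale(t(x)))
  expect_true(all(abs(rowMeans(xs)) < 1e-12))
  expect_true(all(abs(apply(xs, 1, sd) - 1) < 1e-12))

  cl <- cutree(pr$hclust, k = 2)
  lab <- co$metadata$label[match(names(cl), co$metadata$sample_id)]
  purity <- max(table(cl[lab == "metastatic"]))
  expect_gte(purity, 10)
})

test_that("duplicate samples merge at height zero and zero-variance rows are dropped", {
  set.seed(4)
  x <- matrix(rnorm(40), 10, 4,
              dimnames = list(paste0("p", 1:10), paste0("s", 1:4)))
  x[, 2] <- x[, 1]
  pr <- project_and_cluster(x)
  expect_equal(min(pr$heights), 0)

  x[3, ] <- 7
  expect_warning(pr2 <- project_and_cluster(x), "zero-variance")
  expect_false("p3" %in% pr2$probes_used)
})
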