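test_that("feature scores reflect class separation contribution", {
  # duplicated analytic two-point problem: w is proportional to (1, 0)
  x <- rbind(f1 = c(1, 1, -1, -1), f2 = c(0, 0, 0, 0))
  colnames(x) <- paste0("s", 1:4)
  sc <- svm_feature_scores(x, c("a", "a", "b", "b"))
  expect_gt(sc["f1"], 0)
  expect_equal(unname(sc["f2"]), 0)

  # a feature with identical class means scores exactly 0
  set.seed(3)
  x2 <- rbind(signal = c(rnorm(5, 2), rnorm(5, -2)), flat = rep(1:5, 2))
  colnames(x2) <- paste0("s", 1:10)
  lab <- rep(c("a", "b"), each = 5)
  sc2 <- svm_feature_scores(x2, lab)
  expect_equal(unname(sc2["flat"]), 0)

  # negating one feature leaves its score unchanged
  x3 <- x2; x3["signal", ] <- -x3["signal", ]
  sc3 <- svm_feature_scores(x3, lab)
  expect_equal(sc3["signal"], sc2["signal"], tolerance = 1e-3)

  expect_error(svm_feature_scores(x2, rep("a", 10)), "two classes")
})

test_that("the elimination ladder keeps planted features and validates its inputs", {
  pm <- planted_matrix()
  lad <- rsvm_ladder(pm$x, pm$labels, train_idx = c(1:22, 34:41),
                     test_idx = c(23:33, 42:45), ladder = c(20, 10, 5))
  # perfectly separable: zero held-out error at every level containing the planted set
  expect_true(all(lad$error_by_level == 0))
  expect_setequal(lad$features_by_level[["5"]], pm$planted)

  # single-level identity: all features retained
  lad1 <- rsvm_ladder(pm$x, pm$labels, train_idx = c(1:22, 34:41),
                      test_idx = c(23:33, 42:45), ladder = 20)
  expect_setequal(lad1$features_by_level[["20"]], rownames(pm$x))

  expect_error(rsvm_ladder(pm$x, pm$labels, train_idx = 1:30, test_idx = 25:45),
               "disjoint")
  expect_error(rsvm_ladder(pm$x, pm$labels, train_idx = 1:45,
                           test_idx = integer(0)), "non-empty")
})

test_that("bootstrap selection is deterministic and saturates when keeping everything", {
  pm <- planted_matrix(n_features = 30)
  cfg <- rsvm_config(n_bootstrap = 8, keep_per_step = 10, seed = 5)
  a <- bootstrap_select(pm$x, pm$labels, cfg)
  b <- bootstrap_select(pm$x, pm$labels, cfg)
  expect_identical(a$selection_count, b$selection_count)
  expect_identical(a$cv_error_by_level, b$cv_error_by_level)
  expect_setequal(a$signature_probes, names(a$selection_count)[a$selection_count > 0])

  # keep_per_step = n_features: every probe selected in every step
  cfg_all <- rsvm_config(n_bootstrap = 5, keep_per_step = 30, seed = 5)
  full <- bootstrap_select(pm$x, pm$labels, cfg_all)
  expect_true(all(full$selection_count == 5))
})

test_that("selected sets are invariant to global positive rescaling", {
  pm <- planted_matrix(n_features = 25)
  cfg <- rsvm_config(n_bootstrap = 6, keep_per_step = 8, seed = 3)
  a <- bootstrap_select(pm$x, pm$labels, cfg)
  b <- bootstrap_select(pm$x * 3.7, pm$labels, cfg)
  expect_identical(a$selection_count, b$selection_count)
})

test_that("planted probes are recovered with frequency increasing in effect size", {
  freqs <- vapply(c(0.5, 3), function(d) {
    co <- generate_cohort(cohort_config(n_probes = 120, effect_size = d,
                                        penetrance = 1, seed = 13))
    sel <- bootstrap_select(co$expression, co$metadata$label,
                            rsvm_config(n_bootstrap = 15, keep_per_step = 20,
                                        seed = 13))
    mean(sel$selection_count[co$truth])
  }, numeric(1))
  expect_gte(freqs[2], freqs[1])
})

test_that("permuted labels give chance-level out-of-bag error", {
  co <- generate_cohort(cohort_config(n_probes = 200, effect_size = 4,
                                      penetrance = 1, seed = 5))
  cfg <- rsvm_config(n_bootstrap = 40, keep_per_step = 20, seed = 2)
  true_err <- bootstrap_select(co$expression, co$metadata$label, cfg)
  set.seed(99)
  perm <- sample(co$metadata$label)
  null_err <- bootstrap_select(co$expression, perm, cfg)
  e_true <- true_err$cv_error_by_level[["20"]]
  e_null <- null_err$cv_error_by_level[["20"]]
  # informative labels: near-zero error; permuted: between the minority
  # prior (12/45 ~ 0.27, majority voting) and coin flipping
  expect_lt(e_true, 0.1)
  expect_gt(e_null, 0.2)
  expect_lt(e_null, 0.5)
})

test_that("with no signal the selected signature overlaps a second run only at chance level", {
  sig <- function(s) {
    co <- generate_cohort(cohort_config(n_probes = 300, effect_size = 0, seed = s))
    bootstrap_select(co$expression, co$metadata$label,
                     rsvm_config(n_bootstrap = 20, keep_per_step = 30,
                                 seed = s))$signature_probes
  }
  a <- sig(1); b <- sig(2)
  chance <- length(a) * length(b) / 300
  expect_lt(abs(length(intersect(a, b)) - chance), 0.25 * chance)
})

test_that("the default ladder halves geometrically and always contains the keep level", {
  lad <- rsvm_default_ladder(1000, 42)
  expect_equal(lad[1], 1000)
  expect_true(42 %in% lad)
  expect_true(all(diff(lad) < 0))
  expect_true(1 %in% lad)
  expect_equal(rsvm_default_ladder(10, 42), c(10, 5, 2, 1))
})
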