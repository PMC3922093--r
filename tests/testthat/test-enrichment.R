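test_that("probe-to-gene mapping drops symbol-less probes and collapses duplicates", {
  ann <- data.frame(probe_id = c("p1", "p2", "p3"),
                    gene_symbol = c("CD74", "", "CXCL9"))
  expect_equal(map_probes_to_genes(c("p1", "p2", "p3"), ann), c("CD74", "CXCL9"))
  ann2 <- data.frame(probe_id = c("p1", "p2"), gene_symbol = c("PIGR", "PIGR"))
  expect_equal(map_probes_to_genes(c("p1", "p2"), ann2), "PIGR")

  tab <- signature_probe_table()
  expect_equal(nrow(tab), 44)
  expect_equal(sum(nzchar(tab$gene_symbol)), 30)
  syms <- map_probes_to_genes(tab$probe_id,
                              setNames(tab$gene_symbol, tab$probe_id))
  expect_length(syms, 25)
  expect_equal(sum(tab$go_immune == "Yes"), 14)
  expect_setequal(tab$gene_symbol[tab$go_immune == "Yes"],
                  immune_signature_genes())
})

test_that("hypergeometric enrichment matches enumeration and the combinatorial sum", {
  # hand example: N=10, K=4, n=3, a=2 -> p = 40/120 = 1/3
  uni <- paste0("g", 1:10)
  sets <- data.frame(term_id = "T", term_name = "toy",
                     gene_symbol = paste0("g", 1:4))
  res <- hypergeom_enrich(c("g1", "g2", "g10"), sets, universe = uni)
  expect_equal(res$pvalue, 1 / 3)
  expect_equal(res$count, 2)
  expect_equal(res$expected, 3 * 4 / 10)

  # exhaustive enumeration of all draws for small universes
  for (case in list(c(10, 4, 3, 2), c(8, 3, 4, 1), c(12, 5, 6, 4))) {
    N <- case[1]; K <- case[2]; n <- case[3]; a <- case[4]
    uni <- paste0("g", seq_len(N))
    sets <- data.frame(term_id = "T", term_name = "t",
                       gene_symbol = paste0("g", seq_len(K)))
    sel <- c(paste0("g", seq_len(a)), paste0("g", K + seq_len(n - a)))
    res <- hypergeom_enrich(sel, sets, universe = uni)
    expect_equal(res$pvalue, hyper_tail_enum(a, K, n, N))
  }

  # combinatorial-sum oracle across a grid of instances with N <= 60
  set.seed(2)
  for (i in 1:40) {
    N <- sample(10:60, 1); K <- sample(1:(N - 1), 1); n <- sample(1:(N - 1), 1)
    a <- sample(max(1, n - (N - K)):min(n, K), 1)  # feasible overlap only
    uni <- paste0("g", seq_len(N))
    sets <- data.frame(term_id = "T", term_name = "t",
                       gene_symbol = paste0("g", seq_len(K)))
    sel <- c(paste0("g", seq_len(a)),
             if (n > a) paste0("g", K + seq_len(n - a)))
    res <- hypergeom_enrich(sel, sets, universe = uni)
    expect_equal(res$pvalue, hyper_tail_sum(a, K, n, N))
  }
})

test_that("enrichment edge behavior: omitted null rows, monotonicity, infinity sentinel", {
  uni <- paste0("g", 1:30)
  sets <- data.frame(term_id = rep(c("T1", "T2"), c(5, 4)),
                     term_name = rep(c("one", "two"), c(5, 4)),
                     gene_symbol = c(paste0("g", 1:5), paste0("g", 11:14)))
  # selection hits only T1: the a = 0 term is omitted
  res <- hypergeom_enrich(paste0("g", 1:3), sets, universe = uni)
  expect_equal(res$term_id, "T1")

  # p non-increasing in a at fixed (n, K, N)
  ps <- vapply(1:3, function(a) {
    sel <- c(paste0("g", seq_len(a)),
             if (a < 3) paste0("g", 20 + seq_len(3 - a)))
    hypergeom_enrich(sel, sets, universe = uni)$pvalue[1]
  }, numeric(1))
  expect_true(all(diff(ps) <= 0))

  # saturated overlap: b = 0 -> odds ratio reported as +Inf, never NaN
  res_sat <- hypergeom_enrich(paste0("g", 1:5), sets, universe = uni)
  expect_identical(res_sat$odds_ratio, Inf)
  expect_gt(res_sat$pvalue, 0)

  expect_warning(
    res_w <- hypergeom_enrich(c("g1", "not_in_universe"), sets, universe = uni),
    "outside the universe")
  expect_equal(attr(res_w, "n"), 1)
  expect_error(suppressWarnings(hypergeom_enrich("absent", sets, universe = uni)),
               "no selected genes")
})

test_that("random selections are not systematically enriched", {
  co <- generate_cohort(cohort_config(n_probes = 2000, seed = 4))
  gs <- co$genesets
  uni <- unique(gs$gene_symbol)
  n_terms <- length(unique(gs$term_id))
  set.seed(7)
  rej <- replicate(200, {
    e <- hypergeom_enrich(sample(uni, 20), gs)
    sum(e$pvalue < 0.05) / n_terms
  })
  expect_lte(mean(rej), 0.05 * 1.2)
})

test_that("selection and universe sizes are recoverable from a printed table", {
  # round trip from known sizes, with one informative near-saturated term
  n <- 25; N <- 8000; K <- c(300, 40, 6); a <- c(6, 3, 4)
  rows <- data.frame(expected = round(n * K / N, 2),
                     odds_ratio = round((a * (N - K - (n - a))) /
                                          ((n - a) * (K - a)), 2),
                     count = a, size = K)
  expect_equal(reconstruct_table_params(rows), c(n = 25, N = 8000))

  # rows too uninformative to pin the universe: ambiguity is an error
  K2 <- c(300, 40, 1200); a2 <- c(6, 3, 9)
  rows2 <- data.frame(expected = round(n * K2 / N, 2),
                      odds_ratio = round((a2 * (N - K2 - (n - a2))) /
                                           ((n - a2) * (K2 - a2)), 2),
                      count = a2, size = K2)
  expect_error(reconstruct_table_params(rows2), "ambiguous")

  expect_error(reconstruct_table_params(rows[1, ]), "2 rows")
  rows3 <- rows; rows3$expected <- rows3$expected + 5
  expect_error(reconstruct_table_params(rows3), "no \\(n, N\\) pair")
})
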