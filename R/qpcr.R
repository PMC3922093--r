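#' Relative expression by the delta-delta-Ct method
#'
#' For each sample, `dCt = Ct(gene) - Ct(reference)`; subtracting the
#' calibrator sample's dCt gives `ddCt`, and the relative quantity is
#' `RQ = 2^-ddCt` (100% amplification efficiency, a factor of exactly 2
#' per cycle). RQ is invariant to any per-sample constant added to all of
#' a sample's Ct values.
#'
#' @param ct_table Data.frame with columns `sample_id`, `group`, `gene`,
#'   `ct` (e.g. from [generate_qpcr()] or [read_ct_table()]).
#' @param gene Target gene symbol to quantify.
#' @param reference Reference (housekeeping) gene; defaults to the table's
#'   `reference` attribute or `"ACTB"`.
#' @param calibrator Calibrator sample id; defaults to the table's
#'   `calibrator` attribute or `"HT29"`.
#' @return Data.frame with one row per non-calibrator sample measured for
#'   `gene`: `sample_id`, `group`, `delta_ct`, `delta_delta_ct`, `rq`.
#' @export
#' @examples
#' ct <- generate_qpcr(n_per_group = 3, genes = "CD74", effect = 2, seed = 1)
#' delta_delta_ct(ct, "CD74")
delta_delta_ct <- function(ct_table, gene,
                           reference = attr(ct_table, "reference") %||% "ACTB",
                           calibrator = attr(ct_table, "calibrator") %||% "HT29") {
  req <- c("sample_id", "group", "gene", "ct")
  if (!all(req %in% names(ct_table)))
    stopf("Ct table needs columns %s", paste(req, collapse = ", "))
  if (anyDuplicated(ct_table[, c("sample_id", "gene")]))
    stopf("duplicate (sample, gene) rows in the Ct table")

  tgt <- ct_table[ct_table$gene == gene, , drop = FALSE]
  ref <- ct_table[ct_table$gene == reference, , drop = FALSE]
  if (nrow(tgt) == 0L) stopf("no Ct values for gene %s", gene)
  ref_ct <- setNames(ref$ct, ref$sample_id)
  miss_ref <- setdiff(tgt$sample_id, names(ref_ct))
  if (length(miss_ref))
    stopf("missing reference-gene (%s) Ct for sample(s): %s", reference,
          paste(miss_ref, collapse = ", "))
  if (!calibrator %in% tgt$sample_id)
    stopf("calibrator sample %s has no Ct for gene %s", calibrator, gene)
  if (!calibrator %in% names(ref_ct))
    stopf("calibrator sample %s has no Ct for reference gene %s",
          calibrator, reference)

  dct <- tgt$ct - unname(ref_ct[tgt$sample_id])
  dct_cal <- dct[tgt$sample_id == calibrator]
  ddct <- dct - dct_cal
  out <- data.frame(sample_id = tgt$sample_id, group = tgt$group,
                    delta_ct = dct, delta_delta_ct = ddct,
                    rq = 2^(-ddct), stringsAsFactors = FALSE)
  out <- out[out$sample_id != calibrator, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Mann-Whitney (Wilcoxon rank-sum) test
#'
#' `U` is computed from rank sums with midranks for ties. The two-sided
#' p-value is exact — by full enumeration of all
#' `choose(n1 + n2, n1)` group assignments — when the combined sample size
#' is at most `exact_limit`; otherwise the normal approximation with tie
#' correction and continuity correction is used. The exact path handles
#' ties, which the base `wilcox.test` exact mode does not.
#'
#' @param x,y Numeric samples for the two groups.
#' @param exact_limit Largest combined n for exact enumeration
#'   (default 20).
#' @return An object of class `"htest"` with `statistic` (U for the `x`
#'   group), `p.value` and `method`.
#' @export
#' @examples
#' mann_whitney(c(1, 2), c(3, 4))
mann_whitney <- function(x, y, exact_limit = 20L) {
  if (length(x) < 1L || length(y) < 1L) stopf("both groups need at least one value")
  if (anyNA(x) || anyNA(y)) stopf("missing values are not supported")
  n1 <- length(x); n2 <- length(y); n <- n1 + n2
  r <- rank(c(x, y))
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2

  if (n <= exact_limit) {
    idx <- utils::combn(n, n1)
    us <- colSums(matrix(r[idx], nrow = n1)) - n1 * (n1 + 1) / 2
    p <- mean(abs(us - mu) >= abs(u - mu) - 1e-9)
    method <- "Mann-Whitney test (exact permutation)"
  } else {
    ties <- table(r)
    sigma2 <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    z <- (u - mu - sign(u - mu) * 0.5) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    method <- "Mann-Whitney test (normal approximation, tie-corrected)"
  }
  structure(list(statistic = c(U = u), p.value = p, method = method,
                 data.name = sprintf("x (n=%d) vs y (n=%d)", n1, n2)),
            class = "htest")
}

#' Per-gene qPCR group comparison
#'
#' Runs [delta_delta_ct()] for each target gene and compares the relative
#' expression of the two outcome groups with [mann_whitney()].
#'
#' @param ct_table Ct table (see [delta_delta_ct()]).
#' @param genes Target genes; defaults to all non-reference genes present.
#' @param alpha Significance level annotated in the output (default 0.05).
#' @inheritParams delta_delta_ct
#' @return Data.frame of class `"qpcr_validation"`: per gene, the group
#'   median RQs, the U statistic, the two-sided p-value, and a
#'   significance flag at `alpha`.
#' @export
#' @examples
#' ct <- generate_qpcr(n_per_group = 6, genes = c("CD74", "CXCL9"),
#'                     effect = 2, seed = 1)
#' qpcr_compare(ct)
qpcr_compare <- function(ct_table, genes = NULL, alpha = 0.05,
                         reference = attr(ct_table, "reference") %||% "ACTB",
                         calibrator = attr(ct_table, "calibrator") %||% "HT29") {
  if (is.null(genes))
    genes <- setdiff(unique(ct_table$gene), reference)
  rows <- lapply(genes, function(g) {
    rq <- delta_delta_ct(ct_table, g, reference = reference,
                         calibrator = calibrator)
    grps <- unique(rq$group)
    if (length(grps) != 2L)
      stopf("gene %s: expected two outcome groups, found %d", g, length(grps))
    g_nr <- if ("non_recurrent" %in% grps) "non_recurrent" else grps[1]
    g_mm <- setdiff(grps, g_nr)
    a <- rq$rq[rq$group == g_nr]; b <- rq$rq[rq$group == g_mm]
    mw <- mann_whitney(a, b)
    data.frame(gene = g, median_rq_nonrecurrent = median(a),
               median_rq_metastatic = median(b),
               U = unname(mw$statistic), p_value = mw$p.value,
               significant = mw$p.value < alpha, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("qpcr_validation", "data.frame")
  attr(out, "alpha") <- alpha
  out
}
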