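#' Generalized-log transform
#'
#' `glog(x, c) = asinh(x / c)`, a variance-stabilizing transform that is
#' logarithmic for large `x/c` and linear near zero, so `glog(0) = 0` and
#' negative calibrated intensities remain finite.
#'
#' @param x Numeric vector or matrix.
#' @param c Positive scale parameter.
#' @return Transformed values, same shape as `x`.
#' @export
#' @examples
#' glog(0, c = 5)
#' glog(c(1, 10, 100, 1000), c = 10)
glog <- function(x, c) {
  if (!is.numeric(c) || length(c) != 1L || !is.finite(c) || c <= 0)
    stopf("glog scale parameter c must be a single positive number")
  asinh(x / c)
}

#' Variance-stabilizing normalization of a raw expression matrix
#'
#' Each array (column) is affinely calibrated so its median and MAD match
#' the across-array reference (median of the per-array medians/MADs), then
#' the calibrated intensities are passed through the generalized-log
#' transform [glog()]. The scale parameter `c` defaults to the
#' additive-noise floor, estimated as the MAD of the lowest-decile
#' calibrated intensities; the global spread would reflect biological
#' signal rather than noise and under-stabilize. The transform is strictly
#' increasing, so the rank order within each array is preserved.
#'
#' @param raw Non-negative numeric matrix, probes x samples, with dimnames.
#' @param c Optional glog scale parameter; estimated from the data when
#'   `NULL`.
#' @return Matrix of transformed values with the same dimnames, carrying
#'   attributes `glog_c` (the scale used) and `calibration` (per-array
#'   location/scale).
#' @export
#' @examples
#' raw <- matrix(rexp(200, 1 / 50), 50, 4,
#'               dimnames = list(paste0("p", 1:50), paste0("s", 1:4)))
#' norm <- normalize_glog(raw)
#' attr(norm, "glog_c")
normalize_glog <- function(raw, c = NULL) {
  raw <- as.matrix(raw)
  if (!is.numeric(raw)) stopf("expression input must be numeric")
  if (ncol(raw) < 2L) stopf("normalization needs at least 2 arrays")
  if (anyNA(raw) || any(!is.finite(raw))) stopf("expression input contains missing or non-finite values")
  if (any(raw < 0)) stopf("expression input contains negative values; raw intensities must be >= 0")

  med <- apply(raw, 2L, median)
  scl <- apply(raw, 2L, mad)
  if (any(scl == 0)) {
    warnf("%d array(s) have zero MAD; their scale is left uncalibrated", sum(scl == 0))
    scl[scl == 0] <- 1
  }
  m_ref <- median(med); s_ref <- median(scl)
  cal <- sweep(sweep(raw, 2L, med, "-"), 2L, scl / s_ref, "/")
  cal <- cal + m_ref

  if (is.null(c)) {
    # glog is optimally scaled at c = sd_additive / sd_multiplicative;
    # the additive floor is estimated from the lowest-decile intensities and
    # the multiplicative CV taken as the conventional 20% for array data
    low <- cal[cal <= quantile(cal, 0.1)]
    c <- mad(low, center = median(low)) / 0.2
    if (!is.finite(c) || c <= 0) c <- max(s_ref, 1)
  }
  out <- glog(cal, c)
  dimnames(out) <- dimnames(raw)
  attr(out, "glog_c") <- c
  attr(out, "calibration") <- list(median = med, scale = scl,
                                   ref_median = m_ref, ref_scale = s_ref)
  out
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Thin validated wrapper around `stats::p.adjust(method = "BH")`:
#' `q_i = min_{j : p_(j) >= p_(i)} m p_(j) / j`, capped at 1.
#'
#' @param pvalues Numeric vector of p-values in `[0, 1]`.
#' @return q-values, same length and order as the input.
#' @export
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03, 0.04))
bh_adjust <- function(pvalues) {
  if (length(pvalues) == 0L) return(numeric(0))
  if (anyNA(pvalues) || !is.numeric(pvalues) ||
      any(pvalues < 0) || any(pvalues > 1))
    stopf("p-values must be numeric in [0, 1] with no missing values")
  p.adjust(pvalues, method = "BH")
}

#' Univariate differential-expression screen
#'
#' Per-probe Welch two-sample t test on the transformed scale, with
#' Benjamini-Hochberg q-values and the double screen used in outcome
#' studies: flagged when the fold change exceeds `fc_threshold` in
#' magnitude (two-sided, i.e. FC > 2 or FC < 0.5) *and* q falls below
#' `q_threshold`. Fold change is the ratio of anti-transformed group
#' means: `c * sinh(m)` when the matrix carries a `glog_c` attribute from
#' [normalize_glog()], otherwise `2^m` (log2 convention).
#'
#' Heterogeneous signatures, where each affected sample down-regulates a
#' different gene subset, typically produce *no* flagged probes here; that
#' null result is the motivation for multivariate selection
#' ([bootstrap_select()]).
#'
#' @param expr Numeric matrix, probes x samples, transformed scale.
#' @param labels Two-class labeling of the columns (factor or character).
#' @param fc_threshold Fold-change magnitude threshold (default 2).
#' @param q_threshold BH q-value threshold (default 0.05).
#' @return A data.frame of class `"de_result"`: `probe_id`, `mean_diff`
#'   (first factor level minus second), `fold_change`, `t`, `df`, `pvalue`,
#'   `qvalue`, `flagged`.
#' @export
#' @examples
#' co <- generate_cohort(cohort_config(n_probes = 100, seed = 1))
#' de <- differential_screen(co$expression, co$metadata$label)
#' sum(de$flagged)
differential_screen <- function(expr, labels, fc_threshold = 2,
                                q_threshold = 0.05) {
  expr <- as.matrix(expr)
  f <- factor(labels)
  if (nlevels(f) != 2L) stopf("labels must have exactly two classes")
  if (length(f) != ncol(expr)) stopf("labels length must equal number of samples")
  if (any(table(f) < 2L)) stopf("both classes need at least 2 samples")
  if (fc_threshold < 1) stopf("fc_threshold must be >= 1")

  i1 <- which(f == levels(f)[1]); i2 <- which(f == levels(f)[2])
  n1 <- length(i1); n2 <- length(i2)
  m1 <- rowMeans(expr[, i1, drop = FALSE])
  m2 <- rowMeans(expr[, i2, drop = FALSE])
  v1 <- rowSums((expr[, i1, drop = FALSE] - m1)^2) / (n1 - 1)
  v2 <- rowSums((expr[, i2, drop = FALSE] - m2)^2) / (n2 - 1)

  se2 <- v1 / n1 + v2 / n2
  tt <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * pt(-abs(tt), df)

  degenerate <- se2 == 0
  if (any(degenerate)) {
    warnf("%d probe(s) have zero variance in both groups; p set to 1", sum(degenerate))
    tt[degenerate] <- 0; df[degenerate] <- n1 + n2 - 2; p[degenerate] <- 1
  }

  glog_c <- attr(expr, "glog_c")
  if (!is.null(glog_c)) {
    a1 <- glog_c * sinh(m1); a2 <- glog_c * sinh(m2)
    fc <- ifelse(a1 > 0 & a2 > 0, a1 / a2, NA_real_)
    if (anyNA(fc))
      warnf("%d probe(s) have non-positive anti-transformed means; fold change set to NA",
            sum(is.na(fc)))
  } else {
    fc <- 2^(m1 - m2)
  }

  q <- bh_adjust(p)
  flagged <- !is.na(fc) & (fc > fc_threshold | fc < 1 / fc_threshold) &
    q < q_threshold
  out <- data.frame(probe_id = rownames(expr) %||% seq_len(nrow(expr)),
                    mean_diff = unname(m1 - m2), fold_change = unname(fc),
                    t = unname(tt), df = unname(df), pvalue = unname(p),
                    qvalue = unname(q), flagged = unname(flagged),
                    stringsAsFactors = FALSE)
  class(out) <- c("de_result", "data.frame")
  attr(out, "groups") <- levels(f)
  out
}

#' Sample clustering and principal-component projection
#'
#' Sanity-check views over a probe subset: rows are centered and scaled to
#' unit variance, samples are clustered agglomeratively (Euclidean
#' distance, average linkage) and projected on the first two principal
#' components.
#'
#' @param expr Numeric matrix, probes x samples.
#' @param probes Probe ids (rows) to use; defaults to all rows.
#' @return An object of class `"expr_projection"`: list with `hclust` (the
#'   sample dendrogram), `order` (sample ids in dendrogram order),
#'   `heights` (linkage heights), `pca` (samples x 2 coordinate matrix) and
#'   `probes_used`.
#' @export
#' @examples
#' co <- generate_cohort(cohort_config(n_probes = 60, seed = 1))
#' pr <- project_and_cluster(co$expression, co$truth)
#' head(pr$order)
project_and_cluster <- function(expr, probes = rownames(expr)) {
  expr <- as.matrix(expr)
  if (length(probes) == 0L) stopf("probe subset must be non-empty")
  missing <- setdiff(probes, rownames(expr))
  if (length(missing))
    stopf("probes not present in the matrix: %s",
          paste(head(missing, 5L), collapse = ", "))
  x <- expr[probes, , drop = FALSE]
  rv <- apply(x, 1L, sd)
  if (any(rv == 0)) {
    warnf("%d zero-variance row(s) dropped before scaling", sum(rv == 0))
    x <- x[rv > 0, , drop = FALSE]
    if (nrow(x) == 0L) stopf("no rows left after dropping zero-variance probes")
  }
  xs <- t(scale(t(x)))   # row mean 0, row sd 1

  hc <- hclust(dist(t(xs)), method = "average")
  pc <- prcomp(t(xs), center = FALSE, scale. = FALSE)
  coords <- pc$x[, seq_len(min(2L, ncol(pc$x))), drop = FALSE]
  structure(list(hclust = hc, order = colnames(xs)[hc$order],
                 heights = hc$height, pca = coords,
                 probes_used = rownames(xs)),
            class = "expr_projection")
}

#' @export
print.expr_projection <- function(x, ...) {
  cat(sprintf("Sample projection over %d probes, %d samples\n",
              length(x$probes_used), length(x$order)))
  cat("Dendrogram order:", paste(head(x$order, 8L), collapse = ", "),
      if (length(x$order) > 8L) "..." else "", "\n")
  invisible(x)
}

#' @export
plot.expr_projection <- function(x, labels = NULL, ...) {
  op <- graphics::par(mfrow = c(1, 2)); on.exit(graphics::par(op))
  plot(x$hclust, main = "Sample clustering", xlab = "", sub = "", cex = 0.7)
  col <- if (is.null(labels)) 1 else as.integer(factor(labels)) + 1L
  plot(x$pca[, 1], x$pca[, 2], col = col, pch = 19,
       xlab = "PC1", ylab = "PC2", main = "PCA", ...)
  invisible(x)
}
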