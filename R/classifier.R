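#' Below-median counts over a signature
#'
#' For every sample, counts how many signature probes have an expression
#' value strictly below their reference median. With `mode = "loo"` (the
#' default, the literal reading of "below their median hybridization
#' values in all other samples") the reference for sample *i* is the
#' median over all samples except *i*; with `mode = "pooled"` it is the
#' median over all samples. A value equal to the reference does not count,
#' so a constant probe contributes 0 everywhere.
#'
#' @param expr Numeric matrix, probes x samples.
#' @param signature Probe ids (rows of `expr`) forming the signature.
#' @param mode `"loo"` (leave-one-out median, default) or `"pooled"`.
#' @return Named integer vector of per-sample counts in
#'   `[0, length(signature)]`.
#' @export
#' @examples
#' x <- matrix(1:3, nrow = 1, dimnames = list("p1", c("s1", "s2", "s3")))
#' below_median_counts(x, "p1")   # 1, 0, 0
below_median_counts <- function(expr, signature, mode = c("loo", "pooled")) {
  mode <- match.arg(mode)
  expr <- as.matrix(expr)
  if (ncol(expr) < 3L) stopf("need at least 3 samples")
  missing <- setdiff(signature, rownames(expr))
  if (length(missing))
    stopf("signature probes missing from the matrix: %s",
          paste(missing, collapse = ", "))
  x <- expr[signature, , drop = FALSE]
  n <- ncol(x)
  if (mode == "pooled") {
    ref <- apply(x, 1L, median)
    counts <- colSums(x < ref)
  } else {
    counts <- vapply(seq_len(n), function(i) {
      ref <- apply(x[, -i, drop = FALSE], 1L, median)
      sum(x[, i] < ref)
    }, numeric(1))
  }
  setNames(as.integer(counts), colnames(x))
}

#' Classify samples from below-median counts
#'
#' A sample is called metastatic when its count exceeds the cutoff
#' (equivalently, when at least `ceiling(cutoff)` signature probes lie
#' below their reference medians). The published operating point is
#' `cutoff = 8.5`, i.e. at least 9 of 14 probes.
#'
#' @param counts Integer per-sample counts from [below_median_counts()].
#' @param cutoff Threshold, conventionally a half-integer.
#' @return Factor with levels `non_recurrent`, `metastatic`.
#' @export
#' @examples
#' classify_counts(c(a = 9, b = 8), cutoff = 8.5)
classify_counts <- function(counts, cutoff) {
  if (!is.numeric(cutoff) || length(cutoff) != 1L || !is.finite(cutoff))
    stopf("cutoff must be a single finite number")
  factor(ifelse(counts > cutoff, "metastatic", "non_recurrent"),
         levels = c("non_recurrent", "metastatic"))
}

#' ROC analysis of below-median counts
#'
#' Sweeps all half-integer thresholds, computing sensitivity and
#' specificity of the rule "metastatic iff count > threshold". AUC is the
#' Mann-Whitney probability of concordance (ties count 1/2). The selected
#' cutoff maximizes Youden's J = sensitivity + specificity - 1, with ties
#' broken toward higher specificity (and then the higher threshold).
#'
#' @param counts Numeric per-sample scores (below-median counts).
#' @param true_labels Two-class labels aligned with `counts`.
#' @param positive Label of the positive (metastatic) class; defaults to
#'   `"metastatic"` when present, otherwise the rarer class.
#' @return An object of class `"roc_counts"`: list with `thresholds`,
#'   `sensitivity`, `specificity`, `auc`, `cutoff`, `youden`, `counts`,
#'   `labels`, `positive`.
#' @export
#' @examples
#' roc <- roc_analysis(c(3, 5, 1, 4), c("m", "m", "n", "n"), positive = "m")
#' roc$auc   # 0.75
roc_analysis <- function(counts, true_labels, positive = NULL) {
  f <- factor(true_labels)
  if (nlevels(f) != 2L) stopf("true_labels must contain exactly two classes")
  if (length(f) != length(counts)) stopf("counts and labels differ in length")
  if (is.null(positive))
    positive <- if ("metastatic" %in% levels(f)) "metastatic"
                else names(which.min(table(f)))
  if (!positive %in% levels(f)) stopf("positive class '%s' not present", positive)
  is_pos <- f == positive
  n1 <- sum(is_pos); n0 <- sum(!is_pos)

  thr <- seq(floor(min(counts)) - 0.5, ceiling(max(counts)) + 0.5, by = 1)
  sens <- vapply(thr, function(t) sum(counts[is_pos] > t) / n1, numeric(1))
  spec <- vapply(thr, function(t) sum(counts[!is_pos] <= t) / n0, numeric(1))

  # Mann-Whitney AUC via midranks
  r <- rank(counts)
  auc <- (sum(r[is_pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)

  j <- sens + spec - 1
  best <- which(j == max(j))
  best <- best[spec[best] == max(spec[best])]
  # remaining ties (e.g. a perfect-separation gap): take the middle
  # threshold, which generalizes better than either gap edge
  best <- best[ceiling(length(best) / 2)]
  structure(list(thresholds = thr, sensitivity = sens, specificity = spec,
                 auc = auc, cutoff = thr[best], youden = j[best],
                 counts = counts, labels = f, positive = positive),
            class = "roc_counts")
}

#' @export
print.roc_counts <- function(x, ...) {
  i <- which(x$thresholds == x$cutoff)
  cat(sprintf("ROC over below-median counts (positive class: %s)\n", x$positive))
  cat(sprintf("AUC = %.3f; selected cutoff = %.1f (sensitivity %.0f%%, specificity %.0f%%)\n",
              x$auc, x$cutoff, 100 * x$sensitivity[i], 100 * x$specificity[i]))
  invisible(x)
}

#' @export
plot.roc_counts <- function(x, ...) {
  ord <- order(1 - x$specificity, x$sensitivity)
  plot(c(0, (1 - x$specificity)[ord], 1), c(0, x$sensitivity[ord], 1),
       type = "s", xlab = "1 - specificity", ylab = "sensitivity",
       main = sprintf("ROC (AUC = %.3f)", x$auc), xlim = c(0, 1),
       ylim = c(0, 1), ...)
  abline(0, 1, lty = 3)
  i <- which(x$thresholds == x$cutoff)
  points(1 - x$specificity[i], x$sensitivity[i], pch = 19, col = 2)
  invisible(x)
}

#' Fit the below-median signature classifier
#'
#' The model-fitting interface around [below_median_counts()],
#' [roc_analysis()] and [classify_counts()]: computes each sample's
#' below-median count over the signature, selects the count cutoff by ROC
#' analysis against the observed outcome labels (Youden's J) unless a
#' fixed `cutoff` is supplied, and stores the pooled training medians so
#' new samples can be scored with [predict.signature_classifier()].
#'
#' @param expr Numeric matrix, probes x samples (transformed scale).
#' @param signature Probe ids forming the signature.
#' @param labels Outcome labels aligned with the columns; optional when a
#'   fixed `cutoff` is given.
#' @param mode Reference-median mode, `"loo"` (default) or `"pooled"`.
#' @param cutoff Optional fixed cutoff (e.g. `8.5` for the published
#'   operating point); when `NULL` it is selected by ROC analysis.
#' @param positive Positive-class label (see [roc_analysis()]).
#' @return An object of class `"signature_classifier"`: list with
#'   `counts`, `cutoff`, `predicted`, `roc` (when labels are given),
#'   `signature`, `mode`, `train_medians`, `labels`.
#' @export
#' @examples
#' co <- generate_cohort(cohort_config(n_probes = 100, effect_size = 4,
#'                                     penetrance = 1, seed = 1))
#' fit <- signature_classifier(co$expression, co$truth, co$metadata$label)
#' fit
signature_classifier <- function(expr, signature, labels = NULL,
                                 mode = c("loo", "pooled"), cutoff = NULL,
                                 positive = NULL) {
  mode <- match.arg(mode)
  counts <- below_median_counts(expr, signature, mode = mode)
  roc <- NULL
  if (is.null(cutoff)) {
    if (is.null(labels))
      stopf("either outcome labels (for ROC cutoff selection) or a fixed cutoff is required")
    roc <- roc_analysis(counts, labels, positive = positive)
    cutoff <- roc$cutoff
  } else if (!is.null(labels)) {
    roc <- roc_analysis(counts, labels, positive = positive)
  }
  x <- as.matrix(expr)[signature, , drop = FALSE]
  structure(list(counts = counts, cutoff = cutoff,
                 predicted = classify_counts(counts, cutoff),
                 roc = roc, signature = signature, mode = mode,
                 train_medians = apply(x, 1L, median),
                 labels = if (is.null(labels)) NULL else factor(labels)),
            class = "signature_classifier")
}

#' @export
print.signature_classifier <- function(x, ...) {
  cat(sprintf("Below-median signature classifier (%d probes, %s medians)\n",
              length(x$signature), x$mode))
  cat(sprintf("Cutoff: %.1f (metastatic iff count >= %d)\n",
              x$cutoff, ceiling(x$cutoff)))
  print(table(predicted = x$predicted))
  if (!is.null(x$roc)) cat(sprintf("Training AUC: %.3f\n", x$roc$auc))
  invisible(x)
}

#' @export
summary.signature_classifier <- function(object, ...) {
  cat(sprintf("Below-median signature classifier over %d probes\n",
              length(object$signature)))
  cat(sprintf("Reference medians: %s; cutoff %.1f\n", object$mode, object$cutoff))
  if (!is.null(object$labels)) {
    tab <- table(true = object$labels, predicted = object$predicted)
    print(tab)
    if (!is.null(object$roc)) {
      i <- which(object$roc$thresholds == object$cutoff)
      cat(sprintf("AUC %.3f; sensitivity %.0f%%, specificity %.0f%% at cutoff %.1f\n",
                  object$roc$auc, 100 * object$roc$sensitivity[i],
                  100 * object$roc$specificity[i], object$cutoff))
    }
  }
  invisible(object)
}

#' Predict metastasis for new samples
#'
#' Scores new samples against the *training* pooled medians (new data must
#' not shift the reference) and applies the fitted cutoff.
#'
#' @param object A fitted [signature_classifier()].
#' @param newdata Numeric matrix, probes x samples, containing the
#'   signature probes.
#' @param ... Unused.
#' @return Data.frame with `sample_id`, `count`, `predicted`.
#' @export
predict.signature_classifier <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  missing <- setdiff(object$signature, rownames(newdata))
  if (length(missing))
    stopf("signature probes missing from newdata: %s",
          paste(missing, collapse = ", "))
  x <- newdata[object$signature, , drop = FALSE]
  counts <- as.integer(colSums(x < object$train_medians))
  data.frame(sample_id = colnames(newdata) %||% seq_len(ncol(newdata)),
             count = counts,
             predicted = classify_counts(counts, object$cutoff),
             stringsAsFactors = FALSE)
}

#' @export
plot.signature_classifier <- function(x, ...) {
  if (is.null(x$roc)) stopf("no ROC stored; fit with outcome labels to plot")
  plot(x$roc, ...)
}
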