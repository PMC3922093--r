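#' Configuration for bootstrap recursive-SVM selection
#'
#' @param n_bootstrap Number of bootstrap cross-validation steps
#'   (default 100).
#' @param keep_per_step Number of top probes saved from each step
#'   (default 42); the reporting ladder level.
#' @param ladder Strictly decreasing feature-count schedule, or `NULL` to
#'   use geometric halving from all features with `keep_per_step` inserted
#'   as a level (see [rsvm_default_ladder()]).
#' @param svm_cost Soft-margin cost of the linear SVM (default 1; no
#'   per-step tuning).
#' @param seed Integer seed for the bootstrap resampling.
#' @return An object of class `"rsvm_config"`.
#' @export
#' @examples
#' rsvm_config(n_bootstrap = 50, keep_per_step = 10)
rsvm_config <- function(n_bootstrap = 100L, keep_per_step = 42L,
                        ladder = NULL, svm_cost = 1, seed = 1L) {
  if (n_bootstrap < 1L) stopf("n_bootstrap must be >= 1")
  if (keep_per_step < 1L) stopf("keep_per_step must be >= 1")
  if (!is.null(ladder)) {
    ladder <- as.integer(ladder)
    if (any(diff(ladder) >= 0L)) stopf("ladder must be strictly decreasing")
    if (any(ladder < 1L)) stopf("ladder levels must be >= 1")
  }
  if (svm_cost <= 0) stopf("svm_cost must be > 0")
  structure(list(n_bootstrap = as.integer(n_bootstrap),
                 keep_per_step = as.integer(keep_per_step),
                 ladder = ladder, svm_cost = svm_cost,
                 seed = as.integer(seed)),
            class = "rsvm_config")
}

#' Default recursive-elimination ladder
#'
#' Geometric halving from `n_features` down to 1, with `keep` inserted as
#' an explicit level so every run reports a set of exactly `keep` probes.
#'
#' @param n_features Total feature count at the top of the ladder.
#' @param keep Reporting level to insert (default 42).
#' @return Strictly decreasing integer vector starting at `n_features`.
#' @export
#' @examples
#' rsvm_default_ladder(1000, 42)
rsvm_default_ladder <- function(n_features, keep = 42L) {
  n_features <- as.integer(n_features)
  lv <- n_features
  while (lv[length(lv)] > 1L) lv <- c(lv, lv[length(lv)] %/% 2L)
  lv <- sort(unique(c(lv, min(keep, n_features))), decreasing = TRUE)
  lv
}

# global robust rescale so feature scoring (and hence selection) is exactly
# invariant to multiplying the whole matrix by a positive constant; a fixed
# soft-margin cost is otherwise scale sensitive
rescale_global <- function(x) {
  s <- sd(as.numeric(x))
  if (!is.finite(s) || s == 0) return(x)
  x / s
}

#' Per-feature contribution scores from a linear SVM
#'
#' Fits a linear soft-margin SVM and scores each feature by its
#' contribution to class separation, `f_j = w_j (m_j^+ - m_j^-)`, where
#' `w_j` is the hyperplane weight and `m_j^+/-` the class means of feature
#' `j` (with `+` the class on the positive side of the decision function).
#' The score is invariant to swapping class roles and to negating a
#' feature; a feature identical in both classes scores exactly 0.
#'
#' @param x Numeric matrix, features x samples.
#' @param labels Two-class labeling of the columns.
#' @param cost SVM cost parameter (default 1).
#' @return Named numeric vector of scores, one per feature.
#' @export
#' @examples
#' x <- rbind(f1 = c(1, 1, -1, -1), f2 = c(0, 0, 0, 0))
#' colnames(x) <- paste0("s", 1:4)
#' svm_feature_scores(x, c("a", "a", "b", "b"))
svm_feature_scores <- function(x, labels, cost = 1) {
  x <- as.matrix(x)
  f <- factor(labels)
  if (nlevels(f) != 2L) stopf("labels must contain exactly two classes")
  if (length(f) != ncol(x)) stopf("labels length must equal number of samples")
  if (nrow(x) < 1L) stopf("need at least one feature")
  x <- rescale_global(x)

  fit <- e1071::svm(t(x), f, kernel = "linear", cost = cost, scale = FALSE)
  w <- drop(crossprod(fit$coefs, fit$SV))
  # orient w to the class on the positive side of the decision function:
  # the sample with the largest |decision value| is predicted as that side's class
  pred <- predict(fit, t(x), decision.values = TRUE)
  dec <- drop(attr(pred, "decision.values"))
  i_ext <- which.max(abs(dec))
  pos_class <- if (dec[i_ext] >= 0) as.character(pred[i_ext])
               else setdiff(levels(f), as.character(pred[i_ext]))
  m_pos <- rowMeans(x[, f == pos_class, drop = FALSE])
  m_neg <- rowMeans(x[, f != pos_class, drop = FALSE])
  scores <- w * (m_pos - m_neg)
  names(scores) <- rownames(x)
  scores
}

#' One recursive-SVM elimination ladder on a train/test split
#'
#' Starting from all features, repeatedly retrains a linear SVM on the
#' training samples, keeps the top-scoring `level` features at each ladder
#' level (ties broken by feature order for determinism), and records the
#' held-out misclassification rate of the level's model on the test
#' samples.
#'
#' @param expr Numeric matrix, features x samples.
#' @param labels Two-class labeling of all columns.
#' @param train_idx,test_idx Disjoint column index sets.
#' @param ladder Strictly decreasing level schedule; defaults to
#'   [rsvm_default_ladder()] over all features.
#' @param cost SVM cost.
#' @param keep Reporting level inserted into the default ladder
#'   (default 42).
#' @return List with `levels`, `features_by_level` (named list of retained
#'   feature ids), `error_by_level` (named numeric, held-out error).
#' @export
#' @examples
#' co <- generate_cohort(cohort_config(n_probes = 50, seed = 1))
#' rsvm_ladder(co$expression, co$metadata$label,
#'             train_idx = 1:30, test_idx = 31:45,
#'             ladder = c(50, 25, 12, 6))
rsvm_ladder <- function(expr, labels, train_idx, test_idx, ladder = NULL,
                        cost = 1, keep = 42L) {
  expr <- as.matrix(expr)
  f <- factor(labels)
  if (length(intersect(train_idx, test_idx)) > 0L)
    stopf("train and test index sets must be disjoint")
  if (length(test_idx) == 0L) stopf("test set must be non-empty")
  if (length(train_idx) == 0L) stopf("training set must be non-empty")
  ytr <- droplevels(f[train_idx])
  if (nlevels(ytr) != 2L) stopf("training set must contain both classes")
  if (is.null(ladder)) ladder <- rsvm_default_ladder(nrow(expr), keep)
  if (any(ladder > nrow(expr)))
    stopf("ladder level exceeds number of features")

  retained <- rownames(expr) %||% as.character(seq_len(nrow(expr)))
  rownames(expr) <- retained
  expr <- rescale_global(expr)
  xtr <- expr[, train_idx, drop = FALSE]
  xte <- expr[, test_idx, drop = FALSE]
  yte <- factor(f[test_idx], levels = levels(ytr))
  feats <- vector("list", length(ladder))
  errs <- numeric(length(ladder))
  for (k in seq_along(ladder)) {
    lev <- ladder[k]
    if (length(retained) > lev) {
      sc <- svm_feature_scores(xtr[retained, , drop = FALSE], ytr, cost = cost)
      # ties broken by original feature order (stable sort on -score)
      ord <- order(-sc, seq_along(sc))
      retained <- retained[ord[seq_len(lev)]]
      retained <- retained[order(match(retained, rownames(expr)))]
    }
    fit <- e1071::svm(t(xtr[retained, , drop = FALSE]), ytr,
                      kernel = "linear", cost = cost, scale = FALSE)
    pred <- predict(fit, t(xte[retained, , drop = FALSE]))
    errs[k] <- mean(pred != yte)
    feats[[k]] <- retained
  }
  names(feats) <- names(errs) <- as.character(ladder)
  list(levels = ladder, features_by_level = feats, error_by_level = errs)
}

#' Bootstrap recursive-SVM signature selection
#'
#' The discovery engine: for each of `n_bootstrap` steps, a stratified
#' bootstrap sample (with replacement, within class, preserving the class
#' imbalance) forms the training set and the out-of-bag samples the test
#' set; a recursive-SVM elimination ladder is run and the features
#' retained at the ladder level closest to `keep_per_step` are saved.
#' Features selected at least once across all steps form the candidate
#' signature, and the per-level held-out errors averaged over steps give
#' the cross-validation error ladder.
#'
#' @param expr Numeric matrix, probes x samples.
#' @param labels Two-class labeling of the columns.
#' @param config An [rsvm_config()].
#' @return An object of class `"rsvm_selection"`: list with
#'   `selection_count` (named integer over all probes),
#'   `signature_probes` (probes with count >= 1), `cv_error_by_level`
#'   (mean out-of-bag error per ladder level), `error_matrix`
#'   (steps x levels), `report_level`, and `config`.
#' @export
#' @examples
#' co <- generate_cohort(cohort_config(n_probes = 60, seed = 1))
#' sel <- bootstrap_select(co$expression, co$metadata$label,
#'                         rsvm_config(n_bootstrap = 5, keep_per_step = 10, seed = 1))
#' sel
bootstrap_select <- function(expr, labels, config = rsvm_config()) {
  expr <- as.matrix(expr)
  f <- factor(labels)
  if (nlevels(f) != 2L) stopf("labels must contain exactly two classes")
  if (any(table(f) < 4L)) stopf("both classes need at least 4 samples")
  if (!inherits(config, "rsvm_config")) stopf("config must be an rsvm_config()")
  probes <- rownames(expr) %||% as.character(seq_len(nrow(expr)))
  rownames(expr) <- probes

  ladder <- config$ladder %||% rsvm_default_ladder(nrow(expr), config$keep_per_step)
  report_level <- ladder[which.min(abs(ladder - config$keep_per_step))]
  idx_by_class <- split(seq_along(f), f)

  counts <- setNames(integer(length(probes)), probes)
  errmat <- matrix(NA_real_, nrow = config$n_bootstrap, ncol = length(ladder),
                   dimnames = list(NULL, as.character(ladder)))
  with_seed(config$seed, {
    for (b in seq_len(config$n_bootstrap)) {
      repeat {
        train <- unlist(lapply(idx_by_class, function(ii)
          sample(ii, length(ii), replace = TRUE)), use.names = FALSE)
        oob <- setdiff(seq_along(f), unique(train))
        if (length(oob) > 0L) break
        message("empty out-of-bag set; redrawing bootstrap sample")
      }
      lad <- rsvm_ladder(expr, f, train_idx = train, test_idx = oob,
                         ladder = ladder, cost = config$svm_cost)
      saved <- lad$features_by_level[[as.character(report_level)]]
      counts[saved] <- counts[saved] + 1L
      errmat[b, ] <- lad$error_by_level
    }
  })
  structure(list(selection_count = counts,
                 signature_probes = names(counts)[counts > 0L],
                 cv_error_by_level = colMeans(errmat),
                 error_matrix = errmat,
                 report_level = report_level,
                 ladder = ladder,
                 config = config),
            class = "rsvm_selection")
}

#' @export
print.rsvm_selection <- function(x, ...) {
  cat(sprintf("Bootstrap recursive-SVM selection: %d steps, %d probes saved per step\n",
              x$config$n_bootstrap, x$report_level))
  cat(sprintf("Signature: %d probes selected at least once\n",
              length(x$signature_probes)))
  top <- sort(x$selection_count[x$signature_probes], decreasing = TRUE)
  cat("Most frequently selected:\n")
  print(head(top, 10L))
  cat(sprintf("Mean out-of-bag error at the %d-probe level: %.3f\n",
              x$report_level,
              x$cv_error_by_level[as.character(x$report_level)]))
  invisible(x)
}

#' @export
plot.rsvm_selection <- function(x, ...) {
  lv <- x$ladder
  plot(lv, x$cv_error_by_level, log = "x", type = "b", pch = 19,
       xlab = "features retained", ylab = "mean out-of-bag error",
       main = "Recursive-SVM error ladder", ...)
  abline(v = x$report_level, lty = 2)
  invisible(x)
}
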