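#' Kaplan-Meier disease-free survival curves
#'
#' Product-limit estimate `S(t) = prod_{t_j <= t} (1 - d_j / r_j)` per
#' group, computed with `survival::survfit`. Events occurring at the same
#' time as censorings precede them (the standard convention).
#'
#' @param time Positive disease-free times (months).
#' @param event Event indicators: 1 = metastasis confirmed, 0 = censored.
#' @param group Optional group labels; one curve per group.
#' @return An object of class `"km_curve"`: list with `table` (data.frame
#'   `group`, `time`, `n_risk`, `n_event`, `n_censor`, `survival`) and
#'   `fit` (the underlying `survfit` object).
#' @export
#' @examples
#' km <- km_fit(c(1, 2, 3), c(1, 1, 0))
#' km$table
km_fit <- function(time, event, group = NULL) {
  validate_survival(time, event)
  if (is.null(group)) group <- rep("all", length(time))
  if (length(group) != length(time)) stopf("group length must match time")
  d <- data.frame(time = time, event = event, group = factor(group))
  fit <- survival::survfit(survival::Surv(time, event) ~ group, data = d)
  sm <- summary(fit, censored = TRUE)
  grp <- if (is.null(sm$strata)) rep(levels(d$group)[1], length(sm$time))
         else sub("^group=", "", as.character(sm$strata))
  tab <- data.frame(group = grp, time = sm$time, n_risk = sm$n.risk,
                    n_event = sm$n.event, n_censor = sm$n.censor,
                    survival = sm$surv, stringsAsFactors = FALSE)
  structure(list(table = tab, fit = fit), class = "km_curve")
}

validate_survival <- function(time, event) {
  if (length(time) != length(event)) stopf("time and event differ in length")
  if (anyNA(time) || anyNA(event)) stopf("time/event contain missing values")
  if (any(time <= 0)) stopf("survival times must be > 0")
  if (!all(event %in% c(0, 1))) stopf("event flags must be 0 or 1")
  invisible(TRUE)
}

#' @export
print.km_curve <- function(x, ...) {
  cat("Kaplan-Meier disease-free survival\n")
  print(x$fit)
  invisible(x)
}

#' @export
plot.km_curve <- function(x, ...) {
  plot(x$fit, xlab = "disease-free survival time (months)",
       ylab = "cumulative disease-free survival", mark.time = TRUE, ...)
  grps <- unique(x$table$group)
  if (length(grps) > 1L)
    legend("bottomleft", legend = grps, lty = seq_along(grps), bty = "n")
  invisible(x)
}

#' Mantel-Cox log-rank test
#'
#' Compares the survival of two groups with the log-rank statistic
#' `(sum(O1 - E1))^2 / Var`, summing observed-minus-expected events with
#' the hypergeometric variance at each distinct event time, referred to a
#' chi-square distribution with 1 degree of freedom. Computed with
#' `survival::survdiff`.
#'
#' @inheritParams km_fit
#' @param group Two-group labeling.
#' @return An object of class `"htest"` with `statistic` (chisq),
#'   `parameter` (df = 1) and `p.value`.
#' @export
#' @examples
#' logrank_test(c(1, 2, 3, 4), c(1, 1, 1, 1), c("a", "a", "b", "b"))
logrank_test <- function(time, event, group) {
  validate_survival(time, event)
  g <- factor(group)
  if (nlevels(g) != 2L) stopf("log-rank comparison requires exactly two groups")
  if (any(table(g) == 0L)) stopf("both groups must be non-empty")
  if (sum(event) == 0L) stopf("log-rank statistic undefined without any events")
  d <- data.frame(time = time, event = event, group = g)
  sd <- survival::survdiff(survival::Surv(time, event) ~ group, data = d)
  stat <- sd$chisq
  p <- pchisq(stat, df = 1L, lower.tail = FALSE)
  structure(list(statistic = c("chi-squared" = stat),
                 parameter = c(df = 1L), p.value = p,
                 method = "Mantel-Cox log-rank test",
                 data.name = sprintf("%d samples in groups %s",
                                     length(time),
                                     paste(levels(g), collapse = " vs ")),
                 observed = sd$obs, expected = sd$exp),
            class = "htest")
}
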