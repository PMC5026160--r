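#' ROC curve and AUC for integer subscores
#'
#' Builds the ROC curve for an odor-identification subscore under the
#' fixed clinical direction "low score = test-positive" (hyposmia indicates
#' PD). Candidate cutoffs are all achievable integer subscores; a subject
#' is test-positive when `score <= cutoff`. The AUC is the probability that
#' a random case scores below a random control, ties counted 1/2 — computed
#' by the tie-corrected rank (Mann-Whitney) formula, which equals the
#' trapezoidal area of the stepwise curve. The confidence interval uses
#' DeLong's structural-components variance estimate, truncated to `[0, 1]`.
#'
#' @param scores integer subscores.
#' @param labels 0/1 labels, 1 = case (PD).
#' @param level two-sided confidence level, default 0.95.
#' @return object of class `roc_curve` with per-cutoff sensitivity and
#'   specificity, `auc`, `auc_se`, `auc_ci`.
#' @export
roc_with_auc <- function(scores, labels, level = 0.95) {
  scores <- as.numeric(scores)
  labels <- as.numeric(labels)
  stopifnot(length(scores) == length(labels), all(labels %in% c(0, 1)))
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) {
    stop_sniffsel("sniffsel_degeneracy_error",
                  "both classes must be present to form a ROC curve")
  }
  cases <- scores[labels == 1]
  controls <- scores[labels == 0]

  # tie-corrected rank formula: AUC = P(case < control) + 0.5 P(tie)
  r <- rank(c(cases, controls), ties.method = "average")
  auc <- (sum(r[(n1 + 1):(n1 + n0)]) - n0 * (n0 + 1) / 2) / (n1 * n0)

  # DeLong structural components
  v10 <- vapply(cases, function(x) mean((x < controls) + 0.5 * (x == controls)),
                numeric(1))
  v01 <- vapply(controls, function(x) mean((cases < x) + 0.5 * (cases == x)),
                numeric(1))
  s10 <- if (n1 > 1) stats::var(v10) else 0
  s01 <- if (n0 > 1) stats::var(v01) else 0
  se <- sqrt(s10 / n1 + s01 / n0)
  z <- stats::qnorm(1 - (1 - level) / 2)
  ci <- c(max(0, auc - z * se), min(1, auc + z * se))

  cutoffs <- sort(unique(scores))
  sens <- vapply(cutoffs, function(cc) mean(cases <= cc), numeric(1))
  spec <- vapply(cutoffs, function(cc) mean(controls > cc), numeric(1))
  structure(list(cutoffs = cutoffs, sensitivity = sens, specificity = spec,
                 auc = auc, auc_se = se, auc_ci = ci, level = level,
                 n_cases = n1, n_controls = n0,
                 cases = cases, controls = controls,
                 direction = "low score = test-positive"),
            class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("ROC (%s): %d cases vs %d controls\n",
              x$direction, x$n_cases, x$n_controls))
  cat(sprintf("  AUC = %.3f (%.0f%% CI %.3f-%.3f, DeLong)\n",
              x$auc, 100 * x$level, x$auc_ci[1], x$auc_ci[2]))
  invisible(x)
}

#' @export
plot.roc_curve <- function(x, ...) {
  fpr <- c(0, rev(1 - x$specificity), 1)
  tpr <- c(0, rev(x$sensitivity), 1)
  graphics::plot(fpr, tpr, type = "s", xlim = c(0, 1), ylim = c(0, 1),
                 xlab = "1 - specificity", ylab = "sensitivity",
                 main = sprintf("AUC = %.3f", x$auc), ...)
  graphics::abline(0, 1, col = "grey70", lty = 2)
  invisible(x)
}

#' Youden-index cutoff
#'
#' Selects the integer cutoff maximizing J = sensitivity + specificity - 1
#' under the "score <= cutoff = positive" convention, scanning all
#' achievable cutoffs plus the all-negative boundary. Exact ties in J are
#' broken toward higher sensitivity by default (the screening use-case);
#' `ties = "specificity"` prefers the lower cutoff with higher specificity
#' instead (used for the distinction from diagnostic mimics). Remaining
#' ties go to the lower cutoff.
#'
#' @param curve a [roc_with_auc()] result.
#' @param ties `"sensitivity"` (default) or `"specificity"`.
#' @return list with `cutoff`, `J`, `sensitivity`, `specificity`.
#' @export
youden_cutoff <- function(curve, ties = c("sensitivity", "specificity")) {
  ties <- match.arg(ties)
  stopifnot(inherits(curve, "roc_curve"))
  # boundary "nobody positive": sens 0, spec 1, J = 0
  cuts <- c(min(curve$cutoffs) - 1, curve$cutoffs)
  sens <- c(0, curve$sensitivity)
  spec <- c(1, curve$specificity)
  J <- sens + spec - 1
  best <- which(J >= max(J) - 1e-12)
  if (ties == "sensitivity") {
    best <- best[sens[best] >= max(sens[best]) - 1e-12]
  } else {
    best <- best[spec[best] >= max(spec[best]) - 1e-12]
  }
  pick <- best[which.min(cuts[best])]
  list(cutoff = cuts[pick], J = J[pick],
       sensitivity = sens[pick], specificity = spec[pick])
}

#' Confusion table at a fixed cutoff
#'
#' Counts the 2x2 table under "score <= cutoff = test-positive" with
#' reference standard `labels` (1 = disease).
#'
#' @param scores integer subscores.
#' @param labels 0/1 reference labels.
#' @param cutoff integer cutoff.
#' @return object of class `confusion_table` with `tp`, `fp`, `tn`, `fn`.
#' @export
confusion_at_cutoff <- function(scores, labels, cutoff) {
  stopifnot(length(scores) == length(labels), all(labels %in% c(0, 1)))
  pos <- scores <= cutoff
  confusion_table(tp = sum(pos & labels == 1), fp = sum(pos & labels == 0),
                  tn = sum(!pos & labels == 0), fn = sum(!pos & labels == 1))
}

#' @rdname confusion_at_cutoff
#' @param tp,fp,tn,fn non-negative integer counts.
#' @export
confusion_table <- function(tp, fp, tn, fn) {
  counts <- c(tp = tp, fp = fp, tn = tn, fn = fn)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop_sniffsel("sniffsel_value_error", "confusion counts must be non-negative integers")
  }
  structure(as.list(counts), class = "confusion_table")
}

#' @export
print.confusion_table <- function(x, ...) {
  m <- matrix(c(x$tp, x$fn, x$fp, x$tn), 2, 2,
              dimnames = list(c("test+", "test-"), c("disease+", "disease-")))
  print(m)
  invisible(x)
}

#' Exact (Clopper-Pearson) binomial confidence interval
#'
#' Two-sided interval from the beta-quantile closed form; at `x = 0` the
#' lower limit is exactly 0 and the upper is `1 - (alpha/2)^(1/n)`, at
#' `x = n` symmetrically the lower is `(alpha/2)^(1/n)` and the upper 1.
#'
#' @param x number of successes.
#' @param n number of trials (>= 1).
#' @param level two-sided confidence level.
#' @return numeric `c(lower, upper)`.
#' @export
exact_binomial_ci <- function(x, n, level = 0.95) {
  if (n < 1 || x < 0 || x > n || x != round(x) || n != round(n)) {
    stop_sniffsel("sniffsel_value_error", "need integer 0 <= x <= n, n >= 1")
  }
  a <- 1 - level
  lower <- if (x == 0) 0 else stats::qbeta(a / 2, x, n - x + 1)
  upper <- if (x == n) 1 else stats::qbeta(1 - a / 2, x + 1, n - x)
  c(lower = lower, upper = upper)
}

#' Diagnostic accuracy summary with exact confidence intervals
#'
#' Sensitivity, specificity, PPV, NPV and accuracy from a 2x2 table, each
#' with a Clopper-Pearson interval. A metric whose margin is empty (e.g.
#' sensitivity with no diseased subjects) is reported as `NA` and flagged
#' `undefined`, never fabricated. Also reports Youden's J when both
#' sensitivity and specificity are defined.
#'
#' @param table a [confusion_table()].
#' @param level confidence level.
#' @param cutoff optional cutoff annotation carried into the summary.
#' @return object of class `diagnostic_summary`: a list of metric entries
#'   `(estimate, lower, upper, x, n)` plus `J`, `cutoff`, `level`,
#'   `undefined` (character vector of metric names).
#' @export
diagnostic_summary <- function(table, level = 0.95, cutoff = NA) {
  stopifnot(inherits(table, "confusion_table"))
  total <- table$tp + table$fp + table$tn + table$fn
  if (total == 0) {
    stop_sniffsel("sniffsel_value_error", "empty confusion table")
  }
  metric <- function(x, n) {
    if (n == 0) return(list(estimate = NA_real_, lower = NA_real_,
                            upper = NA_real_, x = x, n = n))
    ci <- exact_binomial_ci(x, n, level)
    list(estimate = x / n, lower = ci[["lower"]], upper = ci[["upper"]],
         x = x, n = n)
  }
  out <- list(
    sensitivity = metric(table$tp, table$tp + table$fn),
    specificity = metric(table$tn, table$tn + table$fp),
    ppv = metric(table$tp, table$tp + table$fp),
    npv = metric(table$tn, table$tn + table$fn),
    accuracy = metric(table$tp + table$tn, total)
  )
  undefined <- names(out)[vapply(out, function(m) is.na(m$estimate), logical(1))]
  J <- if (!any(c("sensitivity", "specificity") %in% undefined)) {
    out$sensitivity$estimate + out$specificity$estimate - 1
  } else NA_real_
  structure(c(out, list(J = J, cutoff = cutoff, level = level,
                        undefined = undefined, table = table)),
            class = "diagnostic_summary")
}

#' @export
print.diagnostic_summary <- function(x, ...) {
  if (!is.na(x$cutoff)) cat(sprintf("Cutoff: score <= %g is test-positive\n", x$cutoff))
  for (m in c("sensitivity", "specificity", "ppv", "npv", "accuracy")) {
    e <- x[[m]]
    if (is.na(e$estimate)) {
      cat(sprintf("  %-12s undefined (empty margin)\n", m))
    } else {
      cat(sprintf("  %-12s %s%% (%.0f%% CI %s-%s)  [%d/%d]\n", m,
                  fmt_pct(e$estimate), 100 * x$level,
                  fmt_pct(e$lower), fmt_pct(e$upper), e$x, e$n))
    }
  }
  if (!is.na(x$J)) cat(sprintf("  Youden J     %.3f\n", x$J))
  invisible(x)
}

#' Named clinical prevalence scenario
#'
#' @param name scenario label (e.g. `"general_neurology"`).
#' @param prevalence disease prevalence strictly between 0 and 1.
#' @return object of class `prevalence_scenario`.
#' @export
prevalence_scenario <- function(name, prevalence) {
  if (!is.numeric(prevalence) || prevalence <= 0 || prevalence >= 1) {
    stop_sniffsel("sniffsel_value_error", "prevalence must lie strictly in (0, 1)")
  }
  structure(list(name = name, prevalence = prevalence),
            class = "prevalence_scenario")
}

#' Prevalence-adjusted predictive values
#'
#' Bayes' rule applied to a test's sensitivity and specificity at an
#' assumed disease prevalence pi:
#' `PPV = sens*pi / (sens*pi + (1-spec)*(1-pi))` and
#' `NPV = spec*(1-pi) / (spec*(1-pi) + (1-sens)*pi)`. Used to translate
#' cohort accuracy into settings with a different PD vs mimic case mix
#' (e.g. a general neurological service at 91.8% PD prevalence, or a
#' movement-disorder clinic at 69.0%).
#'
#' @param sensitivity,specificity proportions in `(0, 1]`.
#' @param scenario a [prevalence_scenario()] or a bare prevalence in
#'   `(0, 1)`.
#' @return named numeric `c(ppv, npv)`.
#' @export
predictive_values_at_prevalence <- function(sensitivity, specificity, scenario) {
  pi <- if (inherits(scenario, "prevalence_scenario")) scenario$prevalence
        else as.numeric(scenario)
  if (!is.finite(pi) || pi <= 0 || pi >= 1) {
    stop_sniffsel("sniffsel_value_error", "prevalence must lie strictly in (0, 1)")
  }
  if (sensitivity <= 0 || sensitivity > 1 || specificity <= 0 || specificity > 1) {
    stop_sniffsel("sniffsel_value_error", "sensitivity/specificity must lie in (0, 1]")
  }
  ppv <- sensitivity * pi / (sensitivity * pi + (1 - specificity) * (1 - pi))
  npv <- specificity * (1 - pi) / (specificity * (1 - pi) + (1 - sensitivity) * pi)
  c(ppv = ppv, npv = npv)
}
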