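#' Mann-Whitney U test (two-sided)
#'
#' Rank-sum comparison of two samples. With the smaller sample below 8 the
#' exact permutation distribution of the rank sum is computed (a
#' dynamic-programming convolution over doubled mid-ranks, valid under
#' ties); otherwise the normal approximation with tie-corrected variance is
#' used, without continuity correction. The two-sided exact p-value doubles
#' the smaller tail of the permutation null distribution (capped at 1), the
#' convention of standard exact rank-sum implementations.
#'
#' @param a,b numeric samples (non-empty).
#' @param exact force (`TRUE`) or forbid (`FALSE`) the exact branch;
#'   default `NULL` picks exact when `min(length(a), length(b)) < 8`.
#' @param comparison optional label stored on the result.
#' @return object of class `comparison_result` with `statistic` (U for
#'   sample `a`), `p_value`, `method`, `comparison`.
#' @export
mann_whitney_test <- function(a, b, exact = NULL, comparison = NA_character_) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) == 0 || length(b) == 0) {
    stop_sniffsel("sniffsel_value_error", "both samples must be non-empty")
  }
  n <- length(a); m <- length(b); N <- n + m
  r <- rank(c(a, b), ties.method = "average")
  U <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  if (is.null(exact)) exact <- min(n, m) < 8
  if (exact) {
    p <- mw_exact_p(r, n)
    method <- "Mann-Whitney U (exact enumeration)"
  } else {
    tie_tab <- table(r)
    sigma2 <- n * m / 12 * ((N + 1) - sum(tie_tab^3 - tie_tab) / (N * (N - 1)))
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- (U - n * m / 2) / sqrt(sigma2)
      p <- 2 * stats::pnorm(-abs(z))
    }
    method <- "Mann-Whitney U (normal approximation, tie-corrected)"
  }
  comparison_result(statistic = U, p_value = min(p, 1), method = method,
                    comparison = comparison)
}

# Exact null distribution of the rank sum of the first sample by DP over
# doubled pooled ranks (integers even under average-rank ties). Counts the
# C(N, n) equally likely assignments; the two-sided p doubles the smaller
# tail (capped at 1), the standard exact convention.
mw_exact_p <- function(r, n) {
  N <- length(r)
  w <- as.integer(round(2 * sort(r)))        # doubled ranks, integer
  smax <- sum(utils::tail(w, n))
  # f[k+1, s+1] = number of k-subsets with doubled-rank sum s
  f <- matrix(0, n + 1, smax + 1)
  f[1, 1] <- 1
  for (x in w) {
    for (k in n:1) {                         # descending k: each item used once
      nzs <- which(f[k, ] > 0)
      if (length(nzs)) {
        f[k + 1, nzs + x] <- f[k + 1, nzs + x] + f[k, nzs]
      }
    }
  }
  counts <- f[n + 1, ]
  total <- sum(counts)
  sums <- (seq_along(counts) - 1) / 2        # back to rank-sum scale
  obs <- sum(r[seq_len(n)])
  lo <- sum(counts[sums <= obs + 1e-9]) / total
  hi <- sum(counts[sums >= obs - 1e-9]) / total
  min(1, 2 * min(lo, hi))
}

#' Pearson chi-square test of independence
#'
#' Wrapper over the classical Pearson statistic with `(r-1)(c-1)` degrees
#' of freedom and no continuity correction. All expected counts must be
#' positive.
#'
#' @param table an r x c contingency table of counts.
#' @param comparison optional label.
#' @return a `comparison_result` with `statistic`, `df`, `p_value`.
#' @export
chi_square_test <- function(table, comparison = NA_character_) {
  tab <- as.matrix(table)
  if (any(tab < 0)) stop_sniffsel("sniffsel_value_error", "counts must be non-negative")
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(expected <= 0)) {
    stop_sniffsel("sniffsel_value_error",
                  "zero expected count; chi-square statistic undefined")
  }
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  res <- comparison_result(statistic = unname(ct$statistic),
                           p_value = unname(ct$p.value),
                           method = "Pearson chi-square (no continuity correction)",
                           comparison = comparison)
  res$df <- unname(ct$parameter)
  res
}

#' Bonferroni adjustment
#'
#' `min(1, m * p)` elementwise; the family size defaults to the number of
#' p-values (the set of versus-PD comparisons for one variable within one
#' center, in the tabulation use-case).
#'
#' @param p_values numeric p-values in `[0, 1]`.
#' @param m family size; default `length(p_values)`.
#' @return adjusted p-values.
#' @export
bonferroni_adjust <- function(p_values, m = length(p_values)) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE)) {
    stop_sniffsel("sniffsel_value_error", "p-values must lie in [0, 1]")
  }
  pmin(1, m * p_values)
}

comparison_result <- function(statistic, p_value, method, comparison,
                              p_adjusted = NA_real_) {
  structure(list(statistic = statistic, p_value = p_value,
                 p_adjusted = p_adjusted, method = method,
                 comparison = comparison),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("%s%s: statistic = %.4g, p = %.4g%s\n",
              x$method,
              if (!is.na(x$comparison)) sprintf(" [%s]", x$comparison) else "",
              x$statistic, x$p_value,
              if (!is.na(x$p_adjusted)) sprintf(" (adjusted %.4g)", x$p_adjusted) else ""))
  invisible(x)
}

#' Group descriptives with versus-PD comparisons
#'
#' Builds a cohort-characteristics table in the conventional layout: one
#' row per group with mean +/- SD of age, disease duration and the
#' full-panel sum score, percent female, and p-values of each group's
#' comparison against PD (rank-sum for continuous variables, chi-square
#' for sex), Bonferroni-adjusted per variable across the within-cohort
#' family of versus-PD comparisons.
#'
#' @param cohort an [odor_cohort()] containing a PD group.
#' @param adjust apply Bonferroni adjustment within each variable's family
#'   (default `TRUE`).
#' @return data.frame, one row per group.
#' @export
group_descriptives <- function(cohort, adjust = TRUE) {
  stopifnot(inherits(cohort, "odor_cohort"))
  d <- cohort$data
  if (!"PD" %in% d$group) {
    stop_sniffsel("sniffsel_value_error", "cohort contains no PD group to compare against")
  }
  d$sum_score <- compute_subscore(cohort, cohort$panel$odors)
  groups <- unique(d$group)
  others <- setdiff(groups, "PD")
  pd <- d[d$group == "PD", ]
  row_for <- function(g) {
    gg <- d[d$group == g, ]
    ms <- function(x) if (all(is.na(x))) NA_character_
                      else sprintf("%.1f ± %.1f", mean(x, na.rm = TRUE),
                                   stats::sd(x, na.rm = TRUE))
    data.frame(group = g, n = nrow(gg),
               age = ms(gg$age),
               female_pct = round(100 * mean(gg$sex == "F"), 1),
               duration = ms(gg$disease_duration_years),
               sum_score = ms(gg$sum_score),
               stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, lapply(c("PD", others), row_for))
  pvals <- function(var) {
    vapply(others, function(g) {
      gg <- d[d$group == g, ]
      if (identical(var, "sex")) {
        tab <- rbind(PD = table(factor(pd$sex, c("F", "M"))),
                     other = table(factor(gg$sex, c("F", "M"))))
        if (any(colSums(tab) == 0)) return(NA_real_)
        chi_square_test(tab)$p_value
      } else {
        x <- pd[[var]]; y <- gg[[var]]
        if (all(is.na(y)) || all(is.na(x))) return(NA_real_)
        mann_whitney_test(x[!is.na(x)], y[!is.na(y)])$p_value
      }
    }, numeric(1))
  }
  for (v in c("age", "sex", "disease_duration_years", "sum_score")) {
    p <- pvals(v)
    padj <- if (adjust) bonferroni_adjust(p, m = length(others)) else p
    col <- paste0("p_vs_PD_", sub("disease_duration_years", "duration", v))
    out[[col]] <- c(NA, round(padj, 4))
  }
  out
}
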