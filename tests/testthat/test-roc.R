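test_that("AUC handles separation, symmetry and the hand-counted example", {
  # perfect separation: all cases below all controls
  expect_equal(roc_with_auc(c(2, 3, 5, 6), c(1, 1, 0, 0))$auc, 1.0)
  # identical multisets in both groups
  expect_equal(roc_with_auc(c(4, 7, 4, 7), c(1, 1, 0, 0))$auc, 0.5)
  # PD {4,6} vs controls {5,7}: 3 of 4 pairs concordant
  expect_equal(roc_with_auc(c(4, 6, 5, 7), c(1, 1, 0, 0))$auc, 0.75)
  expect_error(roc_with_auc(1:4, c(1, 1, 1, 1)),
               class = "sniffsel_degeneracy_error")
})

test_that("rank-formula AUC equals exhaustive pair counting on random instances", {
  set.seed(31)
  for (i in 1:25) {
    n1 <- sample(2:25, 1); n0 <- sample(2:25, 1)
    sc <- sample(0:16, n1 + n0, replace = TRUE)
    lab <- rep(c(1, 0), c(n1, n0))
    r <- roc_with_auc(sc, lab)
    expect_equal(r$auc, auc_paircount(sc[lab == 1], sc[lab == 0]))
    expect_true(r$auc_ci[1] <= r$auc && r$auc <= r$auc_ci[2])
    # curve monotonicity along rising cutoffs
    expect_true(all(diff(r$sensitivity) >= 0))
    expect_true(all(diff(r$specificity) <= 0))
  }
})

test_that("DeLong interval matches the reference implementation and shrinks with n", {
  skip_if_not_installed("pROC")
  set.seed(5)
  for (n in c(40, 160)) {
    sc <- sample(0:16, n, replace = TRUE)
    lab <- rbinom(n, 1, plogis(-(sc - 8)))
    if (length(unique(lab)) < 2) next
    r <- roc_with_auc(sc, lab)
    ref <- suppressMessages(pROC::roc(lab, sc, direction = ">"))
    expect_equal(r$auc, as.numeric(pROC::auc(ref)))
    ci <- as.numeric(pROC::ci.auc(ref, method = "delong"))
    expect_equal(unname(r$auc_ci), ci[c(1, 3)], tolerance = 1e-10)
  }
  # width ~ n^(-1/2): quadrupling n roughly halves the width
  mk <- function(n, seed) {
    set.seed(seed)
    sc <- c(rbinom(n, 16, 0.4), rbinom(n, 16, 0.75))
    r <- roc_with_auc(sc, rep(c(1, 0), each = n))
    diff(r$auc_ci)
  }
  w1 <- mk(250, 9); w2 <- mk(1000, 9)
  expect_equal(w2 / w1, 0.5, tolerance = 0.2)
})

test_that("Youden cutoff equals the brute-force scan and honors tie rules", {
  # perfect separation: J = 1, tie rule picks the sensitivity-preserving cutoff
  r <- roc_with_auc(c(3, 4, 10, 12), c(1, 1, 0, 0))
  y <- youden_cutoff(r)
  expect_equal(y$J, 1.0)
  expect_equal(y$sensitivity, 1.0)
  # uninformative data: J = 0 at the boundary
  r0 <- roc_with_auc(c(4, 7, 4, 7), c(1, 1, 0, 0))
  expect_equal(youden_cutoff(r0, ties = "specificity")$J, 0)
  # six-subject hand example and random instances vs exhaustive scan
  set.seed(77)
  for (i in 1:30) {
    n <- sample(6:40, 1)
    sc <- sample(0:16, n, replace = TRUE)
    lab <- c(1, 0, rbinom(n - 2, 1, 0.5))
    r <- roc_with_auc(sc, lab)
    for (rule in c("sensitivity", "specificity")) {
      got <- youden_cutoff(r, ties = rule)
      ref <- brute_youden(sc, lab, ties = rule)
      expect_equal(got$J, ref$J)
      expect_equal(got$sensitivity, ref$sensitivity)
      expect_equal(got$specificity, ref$specificity)
    }
  }
})

test_that("Youden cutoff is invariant to duplicating the dataset", {
  set.seed(13)
  sc <- sample(0:16, 30, replace = TRUE)
  lab <- c(1, 0, rbinom(28, 1, 0.5))
  r1 <- youden_cutoff(roc_with_auc(sc, lab))
  r2 <- youden_cutoff(roc_with_auc(rep(sc, 2), rep(lab, 2)))
  expect_equal(r1, r2)
})

test_that("confusion tables count correctly at a cutoff", {
  sc <- c(3, 8, 10, 12, 5, 11)
  lab <- c(1, 1, 0, 0, 1, 0)
  tab <- confusion_at_cutoff(sc, lab, 8)
  expect_equal(unlist(tab[c("tp", "fp", "tn", "fn")]),
               c(tp = 3, fp = 0, tn = 3, fn = 0))
  tab2 <- confusion_at_cutoff(sc, lab, 4)
  expect_equal(unlist(tab2[c("tp", "fp", "tn", "fn")]),
               c(tp = 1, fp = 0, tn = 3, fn = 2))
  # totals preserved on random data
  set.seed(2)
  sc <- sample(0:16, 40, TRUE); lab <- rbinom(40, 1, 0.5)
  t3 <- confusion_at_cutoff(sc, lab, 9)
  expect_equal(t3$tp + t3$fp + t3$tn + t3$fn, 40)
})

test_that("diagnostic summaries equal independent ratio arithmetic", {
  set.seed(19)
  for (i in 1:20) {
    cnt <- rmultinom(1, 60, c(0.3, 0.2, 0.35, 0.15))
    ds <- diagnostic_summary(confusion_table(cnt[1], cnt[2], cnt[3], cnt[4]))
    if (cnt[1] + cnt[4] > 0)
      expect_equal(ds$sensitivity$estimate, cnt[1] / (cnt[1] + cnt[4]))
    if (cnt[3] + cnt[2] > 0)
      expect_equal(ds$specificity$estimate, cnt[3] / (cnt[3] + cnt[2]))
    if (cnt[1] + cnt[2] > 0)
      expect_equal(ds$ppv$estimate, cnt[1] / (cnt[1] + cnt[2]))
    if (cnt[3] + cnt[4] > 0)
      expect_equal(ds$npv$estimate, cnt[3] / (cnt[3] + cnt[4]))
  }
})

test_that("empty margins are flagged undefined, not fabricated", {
  ds <- diagnostic_summary(confusion_table(0, 0, 12, 0))
  expect_true("sensitivity" %in% ds$undefined)
  expect_true("ppv" %in% ds$undefined)
  expect_true(is.na(ds$sensitivity$estimate))
  expect_equal(ds$specificity$estimate, 1)
  expect_true(is.na(ds$J))
})

test_that("Clopper-Pearson endpoints follow the closed forms", {
  # x = n: lower = (alpha/2)^(1/n)
  ci <- exact_binomial_ci(8, 8, 0.95)
  expect_equal(unname(ci["lower"]), 0.025^(1 / 8), tolerance = 1e-10)
  expect_equal(unname(ci["upper"]), 1)
  expect_equal(round(100 * ci[["lower"]], 1), 63.1)
  # x = 0: upper = 1 - (alpha/2)^(1/n)
  ci0 <- exact_binomial_ci(0, 8, 0.95)
  expect_equal(unname(ci0["upper"]), 1 - 0.025^(1 / 8), tolerance = 1e-10)
  expect_equal(unname(ci0["lower"]), 0)
  expect_error(exact_binomial_ci(9, 8), class = "sniffsel_value_error")
})

test_that("Clopper-Pearson intervals attain nominal coverage", {
  set.seed(41)
  n <- 20; reps <- 10000
  for (p in c(0.1, 0.5, 0.9)) {
    x <- rbinom(reps, n, p)
    lims <- vapply(0:n, function(k) exact_binomial_ci(k, n, 0.95), numeric(2))
    covered <- lims[1, x + 1] <= p & p <= lims[2, x + 1]
    expect_gte(mean(covered), 0.95 - 1e-12)
  }
})

test_that("prevalence-adjusted predictive values follow Bayes identities", {
  pv <- predictive_values_at_prevalence(0.84, 0.88, 0.690)
  expect_equal(unname(pv["ppv"]), 0.84 * 0.69 / (0.84 * 0.69 + 0.12 * 0.31),
               tolerance = 1e-12)
  # monotone in prevalence for an informative test
  p1 <- predictive_values_at_prevalence(0.84, 0.84, 0.918)
  p2 <- predictive_values_at_prevalence(0.84, 0.84, 0.690)
  expect_gt(p1["ppv"], p2["ppv"])
  expect_gt(p2["npv"], p1["npv"])
  # uninformative test: PPV equals prevalence
  u <- predictive_values_at_prevalence(0.6, 0.4, 0.3)
  expect_equal(unname(u["ppv"]), 0.3, tolerance = 1e-12)
  expect_error(predictive_values_at_prevalence(0.8, 0.8, 1),
               class = "sniffsel_value_error")
  s <- prevalence_scenario("clinic", 0.69)
  expect_equal(predictive_values_at_prevalence(0.84, 0.88, s), pv)
})
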