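test_that("Mann-Whitney null and hand-enumerated cases", {
  # identical multisets: U at its null mean, p = 1
  r <- mann_whitney_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(r$statistic, 4.5)
  expect_equal(r$p_value, 1)
  # {1,2} vs {3,4}: 6 orderings, two extreme -> p = 1/3
  expect_equal(mann_whitney_test(c(1, 2), c(3, 4))$p_value, 1 / 3)
  expect_error(mann_whitney_test(numeric(0), 1:3),
               class = "sniffsel_value_error")
})

test_that("exact branch reproduces complete permutation enumeration", {
  set.seed(23)
  for (i in 1:20) {
    n <- sample(2:5, 1); m <- sample(2:5, 1)
    a <- sample(1:6, n, replace = TRUE)      # ties likely
    b <- sample(1:6, m, replace = TRUE)
    got <- mann_whitney_test(a, b, exact = TRUE)$p_value
    expect_equal(got, mw_perm_p(a, b), tolerance = 1e-12,
                 label = sprintf("a=%s b=%s", toString(a), toString(b)))
  }
})

test_that("exact branch agrees with the base tie-free reference", {
  set.seed(71)
  for (i in 1:10) {
    a <- rnorm(6); b <- rnorm(7)               # continuous: no ties
    got <- mann_whitney_test(a, b, exact = TRUE)$p_value
    ref <- wilcox.test(a, b, exact = TRUE)$p.value
    expect_equal(got, ref, tolerance = 1e-12)
  }
})

test_that("exact and normal branches agree near the crossover size", {
  # the worst-case gap between the exact doubled-tail p and the
  # uncorrected normal approximation at min(n) = 8 (tie-free) is 0.0465,
  # by enumeration of the full null distribution; a continuity correction
  # would tighten this but is deliberately not applied
  set.seed(37)
  for (i in 1:20) {
    a <- rnorm(8); b <- rnorm(8)
    pe <- mann_whitney_test(a, b, exact = TRUE)$p_value
    pa <- mann_whitney_test(a, b, exact = FALSE)$p_value
    expect_lt(abs(pe - pa), 0.047)
  }
})

test_that("both tests hold their nominal type-I error under the null", {
  set.seed(55)
  reps <- 10000
  rej_mw <- mean(replicate(reps, {
    mann_whitney_test(rnorm(30), rnorm(30))$p_value < 0.05
  }))
  expect_gte(rej_mw, 0.04); expect_lte(rej_mw, 0.06)
  rej_chi <- mean(replicate(reps, {
    tab <- rbind(table(factor(rbinom(30, 1, 0.5), 0:1)),
                 table(factor(rbinom(30, 1, 0.5), 0:1)))
    if (any(colSums(tab) == 0)) FALSE
    else chi_square_test(tab)$p_value < 0.05
  }))
  expect_gte(rej_chi, 0.04); expect_lte(rej_chi, 0.06)
})

test_that("chi-square matches the hand-computed Pearson formula", {
  # perfectly proportional table: statistic 0, p = 1
  r0 <- chi_square_test(rbind(c(20, 30), c(40, 60)))
  expect_equal(r0$statistic, 0)
  expect_equal(r0$p_value, 1)
  # printed-style 2x2 (sex by group): hand arithmetic
  tab <- rbind(c(50, 84), c(180, 156))
  e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  stat_hand <- sum((tab - e)^2 / e)
  r <- chi_square_test(tab)
  expect_equal(r$statistic, stat_hand, tolerance = 1e-12)
  expect_equal(r$df, 1)
  # transpose invariance
  expect_equal(chi_square_test(t(tab))$statistic, r$statistic)
  expect_error(chi_square_test(rbind(c(0, 0), c(1, 2))),
               class = "sniffsel_value_error")
})

test_that("Bonferroni adjustment caps at one and preserves order", {
  expect_equal(bonferroni_adjust(c(0.01, 0.04), m = 5), c(0.05, 0.20))
  expect_equal(bonferroni_adjust(0.5, m = 3), 1)
  set.seed(3)
  p <- runif(10)
  adj <- bonferroni_adjust(p, m = 10)
  expect_true(all(adj >= p))
  # adjustment is monotone: sorting by raw p leaves adjusted p sorted
  expect_true(!is.unsorted(adj[order(p)]))
  expect_error(bonferroni_adjust(c(0.2, 1.3)), class = "sniffsel_value_error")
})

test_that("group descriptives produce a versus-PD comparison table", {
  p <- ss16_panel()
  pd <- generate_group(calibrate_profile(6.8, 3.1, 16, group = "PD"), 60, p,
                       seed = 1, meta = list(age_mean = 68, age_sd = 9,
                                             female_pct = 37,
                                             duration_mean = 6, duration_sd = 5))
  hc <- generate_group(calibrate_profile(12.7, 2.7, 16, group = "HC"), 80, p,
                       seed = 2, id_prefix = "H",
                       meta = list(age_mean = 69, age_sd = 8, female_pct = 54))
  co <- sniffsel:::bind_cohorts(pd, hc)
  tab <- group_descriptives(co)
  expect_equal(tab$group, c("PD", "HC"))
  expect_equal(tab$n, c(60, 80))
  # strongly separated sum scores give a tiny adjusted p
  expect_lt(tab$p_vs_PD_sum_score[2], 0.001)
  expect_true(is.na(tab$p_vs_PD_duration[2]))   # HC has no duration
})
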