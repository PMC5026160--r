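# shared fixtures and independent oracles

toy_panel <- function(n = 4) {
  odor_panel("toy", paste0("odor", seq_len(n)))
}

# build a small cohort data.frame by hand
toy_cohort_df <- function(panel, responses, group = "HC", center = "A") {
  n <- nrow(responses)
  df <- data.frame(
    subject_id = paste0("S", seq_len(n)),
    center = center,
    group = rep_len(group, n),
    age = 60 + seq_len(n),
    sex = rep_len(c("F", "M"), n),
    disease_duration_years = ifelse(rep_len(group, n) %in%
                                      c("PD", "MSA", "PSP", "ET"), 2.5, NA),
    followup_diagnosis = NA_character_,
    stringsAsFactors = FALSE
  )
  resp <- as.data.frame(responses)
  names(resp) <- paste0("odor_", panel$odors)
  cbind(df, resp)
}

random_cohort <- function(panel, n = 10, seed = 1, group = "HC") {
  set.seed(seed)
  resp <- matrix(rbinom(n * length(panel$odors), 1, 0.6), nrow = n)
  odor_cohort(toy_cohort_df(panel, resp, group = group), panel,
              provenance = "synthetic test fixture")
}

# AUC by exhaustive pair counting: P(case < control) + 0.5 P(tie)
auc_paircount <- function(cases, controls) {
  s <- 0
  for (x in cases) for (z in controls) {
    s <- s + (x < z) + 0.5 * (x == z)
  }
  s / (length(cases) * length(controls))
}

# brute-force Youden scan over every integer cutoff in range (plus the
# all-negative boundary), mirroring the positivity convention score <= c
brute_youden <- function(scores, labels, ties = "sensitivity") {
  cases <- scores[labels == 1]; controls <- scores[labels == 0]
  cuts <- seq(min(scores) - 1, max(scores))
  best <- NULL
  for (cc in cuts) {
    sens <- mean(cases <= cc); spec <- mean(controls > cc)
    J <- sens + spec - 1
    better <- is.null(best) || J > best$J + 1e-12 ||
      (abs(J - best$J) <= 1e-12 &&
         ((ties == "sensitivity" && sens > best$sensitivity + 1e-12) ||
          (ties == "specificity" && spec > best$specificity + 1e-12)))
    if (better) best <- list(cutoff = cc, J = J, sensitivity = sens,
                             specificity = spec)
  }
  best
}

# two-sided Mann-Whitney p by complete enumeration of label assignments
# (doubled smaller tail, capped at 1)
mw_perm_p <- function(a, b) {
  pooled <- c(a, b); n <- length(a); N <- length(pooled)
  r <- rank(pooled, ties.method = "average")
  obs <- sum(r[seq_len(n)])
  combos <- combn(N, n)
  sums <- apply(combos, 2, function(ix) sum(r[ix]))
  lo <- mean(sums <= obs + 1e-9)
  hi <- mean(sums >= obs - 1e-9)
  min(1, 2 * min(lo, hi))
}

# independent ML logistic fit (Newton via base glm)
glm_logistic_coefs <- function(X, y) {
  unname(coef(glm(y ~ X, family = binomial,
                  control = glm.control(epsilon = 1e-12, maxit = 100))))
}

# planted-signal two-group binary design: first k items informative
planted_design <- function(n_per_group, panel, seed, k = 8, shift = -1.5) {
  off <- c(rep(shift, k), rep(0, length(panel$odors) - k))
  cases <- generate_group(group_profile("PD", -0.5, 1.0, item_offsets = off),
                          n_per_group, panel, seed = seed, id_prefix = "case")
  ctrls <- generate_group(group_profile("HC", -0.5, 1.0),
                          n_per_group, panel, seed = seed + 10000L,
                          id_prefix = "ctrl")
  list(
    X = rbind(sniffsel:::response_matrix(cases),
              sniffsel:::response_matrix(ctrls)),
    y = rep(c(1L, 0L), each = n_per_group),
    informative = panel$odors[seq_len(k)]
  )
}
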