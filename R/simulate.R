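#' Latent-trait response model for forced-choice odor identification
#'
#' A diagnostic group's responses follow a one-dimensional item-response
#' model with a guessing floor: subject i draws a latent olfactory ability
#' theta_i ~ Normal(mu, sigma^2) and identifies odor j with probability
#'
#'   p_ij = gamma + (1 - gamma) * plogis(theta_i + b_j),
#'
#' where gamma is the chance rate of the forced-choice format (0.25 for a
#' four-alternative test) and b_j a per-odor difficulty offset. The shared
#' trait induces the between-subject overdispersion that independent
#' Bernoulli items cannot produce: printed sum-score SDs (e.g. 3.1 for PD on
#' a 16-item test) exceed the binomial maximum (about 2.0), so a latent
#' trait is structurally required.
#'
#' @param group group label (one of HC, PD, MSA, PSP, ET, iRBD).
#' @param trait_mean latent ability mean mu, logit scale.
#' @param trait_sd latent ability SD sigma >= 0.
#' @param item_offsets per-odor difficulty offsets b_j (logit scale); a
#'   scalar is recycled to the panel size at generation time. Default 0
#'   (exchangeable odors).
#' @param guess_floor chance rate gamma in `[0, 1)`; default 0.25.
#' @return object of class `group_profile`.
#' @export
group_profile <- function(group, trait_mean, trait_sd, item_offsets = 0,
                          guess_floor = 0.25) {
  if (trait_sd < 0) stop_sniffsel("sniffsel_value_error", "trait_sd must be >= 0")
  if (guess_floor < 0 || guess_floor >= 1) {
    stop_sniffsel("sniffsel_value_error", "guess_floor must lie in [0, 1)")
  }
  structure(list(group = group, trait_mean = trait_mean, trait_sd = trait_sd,
                 item_offsets = item_offsets, guess_floor = guess_floor),
            class = "group_profile")
}

#' @export
print.group_profile <- function(x, ...) {
  cat(sprintf("Group profile %s: mu = %.3f, sigma = %.3f, gamma = %.2f\n",
              x$group, x$trait_mean, x$trait_sd, x$guess_floor))
  invisible(x)
}

# Deterministic sum-score moments under the latent-trait model, by
# Gauss-Hermite quadrature over theta. Var(S) decomposes as
# E[sum p_j(1-p_j)] (within-subject binomial part) + Var(sum p_j) (between).
sumscore_moments <- function(trait_mean, trait_sd, n_items, guess_floor,
                             item_offsets = 0, n_nodes = 60) {
  b <- rep_len(item_offsets, n_items)
  if (trait_sd == 0) {
    p <- guess_floor + (1 - guess_floor) * stats::plogis(trait_mean + b)
    return(list(mean = sum(p), sd = sqrt(sum(p * (1 - p)))))
  }
  gh <- gauss_hermite(n_nodes)
  theta <- trait_mean + sqrt(2) * trait_sd * gh$nodes
  w <- gh$weights / sqrt(pi)
  P <- guess_floor + (1 - guess_floor) *
    stats::plogis(outer(theta, b, `+`))       # nodes x items
  s <- rowSums(P)
  v <- rowSums(P * (1 - P))
  m1 <- sum(w * s)
  var_total <- sum(w * v) + sum(w * s^2) - m1^2
  list(mean = m1, sd = sqrt(max(var_total, 0)))
}

#' Calibrate a group profile to target sum-score moments
#'
#' Finds (mu, sigma) with zero item offsets such that the model-implied mean
#' and SD of the sum score match the targets. Moments are computed by
#' deterministic quadrature (no Monte-Carlo), so the calibration is exactly
#' reproducible; the solver nests two root searches: for a candidate sigma,
#' mu is solved to hit the mean (the mean is strictly increasing in mu),
#' then sigma is solved to hit the SD (increasing in sigma at fixed mean).
#'
#' @param target_mean,target_sd sum-score mean and SD to reproduce, e.g. the
#'   published group values (PD 6.8 / 3.1 and HC 12.7 / 2.7 on a 16-item
#'   test).
#' @param panel_size number of items.
#' @param guess_floor chance rate gamma, default 0.25.
#' @param group label stored on the returned profile.
#' @return a [group_profile()] with `item_offsets = 0`.
#' @export
calibrate_profile <- function(target_mean, target_sd, panel_size,
                              guess_floor = 0.25, group = "custom") {
  lo <- guess_floor * panel_size
  if (!(target_mean > lo && target_mean < panel_size)) {
    stop_sniffsel("sniffsel_calibration_error",
      sprintf("target mean %.2f outside feasible range (%.2f, %d) for gamma = %.2f",
              target_mean, lo, panel_size, guess_floor))
  }
  if (target_sd <= 0) {
    stop_sniffsel("sniffsel_calibration_error", "target_sd must be > 0")
  }
  solve_mu <- function(sigma) {
    # the mean is strictly increasing in mu; widen the bracket as needed
    # (large sigma pushes the required mu far out)
    stats::uniroot(function(mu) {
      sumscore_moments(mu, sigma, panel_size, guess_floor)$mean - target_mean
    }, interval = c(-40, 40), extendInt = "upX", tol = 1e-10,
    maxiter = 500)$root
  }
  sd_at <- function(sigma) {
    sumscore_moments(solve_mu(sigma), sigma, panel_size, guess_floor)$sd
  }
  sd_min <- sd_at(0)
  sigma_hi <- 50
  sd_max <- sd_at(sigma_hi)
  if (target_sd < sd_min || target_sd > sd_max) {
    stop_sniffsel("sniffsel_calibration_error",
      sprintf("target SD %.2f unreachable at mean %.2f: feasible range is [%.3f, %.3f]",
              target_sd, target_mean, sd_min, sd_max))
  }
  sigma <- stats::uniroot(function(s) sd_at(s) - target_sd,
                          interval = c(0, sigma_hi), tol = 1e-8)$root
  group_profile(group, trait_mean = solve_mu(sigma), trait_sd = sigma,
                item_offsets = 0, guess_floor = guess_floor)
}

# cache calibrations keyed by their targets (pure function of the inputs)
.calib_cache <- new.env(parent = emptyenv())
calibrate_profile_cached <- function(target_mean, target_sd, panel_size,
                                     guess_floor = 0.25, group = "custom") {
  key <- paste(target_mean, target_sd, panel_size, guess_floor, sep = "|")
  if (!is.null(.calib_cache[[key]])) {
    pr <- .calib_cache[[key]]
    pr$group <- group
    return(pr)
  }
  pr <- calibrate_profile(target_mean, target_sd, panel_size, guess_floor,
                          group = group)
  .calib_cache[[key]] <- pr
  pr
}

#' Generate subject records for one diagnostic group
#'
#' Draws `n` subjects from a [group_profile()]: each subject draws a latent
#' trait, then independent Bernoulli responses per odor with the
#' guessing-floor success probability. Metadata (age, sex, disease
#' duration) are drawn from normal/Bernoulli approximations if `meta` is
#' given; they never enter the classifier.
#'
#' @param profile a [group_profile()].
#' @param n number of subjects (>= 0).
#' @param panel an [odor_panel()].
#' @param seed integer seed; identical seeds give identical cohorts.
#' @param center center label stored on records.
#' @param meta optional list with elements `age_mean`, `age_sd`,
#'   `female_pct`, and optionally `duration_mean`, `duration_sd` (durations
#'   are truncated at zero).
#' @param id_prefix prefix for generated subject ids.
#' @param followup optional vector of follow-up diagnoses (recycled).
#' @return an [odor_cohort()] with `n` records of the profile's group.
#' @export
generate_group <- function(profile, n, panel, seed, center = "A",
                           meta = NULL, id_prefix = NULL, followup = NA) {
  stopifnot(inherits(profile, "group_profile"), inherits(panel, "odor_panel"))
  if (n < 0) stop_sniffsel("sniffsel_value_error", "n must be >= 0")
  m <- length(panel$odors)
  b <- rep_len(profile$item_offsets, m)
  id_prefix <- id_prefix %||% paste0(center, "_", profile$group)
  dat <- with_seed(seed, {
    theta <- stats::rnorm(n, profile$trait_mean, profile$trait_sd)
    P <- profile$guess_floor + (1 - profile$guess_floor) *
      stats::plogis(outer(theta, b, `+`))
    resp <- matrix(stats::rbinom(n * m, 1L, as.vector(P)), nrow = n)
    age <- if (!is.null(meta)) pmax(18, round(stats::rnorm(n, meta$age_mean, meta$age_sd), 1))
           else rep(70, n)
    sex <- if (!is.null(meta)) ifelse(stats::runif(n) < meta$female_pct / 100, "F", "M")
           else rep("F", n)
    dur <- if (!is.null(meta) && !is.null(meta$duration_mean))
             round(pmax(0, stats::rnorm(n, meta$duration_mean, meta$duration_sd)), 1)
           else if (profile$group %in% c("PD", "MSA", "PSP", "ET"))
             rep(0, n)   # duration is mandatory for manifest disease
           else rep(NA_real_, n)
    list(resp = resp, age = age, sex = sex, dur = dur)
  })
  df <- data.frame(
    subject_id = if (n) sprintf("%s_%04d", id_prefix, seq_len(n)) else character(0),
    center = rep(center, n),
    group = rep(profile$group, n),
    age = dat$age,
    sex = dat$sex,
    disease_duration_years = dat$dur,
    followup_diagnosis = rep_len(followup, max(n, 1))[seq_len(n)],
    stringsAsFactors = FALSE
  )
  if (n) {
    resp <- as.data.frame(dat$resp)
  } else {
    resp <- as.data.frame(matrix(integer(0), nrow = 0, ncol = m))
  }
  names(resp) <- odor_cols(panel)
  odor_cohort(cbind(df, resp), panel,
              provenance = sprintf("synthetic seed=%d", as.integer(seed)))
}

#' Study configuration for the synthetic multi-center design
#'
#' Describes a full study: per-center panels and group specifications
#' (profile plus size plus metadata moments) and a prospective prodromal
#' (iRBD) arm with a configured number of incident-PD converters. All
#' randomness derives from the single `seed` by deterministic stream
#' splitting.
#'
#' @param centers named list; each element is a list with `panel` (an
#'   [odor_panel()]) and `groups`, itself a named list of
#'   `list(profile =, n =, meta =)` entries.
#' @param irbd `NULL` or a list with `n`, `n_converters`,
#'   `converter_profile`, `nonconverter_profile`, optional `meta`, and
#'   `panel`.
#' @param seed master integer seed.
#' @return object of class `study_config`.
#' @export
study_config <- function(centers, irbd = NULL, seed = 1L) {
  for (cn in names(centers)) {
    stopifnot(inherits(centers[[cn]]$panel, "odor_panel"))
    for (g in centers[[cn]]$groups) {
      stopifnot(inherits(g$profile, "group_profile"), g$n >= 0)
    }
  }
  if (!is.null(irbd)) {
    stopifnot(irbd$n >= 0, irbd$n_converters >= 0, irbd$n_converters <= irbd$n,
              inherits(irbd$converter_profile, "group_profile"),
              inherits(irbd$nonconverter_profile, "group_profile"))
  }
  structure(list(centers = centers, irbd = irbd, seed = as.integer(seed)),
            class = "study_config")
}

#' Default synthetic study emulating the published three-center design
#'
#' Group sizes and sum-score calibration targets follow the published
#' cohort table: center A with 336 HC, 134 PD, 23 MSA, 23 PSP and 29 ET on
#' the 16-item test (HC 12.7 +/- 2.7, PD 6.8 +/- 3.1, ...), center B with
#' 150 HC and 400 PD, center C with 120 controls and 112 PD on the 12-item
#' test (10.3 +/- 1.9 vs 6.5 +/- 2.7), and a prospective iRBD arm of 24
#' subjects of whom 8 convert to PD. Converters use the PD olfaction
#' profile (hyposmia precedes conversion); non-converters are calibrated to
#' the published iRBD sum-score row (9.9 +/- 4.4). Ages, sexes and disease
#' durations are drawn from normal/Bernoulli approximations of the same
#' table and are metadata only.
#'
#' @param seed master seed.
#' @return a [study_config()].
#' @export
default_study_config <- function(seed = 1L) {
  p16 <- ss16_panel()
  p12 <- ss12_panel()
  n16 <- length(p16$odors)
  n12 <- length(p12$odors)
  prof <- function(m, s, np, g) calibrate_profile_cached(m, s, np, 0.25, group = g)
  centers <- list(
    A = list(panel = p16, groups = list(
      HC  = list(profile = prof(12.7, 2.7, n16, "HC"),  n = 336,
                 meta = list(age_mean = 68.8, age_sd = 8.3, female_pct = 53.6)),
      PD  = list(profile = prof(6.8, 3.1, n16, "PD"),   n = 134,
                 meta = list(age_mean = 68.0, age_sd = 8.8, female_pct = 37.3,
                             duration_mean = 6.2, duration_sd = 4.8)),
      MSA = list(profile = prof(11.7, 2.1, n16, "MSA"), n = 23,
                 meta = list(age_mean = 63.3, age_sd = 8.9, female_pct = 52.2,
                             duration_mean = 4.2, duration_sd = 3.2)),
      PSP = list(profile = prof(10.9, 2.6, n16, "PSP"), n = 23,
                 meta = list(age_mean = 67.2, age_sd = 6.2, female_pct = 30.4,
                             duration_mean = 3.1, duration_sd = 2.0)),
      ET  = list(profile = prof(12.6, 3.7, n16, "ET"),  n = 29,
                 meta = list(age_mean = 74.5, age_sd = 9.8, female_pct = 58.6,
                             duration_mean = 18.7, duration_sd = 18.0))
    )),
    B = list(panel = p16, groups = list(
      HC = list(profile = prof(12.6, 2.3, n16, "HC"), n = 150,
                meta = list(age_mean = 59.2, age_sd = 7.4, female_pct = 42.0)),
      PD = list(profile = prof(7.4, 3.0, n16, "PD"),  n = 400,
                meta = list(age_mean = 61.4, age_sd = 9.9, female_pct = 37.5,
                            duration_mean = 11.4, duration_sd = 6.3))
    )),
    C = list(panel = p12, groups = list(
      HC = list(profile = prof(10.3, 1.9, n12, "HC"), n = 120,
                meta = list(age_mean = 67.4, age_sd = 10.4, female_pct = 58.3)),
      PD = list(profile = prof(6.5, 2.7, n12, "PD"),  n = 112,
                meta = list(age_mean = 69.2, age_sd = 8.6, female_pct = 50.0,
                            duration_mean = 6.8, duration_sd = 5.4))
    ))
  )
  irbd <- list(
    n = 24, n_converters = 8, panel = p16,
    converter_profile = prof(6.8, 3.1, n16, "iRBD"),
    nonconverter_profile = prof(9.9, 4.4, n16, "iRBD"),
    meta = list(age_mean = 66.0, age_sd = 5.0, female_pct = 12.5)
  )
  study_config(centers, irbd, seed = seed)
}

#' Generate the synthetic study
#'
#' Produces one cohort per configured center plus the prospective iRBD
#' cohort. iRBD converters carry `followup_diagnosis = "PD"` and draw their
#' baseline responses from the converter (PD-like) profile; non-converters
#' carry `"none"`. Deterministic given the config's seed.
#'
#' @param config a [study_config()].
#' @return list with `centers` (named list of [odor_cohort()]) and `irbd`
#'   (an [odor_cohort()] or `NULL`).
#' @export
generate_study <- function(config) {
  stopifnot(inherits(config, "study_config"))
  k <- 0L
  centers <- list()
  for (cn in names(config$centers)) {
    spec <- config$centers[[cn]]
    parts <- list()
    for (gn in names(spec$groups)) {
      g <- spec$groups[[gn]]
      k <- k + 1L
      if (g$n == 0) next
      parts[[gn]] <- generate_group(g$profile, g$n, spec$panel,
                                    seed = child_seed(config$seed, k),
                                    center = cn, meta = g$meta,
                                    id_prefix = paste0(cn, "_", gn))
    }
    if (length(parts)) {
      centers[[cn]] <- do.call(bind_cohorts, unname(parts))
      centers[[cn]]$provenance <- sprintf("synthetic seed=%d center=%s",
                                          config$seed, cn)
    }
  }
  irbd <- NULL
  if (!is.null(config$irbd) && config$irbd$n > 0) {
    sp <- config$irbd
    k <- k + 1L
    conv <- generate_group(sp$converter_profile, sp$n_converters, sp$panel,
                           seed = child_seed(config$seed, k), center = "A",
                           meta = sp$meta, id_prefix = "A_iRBDc",
                           followup = "PD")
    k <- k + 1L
    nonc <- generate_group(sp$nonconverter_profile, sp$n - sp$n_converters,
                           sp$panel, seed = child_seed(config$seed, k),
                           center = "A", meta = sp$meta,
                           id_prefix = "A_iRBDn", followup = "none")
    irbd <- if (sp$n_converters == 0) nonc
            else if (sp$n_converters == sp$n) conv
            else bind_cohorts(conv, nonc)
    irbd$provenance <- sprintf("synthetic seed=%d irbd", config$seed)
  }
  list(centers = centers, irbd = irbd)
}
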