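#' Stratified discovery/validation split
#'
#' Randomly splits a cohort's PD and HC subjects into approximately equal
#' halves, stratified by group (per-group sizes differ by at most 1).
#' Differential-diagnosis groups (MSA, PSP, ET) go wholly to the
#' validation cohort: the odor-selection model is established on PD versus
#' HC only. Disjoint, exhaustive, and reproducible given the seed.
#'
#' @param cohort an [odor_cohort()] containing PD and HC records.
#' @param seed integer seed.
#' @return list with `discovery` and `validation` cohorts.
#' @export
split_discovery_validation <- function(cohort, seed) {
  stopifnot(inherits(cohort, "odor_cohort"))
  d <- cohort$data
  for (g in c("PD", "HC")) {
    if (!any(d$group == g)) {
      stop_sniffsel("sniffsel_value_error",
                    sprintf("cohort lacks required stratum: %s", g))
    }
  }
  disc_idx <- with_seed(seed, {
    unlist(lapply(c("PD", "HC"), function(g) {
      idx <- which(d$group == g)
      n_disc <- floor(length(idx) / 2) +
        (length(idx) %% 2 == 1 && stats::runif(1) < 0.5)
      sample(idx, n_disc)
    }))
  })
  val_idx <- setdiff(seq_len(nrow(d)), disc_idx)
  list(
    discovery = odor_cohort(d[sort(disc_idx), , drop = FALSE], cohort$panel,
                            provenance = paste(cohort$provenance, "discovery")),
    validation = odor_cohort(d[sort(val_idx), , drop = FALSE], cohort$panel,
                             provenance = paste(cohort$provenance, "validation"))
  )
}

#' AUC as a function of nested subset size
#'
#' For each k, scores every evaluation cohort on the k-odor prefix of the
#' entry order and computes the AUC with its DeLong interval; the k = panel
#' size row is by construction the full-test AUC. Per cohort it reports the
#' minimal adequate size — the smallest k whose AUC reaches the lower 95%
#' CI bound of that cohort's full-test AUC (`rule = "ci_lower"`, the
#' default) or whose own CI overlaps the full-test CI
#' (`rule = "ci_overlap"`) — and the optimal size, the smallest k
#' attaining the maximum AUC.
#'
#' The entry order must come from subjects disjoint from every evaluation
#' cohort; pass the discovery subject ids so the overlap can be asserted.
#'
#' @param order an [entry_order()] (or character vector of odor names).
#' @param cohorts named list of [odor_cohort()]s to evaluate.
#' @param case_group,control_groups group labels defining cases (default
#'   PD) and controls (default HC) within each cohort.
#' @param level confidence level.
#' @param discovery_ids subject ids used for selection; any overlap with an
#'   evaluation cohort raises a leakage error.
#' @param rule minimal-adequacy rule, `"ci_lower"` or `"ci_overlap"`.
#' @return object of class `subset_sweep`: data.frame `results`
#'   (cohort, k, auc, ci_lo, ci_hi) plus per-cohort `minimal_k`,
#'   `optimal_k`, `full_auc`, `full_ci`.
#' @export
auc_by_subset_size <- function(order, cohorts, case_group = "PD",
                               control_groups = "HC", level = 0.95,
                               discovery_ids = NULL,
                               rule = c("ci_lower", "ci_overlap")) {
  rule <- match.arg(rule)
  # never-entering items sit at the end of the order, so k = panel size
  # always reproduces the full-test subscore
  odors <- as.character(order)
  if (is.null(names(cohorts))) names(cohorts) <- paste0("cohort", seq_along(cohorts))
  rows <- list()
  minimal_k <- optimal_k <- full_auc <- stats::setNames(numeric(0), character(0))
  full_ci <- list()
  for (cn in names(cohorts)) {
    co <- cohorts[[cn]]
    if (!is.null(discovery_ids)) {
      leak <- intersect(discovery_ids, co$data$subject_id)
      if (length(leak)) {
        stop_sniffsel("sniffsel_leakage_error",
          sprintf("evaluation cohort '%s' shares %d subject(s) with the discovery set (e.g. %s)",
                  cn, length(leak), leak[1]))
      }
    }
    keep <- subset_groups(co, c(case_group, control_groups))
    labels <- as.integer(keep$data$group %in% case_group)
    ks <- seq_along(odors)
    res <- lapply(ks, function(k) {
      sc <- compute_subscore(keep, odors[seq_len(k)])
      rc <- roc_with_auc(sc, labels, level = level)
      data.frame(cohort = cn, k = k, auc = rc$auc,
                 ci_lo = rc$auc_ci[1], ci_hi = rc$auc_ci[2])
    })
    res <- do.call(rbind, res)
    rows[[cn]] <- res
    fa <- res[res$k == length(odors), ]
    full_auc[cn] <- fa$auc
    full_ci[[cn]] <- c(fa$ci_lo, fa$ci_hi)
    adequate <- if (rule == "ci_lower") res$auc >= fa$ci_lo
                else res$ci_hi >= fa$ci_lo
    minimal_k[cn] <- min(res$k[adequate])
    optimal_k[cn] <- min(res$k[res$auc >= max(res$auc) - 1e-12])
  }
  structure(list(results = do.call(rbind, c(rows, list(make.row.names = FALSE))),
                 odors = odors, minimal_k = minimal_k, optimal_k = optimal_k,
                 full_auc = full_auc, full_ci = full_ci,
                 level = level, rule = rule),
            class = "subset_sweep")
}

#' @export
print.subset_sweep <- function(x, ...) {
  cat(sprintf("Subset-size AUC sweep over %d odors (%s rule)\n",
              length(x$odors), x$rule))
  for (cn in names(x$minimal_k)) {
    cat(sprintf("  %-14s full AUC %.3f (%.3f-%.3f); minimal adequate k = %d, optimal k = %d\n",
                cn, x$full_auc[cn], x$full_ci[[cn]][1], x$full_ci[[cn]][2],
                x$minimal_k[cn], x$optimal_k[cn]))
  }
  invisible(x)
}

#' @export
plot.subset_sweep <- function(x, ...) {
  cohorts <- unique(x$results$cohort)
  old <- graphics::par(mfrow = c(1, length(cohorts)))
  on.exit(graphics::par(old))
  for (cn in cohorts) {
    r <- x$results[x$results$cohort == cn, ]
    graphics::plot(r$k, r$auc, type = "b", ylim = c(0.5, 1), pch = 16,
                   xlab = "number of odors", ylab = "AUC", main = cn, ...)
    graphics::arrows(r$k, r$ci_lo, r$k, r$ci_hi, angle = 90, code = 3,
                     length = 0.02, col = "grey40")
    graphics::abline(h = c(x$full_auc[cn], x$full_ci[[cn]]),
                     lty = c(1, 2, 2), col = "steelblue")
  }
  invisible(x)
}

#' Prospective evaluation in a follow-up cohort
#'
#' Applies an a-priori subscore cutoff to baseline responses of a cohort
#' with recorded follow-up diagnoses (the prodromal iRBD design): a
#' subject is test-positive when the baseline subscore is at or below the
#' cutoff, and the reference standard is incident PD at follow-up.
#'
#' @param cohort an [odor_cohort()]; every record must carry a
#'   `followup_diagnosis`.
#' @param subset odor names (or a panel subset label) defining the
#'   subscore.
#' @param cutoff fixed integer cutoff.
#' @param level confidence level.
#' @return a [diagnostic_summary()].
#' @export
evaluate_prospective <- function(cohort, subset, cutoff, level = 0.95) {
  stopifnot(inherits(cohort, "odor_cohort"))
  missing_fu <- is.na(cohort$data$followup_diagnosis)
  if (any(missing_fu)) {
    stop_sniffsel("sniffsel_value_error",
      sprintf("missing followup_diagnosis for subject(s): %s",
              paste(utils::head(cohort$data$subject_id[missing_fu], 5),
                    collapse = ", ")))
  }
  sc <- compute_subscore(cohort, subset)
  labels <- as.integer(cohort$data$followup_diagnosis == "PD")
  diagnostic_summary(confusion_at_cutoff(sc, labels, cutoff),
                     level = level, cutoff = cutoff)
}

# evaluation helper: summary of a subscore at a fixed cutoff for
# case_group vs control_groups inside one cohort
summarize_comparison <- function(cohort, subset, cutoff, case_group,
                                 control_groups, level) {
  keep <- subset_groups(cohort, c(case_group, control_groups))
  labels <- as.integer(keep$data$group %in% case_group)
  sc <- compute_subscore(keep, subset)
  diagnostic_summary(confusion_at_cutoff(sc, labels, cutoff),
                     level = level, cutoff = cutoff)
}

# drop patient records with disease duration above `max_years`; controls
# (no duration) are kept. Errors if a required stratum empties.
filter_duration <- function(cohort, max_years, required = "PD") {
  d <- cohort$data
  keep <- is.na(d$disease_duration_years) | d$disease_duration_years <= max_years
  out <- odor_cohort(d[keep, , drop = FALSE], cohort$panel,
                     provenance = paste0(cohort$provenance,
                                         " duration<=", max_years, "y"))
  for (g in required) {
    if (!any(out$data$group == g)) {
      stop_sniffsel("sniffsel_value_error",
        sprintf("duration filter (<= %g y) left no %s records", max_years, g))
    }
  }
  out
}

#' Run the full discovery/validation study
#'
#' Orchestrates the complete design on a synthetic (or externally loaded)
#' multi-center study:
#' \enumerate{
#'   \item split center A's PD and HC subjects into discovery and
#'     validation halves (mimic groups go wholly to validation);
#'   \item fit the L1 logistic path on the discovery responses and derive
#'     the odor entry order;
#'   \item sweep AUC by nested subset size in every validation cohort,
#'     versus controls and versus the pooled diagnostic mimics (DDs);
#'   \item fix Youden cutoffs on the discovery cohort only — for the full
#'     panel and for the 8-odor prefix — and apply them unchanged
#'     everywhere; the versus-DD comparison uses a configurable lower
#'     cutoff (`dd_cutoff_delta` below the primary one);
#'   \item repeat the accuracy analyses after excluding patients with more
#'     than `max_duration` years of disease duration;
#'   \item model PPV/NPV for named prevalence scenarios from the
#'     versus-DD accuracy;
#'   \item evaluate the fixed cutoffs prospectively in the iRBD cohort
#'     (incident PD as reference standard);
#'   \item if a center uses the 12-item panel whose odors are contained in
#'     the discovery panel, run a separate 12-item-restricted selection
#'     and sweep for it.
#' }
#' Cutoffs are computed exactly once; reruns with the same config and seed
#' are fully deterministic.
#'
#' @param config a [study_config()]; default [default_study_config()].
#' @param level confidence level throughout.
#' @param subset_size size of the reduced panel reported alongside the
#'   full test (default 8).
#' @param dd_cutoff_delta how far below the primary Youden cutoff the
#'   versus-DD cutoff sits (default 1; 0 disables the lowering).
#' @param scenarios named numeric vector of prevalence scenarios.
#' @param rule minimal-adequacy rule passed to [auc_by_subset_size()].
#' @param max_duration duration cap (years) for the early-disease
#'   reanalysis.
#' @return object of class `study_report`.
#' @export
run_full_study <- function(config = default_study_config(seed = 1L),
                           level = 0.95, subset_size = 8,
                           dd_cutoff_delta = 1,
                           scenarios = c(general_neurology = 0.918,
                                         movement_disorder_clinic = 0.690),
                           rule = c("ci_lower", "ci_overlap"),
                           max_duration = 3) {
  rule <- match.arg(rule)
  stopifnot(inherits(config, "study_config"))
  study <- generate_study(config)
  centers <- study$centers
  main <- names(centers)[1]
  cohort_a <- centers[[main]]
  panel <- cohort_a$panel

  sp <- split_discovery_validation(subset_groups(cohort_a, c("PD", "HC")),
                                   seed = child_seed(config$seed, 9001L))
  discovery <- sp$discovery
  validation_a <- odor_cohort(
    rbind(sp$validation$data,
          cohort_a$data[cohort_a$data$group %in% c("MSA", "PSP", "ET"), ,
                        drop = FALSE]),
    panel, provenance = paste(cohort_a$provenance, "validation"))
  disc_ids <- discovery$data$subject_id

  X <- response_matrix(discovery)
  y <- as.integer(discovery$data$group == "PD")
  fit <- lasso_path(X, y)
  order16 <- entry_order(fit)
  odors16 <- as.character(order16)[attr(order16, "entered")]
  reduced <- odors16[seq_len(min(subset_size, length(odors16)))]

  eval_cohorts <- c(list(validation_A = validation_a),
                    centers[setdiff(names(centers), main)])
  # sweep only cohorts on the same panel as discovery
  same_panel <- vapply(eval_cohorts, function(co)
    identical(co$panel$odors, panel$odors), logical(1))
  sweep_hc <- auc_by_subset_size(order16, eval_cohorts[same_panel],
                                 control_groups = "HC", level = level,
                                 discovery_ids = disc_ids, rule = rule)
  has_dd <- vapply(eval_cohorts, function(co)
    any(co$data$group %in% c("MSA", "PSP", "ET")), logical(1))
  sweep_dd <- if (any(has_dd & same_panel)) {
    auc_by_subset_size(order16, eval_cohorts[has_dd & same_panel],
                       control_groups = c("MSA", "PSP", "ET"), level = level,
                       discovery_ids = disc_ids, rule = rule)
  } else NULL

  # cutoffs: fixed once, on discovery only
  disc_labels <- as.integer(discovery$data$group == "PD")
  cut_full <- youden_cutoff(roc_with_auc(compute_subscore(discovery, panel$odors),
                                         disc_labels, level))$cutoff
  cut_red <- youden_cutoff(roc_with_auc(compute_subscore(discovery, reduced),
                                        disc_labels, level))$cutoff
  cutoffs <- list(full = cut_full, reduced = cut_red,
                  full_dd = cut_full - dd_cutoff_delta,
                  reduced_dd = cut_red - dd_cutoff_delta)

  subsets <- list(full = panel$odors, reduced = reduced)
  summaries <- list()
  for (cn in names(eval_cohorts)[same_panel]) {
    co <- eval_cohorts[[cn]]
    summaries[[cn]] <- list(
      vs_controls = lapply(subsets, function(s) {
        cut <- if (length(s) == length(panel$odors)) cut_full else cut_red
        summarize_comparison(co, s, cut, "PD", "HC", level)
      })
    )
    if (any(co$data$group %in% c("MSA", "PSP", "ET"))) {
      summaries[[cn]]$vs_dd <- lapply(subsets, function(s) {
        cut <- if (length(s) == length(panel$odors)) cutoffs$full_dd
               else cutoffs$reduced_dd
        summarize_comparison(co, s, cut, "PD", c("MSA", "PSP", "ET"), level)
      })
    }
  }

  # early-disease reanalysis on the main validation cohort
  duration_restricted <- tryCatch({
    co <- filter_duration(validation_a, max_duration)
    out <- list(vs_controls = lapply(subsets, function(s) {
      cut <- if (length(s) == length(panel$odors)) cut_full else cut_red
      summarize_comparison(co, s, cut, "PD", "HC", level)
    }))
    if (any(co$data$group %in% c("MSA", "PSP", "ET"))) {
      out$vs_dd <- lapply(subsets, function(s) {
        cut <- if (length(s) == length(panel$odors)) cutoffs$full_dd
               else cutoffs$reduced_dd
        summarize_comparison(co, s, cut, "PD", c("MSA", "PSP", "ET"), level)
      })
    }
    out
  }, sniffsel_value_error = function(e) e)

  # prevalence scenarios from the versus-DD accuracy in the main cohort
  scen_rows <- list()
  if (!is.null(summaries[[1]]$vs_dd)) {
    for (sub_nm in names(subsets)) {
      ds <- summaries[[1]]$vs_dd[[sub_nm]]
      if (length(ds$undefined) == 0 ||
          !any(c("sensitivity", "specificity") %in% ds$undefined)) {
        for (scn in names(scenarios)) {
          pv <- predictive_values_at_prevalence(ds$sensitivity$estimate,
                                                ds$specificity$estimate,
                                                scenarios[[scn]])
          scen_rows[[length(scen_rows) + 1]] <- data.frame(
            subset = sub_nm, scenario = scn, prevalence = scenarios[[scn]],
            sensitivity = ds$sensitivity$estimate,
            specificity = ds$specificity$estimate,
            ppv = pv[["ppv"]], npv = pv[["npv"]])
        }
      }
    }
  }
  scenario_table <- if (length(scen_rows)) do.call(rbind, scen_rows) else NULL

  irbd <- NULL
  if (!is.null(study$irbd) &&
      identical(study$irbd$panel$odors, panel$odors)) {
    irbd <- list(
      full = evaluate_prospective(study$irbd, panel$odors, cut_full, level),
      reduced = evaluate_prospective(study$irbd, reduced, cut_red, level)
    )
  }

  # separate selection for a 12-item center whose odors nest in the panel
  sub12 <- NULL
  small_centers <- names(eval_cohorts)[!same_panel]
  for (cn in small_centers) {
    co <- eval_cohorts[[cn]]
    if (all(co$panel$odors %in% panel$odors)) {
      X12 <- X[, co$panel$odors, drop = FALSE]
      fit12 <- lasso_path(X12, y)
      ord12 <- entry_order(fit12)
      sweep12 <- auc_by_subset_size(ord12, stats::setNames(list(co), cn),
                                    control_groups = "HC", level = level,
                                    discovery_ids = disc_ids, rule = rule)
      disc12 <- compute_subscore(discovery, co$panel$odors)
      cut12 <- youden_cutoff(roc_with_auc(disc12, disc_labels, level))$cutoff
      sub12 <- list(center = cn, order = ord12, sweep = sweep12,
                    cutoff = cut12,
                    summary = summarize_comparison(co, co$panel$odors, cut12,
                                                   "PD", "HC", level))
    }
  }

  structure(list(
    seed = config$seed, panel = panel, entry_order = order16,
    reduced_subset = reduced, cutoffs = cutoffs,
    discovery_n = nrow(discovery$data),
    sweep_vs_controls = sweep_hc, sweep_vs_dd = sweep_dd,
    summaries = summaries, duration_restricted = duration_restricted,
    scenario_table = scenario_table, irbd = irbd, panel12 = sub12,
    level = level
  ), class = "study_report")
}

#' @export
print.study_report <- function(x, ...) {
  cat(sprintf("Odor-panel optimization study (seed %d, %d-item panel)\n",
              x$seed, length(x$panel$odors)))
  cat(sprintf("  discovery n = %d; cutoffs: full <= %g, %d-odor <= %g (vs-DD: <= %g / <= %g)\n",
              x$discovery_n, x$cutoffs$full, length(x$reduced_subset),
              x$cutoffs$reduced, x$cutoffs$full_dd, x$cutoffs$reduced_dd))
  cat("  reduced subset:", paste(x$reduced_subset, collapse = ", "), "\n\n")
  print(x$sweep_vs_controls)
  if (!is.null(x$sweep_vs_dd)) print(x$sweep_vs_dd)
  for (cn in names(x$summaries)) {
    cat(sprintf("\n%s, full panel vs controls:\n", cn))
    print(x$summaries[[cn]]$vs_controls$full)
    cat(sprintf("%s, reduced panel vs controls:\n", cn))
    print(x$summaries[[cn]]$vs_controls$reduced)
  }
  if (!is.null(x$scenario_table)) {
    cat("\nPrevalence-modeled predictive values (vs-DD accuracy):\n")
    st <- x$scenario_table
    st$ppv <- round(100 * st$ppv, 1); st$npv <- round(100 * st$npv, 1)
    st$sensitivity <- round(100 * st$sensitivity, 1)
    st$specificity <- round(100 * st$specificity, 1)
    print(st, row.names = FALSE)
  }
  if (!is.null(x$irbd)) {
    cat("\nProspective iRBD evaluation, full panel:\n")
    print(x$irbd$full)
    cat("Prospective iRBD evaluation, reduced panel:\n")
    print(x$irbd$reduced)
  }
  invisible(x)
}
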