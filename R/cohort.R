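#' Cohort container
#'
#' A cohort couples an [odor_panel()] with one row per subject: identifying
#' metadata plus one binary response column per panel odor (1 = odor
#' correctly identified in the forced-choice test, so lower sum scores mean
#' worse olfaction). Construction validates the full schema; invalid data
#' never enters the pipeline.
#'
#' @param data data.frame with columns `subject_id`, `center`, `group`,
#'   `age`, `sex`, `disease_duration_years`, `followup_diagnosis` and one
#'   `odor_<name>` column per panel odor.
#' @param panel an [odor_panel()].
#' @param provenance free-text origin note (`"real"` or a synthetic
#'   seed/config tag).
#' @return object of class `odor_cohort` with elements `panel`, `data`,
#'   `provenance`.
#' @export
odor_cohort <- function(data, panel, provenance = "unspecified") {
  stopifnot(inherits(panel, "odor_panel"))
  data <- validate_cohort_data(data, panel)
  structure(list(panel = panel, data = data, provenance = provenance),
            class = "odor_cohort")
}

cohort_metadata_cols <- function() {
  c("subject_id", "center", "group", "age", "sex",
    "disease_duration_years", "followup_diagnosis")
}

cohort_groups <- function() c("HC", "PD", "MSA", "PSP", "ET", "iRBD")

odor_cols <- function(panel) paste0("odor_", panel$odors)

validate_cohort_data <- function(data, panel) {
  need <- c(cohort_metadata_cols(), odor_cols(panel))
  missing_cols <- setdiff(need, names(data))
  if (length(missing_cols)) {
    stop_sniffsel("sniffsel_schema_error",
      sprintf("cohort is missing column(s): %s", paste(missing_cols, collapse = ", ")))
  }
  data <- data[, need, drop = FALSE]
  data$subject_id <- as.character(data$subject_id)
  data$center <- as.character(data$center)
  data$group <- as.character(data$group)
  data$sex <- as.character(data$sex)
  data$followup_diagnosis <- as.character(data$followup_diagnosis)
  data$age <- as.numeric(data$age)
  data$disease_duration_years <- as.numeric(data$disease_duration_years)

  if (nrow(data) == 0) {
    rownames(data) <- NULL
    return(data)
  }
  if (anyDuplicated(data$subject_id)) {
    dup <- unique(data$subject_id[duplicated(data$subject_id)])
    stop_sniffsel("sniffsel_integrity_error",
      sprintf("duplicate subject_id(s): %s", paste(dup, collapse = ", ")))
  }
  bad_group <- setdiff(unique(data$group), cohort_groups())
  if (length(bad_group)) {
    stop_sniffsel("sniffsel_value_error",
      sprintf("unknown diagnostic group(s): %s (expected %s)",
              paste(bad_group, collapse = ", "),
              paste(cohort_groups(), collapse = "|")))
  }
  bad_sex <- setdiff(unique(stats::na.omit(data$sex)), c("F", "M"))
  if (length(bad_sex)) {
    stop_sniffsel("sniffsel_value_error",
      sprintf("sex must be F or M; found: %s", paste(bad_sex, collapse = ", ")))
  }
  if (anyNA(data$age) || any(data$age < 0)) {
    stop_sniffsel("sniffsel_value_error", "age must be present and non-negative")
  }
  # duration is required for manifest disease; controls and baseline
  # prodromal subjects may leave it empty
  needs_dur <- data$group %in% c("PD", "MSA", "PSP", "ET")
  if (any(needs_dur & is.na(data$disease_duration_years))) {
    bad <- data$subject_id[needs_dur & is.na(data$disease_duration_years)]
    stop_sniffsel("sniffsel_value_error",
      sprintf("disease_duration_years missing for patient record(s): %s",
              paste(utils::head(bad, 5), collapse = ", ")))
  }
  if (any(!is.na(data$disease_duration_years) & data$disease_duration_years < 0)) {
    stop_sniffsel("sniffsel_value_error", "disease_duration_years must be non-negative")
  }
  bad_fu <- setdiff(unique(stats::na.omit(data$followup_diagnosis)),
                    c("PD", "other", "none"))
  if (length(bad_fu)) {
    stop_sniffsel("sniffsel_value_error",
      sprintf("followup_diagnosis must be PD|other|none or empty; found: %s",
              paste(bad_fu, collapse = ", ")))
  }
  for (oc in odor_cols(panel)) {
    v <- data[[oc]]
    if (is.character(v)) v <- suppressWarnings(as.numeric(v))
    ok <- !is.na(v) & (v == 0 | v == 1)
    if (!all(ok)) {
      stop_sniffsel("sniffsel_value_error",
        sprintf("non-binary response in column %s at row(s) %s (responses are forced-choice and must be 0 or 1)",
                oc, paste(utils::head(which(!ok), 5), collapse = ", ")))
    }
    data[[oc]] <- as.integer(v)
  }
  rownames(data) <- NULL
  data
}

#' Read a cohort from CSV
#'
#' Expects the canonical schema: the seven metadata columns followed by one
#' `odor_<name>` column per panel odor; UTF-8, `"."` decimal separator,
#' empty string for missing. Row order is preserved.
#'
#' @param path CSV file path.
#' @param panel the [odor_panel()] the responses are aligned to.
#' @param provenance provenance note stored on the cohort (default
#'   `"real"`).
#' @return an [odor_cohort()].
#' @export
read_cohort <- function(path, panel, provenance = "real") {
  if (!file.exists(path)) {
    stop_sniffsel("sniffsel_io_error", sprintf("cohort file not found: %s", path))
  }
  raw <- utils::read.csv(path, colClasses = "character", check.names = FALSE,
                         na.strings = "", fileEncoding = "UTF-8")
  odor_cohort(raw, panel, provenance = provenance)
}

#' Write a cohort to CSV
#'
#' Columns are emitted in a deterministic order (metadata, then odors in
#' panel order) so that write/read round-trips reproduce the cohort exactly.
#'
#' @param cohort an [odor_cohort()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  stopifnot(inherits(cohort, "odor_cohort"))
  out <- cohort$data[, c(cohort_metadata_cols(), odor_cols(cohort$panel)),
                     drop = FALSE]
  num <- c("age", "disease_duration_years")
  for (cn in num) {
    out[[cn]] <- ifelse(is.na(out[[cn]]), NA,
                        formatC(out[[cn]], format = "g", digits = 15))
  }
  ok <- tryCatch({
    utils::write.csv(out, path, row.names = FALSE, na = "", quote = FALSE,
                     fileEncoding = "UTF-8")
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) {
    stop_sniffsel("sniffsel_io_error",
                  sprintf("cannot write cohort to %s: %s", path,
                          conditionMessage(ok)))
  }
  invisible(path)
}

#' Subscores over an odor subset
#'
#' The subscore of a subject over a set of odors is the number of those
#' odors correctly identified; over the full panel it is the usual test
#' sum score (e.g. the SS-16 sum). Subscores are monotone under subset
#' inclusion.
#'
#' @param cohort an [odor_cohort()].
#' @param subset character vector of odor names; every name must be on the
#'   cohort's panel. A subset label defined on the panel (e.g. `"SS-8"`) is
#'   also accepted.
#' @return integer vector of per-subject counts, in cohort row order.
#' @export
compute_subscore <- function(cohort, subset) {
  stopifnot(inherits(cohort, "odor_cohort"))
  if (length(subset) == 1 && subset %in% names(cohort$panel$subsets)) {
    subset <- cohort$panel$subsets[[subset]]
  }
  unknown <- setdiff(subset, cohort$panel$odors)
  if (length(unknown)) {
    stop_sniffsel("sniffsel_key_error",
      sprintf("odor(s) not on panel '%s': %s", cohort$panel$name,
              paste(unknown, collapse = ", ")))
  }
  cols <- paste0("odor_", subset)
  if (nrow(cohort$data) == 0) return(integer(0))
  as.integer(rowSums(cohort$data[, cols, drop = FALSE]))
}

# matrix of binary responses (subjects x odors), column order = panel order
response_matrix <- function(cohort) {
  m <- as.matrix(cohort$data[, odor_cols(cohort$panel), drop = FALSE])
  colnames(m) <- cohort$panel$odors
  m
}

# keep only rows of the listed groups, same panel/provenance
subset_groups <- function(cohort, groups) {
  odor_cohort(cohort$data[cohort$data$group %in% groups, , drop = FALSE],
              cohort$panel, provenance = cohort$provenance)
}

# bind rows of cohorts sharing a panel
bind_cohorts <- function(...) {
  xs <- list(...)
  panel <- xs[[1]]$panel
  for (x in xs) stopifnot(identical(x$panel$odors, panel$odors))
  odor_cohort(do.call(rbind, lapply(xs, `[[`, "data")), panel,
              provenance = xs[[1]]$provenance)
}

#' @export
print.odor_cohort <- function(x, ...) {
  cat(sprintf("Odor cohort on panel '%s': %d subjects (%s)\n",
              x$panel$name, nrow(x$data), x$provenance))
  if (nrow(x$data)) {
    tab <- table(x$data$group)
    cat("  groups:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  }
  invisible(x)
}
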