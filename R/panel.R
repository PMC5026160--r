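#' Odor panel definitions
#'
#' An odor panel describes an identification test: an ordered set of odor
#' names plus optional named subsets (e.g. the 8-odor screening subset of the
#' 16-item Sniffin' Sticks identification test). Panels are plain
#' configuration, shipped as editable YAML files under `inst/extdata`; only
#' the composition of the published 8-odor subset is treated as fixed
#' knowledge and validated against.
#'
#' @param name panel label, e.g. `"SS-16"`, `"SS-12"` or a custom label.
#' @param odors character vector of unique odor names, in administration
#'   order.
#' @param subsets named list of character vectors, each a subset of `odors`.
#' @return An object of class `odor_panel`.
#' @examples
#' p <- odor_panel("toy", c("rose", "coffee", "mint"),
#'                 subsets = list(pair = c("rose", "mint")))
#' p
#' @export
odor_panel <- function(name, odors, subsets = list()) {
  odors <- as.character(odors)
  if (anyDuplicated(odors)) {
    stop_sniffsel("sniffsel_value_error",
      sprintf("duplicate odor names in panel '%s': %s", name,
              paste(unique(odors[duplicated(odors)]), collapse = ", ")))
  }
  if (length(odors) == 0) {
    stop_sniffsel("sniffsel_value_error", "panel must contain at least one odor")
  }
  if (length(subsets) && (is.null(names(subsets)) || any(!nzchar(names(subsets))))) {
    stop_sniffsel("sniffsel_value_error", "all panel subsets must be named")
  }
  for (nm in names(subsets)) {
    extra <- setdiff(subsets[[nm]], odors)
    if (length(extra)) {
      stop_sniffsel("sniffsel_value_error",
        sprintf("subset '%s' contains odors not on the panel: %s",
                nm, paste(extra, collapse = ", ")))
    }
  }
  if (identical(name, "SS-16") && "SS-8" %in% names(subsets)) {
    if (!setequal(subsets[["SS-8"]], ss8_odors())) {
      stop_sniffsel("sniffsel_value_error",
        "the SS-8 subset of an SS-16 panel must be exactly the eight published screening odors")
    }
  }
  structure(list(name = name, odors = odors,
                 subsets = lapply(subsets, as.character)),
            class = "odor_panel")
}

#' The eight published screening odors
#'
#' The 8-odor subscore of the SS-16 (the "SS-8") consists of licorice, anise,
#' mint, cinnamon, banana, pineapple, rose and coffee.
#'
#' @return character vector of length 8.
#' @export
ss8_odors <- function() {
  c("licorice", "anise", "mint", "cinnamon",
    "banana", "pineapple", "rose", "coffee")
}

#' Read an odor panel from a YAML file
#'
#' Panel files contain `name`, `odors` (a list) and optionally `subsets`
#' (a map from subset label to odor list).
#'
#' @param path path to a YAML panel definition.
#' @return an [odor_panel()].
#' @export
read_panel <- function(path) {
  if (!file.exists(path)) {
    stop_sniffsel("sniffsel_io_error", sprintf("panel file not found: %s", path))
  }
  spec <- yaml::read_yaml(path)
  if (is.null(spec$name) || is.null(spec$odors)) {
    stop_sniffsel("sniffsel_schema_error",
                  "panel YAML must contain 'name' and 'odors'")
  }
  odor_panel(spec$name, unlist(spec$odors),
             subsets = lapply(spec$subsets %||% list(), unlist))
}

#' Built-in SS-16 and SS-12 identification panels
#'
#' Convenience loaders for the panel definitions shipped with the package.
#' The SS-16 file lists sixteen odors including the eight screening odors and
#' carries the `SS-8` subset; the SS-12 is the shorter commercial screening
#' variant, whose odors are a subset of the SS-16 here so that reduced-set
#' subscores can be derived from SS-16 response data.
#'
#' @return an [odor_panel()].
#' @export
ss16_panel <- function() {
  read_panel(system.file("extdata", "ss16.yaml", package = "sniffsel"))
}

#' @rdname ss16_panel
#' @export
ss12_panel <- function() {
  read_panel(system.file("extdata", "ss12.yaml", package = "sniffsel"))
}

#' @export
print.odor_panel <- function(x, ...) {
  cat(sprintf("Odor panel '%s' (%d odors)\n", x$name, length(x$odors)))
  cat("  odors:", paste(x$odors, collapse = ", "), "\n")
  for (nm in names(x$subsets)) {
    cat(sprintf("  subset %s: %s\n", nm, paste(x$subsets[[nm]], collapse = ", ")))
  }
  invisible(x)
}

#' @export
length.odor_panel <- function(x) length(x$odors)
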