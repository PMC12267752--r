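#' Functional ventilation-mode categories
#'
#' Raw ventilator-mode labels are consolidated into four functional
#' categories plus a sentinel for non-invasive or absent ventilation:
#' \describe{
#'   \item{CONTROLLED}{no patient-triggered breaths}
#'   \item{COMBINED}{assist-control modes allowing patient-triggered breaths
#'     besides mandatory breaths; later reassigned by spontaneous
#'     respiratory rate}
#'   \item{ASSISTED}{only patient-triggered breaths (e.g. pressure support)}
#'   \item{CPAP}{continuous positive airway pressure; reassigned to ASSISTED
#'     when delivered through an invasive airway}
#'   \item{NONINVASIVE_OR_NONE}{non-invasive ventilation or no ventilation}
#' }
#'
#' @return Character vector of the five category names.
#' @export
vs_categories <- function() {
  c("CONTROLLED", "COMBINED", "ASSISTED", "CPAP", "NONINVASIVE_OR_NONE")
}

#' Default per-center mode dialects
#'
#' Three mode-label dialects emulating the label inventories of different
#' ventilator parks / charting systems. Each dialect is a total map from a
#' center's raw mode labels to the functional categories of
#' [vs_categories()], and each ships combined and CPAP labels so that every
#' reassignment branch of the harmonization is exercised.
#'
#' @return Named list of three data.frames with columns `raw_label`,
#'   `category`.
#' @export
#' @examples
#' lapply(default_dialects(), head)
default_dialects <- function() {
  d1 <- data.frame(
    raw_label = c("VC-CMV", "PC-CMV", "PC-APRV", "PC-BIPAP", "PC-SIMV",
                  "VC-SIMV", "PC-AC", "SPN-CPAP/PS", "PS", "SPN-PPS",
                  "SPN-CPAP", "NIV", "O2-Therapy", "Standby"),
    category = c("CONTROLLED", "CONTROLLED", "CONTROLLED", "COMBINED",
                 "COMBINED", "COMBINED", "COMBINED", "ASSISTED", "ASSISTED",
                 "ASSISTED", "CPAP", "NONINVASIVE_OR_NONE",
                 "NONINVASIVE_OR_NONE", "NONINVASIVE_OR_NONE"),
    stringsAsFactors = FALSE
  )
  d2 <- data.frame(
    raw_label = c("CMV", "PCV+", "APRV", "CMV/ASSIST", "CMV/ASSIST/AutoFlow",
                  "SIMV", "SIMV/PSV", "MMV/PSV", "PSV/SBT", "PSV",
                  "CPAP", "CPAP/PPS", "NIV/PSV", "None"),
    category = c("CONTROLLED", "CONTROLLED", "CONTROLLED", "COMBINED",
                 "COMBINED", "COMBINED", "COMBINED", "COMBINED", "ASSISTED",
                 "ASSISTED", "CPAP", "CPAP", "NONINVASIVE_OR_NONE",
                 "NONINVASIVE_OR_NONE"),
    stringsAsFactors = FALSE
  )
  d3 <- data.frame(
    raw_label = c("VC", "PC", "PRVC", "Bi-Vente", "SIMV_ASB", "BIPAP_ASB",
                  "ASB", "PS_CPAP", "NAVA", "CPAP_mode", "CPAP_ASB",
                  "NIV_mode", "Geen", "Standby"),
    category = c("CONTROLLED", "CONTROLLED", "CONTROLLED", "COMBINED",
                 "COMBINED", "COMBINED", "ASSISTED", "ASSISTED", "ASSISTED",
                 "CPAP", "CPAP", "NONINVASIVE_OR_NONE", "NONINVASIVE_OR_NONE",
                 "NONINVASIVE_OR_NONE"),
    stringsAsFactors = FALSE
  )
  list(center_1 = d1, center_2 = d2, center_3 = d3)
}

validate_dialect <- function(dialect) {
  stopifnot(is.data.frame(dialect),
            all(c("raw_label", "category") %in% names(dialect)))
  if (anyDuplicated(dialect$raw_label))
    stop("dialect maps a raw label to more than one category")
  bad <- setdiff(unique(dialect$category), vs_categories())
  if (length(bad))
    stop("dialect contains unknown categories: ", paste(bad, collapse = ", "))
  invisible(dialect)
}

#' Map raw ventilator-mode labels to functional categories
#'
#' @param raw_label Character vector of raw mode labels.
#' @param dialect A dialect data.frame (`raw_label`, `category`), e.g. one
#'   element of [default_dialects()].
#' @param strict If `TRUE` (default) an unknown label raises an error of
#'   class `vs_unknown_mode_label`; if `FALSE`, unknown labels map to
#'   `NONINVASIVE_OR_NONE` with a warning.
#' @return Character vector of categories, same length as `raw_label`.
#' @export
#' @examples
#' d <- default_dialects()$center_1
#' map_raw_mode(c("VC-CMV", "PS"), d)
map_raw_mode <- function(raw_label, dialect, strict = TRUE) {
  validate_dialect(dialect)
  idx <- match(raw_label, dialect$raw_label)
  if (anyNA(idx)) {
    unknown <- unique(raw_label[is.na(idx)])
    if (strict) {
      stop(structure(
        class = c("vs_unknown_mode_label", "error", "condition"),
        list(message = paste0("unknown mode label(s): ",
                              paste(unknown, collapse = ", ")),
             call = sys.call(-1))))
    }
    warning("unknown mode label(s) mapped to NONINVASIVE_OR_NONE: ",
            paste(unknown, collapse = ", "))
  }
  out <- dialect$category[idx]
  out[is.na(idx)] <- "NONINVASIVE_OR_NONE"
  out
}

#' Read / write a mode dialect as CSV
#'
#' @param path File path of a CSV with columns `raw_label`, `category`.
#' @return `read_dialect()` returns the validated dialect data.frame.
#' @export
read_dialect <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_dialect(d)
}

#' @rdname read_dialect
#' @param dialect Dialect data.frame to write.
#' @export
write_dialect <- function(dialect, path) {
  validate_dialect(dialect)
  utils::write.csv(dialect, path, row.names = FALSE)
  invisible(path)
}
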