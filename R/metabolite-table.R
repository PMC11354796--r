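#' Metabolite concentration table
#'
#' Container for a patients-by-metabolites matrix of relative
#' concentrations (mM scale) quantified at a single timepoint (before or
#' after treatment). Concentrations must be strictly positive because the
#' downstream fold-change computation takes natural logs.
#'
#' @param values numeric matrix, patients in rows, metabolites in columns,
#'   all entries strictly positive.
#' @param patient_ids character vector of unique patient identifiers
#'   (defaults to `rownames(values)`).
#' @param metabolite_names character vector of unique metabolite names
#'   (defaults to `colnames(values)`).
#' @param timepoint `"before"` or `"after"`.
#'
#' @return An object of class `metabolite_table` with elements `values`
#'   (named matrix) and `timepoint`.
#' @export
metabolite_table <- function(values, patient_ids = rownames(values),
                             metabolite_names = colnames(values),
                             timepoint = c("before", "after")) {
  timepoint <- match.arg(timepoint)
  if (is.data.frame(values)) values <- as.matrix(values)
  if (!is.matrix(values) || !is.numeric(values)) {
    stop_input("'values' must be a numeric matrix")
  }
  if (is.null(patient_ids) || is.null(metabolite_names)) {
    stop_input("patient and metabolite identifiers are required")
  }
  patient_ids <- as.character(patient_ids)
  metabolite_names <- as.character(metabolite_names)
  if (length(patient_ids) != nrow(values)) {
    stop_input("length of 'patient_ids' does not match nrow(values)")
  }
  if (length(metabolite_names) != ncol(values)) {
    stop_input("length of 'metabolite_names' does not match ncol(values)")
  }
  if (anyDuplicated(patient_ids)) {
    stop_input("duplicate patient identifiers: ",
               paste(unique(patient_ids[duplicated(patient_ids)]),
                     collapse = ", "))
  }
  if (anyDuplicated(metabolite_names)) {
    stop_input("duplicate metabolite names: ",
               paste(unique(metabolite_names[duplicated(metabolite_names)]),
                     collapse = ", "))
  }
  dimnames(values) <- list(patient_ids, metabolite_names)
  check_positive_concentrations(values)
  structure(list(values = values, timepoint = timepoint),
            class = "metabolite_table")
}

check_positive_concentrations <- function(values) {
  bad <- which(!is.finite(values) | values <= 0, arr.ind = TRUE)
  if (nrow(bad)) {
    i <- bad[1L, 1L]; j <- bad[1L, 2L]
    stop_input("non-positive or non-finite concentration for patient '",
               rownames(values)[i], "', metabolite '", colnames(values)[j],
               "' (", format(values[i, j]), ")")
  }
  invisible(values)
}

#' @export
print.metabolite_table <- function(x, ...) {
  cat("<metabolite_table> ", nrow(x$values), " patients x ",
      ncol(x$values), " metabolites, timepoint = ", x$timepoint, "\n",
      sep = "")
  invisible(x)
}

#' Time-to-event outcome for one endpoint
#'
#' @param patient_ids unique patient identifiers.
#' @param time follow-up time in months, strictly positive.
#' @param event 0/1 event indicator (1 = relapse/progression for DFS,
#'   1 = death for OS).
#' @param endpoint `"DFS"` or `"OS"`.
#'
#' @return An object of class `survival_outcome` with fields `patient_id`,
#'   `time`, `event`, `endpoint`.
#' @export
survival_outcome <- function(patient_ids, time, event,
                             endpoint = c("DFS", "OS")) {
  endpoint <- match.arg(endpoint)
  patient_ids <- as.character(patient_ids)
  if (anyDuplicated(patient_ids)) stop_input("duplicate patient identifiers")
  n <- length(patient_ids)
  if (length(time) != n || length(event) != n) {
    stop_input("'time' and 'event' must match 'patient_ids' in length")
  }
  if (!is.numeric(time) || any(!is.finite(time)) || any(time <= 0)) {
    bad <- patient_ids[which(!is.finite(time) | time <= 0)[1L]]
    stop_input("non-positive follow-up time for patient '", bad, "'")
  }
  event <- as.numeric(event)
  if (any(!event %in% c(0, 1))) {
    stop_input("'event' must be coded 0/1")
  }
  structure(list(patient_id = patient_ids, time = as.numeric(time),
                 event = event, endpoint = endpoint),
            class = "survival_outcome")
}

#' @export
print.survival_outcome <- function(x, ...) {
  cat("<survival_outcome> ", x$endpoint, ": ", length(x$time),
      " patients, ", sum(x$event), " events\n", sep = "")
  invisible(x)
}

#' @export
as.data.frame.survival_outcome <- function(x, ...) {
  data.frame(patient_id = x$patient_id, time = x$time, event = x$event,
             stringsAsFactors = FALSE)
}

# align an outcome to a given patient id order; error if any id is missing
align_outcome <- function(outcome, patient_ids) {
  idx <- match(patient_ids, outcome$patient_id)
  if (anyNA(idx)) {
    stop_input("outcome is missing patients: ",
               paste(utils::head(patient_ids[is.na(idx)], 5), collapse = ", "))
  }
  survival_outcome(outcome$patient_id[idx], outcome$time[idx],
                   outcome$event[idx], outcome$endpoint)
}
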