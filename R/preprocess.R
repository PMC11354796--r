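#' Sum-normalize a metabolite table
#'
#' Divides every concentration by the per-patient total over all
#' metabolites, so each patient's profile sums to one. This removes
#' overall-intensity differences between samples (dilution, acquisition
#' scaling) before fold changes are computed.
#'
#' @param table a [metabolite_table()].
#' @return A `metabolite_table` whose rows each sum to 1.
#' @export
sum_normalize <- function(table) {
  if (!inherits(table, "metabolite_table")) {
    stop_input("'table' must be a metabolite_table")
  }
  v <- table$values
  check_positive_concentrations(v)
  v <- v / rowSums(v)
  metabolite_table(v, timepoint = table$timepoint)
}

is_sum_normalized <- function(table, tol = 1e-6) {
  all(abs(rowSums(table$values) - 1) < tol)
}

#' Paired log fold changes, after vs before treatment
#'
#' For every patient present at both timepoints, computes the natural-log
#' fold change of each metabolite's sum-normalized concentration:
#' `log_fc[i, m] = ln(after[i, m]) - ln(before[i, m])`. This equals the
#' log of the after/before concentration ratio, so ratio-then-log and
#' log-then-difference coincide; one canonical log-scale representation is
#' stored. Patients present at only one timepoint are dropped with a
#' warning (strictly paired analysis).
#'
#' @param before,after sum-normalized [metabolite_table()]s with the same
#'   metabolite set.
#' @return An object of class `fold_change_matrix` with element `log_fc`,
#'   a patients-by-metabolites numeric matrix.
#' @export
paired_log_fold_change <- function(before, after) {
  for (tb in list(before, after)) {
    if (!inherits(tb, "metabolite_table")) {
      stop_input("inputs must be metabolite_tables")
    }
    if (!is_sum_normalized(tb)) {
      stop_input("tables must be sum-normalized first (see sum_normalize)")
    }
  }
  mb <- colnames(before$values); ma <- colnames(after$values)
  if (!setequal(mb, ma)) {
    stop_input("metabolite sets differ between timepoints: ",
               paste(union(setdiff(mb, ma), setdiff(ma, mb)), collapse = ", "))
  }
  pb <- rownames(before$values); pa <- rownames(after$values)
  common <- intersect(pb, pa)
  if (length(common) < 2L) {
    stop_input("fewer than 2 patients present at both timepoints")
  }
  dropped <- c(setdiff(pb, pa), setdiff(pa, pb))
  if (length(dropped)) {
    warning(length(dropped), " patient(s) present at only one timepoint ",
            "dropped: ", paste(utils::head(dropped, 5), collapse = ", "),
            call. = FALSE)
  }
  b <- before$values[common, mb, drop = FALSE]
  a <- after$values[common, mb, drop = FALSE]
  fold_change_matrix(log(a) - log(b))
}

#' Fold-change matrix constructor
#'
#' @param log_fc numeric matrix of natural-log fold changes with patient
#'   rownames and metabolite colnames; all entries finite.
#' @return An object of class `fold_change_matrix`.
#' @export
fold_change_matrix <- function(log_fc) {
  if (is.data.frame(log_fc)) log_fc <- as.matrix(log_fc)
  if (!is.matrix(log_fc) || !is.numeric(log_fc)) {
    stop_input("'log_fc' must be a numeric matrix")
  }
  if (is.null(rownames(log_fc)) || is.null(colnames(log_fc))) {
    stop_input("'log_fc' needs patient rownames and metabolite colnames")
  }
  if (anyDuplicated(rownames(log_fc)) || anyDuplicated(colnames(log_fc))) {
    stop_input("duplicate patient or metabolite identifiers")
  }
  if (any(!is.finite(log_fc))) {
    bad <- which(!is.finite(log_fc), arr.ind = TRUE)[1L, ]
    stop_input("non-finite log fold change for patient '",
               rownames(log_fc)[bad[1L]], "', metabolite '",
               colnames(log_fc)[bad[2L]], "'")
  }
  structure(list(log_fc = log_fc), class = "fold_change_matrix")
}

#' @export
print.fold_change_matrix <- function(x, ...) {
  cat("<fold_change_matrix> ", nrow(x$log_fc), " patients x ",
      ncol(x$log_fc), " metabolites (natural-log scale)\n", sep = "")
  invisible(x)
}

#' Per-metabolite mean fold changes
#'
#' Summarizes a fold-change matrix per metabolite: the mean of the
#' per-patient after/before ratios (`exp(log_fc)`), the mean log fold
#' change, and the direction of change implied by the mean ratio.
#'
#' @param fc a [fold_change_matrix()].
#' @return A data frame with columns `metabolite`, `mean_ratio`,
#'   `mean_log_fc`, `direction` (`"increase"`, `"decrease"`,
#'   `"no change"`).
#' @export
mean_fold_changes <- function(fc) {
  m <- as_design(fc)
  if (!nrow(m) || !ncol(m)) stop_input("empty fold-change matrix")
  mean_ratio <- colMeans(exp(m))
  mean_log <- colMeans(m)
  dir <- ifelse(mean_ratio > 1, "increase",
                ifelse(mean_ratio < 1, "decrease", "no change"))
  data.frame(metabolite = colnames(m), mean_ratio = unname(mean_ratio),
             mean_log_fc = unname(mean_log), direction = unname(dir),
             stringsAsFactors = FALSE)
}
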