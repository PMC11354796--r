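#' Chi-square test on a contingency table
#'
#' Pearson chi-square test of independence. For 2x2 tables the Yates
#' continuity correction is applied by default, with each `|O - E|`
#' reduced by `min(0.5, |O - E|)` so the correction can never push the
#' statistic past zero; tables larger than 2x2 use the plain uncorrected
#' statistic. Expected counts come from the table margins,
#' `E_ij = row_i * col_j / N`.
#'
#' @param table matrix of non-negative integer counts (r x c), all row and
#'   column margins positive.
#' @param correction apply the clamped continuity correction for 2x2
#'   tables (ignored for larger tables).
#' @return An object of class `contingency_result`: `table`, `expected`,
#'   `statistic`, `df`, `p_value`, `method`.
#' @export
chi2_test <- function(table, correction = TRUE) {
  tab <- validate_counts(table)
  check_flag(correction, "correction")
  ht <- suppressWarnings(stats::chisq.test(tab, correct = correction))
  is2x2 <- all(dim(tab) == 2L)
  structure(list(table = tab, expected = ht$expected,
                 statistic = unname(ht$statistic),
                 df = unname(ht$parameter),
                 p_value = unname(ht$p.value),
                 method = if (is2x2 && correction) "chi2_corrected"
                          else "chi2"),
            class = "contingency_result")
}

#' Fisher's exact test on a 2x2 table
#'
#' Two-sided exact test: the p-value sums the hypergeometric probabilities
#' of all tables with the observed margins whose point probability does
#' not exceed that of the observed table.
#'
#' @param table 2x2 matrix of non-negative integer counts with positive
#'   margins.
#' @return An object of class `contingency_result` (`statistic` is the
#'   conditional odds-ratio estimate, `df` is `NA`).
#' @export
fisher_exact <- function(table) {
  tab <- validate_counts(table)
  if (!all(dim(tab) == 2L)) stop_input("Fisher's exact test needs a 2x2 table")
  ht <- stats::fisher.test(tab)
  N <- sum(tab)
  expected <- outer(rowSums(tab), colSums(tab)) / N
  structure(list(table = tab, expected = expected,
                 statistic = unname(ht$estimate),
                 df = NA_integer_,
                 p_value = unname(ht$p.value),
                 method = "fisher_exact"),
            class = "contingency_result")
}

validate_counts <- function(table) {
  if (is.data.frame(table)) table <- as.matrix(table)
  if (!is.matrix(table) || !is.numeric(table)) {
    stop_input("'table' must be a numeric matrix of counts")
  }
  if (any(!is.finite(table)) || any(table < 0)) {
    stop_input("counts must be non-negative and finite")
  }
  if (any(abs(table - round(table)) > 1e-8)) {
    stop_input("counts must be integers")
  }
  table <- round(table)
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    stop_input("all row and column margins must be positive")
  }
  if (sum(table) < 1) stop_input("empty table")
  table
}

#' @export
print.contingency_result <- function(x, ...) {
  cat("<contingency_result> method = ", x$method, "\n", sep = "")
  if (x$method != "fisher_exact") {
    cat("  chi-square = ", format(x$statistic, digits = 5), " on ",
        x$df, " df, ", sep = "")
  }
  cat("p = ", format(x$p_value, digits = 4), "\n", sep = "")
  invisible(x)
}

#' Cohort characteristics by risk stratum
#'
#' Builds a characteristics report in the standard clinical-table layout:
#' for every requested characteristic, counts and percentages overall and
#' within each risk group, plus an association p-value (continuity-
#' corrected chi-square for 2x2 cross-tabulations, plain chi-square for
#' larger ones). Percentages are computed on available (non-missing) data
#' only and rounded to one decimal.
#'
#' @param clinical data frame of per-patient characteristics.
#' @param risk factor of `low`/`high` labels aligned with `clinical` rows;
#'   both groups must be non-empty.
#' @param characteristics character vector of `clinical` column names to
#'   report (default: every column except `patient_id`).
#' @return Data frame with columns `characteristic`, `level`, `overall_n`,
#'   `overall_pct`, `low_n`, `low_pct`, `high_n`, `high_pct`, `p_value`
#'   (repeated down the levels of a characteristic; `NA` with a console
#'   note when only one level was observed).
#' @export
build_characteristics_table <- function(clinical, risk,
                                        characteristics = NULL) {
  if (!is.data.frame(clinical)) stop_input("'clinical' must be a data frame")
  if (length(risk) != nrow(clinical)) {
    stop_input("'risk' length does not match the clinical table")
  }
  risk <- factor(as.character(risk), levels = c("low", "high"))
  if (any(tabulate(risk, 2L) == 0L)) {
    stop_input("both risk groups must be non-empty")
  }
  characteristics <- characteristics %||%
    setdiff(names(clinical), "patient_id")
  missing <- setdiff(characteristics, names(clinical))
  if (length(missing)) {
    stop_input("unknown characteristic column(s): ",
               paste(missing, collapse = ", "))
  }
  pct <- function(x, n) round(100 * x / n, 1)
  rows <- lapply(characteristics, function(ch) {
    v <- clinical[[ch]]
    ok <- !is.na(v)
    tab <- table(factor(v[ok]), risk[ok])
    lv <- rownames(tab)
    p <- NA_real_
    if (length(lv) < 2L) {
      message("characteristic '", ch, "' has a single observed level; ",
              "p-value omitted")
    } else if (any(colSums(tab) == 0)) {
      message("characteristic '", ch, "' unobserved in one risk group; ",
              "p-value omitted")
    } else {
      p <- chi2_test(unclass(tab))$p_value
    }
    tot <- rowSums(tab)
    data.frame(characteristic = ch, level = lv,
               overall_n = as.integer(tot),
               overall_pct = pct(as.integer(tot), sum(tab)),
               low_n = as.integer(tab[, "low"]),
               low_pct = pct(as.integer(tab[, "low"]), sum(tab[, "low"])),
               high_n = as.integer(tab[, "high"]),
               high_pct = pct(as.integer(tab[, "high"]), sum(tab[, "high"])),
               p_value = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
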