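#' Metabolite-related survival score (MRSS)
#'
#' Per-patient linear risk score: the sum over selected metabolites of the
#' Cox-derived coefficient times the patient's natural-log fold change,
#' `score_i = sum_m beta_m * log_fc[i, m]`.
#'
#' @param fc a [fold_change_matrix()].
#' @param selected either the data frame returned by
#'   [select_significant()] or a named numeric vector of coefficients
#'   (metabolite -> beta). Must be non-empty.
#' @return Named numeric vector of scores (one per patient).
#' @export
compute_mrss <- function(fc, selected) {
  beta <- selection_coefficients(selected)
  m <- as_design(fc)
  missing <- setdiff(names(beta), colnames(m))
  if (length(missing)) {
    stop_input("selected metabolites absent from the fold-change matrix: ",
               paste(missing, collapse = ", "))
  }
  drop(m[, names(beta), drop = FALSE] %*% beta)
}

selection_coefficients <- function(selected) {
  if (is.data.frame(selected)) {
    if (!all(c("metabolite", "beta") %in% names(selected))) {
      stop_input("selection data frame needs 'metabolite' and 'beta' columns")
    }
    beta <- stats::setNames(selected$beta, selected$metabolite)
  } else if (is.numeric(selected) && !is.null(names(selected))) {
    beta <- selected
  } else {
    stop_input("'selected' must be a selection data frame or a named ",
               "numeric vector")
  }
  if (!length(beta)) stop_input("no selected metabolites")
  beta
}

#' Optimal survival cutpoint by maximally selected rank statistics
#'
#' Scans candidate cutpoints (midpoints between consecutive distinct
#' scores whose induced split leaves both groups within the given quantile
#' range) and, at each, computes the absolute standardized two-sample
#' log-rank statistic for `{score <= c}` vs `{score > c}`. Returns the
#' candidate maximizing the statistic; exact ties on the statistic go to
#' the smallest cutpoint. A Lausen-Schumacher-type approximation of the
#' adjusted p-value for the maximal statistic is reported for reference
#' but drives no decision.
#'
#' @param score finite numeric vector (>= 10 subjects).
#' @param outcome a [survival_outcome()] aligned with `score`.
#' @param quantile_range proportions `(lower, upper)` strictly inside
#'   (0, 1); each group must contain at least `lower` of the cohort.
#' @return An object of class `maxstat_cutpoint`: `cutpoint`,
#'   `max_statistic` (absolute standardized log-rank statistic),
#'   `candidates` (data frame of all admissible cutpoints and statistics),
#'   `quantile_range`, `adjusted_p`.
#' @export
maxstat_cutpoint <- function(score, outcome, quantile_range = c(0.10, 0.90)) {
  if (!inherits(outcome, "survival_outcome")) {
    stop_input("'outcome' must be a survival_outcome")
  }
  n <- length(score)
  if (n != length(outcome$time)) {
    stop_input("'score' length does not match the outcome")
  }
  if (n < 10L) stop_input("at least 10 subjects are required")
  if (any(!is.finite(score))) stop_input("scores must be finite")
  if (sum(outcome$event) < 1) stop_input("at least one event is required")
  q <- quantile_range
  if (length(q) != 2L || any(q <= 0) || any(q >= 1) || q[1L] >= q[2L]) {
    stop_input("'quantile_range' must be ordered and strictly inside (0,1)")
  }
  u <- sort(unique(score))
  if (length(u) < 2L) stop_input("all scores are identical")

  time <- outcome$time; event <- outcome$event
  et <- sort(unique(time[event == 1]))
  nt <- length(et)
  n_at <- vapply(et, function(t) sum(time >= t), numeric(1))
  d_at <- vapply(et, function(t) sum(time == t & event == 1), numeric(1))
  var_fac <- ifelse(n_at > 1, d_at * (n_at - d_at) / (n_at - 1), 0)
  # per-subject contributions: number of event times the subject is at
  # risk for, and (for events) the index of the subject's event time
  r_i <- findInterval(time, et)
  j_i <- ifelse(event == 1, match(time, et), NA_integer_)

  ord <- order(score)
  N1 <- numeric(nt); D1 <- numeric(nt)
  cuts <- stats <- nlows <- numeric(0)
  pos <- 1L
  for (k in seq_len(length(u) - 1L)) {
    while (pos <= n && score[ord[pos]] <= u[k]) {
      i <- ord[pos]
      if (r_i[i] >= 1L) N1[seq_len(r_i[i])] <- N1[seq_len(r_i[i])] + 1
      if (!is.na(j_i[i])) D1[j_i[i]] <- D1[j_i[i]] + 1
      pos <- pos + 1L
    }
    n_low <- pos - 1L
    prop <- n_low / n
    if (prop >= q[1L] && prop <= q[2L]) {
      p1 <- N1 / n_at
      O1 <- sum(D1)
      E1 <- sum(d_at * p1)
      V <- sum(var_fac * p1 * (1 - p1))
      z <- if (V > 0) (O1 - E1) / sqrt(V) else 0
      cuts <- c(cuts, (u[k] + u[k + 1L]) / 2)
      stats <- c(stats, abs(z))
      nlows <- c(nlows, n_low)
    }
  }
  if (!length(cuts)) {
    stop_input("no admissible cutpoints within the quantile range")
  }
  best <- which.max(stats)  # candidates ascend, so ties go to smallest c
  structure(list(
    cutpoint = cuts[best],
    max_statistic = stats[best],
    candidates = data.frame(cutpoint = cuts, n_low = nlows,
                            statistic = stats),
    quantile_range = q,
    adjusted_p = maxstat_adjusted_p(stats[best], q[1L], q[2L])
  ), class = "maxstat_cutpoint")
}

# improved-Bonferroni approximation for the null distribution of the
# maximally selected standardized statistic over the quantile band
maxstat_adjusted_p <- function(b, eps1, eps2) {
  if (!is.finite(b) || b <= 1) return(1)
  db <- stats::dnorm(b)
  p <- db * (b - 1 / b) * log((eps2 * (1 - eps1)) / (eps1 * (1 - eps2))) +
    4 * db / b
  min(max(p, 0), 1)
}

#' @export
print.maxstat_cutpoint <- function(x, ...) {
  cat("<maxstat_cutpoint> cutpoint = ", format(x$cutpoint, digits = 5),
      ", max |standardized log-rank| = ",
      format(x$max_statistic, digits = 5),
      " over ", nrow(x$candidates), " candidates\n",
      "adjusted p (Lausen-Schumacher approx., reference only) = ",
      format(x$adjusted_p, digits = 4), "\n", sep = "")
  invisible(x)
}

#' Dichotomize scores at a cutpoint
#'
#' @param score numeric vector of finite scores.
#' @param cutpoint single numeric value.
#' @return Factor with levels `low`/`high`; `high` iff
#'   `score > cutpoint` (a score exactly at the cutpoint is `low`).
#' @export
stratify <- function(score, cutpoint) {
  if (any(!is.finite(score))) stop_input("scores must be finite")
  check_number(cutpoint, "cutpoint")
  factor(ifelse(score > cutpoint, "high", "low"), levels = c("low", "high"))
}

#' Score, cutpoint and risk strata in one step
#'
#' Computes the MRSS from the selected coefficients, finds the maximally
#' selected rank cutpoint against the given endpoint, and labels patients
#' low/high risk.
#'
#' @inheritParams compute_mrss
#' @inheritParams maxstat_cutpoint
#' @return An object of class `mrss_result`: `patient_ids`, `score`,
#'   `coefficients_used`, `cutpoint`, `risk_label`, `max_statistic`,
#'   `candidate_range`, and the full `maxstat` object.
#' @export
mrss_stratify <- function(fc, selected, outcome,
                          quantile_range = c(0.10, 0.90)) {
  score <- compute_mrss(fc, selected)
  ms <- maxstat_cutpoint(score, align_outcome(outcome, names(score)),
                         quantile_range)
  structure(list(
    patient_ids = names(score),
    score = score,
    coefficients_used = selection_coefficients(selected),
    cutpoint = ms$cutpoint,
    risk_label = stats::setNames(stratify(score, ms$cutpoint), names(score)),
    max_statistic = ms$max_statistic,
    candidate_range = quantile_range,
    maxstat = ms
  ), class = "mrss_result")
}

#' @export
print.mrss_result <- function(x, ...) {
  tab <- table(x$risk_label)
  cat("<mrss_result> ", length(x$score), " patients scored on ",
      length(x$coefficients_used), " metabolites\n",
      "cutpoint = ", format(x$cutpoint, digits = 5),
      " -> ", tab[["low"]], " low / ", tab[["high"]], " high risk\n",
      sep = "")
  invisible(x)
}

#' Age/stage-adjusted prognostic Cox models
#'
#' Fits, for each endpoint, a Cox model with three binary covariates:
#' age below 50 years, disease stage III-IV, and MRSS high risk. This
#' quantifies the prognostic information the score adds beyond the two
#' classical factors.
#'
#' @param risk factor of `low`/`high` risk labels.
#' @param clinical data frame with columns `patient_id`, `age_group`
#'   (`"<50"` / `">=50"`) and `stage` (`"I"`..`"IV"`).
#' @param dfs,os [survival_outcome()]s for the two endpoints.
#' @param control passed to [fit_cox()].
#' @return List with `dfs` and `os` (`cox_fit`s) and `table`, a long-form
#'   data frame (`endpoint`, `factor`, `hr`, `ci_lower`, `ci_upper`, `p`).
#' @export
adjusted_models <- function(risk, clinical, dfs, os,
                            control = cox_control()) {
  need <- c("patient_id", "age_group", "stage")
  if (!all(need %in% names(clinical))) {
    stop_input("clinical table needs columns: ",
               paste(setdiff(need, names(clinical)), collapse = ", "))
  }
  if (length(risk) != nrow(clinical)) {
    stop_input("'risk' length does not match the clinical table")
  }
  design <- cbind(
    age_lt50 = as.numeric(clinical$age_group == "<50"),
    stage_iii_iv = as.numeric(clinical$stage %in%
                                c("III", "IV", "III-IV")),
    mrss_high = as.numeric(risk == "high")
  )
  rownames(design) <- clinical$patient_id
  fits <- lapply(list(DFS = dfs, OS = os), function(oc) {
    fit_cox(design, oc, control = control)
  })
  tab <- do.call(rbind, lapply(names(fits), function(ep) {
    ct <- cox_table(fits[[ep]])
    cbind(endpoint = ep, ct[, c("covariate", "hr", "ci_lower",
                                "ci_upper", "p")])
  }))
  names(tab)[names(tab) == "covariate"] <- "factor"
  list(dfs = fits$DFS, os = fits$OS, table = tab)
}

#' Stage-stratified survival analysis of the risk strata
#'
#' Reproduces the standard figure layout for a dichotomized risk score:
#' Kaplan-Meier curves for the four stage-by-risk groups and a two-group
#' log-rank test of low vs high risk within each stage stratum
#' (stages I-II vs III-IV).
#'
#' @param risk factor of `low`/`high` labels.
#' @param stage vector of stages (`"I"`..`"IV"`, or already collapsed
#'   `"I-II"`/`"III-IV"`).
#' @param outcome a [survival_outcome()].
#' @return List with `km` (named list of `km_curve`s for the non-empty
#'   stage-by-risk groups) and `logrank` (per-stage [logrank_test()]
#'   results, `NULL` where a stratum was skipped). Strata with fewer than
#'   two subjects in a risk group, or without events, are skipped with a
#'   warning.
#' @export
stage_stratified_km <- function(risk, stage, outcome) {
  if (!inherits(outcome, "survival_outcome")) {
    stop_input("'outcome' must be a survival_outcome")
  }
  n <- length(outcome$time)
  if (length(risk) != n || length(stage) != n) {
    stop_input("'risk' and 'stage' must match the outcome length")
  }
  sg <- ifelse(as.character(stage) %in% c("I", "II", "I-II"),
               "I-II", "III-IV")
  sg <- factor(sg, levels = c("I-II", "III-IV"))
  grp <- paste(sg, as.character(risk), sep = ".")
  km <- list()
  for (g in sort(unique(grp))) {
    sel <- grp == g
    km[[g]] <- km_one(outcome$time[sel], outcome$event[sel], label = g)
  }
  logrank <- list(`I-II` = NULL, `III-IV` = NULL)
  for (s in levels(sg)) {
    sel <- sg == s
    rl <- factor(as.character(risk)[sel], levels = c("low", "high"))
    if (!sum(sel)) {
      warning("stage stratum ", s, " is empty; skipped", call. = FALSE)
      next
    }
    if (min(tabulate(rl, 2L)) < 2L || sum(outcome$event[sel]) < 1) {
      warning("stage stratum ", s, " has a risk group with < 2 subjects ",
              "or no events; log-rank skipped", call. = FALSE)
      next
    }
    oc <- survival_outcome(outcome$patient_id[sel], outcome$time[sel],
                           outcome$event[sel], outcome$endpoint)
    logrank[[s]] <- logrank_test(oc, rl)
  }
  list(km = km, logrank = logrank, stage_group = sg)
}
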