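#' Variance inflation factors of a covariate matrix
#'
#' For each column j, `VIF_j = 1 / (1 - R2_j)` where `R2_j` is the
#' coefficient of determination of an ordinary least-squares regression
#' (with intercept) of column j on all remaining columns. VIF is a pure
#' design-matrix diagnostic: the outcome plays no role.
#'
#' @param design numeric matrix with column names, more rows than columns,
#'   no constant column. Binary covariates enter as 0/1 numeric columns.
#' @return Named numeric vector of VIFs. Perfect collinearity
#'   (`R2 >= 1 - 1e-12`) yields `Inf` rather than an error.
#' @export
compute_vif <- function(design) {
  X <- as_design(design)
  if (is.null(colnames(X))) stop_input("'design' needs column names")
  p <- ncol(X); n <- nrow(X)
  if (p < 2L) stop_input("VIF needs at least 2 columns")
  if (n <= p) stop_input("VIF needs more rows than columns")
  if (any(!is.finite(X))) stop_input("non-finite covariate values")
  tss <- colSums(scale(X, center = TRUE, scale = FALSE)^2)
  const <- which(tss <= n * 1e-24)
  if (length(const)) {
    stop_input("constant column(s): ", paste(colnames(X)[const],
                                             collapse = ", "))
  }
  vif <- numeric(p)
  for (j in seq_len(p)) {
    fit <- stats::lm.fit(cbind(`(Intercept)` = 1, X[, -j, drop = FALSE]),
                         X[, j])
    r2 <- 1 - sum(fit$residuals^2) / tss[j]
    vif[j] <- if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }
  stats::setNames(vif, colnames(X))
}

#' Recursive VIF-guided Cox modelling
#'
#' Resolves multicollinearity among metabolite fold-change covariates
#' before Cox modelling: the full design (metabolite log fold changes plus
#' forced clinical covariates) is scanned for variance inflation, the
#' metabolite with the highest VIF at or above the threshold is removed,
#' and the scan repeats until every remaining covariate has VIF below the
#' threshold. Forced covariates (e.g. HER-2 and hormonal receptor status)
#' participate in the VIF computation but are never eligible for removal.
#' The Cox model is fitted on the final design (optionally on every
#' intermediate design via `fit_each_cycle`; intermediate coefficients do
#' not affect the trace).
#'
#' Ties on the maximal VIF are broken deterministically by removing the
#' metabolite earliest in alphabetical order.
#'
#' @param fc a [fold_change_matrix()] (or numeric matrix) of metabolite
#'   covariates.
#' @param forced optional numeric matrix/data frame of clinical covariates
#'   that are never removed (rows aligned with `fc`).
#' @param outcome a [survival_outcome()].
#' @param threshold VIF threshold (> 1); the default 3 removes any
#'   metabolite whose VIF reaches 3.
#' @param fit_each_cycle if `TRUE`, a Cox fit is also recorded at every
#'   recursion cycle.
#' @param control passed to [fit_cox()].
#' @return A list with `fit` (the final [fit_cox()] result, whose
#'   `metabolite_covariates` records the surviving metabolites) and
#'   `trace` (class `vif_trace`): per-cycle VIF maps and removals, the
#'   surviving covariates, and the threshold.
#' @export
recursive_vif_cox <- function(fc, forced = NULL, outcome, threshold = 3,
                              fit_each_cycle = FALSE,
                              control = cox_control()) {
  check_number(threshold, "threshold", 1, strict_lower = TRUE)
  M <- as_design(fc)
  if (is.null(colnames(M))) stop_input("metabolite columns need names")
  Fo <- NULL
  if (!is.null(forced)) {
    Fo <- as_design(forced)
    if (is.null(colnames(Fo))) stop_input("forced columns need names")
    if (nrow(Fo) != nrow(M)) stop_input("'forced' rows do not match 'fc'")
    clash <- intersect(colnames(Fo), colnames(M))
    if (length(clash)) {
      stop_input("covariate names shared between metabolites and forced ",
                 "columns: ", paste(clash, collapse = ", "))
    }
  }
  keep <- colnames(M)
  iterations <- list()
  cycle_fits <- if (fit_each_cycle) list() else NULL
  repeat {
    if (!length(keep)) {
      stop_input("threshold eliminates every covariate")
    }
    design <- cbind(M[, keep, drop = FALSE], Fo)
    vif <- compute_vif(design)
    vmet <- vif[keep]
    worst <- max(vmet)
    removed <- NA_character_
    if (worst >= threshold) {
      cand <- names(vmet)[vmet == worst]
      removed <- sort(cand)[1L]
    }
    if (fit_each_cycle) {
      cycle_fits[[length(cycle_fits) + 1L]] <-
        fit_cox(design, outcome, metabolite_covariates = keep,
                control = control)
    }
    iterations[[length(iterations) + 1L]] <-
      list(vif = vif, removed = removed)
    if (is.na(removed)) break
    message("VIF recursion cycle ", length(iterations), ": removed '",
            removed, "' (VIF = ", format(worst, digits = 4), ")")
    keep <- setdiff(keep, removed)
  }
  design <- cbind(M[, keep, drop = FALSE], Fo)
  fit <- fit_cox(design, outcome, metabolite_covariates = keep,
                 control = control)
  trace <- structure(list(iterations = iterations,
                          surviving_covariates = colnames(design),
                          surviving_metabolites = keep,
                          threshold = threshold,
                          n_removed = length(iterations) - 1L,
                          cycle_fits = cycle_fits),
                     class = "vif_trace")
  list(fit = fit, trace = trace)
}

#' @export
print.vif_trace <- function(x, ...) {
  removed <- vapply(x$iterations, function(it) it$removed, character(1))
  removed <- removed[!is.na(removed)]
  cat("<vif_trace> threshold ", x$threshold, ": ", length(removed),
      " recursion cycle(s), ", length(x$surviving_metabolites),
      " metabolites retained\n", sep = "")
  if (length(removed)) {
    cat("removed:", paste(removed, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Flatten a VIF trace to a per-cycle table
#'
#' @param trace a `vif_trace`.
#' @return Data frame with columns `iteration`, `covariate`, `vif`,
#'   `removed_flag`.
#' @export
vif_trace_table <- function(trace) {
  stopifnot(inherits(trace, "vif_trace"))
  do.call(rbind, lapply(seq_along(trace$iterations), function(i) {
    it <- trace$iterations[[i]]
    data.frame(iteration = i, covariate = names(it$vif),
               vif = unname(it$vif),
               removed_flag = !is.na(it$removed) &
                 names(it$vif) == it$removed,
               stringsAsFactors = FALSE)
  }))
}

#' Select metabolites significantly associated with the outcome
#'
#' Filters the metabolite covariates of a converged Cox fit to those with
#' a two-sided Wald p-value below `alpha` (default 0.10, a deliberately
#' permissive screening threshold for score construction). Forced clinical
#' covariates are never selected.
#'
#' @param fit a `cox_fit` from [fit_cox()] or [recursive_vif_cox()].
#' @param alpha selection threshold in (0, 1).
#' @return Data frame (possibly empty) with columns `metabolite`, `beta`,
#'   `hr`, `p`.
#' @export
select_significant <- function(fit, alpha = 0.10) {
  stopifnot(inherits(fit, "cox_fit"))
  check_number(alpha, "alpha", 0, 1, strict_lower = TRUE)
  if (!fit$converged) {
    stop_input("selection requires a converged Cox fit")
  }
  mets <- fit$metabolite_covariates %||% fit$covariates
  sel <- mets[fit$wald_p[mets] < alpha]
  data.frame(metabolite = sel, beta = unname(fit$beta[sel]),
             hr = unname(fit$hr[sel]), p = unname(fit$wald_p[sel]),
             stringsAsFactors = FALSE)
}
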