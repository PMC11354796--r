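#' Cox model fitting control
#'
#' @param eps convergence tolerance on the change in log partial
#'   likelihood between Newton-Raphson iterations.
#' @param max_iter maximum Newton-Raphson iterations.
#' @param beta_bound absolute coefficient bound beyond which a monotone
#'   (divergent) likelihood is flagged.
#' @return A list of control parameters.
#' @export
cox_control <- function(eps = 1e-9, max_iter = 100L, beta_bound = 20) {
  list(eps = check_number(eps, "eps", 0, strict_lower = TRUE),
       max_iter = as.integer(check_number(max_iter, "max_iter", 1)),
       beta_bound = check_number(beta_bound, "beta_bound", 0,
                                 strict_lower = TRUE))
}

# log partial likelihood, score and observed information under the Efron
# tie approximation. Rows of X must already be sorted by ascending time.
# Returns list(ll, U, I). Centering of eta is a numerical guard only; the
# partial likelihood is invariant to it.
efron_derivs <- function(beta, X, time, event) {
  n <- nrow(X); p <- ncol(X)
  eta <- drop(X %*% beta)
  eta <- eta - mean(eta)
  w <- exp(eta)
  ll <- 0; U <- numeric(p); I <- matrix(0, p, p)
  S0 <- 0; S1 <- numeric(p); S2 <- matrix(0, p, p)
  i <- n
  while (i >= 1L) {
    t_i <- time[i]
    j <- i
    while (j >= 1L && time[j] == t_i) j <- j - 1L
    block <- (j + 1L):i
    for (k in block) {
      xk <- X[k, ]
      S0 <- S0 + w[k]
      S1 <- S1 + w[k] * xk
      S2 <- S2 + w[k] * tcrossprod(xk)
    }
    dset <- block[event[block] == 1]
    dn <- length(dset)
    if (dn > 0L) {
      wd <- w[dset]
      Xd <- X[dset, , drop = FALSE]
      Sd0 <- sum(wd)
      Sd1 <- colSums(Xd * wd)
      Sd2 <- crossprod(Xd * wd, Xd)
      ll <- ll + sum(eta[dset])
      U <- U + colSums(Xd)
      for (l in seq_len(dn) - 1L) {
        f <- l / dn
        A <- S0 - f * Sd0
        Z <- S1 - f * Sd1
        ll <- ll - log(A)
        U <- U - Z / A
        I <- I + (S2 - f * Sd2) / A - tcrossprod(Z / A)
      }
    }
    i <- j
  }
  list(ll = ll, U = U, I = I)
}

# score test of H0: beta = 0 (used internally; equals the log-rank test
# for a single binary covariate without ties)
cox_score_test <- function(X, time, event) {
  ord <- order(time)
  d <- efron_derivs(numeric(ncol(X)), X[ord, , drop = FALSE],
                    time[ord], event[ord])
  stat <- drop(crossprod(d$U, solve(d$I, d$U)))
  list(statistic = stat,
       p_value = stats::pchisq(stat, df = ncol(X), lower.tail = FALSE))
}

#' Fit a Cox proportional hazards model
#'
#' Maximizes the Cox partial likelihood with the Efron tie approximation
#' by Newton-Raphson with step-halving, starting from zero. Convergence is
#' declared when the change in log partial likelihood falls below
#' `control$eps`. Standard errors come from the inverse observed
#' information at the optimum; hazard ratios, 95% Wald confidence
#' intervals and two-sided Wald p-values are deterministic transforms of
#' the coefficients and standard errors.
#'
#' A diverging coefficient (monotone likelihood / separation) is flagged
#' via `converged = FALSE` and `monotone = TRUE` rather than returned
#' silently; a rank-deficient design is an error naming the collinear
#' columns.
#'
#' @param x covariates: a [fold_change_matrix()] or a numeric matrix with
#'   column names (and, if available, patient rownames used to align rows
#'   with `outcome`).
#' @param outcome a [survival_outcome()].
#' @param metabolite_covariates optional character vector marking which
#'   columns are metabolites (eligible for data-driven selection, see
#'   [select_significant()]); `NULL` means all columns.
#' @param control see [cox_control()].
#'
#' @return An object of class `cox_fit` with elements `covariates`,
#'   `beta`, `se`, `hr`, `ci_lower`, `ci_upper`, `wald_z`, `wald_p`,
#'   `loglik`, `loglik_null`, `n_iter`, `converged`, `monotone`, `n`,
#'   `n_events`, `metabolite_covariates`.
#' @export
fit_cox <- function(x, outcome, metabolite_covariates = NULL,
                    control = cox_control()) {
  X <- as_design(x)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  if (!inherits(outcome, "survival_outcome")) {
    stop_input("'outcome' must be a survival_outcome")
  }
  if (!is.null(rownames(X))) {
    outcome <- align_outcome(outcome, rownames(X))
  } else if (nrow(X) != length(outcome$time)) {
    stop_input("covariate rows do not match the outcome")
  }
  time <- outcome$time; event <- outcome$event
  n <- nrow(X); p <- ncol(X)
  if (sum(event) < 1) stop_input("at least one event is required")
  if (any(!is.finite(X))) stop_input("non-finite covariate values")

  # rank check on the centered design; names the offending columns
  Xc <- scale(X, center = TRUE, scale = FALSE)
  qd <- qr(Xc, tol = 1e-9)
  if (qd$rank < p) {
    bad <- colnames(X)[qd$pivot[(qd$rank + 1L):p]]
    stop_input("design is rank deficient (constant or collinear columns): ",
               paste(bad, collapse = ", "))
  }

  ord <- order(time)
  Xs <- X[ord, , drop = FALSE]
  ts <- time[ord]; ev <- event[ord]

  beta <- numeric(p)
  d <- efron_derivs(beta, Xs, ts, ev)
  ll_null <- d$ll
  ll <- d$ll
  converged <- FALSE
  monotone <- FALSE
  iter <- 0L
  while (iter < control$max_iter) {
    iter <- iter + 1L
    step <- tryCatch(solve(d$I, d$U), error = function(e) NULL)
    if (is.null(step)) { monotone <- TRUE; break }
    s <- 1
    repeat {
      cand <- beta + s * step
      dc <- efron_derivs(cand, Xs, ts, ev)
      if (dc$ll >= ll - 1e-12 || s < 1e-8) break
      s <- s / 2
    }
    delta <- dc$ll - ll
    beta <- cand; d <- dc; ll <- dc$ll
    if (abs(delta) < control$eps) { converged <- TRUE; break }
  }
  grad_norm <- sqrt(sum(d$U^2))
  if (max(abs(beta)) > control$beta_bound && grad_norm > 1e-10) {
    monotone <- TRUE
  }
  if (monotone) {
    converged <- FALSE
    warning("monotone likelihood suspected: a coefficient is diverging",
            call. = FALSE)
  }

  vcov <- tryCatch(solve(d$I), error = function(e) matrix(NA_real_, p, p))
  se <- sqrt(diag(vcov))
  z <- beta / se
  structure(list(
    covariates = colnames(X),
    beta = stats::setNames(beta, colnames(X)),
    se = stats::setNames(se, colnames(X)),
    hr = stats::setNames(exp(beta), colnames(X)),
    ci_lower = stats::setNames(exp(beta - 1.96 * se), colnames(X)),
    ci_upper = stats::setNames(exp(beta + 1.96 * se), colnames(X)),
    wald_z = stats::setNames(z, colnames(X)),
    wald_p = stats::setNames(2 * stats::pnorm(-abs(z)), colnames(X)),
    loglik = ll, loglik_null = ll_null,
    n_iter = iter, converged = converged, monotone = monotone,
    n = n, n_events = sum(event),
    metabolite_covariates = metabolite_covariates,
    vcov = vcov
  ), class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, digits = 3, ...) {
  cat("<cox_fit> n = ", x$n, ", events = ", x$n_events,
      ", loglik = ", format(x$loglik, digits = 6),
      if (!x$converged) " [NOT CONVERGED]", "\n", sep = "")
  tab <- data.frame(beta = x$beta, se = x$se, HR = x$hr,
                    lower95 = x$ci_lower, upper95 = x$ci_upper,
                    p = x$wald_p)
  print(round(tab, digits), ...)
  invisible(x)
}

#' Tidy coefficient table of a Cox fit
#'
#' @param fit a `cox_fit`.
#' @return A data frame with one row per covariate: `covariate`, `beta`,
#'   `se`, `hr`, `ci_lower`, `ci_upper`, `p`.
#' @export
cox_table <- function(fit) {
  stopifnot(inherits(fit, "cox_fit"))
  data.frame(covariate = fit$covariates, beta = unname(fit$beta),
             se = unname(fit$se), hr = unname(fit$hr),
             ci_lower = unname(fit$ci_lower), ci_upper = unname(fit$ci_upper),
             p = unname(fit$wald_p), stringsAsFactors = FALSE)
}
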