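# Independent reference implementations used as oracles. These are coded
# as directly as possible from the definitions (explicit loops, stats::lm,
# survival::survdiff) and share no code with the package internals.

# Efron-approximation log partial likelihood, straight from the definition
naive_efron_loglik <- function(beta, X, time, event) {
  eta <- drop(X %*% beta)
  ll <- 0
  for (t in sort(unique(time[event == 1]))) {
    D <- which(time == t & event == 1)
    R <- which(time >= t)
    d <- length(D)
    ll <- ll + sum(eta[D])
    for (l in seq_len(d) - 1) {
      ll <- ll - log(sum(exp(eta[R])) - (l / d) * sum(exp(eta[D])))
    }
  }
  ll
}

# generic numerical maximization of the naive likelihood
maximize_efron <- function(X, time, event) {
  opt <- stats::optim(rep(0, ncol(X)),
                      function(b) -naive_efron_loglik(b, X, time, event),
                      method = "BFGS",
                      control = list(maxit = 1000, reltol = 1e-14))
  opt$par
}

# small random survival datasets, optionally with heavy ties
rand_surv_data <- function(n, p, seed, tie = TRUE) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p)
  colnames(X) <- paste0("x", seq_len(p))
  rownames(X) <- paste0("p", seq_len(n))
  time <- if (tie) sample(1:4, n, replace = TRUE) else round(rexp(n), 6)
  event <- rbinom(n, 1, 0.7)
  if (sum(event) == 0) event[which.min(time)] <- 1
  list(X = X,
       outcome = metabosurv::survival_outcome(rownames(X), time, event,
                                              "DFS"))
}

# per-column VIF via stats::lm
naive_vif <- function(X) {
  v <- vapply(seq_len(ncol(X)), function(j) {
    df <- data.frame(y = X[, j], X[, -j, drop = FALSE])
    1 / (1 - summary(stats::lm(y ~ ., data = df))$r.squared)
  }, numeric(1))
  stats::setNames(v, colnames(X))
}

# naive recursion: recompute every OLS from scratch each cycle
naive_vif_recursion <- function(M, forced, threshold) {
  keep <- colnames(M)
  removed <- character(0)
  repeat {
    X <- cbind(M[, keep, drop = FALSE], forced)
    v <- naive_vif(X)[keep]
    if (max(v) < threshold) break
    worst <- sort(names(v)[v == max(v)])[1L]
    removed <- c(removed, worst)
    keep <- setdiff(keep, worst)
    if (!length(keep)) stop("all metabolites removed")
  }
  list(removed = removed, surviving = keep)
}

# exhaustive maxstat scan, log-rank statistic from survival::survdiff
brute_maxstat <- function(score, time, event, qr = c(0.1, 0.9)) {
  u <- sort(unique(score))
  best <- NULL
  for (k in seq_len(length(u) - 1L)) {
    cut <- (u[k] + u[k + 1L]) / 2
    low <- factor(score <= cut, levels = c(TRUE, FALSE))
    prop <- mean(score <= cut)
    if (prop < qr[1L] || prop > qr[2L]) next
    sd <- survival::survdiff(survival::Surv(time, event) ~ low, rho = 0)
    stat <- sqrt(sd$chisq)
    if (is.null(best) || stat > best$stat + 1e-12) {
      best <- list(cut = cut, stat = stat)
    }
  }
  best
}

# random correlated design for the VIF oracle tests
rand_correlated_design <- function(n, p, seed) {
  set.seed(seed)
  q <- sample(1:2, 1)
  L <- matrix(rbinom(p * q, 1, 0.4) * runif(p * q, 0.5, 1.5), p, q)
  X <- matrix(rnorm(n * q), n, q) %*% t(L) + matrix(rnorm(n * p), n, p)
  colnames(X) <- paste0("m", seq_len(p))
  rownames(X) <- paste0("p", seq_len(n))
  X
}

fc_of <- function(cohort) {
  metabosurv::paired_log_fold_change(
    metabosurv::sum_normalize(cohort$before),
    metabosurv::sum_normalize(cohort$after))
}
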