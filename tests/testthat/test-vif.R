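# centered orthonormal basis: columns have mean zero and exact unit norms
orthobasis <- function(n, k, seed) {
  set.seed(seed)
  Z <- scale(matrix(rnorm(n * k), n, k), center = TRUE, scale = FALSE)
  qr.Q(qr(Z))
}

test_that("VIF closed forms: orthogonal, correlated pair, perfect collinearity", {
  Q <- orthobasis(24, 3, seed = 5)
  X <- Q
  colnames(X) <- c("a", "b", "c")
  expect_equal(unname(compute_vif(X)), rep(1, 3), tolerance = 1e-10)

  # sample correlation of (x1, x2) exactly 0.9, x3 orthogonal to both
  X2 <- cbind(a = Q[, 1], b = 0.9 * Q[, 1] + sqrt(1 - 0.81) * Q[, 2],
              c = Q[, 3])
  v <- compute_vif(X2)
  expect_equal(unname(v["a"]), 1 / (1 - 0.81), tolerance = 1e-10)
  expect_equal(unname(v["b"]), 1 / (1 - 0.81), tolerance = 1e-10)
  expect_equal(unname(v["c"]), 1, tolerance = 1e-10)

  X3 <- cbind(a = Q[, 1], b = Q[, 2], c = Q[, 1] + Q[, 2])
  expect_true(all(is.infinite(compute_vif(X3))))

  X4 <- cbind(a = Q[, 1], b = rep(2, 24))
  expect_error(compute_vif(X4), "constant column")
})

test_that("VIF matches the lm-based reference on random designs", {
  for (s in 1:20) {
    X <- rand_correlated_design(n = sample(20:50, 1), p = sample(4:8, 1),
                                seed = 500 + s)
    expect_equal(compute_vif(X), naive_vif(X), tolerance = 1e-8)
  }
})

test_that("recursive elimination matches naive per-cycle recomputation", {
  for (s in 1:40) {
    n <- sample(25:50, 1)
    p <- sample(4:10, 1)
    M <- rand_correlated_design(n, p, seed = 700 + s)
    set.seed(9000 + s)
    forced <- cbind(her2 = rbinom(n, 1, 0.4),
                    hormonal_receptor = rbinom(n, 1, 0.7))
    rownames(forced) <- rownames(M)
    threshold <- sample(c(1.5, 2, 3, 5), 1)
    time <- sample(1:10, n, replace = TRUE)
    event <- rbinom(n, 1, 0.7); if (!sum(event)) event[1] <- 1
    oc <- survival_outcome(rownames(M), time, event, "DFS")

    ref <- tryCatch(naive_vif_recursion(M, forced, threshold),
                    error = function(e) NULL)
    if (is.null(ref)) {
      expect_error(
        suppressMessages(recursive_vif_cox(M, forced, oc, threshold)),
        "eliminates every covariate")
      next
    }
    rv <- suppressMessages(suppressWarnings(
      recursive_vif_cox(M, forced, oc, threshold)))
    removed <- vapply(rv$trace$iterations, function(it) it$removed,
                      character(1))
    expect_identical(removed[!is.na(removed)], ref$removed)
    expect_identical(rv$trace$surviving_metabolites, ref$surviving)
    # post-condition audit: recomputed VIF on the final design is below
    # threshold for every metabolite
    final <- compute_vif(cbind(M[, ref$surviving, drop = FALSE], forced))
    expect_lt(max(final[ref$surviving]), threshold)
  }
})

test_that("raising the threshold never removes more covariates", {
  for (s in 1:10) {
    M <- rand_correlated_design(40, 8, seed = 800 + s)
    oc <- survival_outcome(rownames(M), sample(1:10, 40, replace = TRUE),
                           rbinom(40, 1, 0.8), "DFS")
    n_rem <- sapply(c(1.8, 3, 6), function(thr) {
      rv <- tryCatch(
        suppressMessages(suppressWarnings(
          recursive_vif_cox(M, NULL, oc, thr))),
        error = function(e) NULL)
      if (is.null(rv)) ncol(M) else rv$trace$n_removed
    })
    expect_true(all(diff(n_rem) <= 0))
  }
})

test_that("forced clinical covariates are never removed", {
  n <- 40
  set.seed(31)
  M <- rand_correlated_design(n, 4, seed = 31)
  forced <- cbind(her2 = M[, 1] + rnorm(n, 0, 0.05))
  rownames(forced) <- rownames(M)
  oc <- survival_outcome(rownames(M), sample(1:8, n, replace = TRUE),
                         rbinom(n, 1, 0.8), "DFS")
  rv <- suppressMessages(suppressWarnings(
    recursive_vif_cox(M, forced, oc, threshold = 3)))
  removed <- vapply(rv$trace$iterations, function(it) it$removed,
                    character(1))
  expect_false("her2" %in% removed)
  expect_true("her2" %in% rv$trace$surviving_covariates)
  expect_true("m1" %in% removed)  # its collinear metabolite partner goes
})

test_that("selection keeps metabolites below alpha, never forced covariates", {
  d <- rand_surv_data(n = 60, p = 4, seed = 77, tie = TRUE)
  fit <- fit_cox(d$X, d$outcome, metabolite_covariates = c("x1", "x2"))
  sel <- select_significant(fit, alpha = 0.5)
  expect_true(all(sel$metabolite %in% c("x1", "x2")))
  expect_setequal(sel$metabolite,
                  names(which(fit$wald_p[c("x1", "x2")] < 0.5)))

  none <- select_significant(fit, alpha = 1e-12)
  expect_identical(nrow(none), 0L)
  expect_error(compute_mrss(fold_change_matrix(d$X), none),
               "no selected metabolites")
})
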