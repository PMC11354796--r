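test_that("MRSS is the coefficient-weighted sum of log fold changes", {
  m <- matrix(c(1, 0, 0.5,
                1, 0, -2,
                1, 0, 0,
                1, 0, 1), 4, 3, byrow = TRUE,
              dimnames = list(paste0("p", 1:4),
                              c("Histidine", "Lactate", "Serine")))
  beta <- c(Histidine = -0.5, Serine = 2)
  expect_equal(unname(compute_mrss(fold_change_matrix(m), beta)),
               c(0.5, -4.5, -0.5, 1.5))

  # published hazard ratios as coefficients, unit fold changes
  hr_beta <- c(Histidine = log(0.32), Lactate = log(0.32),
               Serine = log(5.06), Taurine = log(2.51))
  unit <- matrix(1, 1, 4, dimnames = list("p1", names(hr_beta)))
  expect_equal(unname(compute_mrss(fold_change_matrix(unit), hr_beta)),
               0.263, tolerance = 1e-3)

  zero <- c(Histidine = 0, Serine = 0)
  expect_equal(unname(compute_mrss(fold_change_matrix(m), zero)),
               rep(0, 4))
  expect_error(compute_mrss(fold_change_matrix(m), c(Taurine = 1)),
               "absent from the fold-change matrix")
})

test_that("MRSS is linear and ignores zero-coefficient metabolites", {
  set.seed(15)
  m <- matrix(rnorm(40), 10, 4,
              dimnames = list(paste0("p", 1:10), paste0("M", 1:4)))
  beta <- c(M1 = 0.7, M3 = -1.2)
  s <- compute_mrss(fold_change_matrix(m), beta)
  expect_equal(compute_mrss(fold_change_matrix(3 * m), beta), 3 * s,
               tolerance = 1e-12)
  expect_equal(compute_mrss(fold_change_matrix(m), c(beta, M2 = 0)), s,
               tolerance = 1e-12)
})

test_that("perfect separation places the cutpoint between the groups", {
  score <- 1:20
  # top half: early events; bottom half: censored late
  time <- c(rep(50, 10), 1:10)
  event <- c(rep(0, 10), rep(1, 10))
  oc <- survival_outcome(paste0("p", 1:20), time, event, "DFS")
  ms <- maxstat_cutpoint(score, oc)
  expect_equal(ms$cutpoint, 10.5)
  expect_error(maxstat_cutpoint(rep(1, 20), oc), "identical")
  expect_error(
    maxstat_cutpoint(score,
                     survival_outcome(paste0("p", 1:20), time,
                                      rep(0, 20), "DFS")),
    "at least one event")
})

test_that("selected cutpoint equals the exhaustive brute-force argmax", {
  for (s in 1:30) {
    set.seed(1200 + s)
    n <- sample(15:60, 1)
    score <- round(rnorm(n), 2)  # rounding forces some tied scores
    time <- sample(1:15, n, replace = TRUE)
    event <- rbinom(n, 1, 0.6)
    if (!sum(event)) event[1] <- 1
    oc <- survival_outcome(paste0("p", 1:n), time, event, "DFS")
    ref <- brute_maxstat(score, time, event)
    if (is.null(ref)) next
    ms <- maxstat_cutpoint(score, oc)
    expect_equal(ms$cutpoint, ref$cut, tolerance = 1e-10)
    expect_equal(ms$max_statistic, ref$stat, tolerance = 1e-8)
  }
})

test_that("any strictly monotone transform of scores yields the same strata", {
  set.seed(33)
  n <- 40
  score <- rnorm(n)
  oc <- survival_outcome(paste0("p", 1:n), sample(1:20, n, replace = TRUE),
                         rbinom(n, 1, 0.6), "DFS")
  if (!sum(oc$event)) oc$event[1] <- 1
  ms1 <- maxstat_cutpoint(score, oc)
  r1 <- stratify(score, ms1$cutpoint)
  for (f in list(function(x) exp(x), function(x) x^3 + 5 * x)) {
    ms2 <- maxstat_cutpoint(f(score), oc)
    expect_identical(stratify(f(score), ms2$cutpoint), r1)
  }
})

test_that("stratify uses a strict threshold: ties at the cutpoint are low", {
  expect_identical(as.character(stratify(c(1, 2, 3), 2)),
                   c("low", "low", "high"))
  expect_identical(as.character(stratify(c(1, 1.5), 10)), c("low", "low"))
})

test_that("adjusted models recover a planted risk effect and are null under shuffling", {
  set.seed(91)
  mean_null <- replicate(30, {
    co <- generate_cohort(cohort_config(
      n_patients = 120, true_beta = c(Serine = 0),
      seed = sample.int(1e6, 1)))
    risk <- factor(sample(rep(c("low", "high"), c(85, 35))),
                   levels = c("low", "high"))
    am <- adjusted_models(risk, co$clinical, co$dfs, co$os)
    log(am$dfs$hr[["mrss_high"]])
  })
  expect_lt(abs(mean(mean_null)), 0.2)

  co <- generate_cohort(cohort_config(n_patients = 300, seed = 7))
  risk <- stratify(co$truth$linear_predictor,
                   median(co$truth$linear_predictor))
  am <- adjusted_models(risk, co$clinical, co$dfs, co$os)
  expect_gt(am$dfs$hr[["mrss_high"]], 1)
  expect_lt(am$dfs$wald_p[["mrss_high"]], 0.05)
  expect_identical(sort(unique(am$table$factor)),
                   sort(c("age_lt50", "stage_iii_iv", "mrss_high")))
})

test_that("stage-stratified analysis skips degenerate strata and finds planted effects", {
  # identical survival in all four groups: p = 1 within each stage
  n <- 40
  stage <- rep(c("I", "III"), each = 20)
  time <- rep(rep(1:10, each = 2), 2)  # low/high share every event time
  oc <- survival_outcome(paste0("p", 1:n), time, rep(1, n), "DFS")
  risk <- factor(rep(c("low", "high"), 20), levels = c("low", "high"))
  res <- stage_stratified_km(risk, stage, oc)
  expect_equal(res$logrank[["I-II"]]$p_value, 1)
  expect_equal(res$logrank[["III-IV"]]$p_value, 1)
  expect_length(res$km, 4)

  # effect only in stage I-II
  set.seed(55)
  n2 <- 120
  stage2 <- rep(c("II", "IV"), each = n2 / 2)
  risk2 <- factor(rep(c("low", "high"), n2 / 2), levels = c("low", "high"))
  haz <- ifelse(stage2 == "II" & risk2 == "high", 0.15, 0.02)
  t2 <- pmin(rexp(n2, haz), 40)
  oc2 <- survival_outcome(paste0("q", 1:n2), t2,
                          as.numeric(t2 < 40), "DFS")
  res2 <- stage_stratified_km(risk2, stage2, oc2)
  expect_lt(res2$logrank[["I-II"]]$p_value, 0.01)
  expect_gt(res2$logrank[["III-IV"]]$p_value, 0.05)

  # single high-risk patient in a stratum: skipped with a warning
  risk3 <- factor(c(rep("low", 19), "high", rep(c("low", "high"), 10)),
                  levels = c("low", "high"))
  stage3 <- rep(c("I", "IV"), c(20, 20))
  oc3 <- survival_outcome(paste0("r", 1:40),
                          sample(1:10, 40, replace = TRUE),
                          rbinom(40, 1, 0.7), "DFS")
  expect_warning(res3 <- stage_stratified_km(risk3, stage3, oc3),
                 "< 2 subjects")
  expect_null(res3$logrank[["I-II"]])
})

test_that("maxstat null calibration: adjusted p approximation is conservative-ish", {
  # under a null score, the maximal statistic exceeds the 95th percentile
  # of its own permutation distribution about 5% of the time
  set.seed(321)
  n <- 40
  time <- sample(1:20, n, replace = TRUE)
  event <- rbinom(n, 1, 0.6)
  if (!sum(event)) event[1] <- 1
  oc <- survival_outcome(paste0("p", 1:n), time, event, "DFS")
  stats <- replicate(120, {
    maxstat_cutpoint(rnorm(n), oc)$max_statistic
  })
  q95 <- quantile(stats, 0.95)
  extra <- replicate(120, maxstat_cutpoint(rnorm(n), oc)$max_statistic)
  expect_gt(mean(extra > q95), 0.005)
  expect_lt(mean(extra > q95), 0.15)
})
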