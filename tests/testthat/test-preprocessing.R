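mk_table <- function(values, timepoint = "before",
                     ids = sprintf("P%02d", seq_len(nrow(values))),
                     mets = sprintf("M%02d", seq_len(ncol(values)))) {
  dimnames(values) <- list(ids, mets)
  metabolite_table(values, timepoint = timepoint)
}

test_that("sum normalization divides each row by its total", {
  tab <- mk_table(rbind(c(2, 3, 5), c(1, 1, 2)))
  norm <- sum_normalize(tab)
  expect_equal(unname(norm$values[1, ]), c(0.2, 0.3, 0.5))
  expect_equal(rowSums(norm$values), c(P01 = 1, P02 = 1), tolerance = 1e-12)

  one <- sum_normalize(mk_table(matrix(7.3, 1, 1)))
  expect_equal(unname(one$values[1, 1]), 1)

  flat <- sum_normalize(mk_table(matrix(1, 1, 4)))
  expect_equal(unname(flat$values[1, ]), rep(0.25, 4))
})

test_that("non-positive concentrations are rejected with context", {
  vals <- matrix(c(1, 2, 0.5, -1), 2, 2,
                 dimnames = list(c("A", "B"), c("Serine", "Taurine")))
  expect_error(metabolite_table(vals), "patient 'B'.*Taurine")
})

test_that("paired log fold change is the difference of log-normalized values", {
  before <- sum_normalize(mk_table(rbind(c(0.2, 0.3, 0.5), c(0.5, 0.375, 0.125))))
  after_vals <- rbind(c(0.4, 0.2, 0.4), c(0.125, 0.375, 0.5))
  after <- sum_normalize(mk_table(after_vals, timepoint = "after"))
  fc <- paired_log_fold_change(before, after)
  expect_equal(fc$log_fc["P01", "M01"], log(2), tolerance = 1e-12)
  expect_equal(fc$log_fc["P02", "M01"], log(0.25), tolerance = 1e-12)

  same <- paired_log_fold_change(before, mk_table(before$values,
                                                  timepoint = "after"))
  expect_true(all(same$log_fc == 0))
})

test_that("pairing drops patients missing one timepoint and rejects mismatches", {
  set.seed(7)
  b <- sum_normalize(mk_table(matrix(runif(9, 1, 2), 3, 3)))
  a_vals <- matrix(runif(6, 1, 2), 2, 3,
                   dimnames = list(c("P01", "P02"), c("M01", "M02", "M03")))
  a <- sum_normalize(metabolite_table(a_vals, timepoint = "after"))
  expect_warning(fc <- paired_log_fold_change(b, a), "one timepoint")
  expect_identical(rownames(fc$log_fc), c("P01", "P02"))

  disjoint <- sum_normalize(mk_table(matrix(runif(6, 1, 2), 2, 3),
                                     ids = c("Q1", "Q2"),
                                     timepoint = "after"))
  expect_error(paired_log_fold_change(b, disjoint), "fewer than 2")

  othermets <- sum_normalize(mk_table(matrix(runif(9, 1, 2), 3, 3),
                                      mets = c("A", "B", "C"),
                                      timepoint = "after"))
  expect_error(paired_log_fold_change(b, othermets), "metabolite sets differ")

  raw <- mk_table(matrix(runif(9, 1, 2), 3, 3), timepoint = "after")
  expect_error(paired_log_fold_change(b, raw), "sum-normalized")
})

test_that("normalization is invariant to per-patient scaling of raw rows", {
  set.seed(11)
  vals <- matrix(runif(20, 0.5, 4), 4, 5)
  scaled <- vals * c(1, 10, 0.01, 1000)
  expect_equal(sum_normalize(mk_table(vals))$values,
               sum_normalize(mk_table(scaled))$values, tolerance = 1e-12)
})

test_that("swapping before and after negates every log fold change", {
  set.seed(13)
  b <- sum_normalize(mk_table(matrix(runif(15, 1, 3), 3, 5)))
  a <- sum_normalize(mk_table(matrix(runif(15, 1, 3), 3, 5),
                              timepoint = "after"))
  fc <- paired_log_fold_change(b, a)
  b2 <- metabolite_table(a$values, timepoint = "before")
  a2 <- metabolite_table(b$values, timepoint = "after")
  rev_fc <- paired_log_fold_change(b2, a2)
  expect_equal(rev_fc$log_fc, -fc$log_fc, tolerance = 1e-12)
})

test_that("mean fold changes summarize ratios and direction", {
  m <- rbind(c(log(2), 0), c(log(0.5), 0))
  dimnames(m) <- list(c("P1", "P2"), c("Serine", "Taurine"))
  mf <- mean_fold_changes(fold_change_matrix(m))
  expect_equal(mf$mean_ratio[mf$metabolite == "Serine"], 1.25)
  expect_equal(mf$mean_log_fc[mf$metabolite == "Serine"], 0)
  expect_identical(mf$direction[mf$metabolite == "Serine"], "increase")
  expect_identical(mf$direction[mf$metabolite == "Taurine"], "no change")

  single <- matrix(log(3), 1, 1, dimnames = list("P1", "Serine"))
  expect_equal(mean_fold_changes(fold_change_matrix(single))$mean_ratio, 3)
})
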