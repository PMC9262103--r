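test_that("qc_filter removes columns for the documented reasons, in order", {
  set.seed(1)
  n <- 100
  good <- rnorm(n)
  mostly_missing <- c(rnorm(49), rep(NA, 51))
  constant <- rep(3.5, n)
  near_constant <- c(rep(7, 96), 1, 2, 3, 4)
  tab <- subject_table(cbind(good = good, mm = mostly_missing,
                             const = constant, nc = near_constant))
  res <- qc_filter(tab)
  expect_setequal(res$report$variable, c("mm", "const", "nc"))
  expect_equal(res$report$reason[res$report$variable == "mm"], "missing_gt_50pct")
  expect_equal(res$report$reason[res$report$variable == "const"], "zero_sd")
  expect_equal(res$report$reason[res$report$variable == "nc"], "gt_95pct_identical")
  expect_equal(res$table$variable_names, "good")
  expect_equal(attr(res$report, "retained_count"), 1L)
  # a column that is both >50% missing and constant reports the first reason
  both <- c(rep(5, 40), rep(NA, 60))
  res2 <- qc_filter(subject_table(cbind(good = good, both = both)))
  expect_equal(res2$report$reason, "missing_gt_50pct")
})

test_that("qc_filter is idempotent and errors on an empty result", {
  set.seed(2)
  tab <- subject_table(matrix(rnorm(200), 50, 4))
  once <- qc_filter(tab)
  twice <- qc_filter(once$table)
  expect_equal(nrow(twice$report), 0L)
  expect_equal(twice$table$values, once$table$values)
  all_bad <- subject_table(cbind(a = rep(1, 10), b = rep(2, 10)))
  expect_error(qc_filter(all_bad), "empty table")
})

test_that("impute_missing fills holes with the column median and keeps the mask", {
  tab <- subject_table(cbind(a = c(1, NA, 3), b = c(5, 6, 7),
                             c = c(1, 1, NA)))
  tab$values <- rbind(tab$values, c(2, 8, 4))
  tab <- subject_table(tab$values)  # 4 rows: a=(1,NA,3,2), c=(1,1,NA,4)
  out <- impute_missing(tab)
  expect_equal(out$values[2, "a"], 2)       # median of {1,3,2}
  expect_equal(out$values[3, "c"], 1)       # median of {1,1,4}
  expect_equal(out$values[, "b"], tab$values[, "b"])  # untouched
  expect_true(out$missing_mask[2, "a"])     # provenance retained
  expect_false(anyNA(out$values))
})

test_that("inverse_normal_transform produces exact Blom scores", {
  tab <- subject_table(cbind(x = c(1, 2, 3)))
  out <- inverse_normal_transform(tab)
  expect_equal(out$values[, "x"],
               qnorm(c(0.625, 1.625, 2.625) / 3.25),
               ignore_attr = TRUE)
  expect_equal(out$values[2, "x"], 0)
  # n = 2: antisymmetric about zero
  out2 <- inverse_normal_transform(subject_table(cbind(x = c(10, 20))))
  expect_equal(out2$values[1, "x"], -out2$values[2, "x"])
  expect_equal(out2$values[2, "x"], qnorm(1.625 / 2.25))
  # monotone: rank order preserved
  x <- c(5, 1, 3)
  out3 <- inverse_normal_transform(subject_table(cbind(x = x)))
  expect_equal(order(out3$values[, "x"]), order(x))
  expect_error(inverse_normal_transform(subject_table(cbind(x = rep(1, 5)))),
               "constant")
})

test_that("Blom-transformed columns match theory: mean and perfect rank correlation", {
  set.seed(3)
  n <- 137
  tab <- subject_table(cbind(a = rexp(n), b = rnorm(n)^3))
  out <- inverse_normal_transform(tab)
  theoretical <- qnorm((seq_len(n) - 3 / 8) / (n + 1 / 4))
  for (j in 1:2) {
    expect_lt(abs(mean(out$values[, j]) - mean(theoretical)), 1e-8)
    expect_equal(cor(out$values[, j], theoretical[rank(tab$values[, j])]), 1)
  }
})

test_that("deconfound matches hand OLS and leaves residuals orthogonal", {
  tab <- subject_table(cbind(y = c(1, 2, 3, 4)))
  conf <- subject_table(cbind(c1 = c(1, 1, 2, 2)))
  out <- deconfound(tab, conf)
  expect_equal(out$values[, "y"], c(-0.5, 0.5, -0.5, 0.5), ignore_attr = TRUE)
  # residuals orthogonal to intercept and confounds
  set.seed(4)
  tab2 <- subject_table(matrix(rnorm(300), 50, 6))
  conf2 <- subject_table(matrix(rnorm(150), 50, 3),
                         subject_ids = tab2$subject_ids)
  res <- deconfound(tab2, conf2)
  D <- cbind(1, scale(conf2$values))
  expect_lt(max(abs(crossprod(res$values, D))), 1e-8)
  # a column equal to a confound is annihilated
  tab3 <- subject_table(cbind(y = conf2$values[, 1]),
                        subject_ids = conf2$subject_ids)
  expect_lt(max(abs(deconfound(tab3, conf2)$values)), 1e-10)
  # collinear confounds are a named error
  conf_bad <- subject_table(cbind(a = rnorm(50), b = 0),
                            subject_ids = tab2$subject_ids)
  conf_bad$values[, "b"] <- 2 * conf_bad$values[, "a"]
  expect_error(deconfound(tab2, conf_bad), "collinear|rank-deficient")
})

test_that("deconfound can append squared confound copies", {
  set.seed(5)
  n <- 80
  age <- rnorm(n)
  y <- age^2 + rnorm(n, sd = 0.01)
  tab <- subject_table(cbind(y = y))
  conf <- subject_table(cbind(age = age), subject_ids = tab$subject_ids)
  lin_only <- deconfound(tab, conf)
  with_sq <- deconfound(tab, conf, square = "age")
  expect_lt(sd(with_sq$values), sd(lin_only$values))
})

test_that("sign_flip negates negatively correlated variables and honours manual overrides", {
  set.seed(6)
  bench <- rnorm(100)
  tab <- subject_table(cbind(income = bench, anti = -bench + rnorm(100, sd = 0.1),
                             noise = rnorm(100)))
  res <- sign_flip(tab, "income")
  expect_true("anti" %in% res$record$flipped_variables)
  expect_false("income" %in% res$record$flipped_variables)
  expect_equal(res$table$values[, "anti"], -tab$values[, "anti"])
  # a manual flip of an auto-flipped variable undoes it
  res2 <- sign_flip(tab, "income", manual_flips = "anti")
  expect_false("anti" %in% res2$record$flipped_variables)
  expect_equal(res2$table$values[, "anti"], tab$values[, "anti"])
  expect_error(sign_flip(tab, "income", manual_flips = "income"), "benchmark")
})

test_that("sign flips leave covariance eigenvalues untouched", {
  set.seed(7)
  tab <- subject_table(matrix(rnorm(500), 50, 10))
  scr <- scramble_signs(tab, 0.5, rng_seed = 11)
  ev0 <- eigen(cov(tab$values), only.values = TRUE)$values
  ev1 <- eigen(cov(scr$table$values), only.values = TRUE)$values
  expect_lt(max(abs(ev0 - ev1)), 1e-10)
})

test_that("preprocess pipeline runs end to end in the documented order", {
  set.seed(8)
  n <- 60
  raw <- cbind(income = rnorm(n), a = rnorm(n), b = rnorm(n),
               junk = rep(1, n))
  raw[sample(n, 5), "a"] <- NA
  tab <- subject_table(raw)
  conf <- subject_table(cbind(c1 = rnorm(n)), subject_ids = tab$subject_ids)
  out <- preprocess(tab, confounds = conf, benchmark = "income")
  expect_equal(out$qc_report$variable, "junk")
  expect_false(anyNA(out$table$values))
  expect_lt(max(abs(crossprod(out$table$values, cbind(1, scale(conf$values))))), 1e-6)
  expect_equal(out$sign_flip_record$benchmark_variable, "income")
})
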