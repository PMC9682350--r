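# Cleaning rules, report arithmetic, and fit/apply preprocessing.

test_that("duplicate rows collapse or drop according to target agreement", {
  v <- matrix(rnorm(12), 4, 3, dimnames = list(NULL, c("a", "b", "c")))
  v[2, ] <- v[1, ]
  ft <- feature_table(v, c(1, 1, 0, 1))
  out <- resolve_duplicate_rows(ft)
  expect_equal(nrow(out$table$values), 3)
  expect_equal(out$report$collapsed_duplicate_rows, 1)

  ft2 <- feature_table(v, c(0, 1, 0, 1))
  out2 <- resolve_duplicate_rows(ft2)
  expect_equal(nrow(out2$table$values), 2)
  expect_equal(length(out2$report$removed_conflicting_rows), 2)

  v3 <- matrix(rnorm(12), 4, 3, dimnames = list(NULL, c("a", "b", "c")))
  ft3 <- feature_table(v3, c(0, 1, 0, 1))
  expect_equal(resolve_duplicate_rows(ft3)$table$values, v3,
               ignore_attr = TRUE)
})

test_that("high-missing rule is >= at the threshold", {
  v <- matrix(rnorm(300), 100, 3, dimnames = list(NULL, c("m96", "m95", "full")))
  v[1:96, "m96"] <- NA
  v[1:95, "m95"] <- NA
  ft <- feature_table(v, rep(c(0, 1), 50))
  out <- drop_high_missing(ft, 0.95)
  expect_setequal(out$report$dropped_high_missing, c("m96", "m95"))
  expect_equal(colnames(out$table$values), "full")
})

test_that("near-constant rule covers constant and 99%-dominant columns", {
  v <- cbind(const = rep(7, 100), dom = c(rep(0, 99), 1),
             bal = rep(c(0, 1), 50), cont = rnorm(100))
  ft <- feature_table(v, rep(c(0, 1), 50))
  out <- drop_near_constant(ft, 0.99)
  expect_setequal(out$report$dropped_near_constant, c("const", "dom"))
  expect_setequal(colnames(out$table$values), c("bal", "cont"))
})

test_that("duplicate columns collapse to the lexicographically first name", {
  v <- cbind(b_col = rnorm(50), a_col = NA_real_, c_col = rnorm(50))
  v[, "a_col"] <- v[, "b_col"]
  near <- v[, "b_col"]; near[1] <- NA
  v <- cbind(v, near_dup = near)
  ft <- feature_table(v, rep(c(0, 1), 25))
  out <- collapse_duplicate_columns(ft)
  expect_true("a_col" %in% colnames(out$table$values))
  expect_false("b_col" %in% colnames(out$table$values))
  # one missing cell difference means both columns are kept
  expect_true("near_dup" %in% colnames(out$table$values))
  expect_equal(out$report$collapsed_duplicate_columns,
               list(c("a_col", "b_col")))
})

test_that("pipeline report arithmetic matches planted defects exactly", {
  fx <- make_cleaning_fixture()
  out <- clean_feature_table(fx$table)
  rep <- out$report
  exp <- fx$expected
  expect_equal(rep$n_rows_in, exp$n_rows_in)
  expect_equal(rep$n_rows_out, exp$n_rows_out)
  expect_equal(rep$n_cols_in, exp$n_cols_in)
  expect_equal(rep$n_cols_out, exp$n_cols_out)
  expect_equal(rep$collapsed_duplicate_rows, exp$collapsed_duplicate_rows)
  expect_equal(rep$removed_conflicting_rows, exp$removed_conflicting_rows)
  expect_equal(rep$dropped_high_missing, exp$dropped_high_missing)
  expect_equal(rep$dropped_near_constant, exp$dropped_near_constant)
  expect_equal(rep$collapsed_duplicate_columns, exp$collapsed_duplicate_columns)
  # column arithmetic invariant
  n_collapsed_extra <- sum(lengths(rep$collapsed_duplicate_columns)) -
    length(rep$collapsed_duplicate_columns)
  expect_equal(rep$n_cols_out,
               rep$n_cols_in - length(rep$dropped_high_missing) -
                 length(rep$dropped_near_constant) - n_collapsed_extra)
})

test_that("winsorization matches the sort-and-interpolate percentile oracle", {
  x <- as.numeric(1:100)
  b <- winsorize_fit(x, 5, 95)
  # linear-interpolation percentile oracle: p-th percentile of sorted x
  oracle_q <- function(v, p) {
    v <- sort(v); h <- (length(v) - 1) * p + 1
    lo <- floor(h); v[lo] + (h - lo) * (v[min(lo + 1, length(v))] - v[lo])
  }
  expect_equal(b[1], oracle_q(x, 0.05))
  expect_equal(b[2], oracle_q(x, 0.95))
  w <- winsorize_apply(x, b)
  expect_true(all(w >= b[1] & w <= b[2]))
  # idempotence under the same fitted bounds
  expect_equal(winsorize_apply(w, b), w)
  # constant column unchanged
  expect_equal(winsorize_apply(rep(3, 10), winsorize_fit(rep(3, 10))),
               rep(3, 10))
  # missing passes through
  expect_true(is.na(winsorize_apply(c(1, NA), b)[2]))
  expect_error(winsorize_fit(c(NA_real_, NA_real_)), "non-missing")
})

test_that("min-max scaling maps training to [0,1] without re-clipping", {
  r <- minmax_fit(c(2, 4, 6))
  expect_equal(minmax_apply(c(2, 4, 6), r), c(0, 0.5, 1))
  expect_equal(minmax_apply(8, r), 1.5)
  expect_true(is.na(minmax_apply(NA_real_, r)))
  expect_error(minmax_fit(rep(5, 4)), "range")
})

test_that("constant imputation follows the model-family policy", {
  v <- matrix(c(1, NA, 3, NA), 2, 2, dimnames = list(NULL, c("a", "b")))
  p1 <- preprocess_policy(impute_constant = 1)
  expect_equal(impute_mnar(v, p1)[is.na(v)], c(1, 1))
  p2 <- preprocess_policy(scale = "none", impute_constant = -99999)
  expect_equal(impute_mnar(v, p2)[is.na(v)], c(-99999, -99999))
  pn <- preprocess_policy(scale = "none", impute_constant = "native_missing")
  expect_identical(impute_mnar(v, pn), v)
})

test_that("fold preprocessing is fitted on training values only", {
  train <- c(rnorm(50), NA)
  held <- c(1e6, -1e6)  # extreme held-out values must not move the fit
  b_train <- winsorize_fit(train)
  b_all <- winsorize_fit(c(train, held))
  expect_false(isTRUE(all.equal(b_train, b_all)))
  X <- cbind(f = train)
  fit <- fit_preprocess(X, preprocess_policy(impute_constant = 1))
  expect_equal(unname(fit$bounds[, "f"]), unname(b_train))
  # held-out extremes are clipped at the *training* percentiles, then
  # scaled with the training range: they land on 0/1, not on new bounds
  out <- apply_preprocess(fit, cbind(f = held))
  expect_equal(unname(out[, 1]), c(1, 0))
})
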