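test_that("csv_header reader parses rows, missing markers and errors", {
  path <- write_cleveland_csv(cleveland_rows())
  coh <- read_cohort(path, cleveland_schema(), "csv_header")
  expect_s3_class(coh, "cohort")
  expect_equal(nrow(coh$X), 3)
  expect_equal(ncol(coh$X), 13)
  expect_equal(coh$y, c(0L, 1L, 0L))
  expect_false(any(coh$missing_mask))

  rows <- cleveland_rows()
  rows[2] <- sub(",3,3,1$", ",?,3,1", rows[2])   # missing ca
  coh2 <- read_cohort(write_cleveland_csv(rows), cleveland_schema())
  expect_true(coh2$missing_mask[2, "ca"])
  expect_true(is.na(coh2$X[2, "ca"]))

  bad <- tempfile(fileext = ".csv")
  writeLines(c("a,b,target", "1,2,0"), bad)
  expect_error(read_cohort(bad, cleveland_schema()), "schema")
  expect_error(read_cohort(tempfile(), cleveland_schema()), "not found")
})

test_that("uci_processed dialect handles '?', binarizes the outcome, and checks width", {
  path <- tempfile(fileext = ".data")
  writeLines(synthetic_uci_lines(), path)
  coh <- read_cohort(path, cleveland_schema(), "uci_processed")
  expect_equal(nrow(coh$X), 5)
  expect_equal(coh$y, c(0L, 1L, 1L, 1L, 0L))   # codes 2 and 3 map to 1
  expect_true(coh$missing_mask[3, "ca"])
  expect_true(coh$missing_mask[4, "thal"])

  short <- tempfile(fileext = ".data")
  writeLines("1,2,3,4,5,6,7,8,9,10,11,12,0", short)  # 12 features + target
  expect_error(read_cohort(short, cleveland_schema(), "uci_processed"), "schema")

  nonnum <- tempfile(fileext = ".data")
  writeLines(sub("^63.0", "abc", synthetic_uci_lines()[1]), nonnum)
  expect_error(read_cohort(nonnum, cleveland_schema(), "uci_processed"),
               "parse error.*age.*row 1")
})

test_that("write_cohort/read_cohort round-trips both dialects with missing cells", {
  rows <- cleveland_rows()
  rows[1] <- sub("^63,", "?,", rows[1])
  coh <- read_cohort(write_cleveland_csv(rows), cleveland_schema())
  for (dialect in c("csv_header", "uci_processed")) {
    p <- tempfile()
    write_cohort(coh, p, dialect)
    back <- read_cohort(p, cleveland_schema(), dialect)
    expect_equal(back$X, coh$X)
    expect_equal(back$y, coh$y)
    expect_equal(back$missing_mask, coh$missing_mask)
  }
})

test_that("impute fills by column statistic, preserves observed cells, breaks ties first-seen", {
  X <- cbind(a = c(1, 2, NA, 3), b = c(5, NA, 7, 30),
             g = c(1, 1, 2, NA), s = c(0, 1, NA, 1))
  coh <- cohort(X, c(0, 1, 0, 1), toy_schema())
  out <- impute(coh, "mean")
  expect_false(any(out$missing_mask))
  expect_equal(unname(out$X[3, "a"]), 2)         # mean of 1,2,3
  expect_equal(unname(out$X[2, "b"]), 14)        # mean of 5,7,30
  expect_equal(unname(out$X[4, "g"]), 1)         # modal level
  expect_equal(unname(out$X[3, "s"]), 1)         # mode of 0,1,1
  expect_equal(unname(out$X[1, "a"]), 1)         # observed untouched

  med <- impute(coh, "median")
  expect_equal(unname(med$X[2, "b"]), 7)

  # tie: levels 1 and 2 equally frequent, 2 encountered first
  Xt <- cbind(a = 1:4, b = 1:4, g = c(2, 1, 2, NA), s = c(0, 0, 1, 1))
  tie <- impute(cohort(Xt, c(0, 1, 0, 1), toy_schema()))
  expect_equal(unname(tie$X[4, "g"]), 2)

  Xm <- cbind(a = c(NA, NA, NA, NA), b = 1:4, g = c(1, 1, 2, 2), s = c(0, 1, 0, 1))
  expect_error(impute(cohort(Xm, c(0, 1, 0, 1), toy_schema())), "unimputable")
})

test_that("min-max scaling maps the fit split to [0,1], constants to 0, and never clips", {
  X <- cbind(a = c(2, 4, 6), b = c(5, 5, 5), g = c(1, 2, 3), s = c(0, 1, 0))
  coh <- cohort(X, c(0, 1, 0), toy_schema())
  fit <- minmax_fit_transform(coh)
  expect_equal(unname(fit$cohort$X[, "a"]), c(0, 0.5, 1))
  expect_equal(unname(fit$cohort$X[, "b"]), c(0, 0, 0))
  expect_equal(fit$cohort$X[, "g"], X[, "g"])    # categorical untouched

  X2 <- X; X2[, "a"] <- c(8, 2, 4)
  out <- minmax_fit_transform(cohort(X2, c(0, 1, 0), toy_schema()), fit$params)
  expect_equal(unname(out$cohort$X[1, "a"]), 1.5)  # out of range, not clipped

  # property: fitting split always lands on [0,1] with min 0 / max 1
  for (s in 1:5) {
    set.seed(s)
    Xr <- cbind(a = rnorm(20), b = runif(20, -5, 5), g = sample(1:3, 20, TRUE),
                s = sample(0:1, 20, TRUE))
    sc <- minmax_fit_transform(cohort(Xr, rep_len(0:1, 20), toy_schema()))$cohort
    expect_equal(range(sc$X[, "a"]), c(0, 1))
    expect_equal(range(sc$X[, "b"]), c(0, 1))
  }
})

test_that("one-hot expands multi-level categoricals only, with exactly one hot per row", {
  coh <- read_cohort(write_cleveland_csv(cleveland_rows()), cleveland_schema())
  oh <- one_hot(coh)
  expect_equal(sum(grepl("^cp=", colnames(oh$X))), 4)
  expect_true("sex" %in% colnames(oh$X))          # binary passthrough
  expect_false(any(grepl("^sex=", colnames(oh$X))))
  for (feat in c("cp", "restecg", "slope", "ca", "thal")) {
    block <- oh$X[, grepl(paste0("^", feat, "="), colnames(oh$X)), drop = FALSE]
    expect_equal(unname(rowSums(block)), rep(1, 3))
  }
  bad <- coh
  bad$X[1, "cp"] <- 9
  expect_error(one_hot(bad), "unknown level")
})

test_that("SMOTE interpolates along minority segments, balances, and is reproducible", {
  # already balanced: unchanged
  sc <- small_signal_cohort(n = 60, seed = 2)
  bal_y <- rep_len(0:1, 60)
  bal <- cohort(sc$X, bal_y, sc$schema)
  expect_identical(smote(bal, seed = 1), bal)

  # two minority points at the corners of the unit square: synthetic points
  # lie on the segment, so both coordinates are equal
  X <- cbind(a = c(0, 1, runif(10)), b = c(0, 1, runif(10)),
             g = rep(1, 12), s = rep(0, 12))
  y <- c(1, 1, rep(0, 10))
  seg <- smote(cohort(X, y, toy_schema()), k = 1, seed = 7)
  new_rows <- seg$X[13:nrow(seg$X), , drop = FALSE]
  expect_equal(unname(new_rows[, "a"]), unname(new_rows[, "b"]))
  expect_true(all(new_rows[, "a"] >= 0 & new_rows[, "a"] <= 1))
  expect_true(all(seg$y[13:length(seg$y)] == 1))
  expect_equal(sum(seg$y == 0), 10)               # majority never shrinks
  expect_equal(sum(seg$y == 1), 10)               # balanced after

  expect_identical(smote(cohort(X, y, toy_schema()), k = 1, seed = 7), seg)
  expect_error(smote(cohort(X, y, toy_schema()), k = 5), "neighbor|needs more")
})

test_that("class balance report counts and errors", {
  expect_equal(class_balance_report(c(1, 1, 0))$count, c(1L, 2L))
  r <- class_balance_report(small_signal_cohort(n = 50, seed = 3))
  expect_equal(sum(r$count), 50)
  expect_equal(sum(r$proportion), 1)
  expect_error(class_balance_report(integer(0)), "empty")
})

test_that("statistical descriptors use linear-interpolation quartiles and degenerate rules", {
  X <- cbind(a = c(1, 2, 3, 4), b = c(7, 7, 7, 7), g = c(1, 1, 2, 2), s = c(0, 0, 1, 1))
  coh <- cohort(X, c(0, 1, 0, 1), toy_schema())
  out <- statistical_descriptors(coh, strata = rep(1, 4))
  aug <- out$cohort
  expect_equal(unname(aug$X[, "a_iqr"]), rep(1.5, 4))   # Q3 3.25 - Q1 1.75
  expect_equal(unname(aug$X[, "b_sd"]), rep(0, 4))
  expect_equal(unname(aug$X[, "b_iqr"]), rep(0, 4))
  # single stratum: descriptor columns constant over the cohort
  desc_cols <- setdiff(colnames(aug$X), colnames(coh$X))
  for (cl in desc_cols[!grepl("_freq$", desc_cols)])
    expect_equal(length(unique(aug$X[, cl])), 1)
  # categorical frequency column: row's own level share within stratum
  expect_equal(unname(aug$X[, "g_freq"]), rep(0.5, 4))

  # stratum with < 2 rows: SD defined as 0, no error
  out2 <- statistical_descriptors(coh, strata = c(1, 2, 2, 2))
  expect_equal(unname(out2$cohort$X[1, "a_sd"]), 0)
})

test_that("design matrix expands selected categoricals after subset decoding", {
  sc <- small_signal_cohort(n = 40, seed = 5)
  m <- design_matrix(sc, c("age", "cp", "sex"))
  expect_equal(colnames(m), c("age", "cp=1", "cp=2", "cp=3", "cp=4", "sex"))
  expect_equal(unname(rowSums(m[, 2:5])), rep(1, 40))
  expect_error(design_matrix(sc, character(0)), "empty")
  expect_error(design_matrix(sc, "nope"), "unknown")
})
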