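test_that("GCT round-trips and validates its declared dimensions", {
  vals <- matrix(c(1.5, 0, 2, 3.25, 10, 0.01), nrow = 3,
                 dimnames = list(paste0("f", 1:3), c("sampA", "sampB")))
  path <- write_toy_gct(vals)
  m <- read_gct(path)
  expect_equal(dim(m$values), c(3L, 2L))
  expect_equal(unname(m$values), unname(vals))
  expect_equal(m$feature_ids, paste0("f", 1:3))

  out <- tempfile(fileext = ".gct")
  write_gct(m, out)
  expect_equal(read_gct(out)$values, m$values)

  # header declares 4 rows, body has 3
  lines <- readLines(path)
  lines[2] <- "4\t2"
  bad <- tempfile(fileext = ".gct")
  writeLines(lines, bad)
  expect_error(read_gct(bad), "dimension mismatch")

  # non-numeric cell is reported with its location
  lines <- readLines(path)
  lines[4] <- sub("1.5", "oops", lines[4])
  writeLines(lines, bad)
  expect_error(read_gct(bad), "oops.*f1|f1.*oops")
})

test_that("per-tissue summaries follow the mean/SE rules incl. single-subject SE", {
  vals <- matrix(c(2, 4, 7, 5, 5, 5), nrow = 1,
                 dimnames = list("g1", paste0("s", 1:6)))
  st <- setNames(c("A", "A", "B", "C", "C", "C"), paste0("s", 1:6))
  m <- expression_matrix(vals, sample_tissue = st)
  ts <- summarize_by_tissue(m)
  expect_equal(unname(ts$mean["g1", c("A", "B", "C")]), c(3, 7, 5))
  # two-point tissue: sd = sqrt(2), se = sqrt(2)/sqrt(2) = 1
  expect_equal(unname(ts$se["g1", "A"]), 1)
  # single-subject tissue: SE set to exactly 1
  expect_identical(unname(ts$se["g1", "B"]), 1)
  # identical replicates: zero SE floored at a small positive epsilon
  expect_gt(ts$se["g1", "C"], 0)
  expect_lt(ts$se["g1", "C"], 1e-4)
  expect_true("g1" %in% attr(ts, "se_floored"))
  expect_error(summarize_by_tissue(m, setNames(rep("A", 5), paste0("s", 1:5))),
               "tissue")
})

test_that("summaries match a direct two-pass mean/SD oracle on random data", {
  set.seed(101)
  n_t <- 6; per <- 5
  vals <- matrix(rexp(40 * n_t * per), nrow = 40)
  rownames(vals) <- paste0("g", 1:40)
  colnames(vals) <- paste0("s", seq_len(n_t * per))
  st <- setNames(rep(paste0("t", 1:n_t), each = per), colnames(vals))
  ts <- summarize_by_tissue(expression_matrix(vals, sample_tissue = st))
  for (t in paste0("t", 1:n_t)) {
    x <- vals[, st == t, drop = FALSE]
    expect_equal(unname(ts$mean[, t]), unname(apply(x, 1, mean)),
                 tolerance = 1e-12)
    expect_equal(unname(ts$se[, t]), unname(apply(x, 1, sd) / sqrt(per)),
                 tolerance = 1e-12)
  }
})

test_that("low-expression filters implement both published variants and are idempotent", {
  means <- rbind(g1 = c(0.0, 0.005, 0.01), g2 = c(0, 0, 100), g3 = c(5, 6, 7))
  ts <- make_ts(means)
  f <- filter_low_expression(ts, cutoff = 0.01, mode = "all_tissues")
  expect_equal(f$feature_ids, c("g2", "g3"))   # g1 <= 0.01 everywhere

  ts5 <- make_ts(rbind(gA = c(0, 0, 0, 0, 2), gB = c(1, 1, 1, 1, 1)))
  expect_equal(filter_low_expression(ts5, 0.5, "k_or_more_tissues", k = 4)$feature_ids,
               "gB")
  expect_equal(filter_low_expression(ts5, 0.5, "k_or_more_tissues", k = 5)$feature_ids,
               c("gA", "gB"))

  set.seed(3)
  m <- expression_matrix(matrix(rexp(60), 10,
                                dimnames = list(paste0("g", 1:10), paste0("s", 1:6))))
  once <- filter_low_expression(m, cutoff = 0.5)
  twice <- filter_low_expression(once, cutoff = 0.5)
  expect_identical(twice$values, once$values)
})

test_that("tissue correlation QC excludes discordant tissues but never a duplicate of a kept one", {
  set.seed(4)
  base <- rnorm(10, 5)
  means <- cbind(A = base + rnorm(10, 0, 0.1), B = base + rnorm(10, 0, 0.1),
                 D = base + rnorm(10, 0, 0.1),
                 C = -base)   # anti-correlated tissue
  rownames(means) <- paste0("g", 1:10)
  res <- tissue_correlation_qc(make_ts(means), threshold = 0)
  expect_equal(res$excluded$tissue, "C")
  expect_setequal(res$summary$tissues, c("A", "B", "D"))

  ident <- matrix(rep(rnorm(8), 3), ncol = 3, dimnames = list(paste0("g", 1:8), c("A", "B", "C")))
  res2 <- tissue_correlation_qc(make_ts(ident), threshold = 0.5)
  expect_equal(nrow(res2$excluded), 0L)

  # a duplicated pair: both members share identical correlation vectors, so
  # one is never dropped while its twin is kept
  means4 <- cbind(A = base, A2 = base, B = base + rnorm(10, 0, .2), C = rnorm(10))
  rownames(means4) <- paste0("g", 1:10)
  res3 <- tissue_correlation_qc(make_ts(means4), threshold = 0.3)
  expect_false(xor("A" %in% res3$excluded$tissue, "A2" %in% res3$excluded$tissue))

  expect_error(tissue_correlation_qc(make_ts(matrix(1:3, 1, 3))), "feature")
})

test_that("rank-to-normal maps samples onto the fixed quantile grid, invariant to monotone transforms", {
  m <- expression_matrix(matrix(c(10, 20, 30), 3, 1,
                                dimnames = list(paste0("g", 1:3), "s1")))
  r <- rank_to_normal(m)
  expect_equal(unname(r$values[, 1]), qnorm(c(1, 3, 5) / 6), tolerance = 1e-12)

  set.seed(5)
  v <- matrix(rexp(200), 50, 4, dimnames = list(paste0("g", 1:50), paste0("s", 1:4)))
  a <- rank_to_normal(expression_matrix(v))
  b <- rank_to_normal(expression_matrix(log1p(v)))   # monotone transform
  expect_identical(a$values, b$values)
  grid <- qnorm((seq_len(50) - 0.5) / 50)
  for (j in 1:4) {
    expect_lt(abs(mean(a$values[, j])), 1e-9)
    expect_equal(unname(sort(a$values[, j])), grid, tolerance = 1e-12)
  }
  # opposite orderings give sign-reversed grids
  m2 <- expression_matrix(cbind(s1 = c(1, 2, 3), s2 = c(3, 2, 1)),
                          feature_ids = paste0("g", 1:3))
  r2 <- rank_to_normal(m2)
  expect_equal(r2$values[, "s1"], -r2$values[, "s2"], ignore_attr = TRUE)

  const <- expression_matrix(matrix(5, 3, 1, dimnames = list(paste0("g", 1:3), "s1")))
  expect_error(rank_to_normal(const), "constant sample")
})

test_that("sample correlation filter flags duplicates high and passes tiny groups through", {
  set.seed(6)
  v <- matrix(rnorm(200 * 11), 200, 11)
  v <- cbind(v, v[, 11] + rnorm(200, 0, 1e-3))   # near-duplicate of sample 11
  colnames(v) <- paste0("s", 1:12)
  rownames(v) <- paste0("g", 1:200)
  res <- sample_correlation_filter(expression_matrix(v, transformed = TRUE))
  expect_true(all(c("s11", "s12") %in% res$removed$sample))
  expect_true(all(res$removed$reason[res$removed$sample %in% c("s11", "s12")] ==
                    "high_correlation"))

  ident <- matrix(rep(rnorm(50), 5), 50, 5,
                  dimnames = list(paste0("g", 1:50), paste0("s", 1:5)))
  res2 <- sample_correlation_filter(expression_matrix(ident, transformed = TRUE))
  expect_equal(nrow(res2$removed), 0L)

  small <- expression_matrix(v[, 1:3], transformed = TRUE)
  expect_warning(res3 <- sample_correlation_filter(small), "passed through")
  expect_equal(ncol(res3$matrix$values), 3L)
})

test_that("sparse features are dropped at the <=9 observations boundary", {
  v <- matrix(NA_real_, 3, 12, dimnames = list(paste0("g", 1:3), paste0("s", 1:12)))
  v[1, 1:9] <- 1    # exactly 9 observations: dropped
  v[2, 1:10] <- 1   # 10 observations: kept
  v[3, ] <- 1
  m <- expression_matrix(v)
  out <- drop_sparse_features(m)
  expect_equal(out$feature_ids, c("g2", "g3"))
  expect_identical(drop_sparse_features(m, min_obs = 0L)$feature_ids,
                   m$feature_ids[rowSums(!is.na(v)) > 0])
})
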