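test_that("the Huber line fit handles perfect, constant and outlier inputs", {
  # exactly linear: zero residuals, equal weights 1/s, unit slope
  fit <- fit_huber_line(1:5, rep(2, 5))
  expect_equal(fit$beta1, 1, tolerance = 1e-12)
  expect_equal(fit$residuals, rep(0, 5), tolerance = 1e-12)
  expect_equal(fit$weights, rep(0.5, 5), tolerance = 1e-12)

  # constant y: zero slope, equal weights
  fitc <- fit_huber_line(rep(3, 6), rep(1, 6))
  expect_equal(fitc$beta1, 0, tolerance = 1e-12)
  expect_equal(fitc$weights, rep(1, 6), tolerance = 1e-12)

  # gross outlier at the top position is downweighted below the rest
  fito <- fit_huber_line(c(1, 2, 3, 4, 50), rep(1, 5))
  expect_lt(fito$weights[5], min(fito$weights[1:4]))

  expect_error(fit_huber_line(c(1, 2, NA), rep(1, 3)), "finite")
  expect_error(fit_huber_line(1:4, c(1, 1, 0, 1)), "> 0")
  expect_error(fit_huber_line(1:2, 1:2), "3 tissues")
})

test_that("larger residuals never earn larger weights under equal SEs", {
  set.seed(11)
  for (i in 1:25) {
    y <- rnorm(12) + c(rep(0, 10), 5, -5)[sample(12)]
    fit <- fit_huber_line(sort(y), rep(1, 12))
    ord <- order(abs(fit$residuals))
    expect_true(all(diff(fit$weights[ord]) <= 1e-12))
  }
})

test_that("REZ reproduces the equal-weight closed form on a linear ramp", {
  ts <- make_ts(matrix(1:5, 1, 5))
  pr <- rez_scores(ts)
  # perfect line: k collapses to 0, weights equal -> mu 3, sigma sqrt(2/0.8)
  expect_equal(pr$robust_mean[1], 3, tolerance = 1e-10)
  expect_equal(pr$robust_sd[1], sqrt(2 / 0.8), tolerance = 1e-10)
  expect_equal(unname(pr$score[1, 5]), 2 / (sqrt(2 / 0.8) * sqrt(1.5)),
               tolerance = 1e-10)
  expect_equal(unname(pr$score[1, 5]), 1.0328, tolerance = 1e-4)
  # z = 0 -> p = 1; p decreases monotonically in |z|
  expect_equal(unname(pr$pvalue[1, 3]), 1, tolerance = 1e-10)
  expect_true(all(diff(pr$pvalue[1, 3:5]) < 0))
})

test_that("rez_scores equals the independent IRLS oracle on random features", {
  set.seed(12)
  G <- 100; N <- 20
  mean <- matrix(rnorm(G * N, 5, 2), G, N)
  # sprinkle outliers so the Huber branch is exercised
  mean[cbind(1:G, sample(N, G, TRUE))] <- rnorm(G, 20, 3)
  se <- matrix(runif(G * N, 0.2, 2), G, N)
  ts <- make_ts(mean, se)
  pr <- rez_scores(ts)
  for (g in 1:G) {
    o <- oracle_rez(ts$mean[g, ], ts$se[g, ])
    expect_equal(unname(pr$score[g, ]), unname(o$z), tolerance = 1e-8)
    expect_equal(unname(pr$pvalue[g, ]), unname(o$p), tolerance = 1e-8)
  }
})

test_that("degenerate constant features get zero scores, unit p, and a flag", {
  ts <- make_ts(rbind(g1 = rep(4, 5), g2 = 1:5))
  pr <- rez_scores(ts)
  expect_equal(unname(pr$score["g1", ]), rep(0, 5))
  expect_equal(unname(pr$pvalue["g1", ]), rep(1, 5))
  expect_true("g1" %in% pr$flags)
  expect_false("g2" %in% pr$flags)
})

test_that("conventional z-scores match direct arithmetic and are location-invariant", {
  ts <- make_ts(matrix(1:3, 1, 3))
  expect_equal(unname(conventional_z(ts)$score[1, ]), c(-1, 0, 1))

  ts2 <- make_ts(matrix(c(0, 0, 0, 0, 10), 1, 5))
  expect_equal(unname(conventional_z(ts2)$score[1, 5]), 8 / sd(c(0, 0, 0, 0, 10)),
               tolerance = 1e-12)
  expect_equal(unname(conventional_z(ts2)$score[1, 5]), 1.7889, tolerance = 1e-4)

  set.seed(13)
  y <- rnorm(8)
  z1 <- conventional_z(make_ts(matrix(y, 1)))$score
  z2 <- conventional_z(make_ts(matrix(y + 42, 1)))$score
  expect_equal(z1, z2, tolerance = 1e-10)
})

test_that("MAD z-scores drop zero deviations and match hand evaluation", {
  ts <- make_ts(matrix(c(1, 2, 3, 4, 100), 1, 5))
  pm <- mad_z(ts)
  # M = 3; nonzero deviations (2,1,1,97); MAD = 1.4826 * 1.5
  expect_equal(unname(pm$score[1, ]), abs(c(1, 2, 3, 4, 100) - 3) / (1.4826 * 1.5),
               tolerance = 1e-12)
  expect_equal(unname(pm$score[1, 5]), 43.62, tolerance = 1e-2)
  expect_null(pm$pvalue)
  expect_equal(unname(pm$sign[1, ]), c(-1, -1, 0, 1, 1))

  flat <- mad_z(make_ts(matrix(7, 1, 4)))
  expect_equal(unname(flat$score[1, ]), rep(0, 4))
  expect_true("g1" %in% flat$flags)

  # random features: exact agreement with direct formula evaluation
  set.seed(14)
  m <- matrix(rnorm(30 * 8), 30, 8)
  pm2 <- mad_z(make_ts(m))
  for (g in 1:30) {
    M <- median(m[g, ]); dev <- abs(m[g, ] - M)
    expect_equal(unname(pm2$score[g, ]), dev / (1.4826 * median(dev[dev > 0])),
                 tolerance = 1e-14)
  }
})

test_that("RVP is a scale-invariant simplex: rows in [0,1] summing to one", {
  expect_equal(unname(rvp(make_ts(matrix(c(0, 0, 5), 1)))$score[1, ]), c(0, 0, 1))
  expect_equal(unname(rvp(make_ts(matrix(c(3, 4), 1)))$score[1, ]), c(0.36, 0.64))

  set.seed(15)
  m <- matrix(rexp(25 * 6), 25, 6)
  r1 <- rvp(make_ts(m)); r2 <- rvp(make_ts(3.7 * m))
  expect_equal(r1$score, r2$score, tolerance = 1e-12)
  expect_true(all(r1$score >= 0 & r1$score <= 1))
  expect_equal(unname(rowSums(r1$score)), rep(1, 25), tolerance = 1e-12)
  # direct formula agreement
  expect_equal(r1$score, m^2 / rowSums(m^2), ignore_attr = TRUE, tolerance = 1e-14)

  zero <- rvp(make_ts(matrix(0, 1, 4)))
  expect_true(all(is.na(zero$score[1, ])))
  expect_true("g1" %in% zero$flags)
})

test_that("transcript profiles collapse to genes by the max-scoring transcript", {
  sc <- rbind(tx1 = c(2.0, 1.0), tx2 = c(210.3, 0.5), tx3 = c(4, 4))
  colnames(sc) <- c("brain", "liver")
  pv <- matrix(c(0.5, 1e-9, 0.2, 0.9, 0.8, 0.1), 3, 2,
               dimnames = dimnames(sc))
  prof <- dese:::new_profile(sc, pv, "rez", "transcript", lambda = sqrt(1.5))
  map <- c(tx1 = "CACNA1C", tx2 = "CACNA1C", tx3 = "OTHER")
  g <- collapse_to_gene(prof, map)
  expect_equal(unname(g$score["CACNA1C", "brain"]), 210.3)
  expect_equal(unname(g$pvalue["CACNA1C", "brain"]), 1e-9)
  expect_equal(attr(g, "representative")["CACNA1C", "brain"], "tx2",
               ignore_attr = TRUE)
  # single-transcript gene passes through unchanged
  expect_equal(unname(g$score["OTHER", ]), unname(sc["tx3", ]))
  # permutation of transcript rows does not change the collapse
  prof2 <- dese:::new_profile(sc[c(3, 1, 2), ], pv[c(3, 1, 2), ], "rez",
                              "transcript")
  g2 <- collapse_to_gene(prof2, map)
  expect_equal(g2$score[rownames(g$score), ], g$score)

  expect_warning(collapse_to_gene(prof, map[-3]), "without a gene mapping")
})

test_that("selectivity calls apply per-gene Bonferroni across transcripts", {
  set.seed(16)
  n_tx <- 26
  pv <- matrix(1, n_tx + 1, 2,
               dimnames = list(c(paste0("tx", 1:n_tx), "txB"), c("cortex", "liver")))
  sc <- matrix(1, n_tx + 1, 2, dimnames = dimnames(pv))
  map <- c(setNames(rep("GENE26", n_tx), paste0("tx", 1:n_tx)), txB = "GENE1")
  # just below and just above alpha / 26
  pv["tx1", "cortex"] <- 0.05 / 26 * 0.99
  pv["tx2", "liver"] <- 0.05 / 26 * 1.01
  prof <- dese:::new_profile(sc, pv, "rez", "transcript")
  sets <- declare_selective_genes(prof, alpha = 0.05, transcript_gene_map = map)
  expect_true("GENE26" %in% sets$cortex)
  expect_false("GENE26" %in% sets$liver)
  # alpha = 1: thresholds relax to 1/n_tx, so both sub-threshold transcripts pass
  sets1 <- declare_selective_genes(prof, alpha = 1, transcript_gene_map = map)
  expect_true("GENE26" %in% sets1$cortex)
  expect_true("GENE26" %in% sets1$liver)
  expect_false("GENE1" %in% sets1$cortex)   # its only transcript has p = 1
  # all-one p-values yield empty sets at conventional alpha
  pv[] <- 1
  prof1 <- dese:::new_profile(sc, pv, "rez", "transcript")
  empty <- declare_selective_genes(prof1, alpha = 0.05, transcript_gene_map = map)
  expect_true(all(lengths(empty) == 0))
  # measures without p-values refuse the operation
  pm <- dese:::new_profile(sc, NULL, "mad_z", "gene")
  expect_error(declare_selective_genes(pm), "no p-values")
})
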