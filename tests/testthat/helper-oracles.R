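# Independent oracles and small fixture builders shared across the suite.

# TissueSummary straight from a mean/se matrix pair (bypasses sample-level
# summarization for tests that specify tissue means directly).
make_ts <- function(mean, se = NULL) {
  mean <- as.matrix(mean)
  if (is.null(rownames(mean))) rownames(mean) <- paste0("g", seq_len(nrow(mean)))
  if (is.null(colnames(mean))) colnames(mean) <- paste0("t", seq_len(ncol(mean)))
  if (is.null(se)) se <- matrix(1, nrow(mean), ncol(mean))
  se <- as.matrix(se)
  dimnames(se) <- dimnames(mean)
  structure(list(mean = mean, se = se, tissues = colnames(mean),
                 feature_ids = rownames(mean),
                 n_samples = stats::setNames(rep(2L, ncol(mean)), colnames(mean)),
                 level = "gene"),
            class = "TissueSummary")
}

# Brute-force REZ oracle written straight from the printed update rules,
# independently of the package's code path: lm() refits per IRLS iteration.
oracle_rez <- function(y, s, lambda = sqrt(1.5), max_iter = 100, tol = 1e-6) {
  ord <- order(y, seq_along(y))   # ties by position = label order for gN ids
  ys <- y[ord]; ss <- s[ord]
  n <- length(y); pos <- seq_len(n)
  w <- 1 / ss
  fit <- stats::lm(ys ~ pos, weights = w)
  e <- stats::residuals(fit)
  for (it in seq_len(max_iter)) {
    wn <- w / sum(w)
    k <- 1.345 * sqrt(sum(wn * (e - sum(wn * e))^2))
    if (!is.finite(k) || k == 0) break
    w_new <- ifelse(abs(e) <= k, 1 / ss, k / (ss * abs(e)))
    delta <- max(abs(w_new - w))
    w <- w_new
    fit <- stats::lm(ys ~ pos, weights = w)
    e <- stats::residuals(fit)
    if (delta < tol) break
  }
  wo <- numeric(n); wo[ord] <- w
  wn <- wo / sum(wo)
  mu <- sum(wn * y)
  sig <- sqrt(sum(wn * (y - mu)^2) / (1 - sum(wn^2)))
  z <- (y - mu) / (sig * lambda)
  list(z = z, p = ifelse(z >= 0, 2 * pnorm(-z), 2 * pnorm(z)),
       mu = mu, sigma = sig, weights = wn)
}

# Exhaustive one-sided rank-sum oracle: enumerate every assignment of the
# foreground labels to ranks and count assignments with U at least as large.
oracle_wilcoxon <- function(fg, bg) {
  scores <- c(fg, bg)
  n1 <- length(fg)
  U_obs <- sum(rank(scores)[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combos <- utils::combn(length(scores), n1)
  r <- rank(scores)
  Us <- apply(combos, 2, function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2)
  list(U = U_obs, p = mean(Us >= U_obs))
}

# Tiny GCT text fixture on disk; returns the path.
write_toy_gct <- function(values, path = tempfile(fileext = ".gct")) {
  rn <- rownames(values) %||% paste0("f", seq_len(nrow(values)))
  cn <- colnames(values) %||% paste0("s", seq_len(ncol(values)))
  lines <- c("#1.2", paste(nrow(values), ncol(values), sep = "\t"),
             paste(c("Name", "Description", cn), collapse = "\t"),
             vapply(seq_len(nrow(values)), function(i)
               paste(c(rn[i], paste0("SYM", i), values[i, ]), collapse = "\t"),
               character(1)))
  writeLines(lines, path)
  path
}

`%||%` <- function(a, b) if (is.null(a)) b else a
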