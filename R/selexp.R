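# Selective-expression measures: the robust-regression z-score (REZ) built
# on Huber IRLS over rank-sorted tissue means, plus the conventional
# z-score, the MAD robust z-score and the RVP projection ratio.

#' Huber robust line fit over sorted tissue means
#'
#' Fits \eqn{y_{(i)} = \beta_0 + \beta_1 i + e_{(i)}} on the rank positions
#' `i = 1..N` of ascending-sorted tissue means by iteratively reweighted
#' least squares.  At each iteration the weights are
#' \eqn{w_{(i)} = 1/s_{(i)}} when \eqn{|e_{(i)}| \le k} and
#' \eqn{k/(s_{(i)} |e_{(i)}|)} otherwise, where the cutoff
#' `k = 1.345 * (weighted SD of the residuals)` is recomputed each
#' iteration using the current normalized weights (this weighted form is
#' invariant to the units of the SEs, unlike multiplying residuals by the
#' raw `1/s` weights).  Iteration stops when the maximum absolute weight
#' change drops below `tol`, when `k` collapses to 0 (all weighted residuals
#' equal, e.g. a perfect line), or at `max_iter`.
#'
#' The idea: after sorting, the non-selective majority of tissue means lies
#' close to a straight line; selectively expressed tissues fall off the line
#' and receive small weights, as do tissues with large standard errors.
#'
#' @param sorted_means numeric vector of ascending-sorted tissue means
#'   \eqn{y_{(i)}} (length N >= 3).
#' @param sorted_ses positive standard errors \eqn{s_{(i)}} in the same order.
#' @param k_mult the Huber tuning multiplier (1.345).
#' @param tol convergence tolerance on the max absolute weight change.
#' @param max_iter iteration cap.
#' @return object of class `HuberFit`: `beta0`, `beta1`, `residuals`,
#'   `weights` (converged, sorted order), `k`, `n_iter`, `converged`.
#' @export
fit_huber_line <- function(sorted_means, sorted_ses, k_mult = 1.345,
                           tol = 1e-6, max_iter = 100L) {
  y <- as.numeric(sorted_means)
  s <- as.numeric(sorted_ses)
  n <- length(y)
  if (n < 3) stop_input("need at least 3 tissues for the robust line fit")
  if (length(s) != n) stop_input("means and SEs differ in length")
  if (!all(is.finite(y)) || !all(is.finite(s)))
    stop_input("non-finite means or SEs")
  if (any(s <= 0)) stop_input("standard errors must be > 0")
  i <- seq_len(n)

  wls <- function(w) {
    # closed-form weighted least squares for intercept + slope
    sw <- sum(w); swx <- sum(w * i); swy <- sum(w * y)
    sxx <- sum(w * i * i); sxy <- sum(w * i * y)
    den <- sw * sxx - swx^2
    b1 <- (sw * sxy - swx * swy) / den
    b0 <- (swy - b1 * swx) / sw
    c(b0, b1)
  }

  w <- 1 / s
  beta <- wls(w)
  e <- y - beta[1] - beta[2] * i
  k <- 0
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    wn <- w / sum(w)
    k <- k_mult * sqrt(sum(wn * (e - sum(wn * e))^2))
    if (!is.finite(k) || k == 0) { converged <- TRUE; break }
    w_new <- ifelse(abs(e) <= k, 1 / s, k / (s * abs(e)))
    delta <- max(abs(w_new - w))
    w <- w_new
    beta <- wls(w)
    e <- y - beta[1] - beta[2] * i
    if (delta < tol) { converged <- TRUE; break }
  }
  structure(list(beta0 = beta[1], beta1 = beta[2], residuals = e,
                 weights = w, k = k, n_iter = iter, converged = converged),
            class = "HuberFit")
}

# Shared constructor for profile objects.
new_profile <- function(score, pvalue, measure, level, lambda = NA_real_,
                        robust_mean = NULL, robust_sd = NULL, flags = NULL,
                        sign = NULL) {
  if (!is.null(pvalue)) dimnames(pvalue) <- dimnames(score)
  structure(list(feature_ids = rownames(score), tissues = colnames(score),
                 score = score, pvalue = pvalue, measure = measure,
                 level = level, lambda = lambda, robust_mean = robust_mean,
                 robust_sd = robust_sd,
                 flags = flags %||% character(0), sign = sign),
            class = "SelectiveExpressionProfile")
}

#' @export
print.SelectiveExpressionProfile <- function(x, ...) {
  cat(sprintf("SelectiveExpressionProfile (%s, %s level): %d feature(s) x %d tissue(s)%s\n",
              x$measure, x$level, nrow(x$score), ncol(x$score),
              if (length(x$flags)) sprintf("; %d degenerate", length(x$flags)) else ""))
  invisible(x)
}

two_sided_normal_p <- function(z) ifelse(z >= 0, 2 * stats::pnorm(z, lower.tail = FALSE),
                                         2 * stats::pnorm(z))

#' Robust-regression z-scores (REZ) of selective expression
#'
#' For every feature: sort the N tissue means ascending (ties broken by
#' tissue label so results are deterministic), run [fit_huber_line()], map
#' the converged weights back to tissue order and standardize them to
#' \eqn{\grave w_i = w_i / \sum_j w_j}.  The robust mean is
#' \eqn{\hat\mu_w = \sum \grave w_i y_i} and the robust SD
#' \eqn{\hat\sigma_w = \sqrt{\sum \grave w_i (y_i - \hat\mu_w)^2 /
#' (1 - \sum \grave w_i^2)}}.  The score is
#' \eqn{\grave z_i = (y_i - \hat\mu_w)/(\hat\sigma_w \lambda)} with the
#' calibration constant \eqn{\lambda = \sqrt{1.5}} by default, and the
#' two-sided p-value comes from the standard normal CDF.
#'
#' Degenerate features (zero robust SD, or a single tissue absorbing all
#' weight) get score 0 / p 1 and are listed in the profile's `flags` so
#' downstream rank operations stay total.
#'
#' @param s a `TissueSummary` from [summarize_by_tissue()].
#' @param lambda calibration constant (default `sqrt(1.5)`).
#' @param ... passed to [fit_huber_line()].
#' @return a `SelectiveExpressionProfile` with scores, p-values, per-feature
#'   robust means/SDs and the converged weights in `attr(, "weights")`.
#' @export
rez_scores <- function(s, lambda = sqrt(1.5), ...) {
  stopifnot(inherits(s, "TissueSummary"))
  N <- length(s$tissues)
  if (N < 3) stop_input("REZ needs at least 3 tissues")
  G <- nrow(s$mean)
  score <- pval <- wmat <- matrix(NA_real_, G, N, dimnames = dimnames(s$mean))
  mu_w <- sd_w <- rep(NA_real_, G)
  flags <- character(0)
  for (g in seq_len(G)) {
    y <- s$mean[g, ]
    se <- s$se[g, ]
    ok <- which(is.finite(y) & is.finite(se))
    if (length(ok) < 3) { flags <- c(flags, rownames(s$mean)[g]); next }
    ord <- ok[order(y[ok], s$tissues[ok])]   # stable: mean then label
    fit <- fit_huber_line(y[ord], se[ord], ...)
    w <- numeric(N)
    w[ord] <- fit$weights
    wn <- w[ok] / sum(w[ok])
    mu <- sum(wn * y[ok])
    denom <- 1 - sum(wn^2)
    ss <- sum(wn * (y[ok] - mu)^2)
    mu_w[g] <- mu
    wmat[g, ok] <- wn
    if (denom <= 0 || ss <= 0) {
      score[g, ok] <- 0
      pval[g, ok] <- 1
      sd_w[g] <- 0
      flags <- c(flags, rownames(s$mean)[g])
      next
    }
    sig <- sqrt(ss / denom)
    sd_w[g] <- sig
    z <- (y[ok] - mu) / (sig * lambda)
    score[g, ok] <- z
    pval[g, ok] <- two_sided_normal_p(z)
  }
  out <- new_profile(score, pval, "rez", s$level, lambda = lambda,
                     robust_mean = mu_w, robust_sd = sd_w, flags = flags)
  attr(out, "weights") <- wmat
  out
}

#' Conventional z-scores of selective expression
#'
#' Per feature, \eqn{z_{c,i} = (y_i - \hat\mu)/\hat\sigma} with the plain
#' mean and (n-1)-denominator SD across tissues; two-sided normal p-values.
#'
#' @inheritParams rez_scores
#' @export
conventional_z <- function(s) {
  stopifnot(inherits(s, "TissueSummary"))
  if (length(s$tissues) < 2) stop_input("need at least 2 tissues")
  mu <- rowMeans(s$mean, na.rm = TRUE)
  sdv <- apply(s$mean, 1, stats::sd, na.rm = TRUE)
  flags <- rownames(s$mean)[!is.finite(sdv) | sdv == 0]
  z <- (s$mean - mu) / ifelse(sdv > 0, sdv, Inf)   # degenerate rows -> 0
  z[!is.finite(s$mean)] <- NA_real_
  p <- two_sided_normal_p(z)
  p[is.na(z)] <- NA_real_
  new_profile(z, p, "conventional_z", s$level, lambda = 1, flags = flags)
}

#' MAD robust z-scores of selective expression
#'
#' Per feature, \eqn{z_{MAD,i} = |y_i - M| / MAD} where `M` is the median of
#' the tissue means and `MAD = 1.4826 * median(|y_j - M|)` with exact-zero
#' deviations removed before the median (so identical-to-median tissues
#' cannot zero out the scale).  The score is unsigned; the deviation sign is
#' kept in the profile's `sign` field so direction is recoverable.  No
#' p-value is defined for this measure.
#'
#' @inheritParams rez_scores
#' @export
mad_z <- function(s) {
  stopifnot(inherits(s, "TissueSummary"))
  if (length(s$tissues) < 3) stop_input("need at least 3 tissues")
  G <- nrow(s$mean)
  score <- sgn <- matrix(NA_real_, G, ncol(s$mean), dimnames = dimnames(s$mean))
  flags <- character(0)
  for (g in seq_len(G)) {
    y <- s$mean[g, ]
    ok <- is.finite(y)
    M <- stats::median(y[ok])
    dev <- abs(y - M)
    nz <- dev[ok & dev > 0]
    if (!length(nz)) {
      score[g, ok] <- 0
      sgn[g, ok] <- 0
      flags <- c(flags, rownames(s$mean)[g])
      next
    }
    mad <- 1.4826 * stats::median(nz)
    score[g, ok] <- dev[ok] / mad
    sgn[g, ok] <- sign(y[ok] - M)
  }
  new_profile(score, NULL, "mad_z", s$level, flags = flags, sign = sgn)
}

#' Ratio of vector-scalar projection (RVP)
#'
#' Per feature, \eqn{RVP_i = y_i^2 / \sum_j y_j^2}: the share of tissue `i`
#' in the squared length of the expression vector.  Rows sum to 1 over
#' tissues with defined values; all-zero features are flagged and left `NA`.
#'
#' @inheritParams rez_scores
#' @export
rvp <- function(s) {
  stopifnot(inherits(s, "TissueSummary"))
  y2 <- s$mean^2
  tot <- rowSums(y2, na.rm = TRUE)
  flags <- rownames(s$mean)[tot == 0]
  score <- y2 / ifelse(tot > 0, tot, NA_real_)
  new_profile(score, NULL, "rvp", s$level, flags = flags)
}

#' Compute a selective-expression profile by name
#'
#' @param s a `TissueSummary`.
#' @param measure one of `"rez"`, `"conventional_z"` (alias `"z"`),
#'   `"mad_z"` (`"mad"`), `"rvp"`.
#' @param lambda calibration constant for REZ.
#' @export
selective_expression <- function(s, measure = c("rez", "conventional_z", "z",
                                                "mad_z", "mad", "rvp"),
                                 lambda = sqrt(1.5)) {
  measure <- match.arg(measure)
  switch(measure,
         rez = rez_scores(s, lambda = lambda),
         conventional_z = , z = conventional_z(s),
         mad_z = , mad = mad_z(s),
         rvp = rvp(s))
}

#' Collapse a transcript-level profile to gene level
#'
#' In each tissue a gene is represented by its transcript with the largest
#' selective-expression score; that transcript's p-value is carried along.
#' Transcripts missing from the map are excluded with a warning.
#'
#' @param p a transcript-level `SelectiveExpressionProfile`.
#' @param transcript_gene_map named character vector, transcript id -> gene id.
#' @return gene-level profile; `attr(, "representative")` records the chosen
#'   transcript per gene x tissue.
#' @export
collapse_to_gene <- function(p, transcript_gene_map, mode = c("max")) {
  mode <- match.arg(mode)
  stopifnot(inherits(p, "SelectiveExpressionProfile"))
  genes_of <- transcript_gene_map[p$feature_ids]
  unmapped <- p$feature_ids[is.na(genes_of)]
  if (length(unmapped)) {
    warning(sprintf("%d transcript(s) without a gene mapping excluded",
                    length(unmapped)))
  }
  keep <- !is.na(genes_of)
  sc <- p$score[keep, , drop = FALSE]
  pv <- if (!is.null(p$pvalue)) p$pvalue[keep, , drop = FALSE]
  genes_of <- genes_of[keep]
  genes <- unique(unname(genes_of))
  score <- matrix(NA_real_, length(genes), ncol(sc),
                  dimnames = list(genes, colnames(sc)))
  pval <- if (!is.null(pv)) score
  rep_tx <- matrix(NA_character_, length(genes), ncol(sc),
                   dimnames = list(genes, colnames(sc)))
  rows_by_gene <- split(seq_along(genes_of), genes_of)
  for (g in genes) {
    rows <- rows_by_gene[[g]]
    sub <- sc[rows, , drop = FALSE]
    for (t in seq_len(ncol(sub))) {
      col <- sub[, t]
      if (all(is.na(col))) next
      best <- which.max(col)   # NA-safe: which.max ignores NA
      score[g, t] <- col[best]
      rep_tx[g, t] <- rownames(sub)[best]
      if (!is.null(pv)) pval[g, t] <- pv[rows[best], t]
    }
  }
  out <- new_profile(score, pval, p$measure, "gene", lambda = p$lambda,
                     flags = p$flags)
  attr(out, "representative") <- rep_tx
  out
}

#' Per-tissue sets of significantly selectively expressed genes
#'
#' At transcript level a gene is declared selective in a tissue when any of
#' its transcripts passes `alpha / (number of transcripts of that gene)`
#' (Bonferroni within the gene).  At gene level the threshold is
#' `alpha / (number of genes)`.
#'
#' @param p a `SelectiveExpressionProfile` carrying p-values (`rez` or
#'   `conventional_z`).
#' @param alpha family-wise level (default 0.05).
#' @param correction only `"bonferroni"` is implemented.
#' @param transcript_gene_map required when `p` is transcript-level.
#' @param direction `"high"` restricts to positive scores (selectively *high*
#'   expression, the enrichment direction of interest); `"both"` keeps any
#'   significant deviation.
#' @return named list, tissue -> character vector of selective genes.
#' @export
declare_selective_genes <- function(p, alpha = 0.05,
                                    correction = c("bonferroni"),
                                    transcript_gene_map = NULL,
                                    direction = c("high", "both")) {
  correction <- match.arg(correction)
  direction <- match.arg(direction)
  stopifnot(inherits(p, "SelectiveExpressionProfile"))
  if (is.null(p$pvalue))
    stop_input("measure '%s' has no p-values; selectivity calls unsupported",
               p$measure)
  pv <- p$pvalue
  if (direction == "high") pv[p$score < 0] <- 1
  if (p$level == "gene") {
    thr <- alpha / nrow(pv)
    sets <- lapply(seq_len(ncol(pv)), function(t) {
      rownames(pv)[which(pv[, t] < thr)]
    })
  } else {
    if (is.null(transcript_gene_map))
      stop_input("transcript-level profile needs a transcript_gene_map")
    genes_of <- transcript_gene_map[p$feature_ids]
    if (anyNA(genes_of)) stop_input("unmapped transcripts in profile")
    n_tx <- table(genes_of)
    thr <- alpha / as.numeric(n_tx[genes_of])   # per-transcript threshold
    sets <- lapply(seq_len(ncol(pv)), function(t) {
      unique(unname(genes_of[which(pv[, t] < thr)]))
    })
  }
  stats::setNames(sets, colnames(pv))
}

#' Write a selective-expression profile to TSV
#'
#' Long format: feature, tissue, score, p (when defined), measure.
#'
#' @param p a `SelectiveExpressionProfile`.
#' @param path output file.
#' @param seed seed recorded in the provenance header.
#' @export
write_profile_tsv <- function(p, path, seed = NA) {
  df <- data.frame(feature = rep(p$feature_ids, times = length(p$tissues)),
                   tissue = rep(p$tissues, each = length(p$feature_ids)),
                   score = as.vector(p$score),
                   p = if (is.null(p$pvalue)) NA_real_ else as.vector(p$pvalue),
                   measure = p$measure, stringsAsFactors = FALSE)
  write_tsv_with_header(df, path,
                        params = list(measure = p$measure, level = p$level,
                                      lambda = p$lambda), seed = seed)
}
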