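# Reading multi-tissue expression data, quality control, and per-tissue
# summaries (the y_i / s_i that feed the selective-expression measures).

#' Construct a multi-tissue expression matrix
#'
#' Container for a feature-by-sample expression matrix together with the
#' sample-to-tissue assignment.  Values are expected to be TPM-like
#' (non-negative) unless they have been transformed (e.g. by
#' [rank_to_normal()]), in which case negativity is allowed.
#'
#' @param values numeric matrix, features in rows and samples in columns.
#' @param feature_ids character vector of unique feature identifiers
#'   (defaults to `rownames(values)`).
#' @param sample_ids character vector of sample identifiers (defaults to
#'   `colnames(values)`).
#' @param sample_tissue named character vector mapping every sample id to a
#'   tissue label; may be `NULL` until tissues are known.
#' @param feature_symbols optional character vector of official symbols.
#' @param level one of `"gene"`, `"transcript"`, `"exon"`.
#' @param check validate invariants (finite, non-negative unless transformed).
#' @param transformed set to `TRUE` for matrices on a transformed scale where
#'   negative values are legitimate.
#' @return an object of class `ExpressionMatrix`.
#' @export
expression_matrix <- function(values, feature_ids = rownames(values),
                              sample_ids = colnames(values),
                              sample_tissue = NULL, feature_symbols = NULL,
                              level = c("gene", "transcript", "exon"),
                              check = TRUE, transformed = FALSE) {
  level <- match.arg(level)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(feature_ids)) feature_ids <- paste0("feature", seq_len(nrow(values)))
  if (is.null(sample_ids)) sample_ids <- paste0("sample", seq_len(ncol(values)))
  feature_ids <- as.character(feature_ids)
  sample_ids <- as.character(sample_ids)
  if (check) {
    if (anyDuplicated(feature_ids))
      stop_input("feature ids must be unique")
    if (length(feature_ids) != nrow(values) || length(sample_ids) != ncol(values))
      stop_input("id lengths do not match matrix dimensions")
    finite_ok <- is.finite(values) | is.na(values)
    if (!all(finite_ok))
      stop_input("expression values must be finite or NA")
    if (!transformed && any(values < 0, na.rm = TRUE))
      stop_input("TPM-scale expression values must be >= 0")
    if (!is.null(sample_tissue)) {
      missing_map <- setdiff(sample_ids, names(sample_tissue))
      if (length(missing_map))
        stop_input("samples without a tissue label: %s",
                   paste(utils::head(missing_map, 5), collapse = ", "))
    }
  }
  dimnames(values) <- list(feature_ids, sample_ids)
  structure(list(values = values, feature_ids = feature_ids,
                 sample_ids = sample_ids,
                 sample_tissue = if (is.null(sample_tissue)) NULL
                                 else sample_tissue[sample_ids],
                 feature_symbols = feature_symbols, level = level,
                 transformed = transformed),
            class = "ExpressionMatrix")
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix: %d %s feature(s) x %d sample(s)%s\n",
              nrow(x$values), x$level, ncol(x$values),
              if (is.null(x$sample_tissue)) ""
              else sprintf(" in %d tissue(s)", length(unique(x$sample_tissue)))))
  invisible(x)
}

#' @export
dim.ExpressionMatrix <- function(x) dim(x$values)

# Subset an ExpressionMatrix by feature index/ids (rows) or samples (cols).
subset_expression <- function(m, features = NULL, samples = NULL) {
  v <- m$values
  if (!is.null(features)) v <- v[features, , drop = FALSE]
  if (!is.null(samples)) v <- v[, samples, drop = FALSE]
  sym <- m$feature_symbols
  if (!is.null(sym)) {
    names(sym) <- m$feature_ids
    sym <- unname(sym[rownames(v)])
  }
  expression_matrix(v, sample_tissue = m$sample_tissue, feature_symbols = sym,
                    level = m$level, transformed = m$transformed, check = FALSE)
}

#' Read a GCT 1.2 expression file
#'
#' GCT is the tab-delimited dialect used by GTEx TPM releases: a `#1.2`
#' version line, a `rows<TAB>cols` dimension line, then a header of
#' `Name`, `Description` and sample ids.
#'
#' @param path path to an (uncompressed or gz) GCT file.
#' @param level feature level recorded on the result.
#' @return an [expression_matrix()] with symbols from the Description column.
#' @export
read_gct <- function(path, level = "gene") {
  lines <- readLines(path)
  if (length(lines) < 3) stop_input("GCT file too short: %s", path)
  if (!grepl("^#1\\.2", lines[[1]]))
    stop_input("not a GCT 1.2 file (version line is %s)", lines[[1]])
  dims <- suppressWarnings(as.integer(strsplit(lines[[2]], "\t")[[1]]))
  if (length(dims) < 2 || anyNA(dims[1:2]))
    stop_input("malformed GCT dimension line: %s", lines[[2]])
  body <- utils::read.delim(text = lines[-(1:2)], check.names = FALSE,
                            stringsAsFactors = FALSE)
  if (!all(c("Name", "Description") %in% names(body)[1:2]))
    stop_input("GCT header must start with Name and Description columns")
  n_samp <- ncol(body) - 2L
  if (nrow(body) != dims[1] || n_samp != dims[2])
    stop_input("GCT dimension mismatch: header declares %d x %d, body has %d x %d",
               dims[1], dims[2], nrow(body), n_samp)
  vals <- as.matrix(body[, -(1:2), drop = FALSE])
  if (!is.numeric(vals)) {
    for (j in seq_len(ncol(vals))) {
      col <- suppressWarnings(as.numeric(vals[, j]))
      bad <- which(is.na(col) & !is.na(body[[j + 2]]) & body[[j + 2]] != "NA")
      if (length(bad))
        stop_input("non-numeric value '%s' at row %d (feature %s), column %s",
                   body[bad[1], j + 2], bad[1], body$Name[bad[1]],
                   names(body)[j + 2])
      vals[, j] <- col
    }
    storage.mode(vals) <- "double"
  }
  rownames(vals) <- body$Name
  expression_matrix(vals, feature_symbols = body$Description, level = level)
}

#' Write a GCT 1.2 expression file
#'
#' @param m an [expression_matrix()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gct <- function(m, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("#1.2", paste(nrow(m$values), ncol(m$values), sep = "\t")), con)
  df <- data.frame(Name = m$feature_ids,
                   Description = m$feature_symbols %||% m$feature_ids,
                   m$values, check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a plain TSV expression matrix
#'
#' First column = feature id, remaining columns = samples; `NA` cells allowed.
#'
#' @inheritParams read_gct
#' @export
read_expression_tsv <- function(path, level = "gene") {
  df <- read_tsv_skip_comments(path, check.names = FALSE)
  vals <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(vals) <- "double"
  rownames(vals) <- as.character(df[[1]])
  expression_matrix(vals, level = level)
}

#' Read a two-column sample-to-tissue map
#'
#' @param path TSV with columns `sample` and `tissue` (any header names; the
#'   first two columns are used).
#' @return named character vector (names = sample ids).
#' @export
read_sample_map <- function(path) {
  df <- read_tsv_skip_comments(path)
  stats::setNames(as.character(df[[2]]), as.character(df[[1]]))
}

#' Summarize expression per tissue
#'
#' Computes, for every feature, the mean and standard error of expression in
#' each tissue.  The standard error is the sample standard deviation
#' (n − 1 denominator) divided by sqrt(n); when a tissue contributes a single
#' observation the SE is set to 1 so that single-subject datasets (e.g.
#' BrainSpan regions) remain usable.  Exact-zero SEs from identical
#' replicates are floored at `1e-6 * (mean expression + 1)` so downstream
#' z-scores stay finite; affected features are recorded in
#' `attr(, "se_floored")`.
#'
#' @param m an [expression_matrix()].
#' @param sample_tissue named character vector; defaults to the map stored in
#'   `m`.
#' @return an object of class `TissueSummary` with fields `mean`, `se`
#'   (feature x tissue matrices), `tissues`, `feature_ids`, `n_samples`.
#' @export
summarize_by_tissue <- function(m, sample_tissue = m$sample_tissue) {
  if (is.null(sample_tissue)) stop_input("no sample-to-tissue map available")
  sample_tissue <- sample_tissue[m$sample_ids]
  if (anyNA(sample_tissue)) stop_input("samples without a tissue label")
  tissues <- unique(unname(sample_tissue))
  G <- nrow(m$values)
  mu <- se <- matrix(NA_real_, G, length(tissues),
                     dimnames = list(m$feature_ids, tissues))
  n_samples <- integer(length(tissues))
  names(n_samples) <- tissues
  for (t in seq_along(tissues)) {
    x <- m$values[, sample_tissue == tissues[t], drop = FALSE]
    n_samples[t] <- ncol(x)
    if (ncol(x) == 0) stop_input("tissue '%s' has zero samples", tissues[t])
    nobs <- rowSums(!is.na(x))
    mt <- rowMeans(x, na.rm = TRUE)
    mt[nobs == 0] <- NA_real_
    dev2 <- rowSums((x - mt)^2, na.rm = TRUE)
    st <- sqrt(dev2 / pmax(nobs - 1, 1)) / sqrt(pmax(nobs, 1))
    st[nobs == 1] <- 1          # single-subject rule
    st[nobs == 0] <- NA_real_
    mu[, t] <- mt
    se[, t] <- st
  }
  eps <- 1e-6 * (mean(mu, na.rm = TRUE) + 1)
  floored <- which(se <= 0 & !is.na(se), arr.ind = TRUE)
  if (nrow(floored)) se[floored] <- eps
  out <- structure(list(mean = mu, se = se, tissues = tissues,
                        feature_ids = m$feature_ids, n_samples = n_samples,
                        level = m$level),
                   class = "TissueSummary")
  attr(out, "se_floored") <- unique(rownames(mu)[floored[, 1]])
  out
}

#' @export
print.TissueSummary <- function(x, ...) {
  cat(sprintf("TissueSummary: %d feature(s) x %d tissue(s) (%d-%d samples/tissue)\n",
              nrow(x$mean), length(x$tissues), min(x$n_samples), max(x$n_samples)))
  invisible(x)
}

subset_summary <- function(s, features) {
  s$mean <- s$mean[features, , drop = FALSE]
  s$se <- s$se[features, , drop = FALSE]
  s$feature_ids <- rownames(s$mean)
  s
}

#' Remove features with negligible expression
#'
#' Two modes mirror the published QC variants: `all_tissues` drops features
#' with at most `cutoff` TPM in every tissue; `k_or_more_tissues` drops
#' features whose expression is below `cutoff` in at least `k` tissues.
#'
#' @param x an [expression_matrix()] (filtered on sample values) or a
#'   `TissueSummary` (filtered on tissue means).
#' @param cutoff TPM threshold (default 0.01).
#' @param mode filtering rule, see above.
#' @param k tissue count for `k_or_more_tissues`.
#' @return object of the same class with failing features removed.
#' @export
filter_low_expression <- function(x, cutoff = 0.01,
                                  mode = c("all_tissues", "k_or_more_tissues"),
                                  k = NULL) {
  mode <- match.arg(mode)
  stopifnot(cutoff >= 0)
  vals <- if (inherits(x, "TissueSummary")) x$mean
          else if (inherits(x, "ExpressionMatrix")) x$values
          else stop_input("unsupported input of class %s", class(x)[1])
  if (mode == "all_tissues") {
    keep <- apply(vals, 1, function(v) any(v > cutoff, na.rm = TRUE))
  } else {
    if (is.null(k) || k < 1 || k > ncol(vals))
      stop_input("k must be in 1..%d for k_or_more_tissues mode", ncol(vals))
    keep <- rowSums(vals < cutoff, na.rm = TRUE) < k
  }
  if (inherits(x, "TissueSummary")) subset_summary(x, which(keep))
  else subset_expression(x, which(keep))
}

#' Exclude tissues poorly correlated with the rest
#'
#' Computes pairwise Pearson correlations between per-tissue mean-expression
#' vectors (across features) and drops every tissue whose *median*
#' correlation with the other tissues falls below `threshold`.  Tissues with
#' a constant mean vector (correlation undefined) are excluded with reason
#' `"degenerate"`.
#'
#' @param s a `TissueSummary`.
#' @param threshold median-correlation cutoff (default 0.3).
#' @return list with elements `summary` (survivors) and `excluded`
#'   (data.frame of tissue, median_correlation, reason).
#' @export
tissue_correlation_qc <- function(s, threshold = 0.3) {
  stopifnot(inherits(s, "TissueSummary"))
  if (length(s$tissues) < 3) stop_input("need at least 3 tissues")
  if (nrow(s$mean) < 2) stop_input("correlation undefined with fewer than 2 features")
  sds <- apply(s$mean, 2, stats::sd, na.rm = TRUE)
  degen <- which(!is.finite(sds) | sds == 0)
  C <- suppressWarnings(stats::cor(s$mean, use = "pairwise.complete.obs"))
  diag(C) <- NA
  med <- apply(C, 2, stats::median, na.rm = TRUE)
  low <- which(med < threshold)
  excl_idx <- union(degen, low)
  excluded <- data.frame(tissue = s$tissues[excl_idx],
                         median_correlation = med[excl_idx],
                         reason = ifelse(excl_idx %in% degen, "degenerate",
                                         "low_correlation"),
                         stringsAsFactors = FALSE, row.names = NULL)
  keep <- setdiff(seq_along(s$tissues), excl_idx)
  s$mean <- s$mean[, keep, drop = FALSE]
  s$se <- s$se[, keep, drop = FALSE]
  s$tissues <- s$tissues[keep]
  s$n_samples <- s$n_samples[keep]
  list(summary = s, excluded = excluded)
}

#' Rank-based inverse-normal transform per sample
#'
#' Within each sample the features are ranked (average ranks on ties) and
#' mapped to standard-normal quantiles \eqn{\Phi^{-1}((r - 0.5)/G)}.  This
#' is the standardization applied to microarray samples so that every sample
#' shares the same marginal distribution, removing batch/scale effects.
#'
#' @param m an [expression_matrix()].
#' @return a transformed [expression_matrix()] (negative values allowed).
#' @export
rank_to_normal <- function(m) {
  v <- m$values
  G <- nrow(v)
  if (G < 2) stop_input("need at least 2 features")
  out <- apply(v, 2, function(col) {
    if (length(unique(col[!is.na(col)])) < 2)
      stop_input("constant sample: rank transform undefined")
    r <- rank(col, ties.method = "average", na.last = "keep")
    stats::qnorm((r - 0.5) / sum(!is.na(col)))
  })
  dimnames(out) <- dimnames(v)
  expression_matrix(out, sample_tissue = m$sample_tissue,
                    feature_symbols = m$feature_symbols, level = m$level,
                    transformed = TRUE)
}

#' Remove samples with aberrant correlation to their group
#'
#' Within each sample group (by default all samples; typically one GEO series
#' of one tissue), all pairwise Pearson correlations are pooled.  A sample is
#' removed when its median pairwise correlation falls below the `low_q`
#' quantile of the pooled distribution (outlier sample) or when its maximum
#' pairwise correlation exceeds the `high_q` quantile (near-duplicate pair).
#' Groups with fewer than 4 samples are passed through with a warning.
#'
#' @param m an [expression_matrix()].
#' @param low_q,high_q pooled-correlation quantiles (defaults 0.05 / 0.95).
#' @param groups optional factor/character of length `ncol` assigning samples
#'   to filtering groups.
#' @return list with `matrix` (survivors) and `removed` (data.frame of
#'   sample, group, reason).
#' @export
sample_correlation_filter <- function(m, low_q = 0.05, high_q = 0.95,
                                      groups = NULL) {
  stopifnot(low_q >= 0, high_q <= 1, low_q < high_q)
  if (is.null(groups)) groups <- rep("all", ncol(m$values))
  groups <- as.character(groups)
  removed <- data.frame(sample = character(0), group = character(0),
                        reason = character(0), stringsAsFactors = FALSE)
  for (g in unique(groups)) {
    idx <- which(groups == g)
    if (length(idx) < 4) {
      warning(sprintf("group '%s' has %d (<4) samples; passed through unfiltered",
                      g, length(idx)))
      next
    }
    C <- suppressWarnings(stats::cor(m$values[, idx, drop = FALSE],
                                     use = "pairwise.complete.obs"))
    pooled <- C[upper.tri(C)]
    lo <- stats::quantile(pooled, low_q, na.rm = TRUE, names = FALSE)
    hi <- stats::quantile(pooled, high_q, na.rm = TRUE, names = FALSE)
    diag(C) <- NA
    med <- apply(C, 2, stats::median, na.rm = TRUE)
    mx <- suppressWarnings(apply(C, 2, max, na.rm = TRUE))
    flag_low <- med < lo
    flag_high <- mx > hi
    for (j in which(flag_low | flag_high)) {
      removed <- rbind(removed, data.frame(
        sample = m$sample_ids[idx[j]], group = g,
        reason = if (flag_high[j]) "high_correlation" else "low_correlation",
        stringsAsFactors = FALSE))
    }
  }
  keep <- setdiff(m$sample_ids, removed$sample)
  list(matrix = subset_expression(m, samples = keep), removed = removed)
}

#' Drop features with too few observed values
#'
#' @param m an [expression_matrix()].
#' @param min_obs features with `min_obs` or fewer non-missing values are
#'   removed (default 9, i.e. features need at least 10 observations).
#' @export
drop_sparse_features <- function(m, min_obs = 9L) {
  stopifnot(min_obs >= 0)
  keep <- rowSums(!is.na(m$values)) > min_obs
  subset_expression(m, which(keep))
}

#' Restrict features to those with an official symbol
#'
#' Optional id-to-symbol filter mirroring the exclusion of Ensembl ids with
#' no official gene symbol; operates on a caller-supplied map (no lookup
#' service is queried).
#'
#' @param m an [expression_matrix()].
#' @param id_symbol named character vector mapping feature id to symbol;
#'   features absent from the map, or mapping to `NA`/empty, are dropped.
#' @export
filter_unmapped_symbols <- function(m, id_symbol) {
  sym <- id_symbol[m$feature_ids]
  keep <- !is.na(sym) & nzchar(sym)
  out <- subset_expression(m, which(keep))
  out$feature_symbols <- unname(sym[keep])
  out
}
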