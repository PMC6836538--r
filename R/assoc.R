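# Gene-based association from GWAS summary statistics: variant-to-gene
# assignment, the effective-chi-square (ECS) gene p-value with LD-aware
# degrees of freedom, and the conditional entry procedure that removes
# redundantly associated genes.

#' Read GWAS summary statistics from a delimited table
#'
#' @param path TSV/CSV file.
#' @param cols named list mapping the required fields `snp`, `chr`, `bp`,
#'   `p` to column names in the file.
#' @param sep field separator (default tab).
#' @return data.frame with columns `variant_id`, `chrom`, `pos`, `pvalue`.
#' @export
read_gwas_tsv <- function(path, cols = list(snp = "SNP", chr = "CHR",
                                            bp = "BP", p = "P"), sep = "\t") {
  df <- utils::read.delim(path, sep = sep, comment.char = "#",
                          stringsAsFactors = FALSE)
  missing_cols <- setdiff(unlist(cols), names(df))
  if (length(missing_cols))
    stop_input("GWAS table lacks column(s): %s", paste(missing_cols, collapse = ", "))
  out <- data.frame(variant_id = as.character(df[[cols$snp]]),
                    chrom = as.character(df[[cols$chr]]),
                    pos = as.integer(df[[cols$bp]]),
                    pvalue = as.numeric(df[[cols$p]]),
                    stringsAsFactors = FALSE)
  if (any(!is.finite(out$pvalue) | out$pvalue <= 0 | out$pvalue > 1))
    stop_input("GWAS p-values must lie in (0, 1]")
  if (any(out$pos <= 0)) stop_input("variant positions must be positive")
  out
}

#' Read a gene model table
#'
#' Accepts a RefSeq-style TSV (columns gene_id, symbol, chrom, strand,
#' start, end; 1-based inclusive) or BED (`format = "bed"`; 0-based
#' half-open, converted to 1-based inclusive via start+1).
#'
#' @param path input file.
#' @param format `"tsv"` or `"bed"`.
#' @export
read_gene_model <- function(path, format = c("tsv", "bed")) {
  format <- match.arg(format)
  if (format == "tsv") {
    df <- read_tsv_skip_comments(path)
    need <- c("gene_id", "chrom", "start", "end")
    if (!all(need %in% names(df)))
      stop_input("gene model needs columns: %s", paste(need, collapse = ", "))
    out <- data.frame(gene_id = as.character(df$gene_id),
                      symbol = as.character(df$symbol %||% df$gene_id),
                      chrom = as.character(df$chrom),
                      strand = as.character(df$strand %||% "+"),
                      start = as.integer(df$start), end = as.integer(df$end),
                      stringsAsFactors = FALSE)
  } else {
    df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
    out <- data.frame(gene_id = as.character(df[[4]]),
                      symbol = as.character(df[[4]]),
                      chrom = as.character(df[[1]]),
                      strand = if (ncol(df) >= 6) as.character(df[[6]]) else "+",
                      start = as.integer(df[[2]]) + 1L,   # 0-based -> 1-based
                      end = as.integer(df[[3]]),
                      stringsAsFactors = FALSE)
  }
  if (any(out$start > out$end)) stop_input("gene model has start > end")
  out
}

#' Assign GWAS variants to genes within a flanking window
#'
#' A variant lands on every gene whose body extended by `flank` bp contains
#' its position on the same chromosome; variants may be shared by
#' overlapping genes.  Genes receiving no variants are omitted.
#'
#' @param gwas data.frame as from [read_gwas_tsv()].
#' @param model gene-model data.frame ([read_gene_model()]).
#' @param flank window in bp on each side of the gene body (default 5000).
#' @return named list, gene id -> character vector of variant ids.
#' @export
assign_variants_to_genes <- function(gwas, model, flank = 5000) {
  stopifnot(flank >= 0)
  out <- vector("list", nrow(model))
  names(out) <- model$gene_id
  by_chr <- split(gwas[, c("variant_id", "pos")], gwas$chrom)
  for (i in seq_len(nrow(model))) {
    g <- by_chr[[model$chrom[i]]]
    if (is.null(g)) next
    hit <- g$pos >= model$start[i] - flank & g$pos <= model$end[i] + flank
    if (any(hit)) out[[i]] <- g$variant_id[hit]
  }
  out[!vapply(out, is.null, TRUE)]
}

# Drop variants that are (near-)perfect LD copies of an earlier variant in
# the set: redundant association carries no information and breaks the
# moment-matching variance otherwise.
dedup_perfect_ld <- function(ids, R, r2_max = 1 - 1e-6) {
  if (length(ids) < 2) return(ids)
  keep <- 1L
  for (j in 2:length(ids)) {
    if (max(R[j, keep]^2) < r2_max) keep <- c(keep, j)
  }
  ids[keep]
}

#' Effective-chi-square gene-based association p-value
#'
#' Each variant p-value is converted to a 1-df chi-square
#' `q_k = qchisq(p_k, 1, lower.tail = FALSE)` and the statistic is
#' `T = sum(q_k)` over the gene's `m` variants after collapsing
#' perfect-LD duplicates.  Under the null `E[T] = m` and
#' `Var[T] = 2m + 4 * sum_{i<j} r_ij^2` (for jointly normal variant
#' z-scores, `cor(q_i, q_j) = r_ij^2`), so `T` is referred to a scaled
#' chi-square with effective degrees of freedom `f = 2 E^2 / Var` by moment
#' matching: `raw_p = P(chisq_f > T f / E)`.  LD thus shrinks the effective
#' number of independent chi-squares the gene contributes.
#'
#' @param variant_ps numeric vector of variant p-values in (0, 1].
#' @param ld_matrix correlation matrix of the variants' reference genotypes
#'   (defaults to the identity, i.e. LD-free).
#' @param min_p floor applied to incoming p-values (default 1e-300).
#' @return list with `p`, `statistic` (T), `edf` (f), `n_variants` (after
#'   duplicate collapse).
#' @export
ecs_gene_p <- function(variant_ps, ld_matrix = NULL, min_p = 1e-300) {
  m0 <- length(variant_ps)
  if (m0 < 1) stop_input("need at least one variant")
  p <- clamp_p(as.numeric(variant_ps), min_p)
  if (any(p > 1)) stop_input("p-values must be <= 1")
  if (is.null(ld_matrix)) ld_matrix <- diag(m0)
  ld_matrix <- as.matrix(ld_matrix)
  idx <- seq_len(m0)
  if (m0 > 1) {
    keep <- 1L
    for (j in 2:m0) if (max(ld_matrix[j, keep]^2) < 1 - 1e-6) keep <- c(keep, j)
    idx <- keep
  }
  p <- p[idx]
  R <- ld_matrix[idx, idx, drop = FALSE]
  m <- length(idx)
  q <- stats::qchisq(p, df = 1, lower.tail = FALSE)
  Tstat <- sum(q)
  E <- m
  V <- 2 * m + 4 * sum(R[upper.tri(R)]^2)
  f <- 2 * E^2 / V
  list(p = stats::pchisq(Tstat * f / E, df = f, lower.tail = FALSE),
       statistic = Tstat, edf = f, n_variants = m)
}

#' Conditional effective-chi-square gene analysis
#'
#' Processes genes one by one in the supplied entry order.  Each candidate's
#' unsigned variant z-scores (`|z| = qnorm(1 - p/2)`) are projected onto the
#' span of all previously *selected* genes' variants using the LD
#' correlations: `z_resid = z_c - R_cs R_ss^{-1} z_s`, with residual
#' correlation `R_cc - R_cs R_ss^{-1} R_sc`.  Residual variances are floored
#' and renormalized to a correlation matrix, residual z-scores standardized
#' accordingly, and [ecs_gene_p()] applied to the residual p-values.  A gene
#' is selected when its conditional p passes Bonferroni at
#' `alpha / (number of candidates)`; its variants then join the conditioning
#' set.  A gene in perfect LD with an already-selected gene is fully
#' explained away (residual z ~ 0, conditional p ~ 1).
#'
#' Genes whose raw p-value misses the permissive screen `screen_p` skip the
#' projection (their conditional p equals the raw p) — they cannot reach the
#' Bonferroni threshold but stay in the output table.
#'
#' @param ordered_genes character vector: entry order (first = highest
#'   priority).  Must cover all candidates.
#' @param gene_variants named list, gene -> variant ids
#'   ([assign_variants_to_genes()]).
#' @param variant_p named numeric vector of variant p-values.
#' @param ld an `LdReference`.
#' @param alpha family-wise level for selection (default 0.05).
#' @param screen_p raw-p screen for entering the projection (default 0.01;
#'   `1` disables the screen).
#' @param ridge ridge added to the selected-set correlation before inversion.
#' @param var_floor floor on residual variances before renormalization.
#' @return data.frame of class `GeneAssocResult`: gene_id, n_variants,
#'   raw_p, cond_p, entry_rank, selected.
#' @export
conditional_ecs <- function(ordered_genes, gene_variants, variant_p, ld,
                            alpha = 0.05, screen_p = 0.01,
                            ridge = 1e-6, var_floor = 1e-4) {
  missing_genes <- setdiff(ordered_genes, names(gene_variants))
  if (length(missing_genes))
    stop_input("ordered genes missing from gene_variants: %s",
               paste(utils::head(missing_genes, 5), collapse = ", "))
  n_cand <- length(ordered_genes)
  thr <- alpha / n_cand
  raw <- vapply(ordered_genes, function(g) {
    vs <- gene_variants[[g]]
    ecs_gene_p(variant_p[vs], ld_cor(ld, vs))$p
  }, 1.0)
  cond <- raw
  selected <- logical(n_cand)
  names(selected) <- ordered_genes
  sel_variants <- character(0)
  z_all <- stats::qnorm(clamp_p(variant_p, warn = FALSE) / 2, lower.tail = FALSE)
  for (k in seq_len(n_cand)) {
    g <- ordered_genes[k]
    vs <- gene_variants[[g]]
    if (raw[k] <= screen_p && length(sel_variants)) {
      sel <- dedup_perfect_ld(sel_variants, ld_cor(ld, sel_variants))
      Rss <- ld_cor(ld, sel) + diag(ridge, length(sel))
      Rcs <- ld_cor(ld, vs, sel)
      A <- Rcs %*% solve(Rss)
      zr <- as.numeric(z_all[vs] - A %*% z_all[sel])
      Rrr <- ld_cor(ld, vs) - A %*% t(Rcs)
      d <- pmax(diag(Rrr), var_floor)
      zrn <- zr / sqrt(d)
      Rn <- Rrr / sqrt(outer(d, d))
      diag(Rn) <- 1
      Rn[Rn > 1] <- 1
      Rn[Rn < -1] <- -1
      pr <- 2 * stats::pnorm(abs(zrn), lower.tail = FALSE)
      cond[k] <- ecs_gene_p(pr, Rn)$p
    }
    if (cond[k] < thr) {
      selected[k] <- TRUE
      sel_variants <- union(sel_variants, vs)
    }
  }
  out <- data.frame(gene_id = ordered_genes,
                    n_variants = vapply(gene_variants[ordered_genes], length, 1L),
                    raw_p = unname(raw), cond_p = unname(cond),
                    entry_rank = seq_len(n_cand),
                    selected = unname(selected),
                    stringsAsFactors = FALSE, row.names = NULL)
  class(out) <- c("GeneAssocResult", "data.frame")
  out
}

#' Significant genes after multiple-testing correction
#'
#' @param results a `GeneAssocResult` data.frame.
#' @param alpha family-wise level (default 0.05).
#' @param correction only `"bonferroni"`.
#' @param use `"cond_p"` (default) or `"raw_p"`.
#' @return character vector of gene ids with p below `alpha / n_tested`.
#' @export
significant_genes <- function(results, alpha = 0.05,
                              correction = c("bonferroni"), use = "cond_p") {
  correction <- match.arg(correction)
  p <- results[[use]]
  results$gene_id[p < alpha / nrow(results)]
}
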