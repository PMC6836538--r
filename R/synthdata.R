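# Synthetic data: multi-tissue expression with planted selectively
# expressed gene sets, a tiled gene model, and LD-blocked GWAS z-scores
# whose causal genes concentrate in one designated driver tissue.  Every
# stage of the pipeline — and the end-to-end loop — is testable from these
# generators without any external download.

#' Specification of a planted synthetic scenario
#'
#' Defaults describe the study conditions used throughout the package's
#' tests: 40 tissues x 1000 genes with 10 RNA-seq-like samples per tissue;
#' 40% of genes selectively expressed (split evenly and disjointly across
#' tissues, 10 genes each); a 5-SD selective mean shift; 10 causal genes all
#' drawn from the driver tissue's selective set; 4 variants per gene in
#' exchangeable LD blocks of 4 variants (rho 0.5), i.e. LD confined within
#' gene bodies so gene-level association is cleanly attributable;
#' per-variant joint non-centrality 2 (marginal |z| around 5 at causal
#' variants).  Setting `ld_block_size` to a multiple of
#' `variants_per_gene` (with a gene gap below twice the flank irrelevant
#' here) makes blocks span adjacent genes, turning the block-mates of
#' causal genes into LD shadows — the construction used to probe
#' conditional redundancy removal.
#'
#' @param n_tissues,n_genes,n_samples_per_tissue scenario dimensions.
#' @param transcripts_per_gene transcripts per gene (1 = gene-level).
#' @param driver_tissue label of the planted driver tissue.
#' @param selective_gene_fraction fraction of genes selectively expressed in
#'   some tissue (partitioned evenly across tissues).
#' @param selective_effect mean shift of planted genes in their tissue, in
#'   units of the sample noise SD.
#' @param n_causal_genes number of trait genes carrying GWAS signal.
#' @param causal_overlap fraction of causal genes drawn from the driver
#'   tissue's selective set (rest drawn from non-selective genes).
#' @param variants_per_gene variants placed in each gene body.
#' @param ld_block_size variants per exchangeable LD block (blocks are laid
#'   along the genome irrespective of gene boundaries).
#' @param ld_rho within-block correlation.
#' @param gwas_ncp joint per-variant non-centrality at causal-gene variants;
#'   marginal variant means are `R %*% delta`, so LD spreads signal into
#'   shadow genes.
#' @param gene_length,gene_gap gene-body length and intergenic gap in bp.
#' @param baseline_mean,noise_sd log2-scale expression baseline and sample
#'   noise SD.
#' @param distribution `"normal"` (log-normal TPM) or `"uniform"` noise on
#'   the log scale.
#' @param value_scale `"tpm"` exponentiates the log-scale values to
#'   TPM-like positives (RNA-seq emulation); `"normal"` keeps them as-is,
#'   emulating microarray data after the rank-based inverse-normal
#'   transform (tissue means then are exactly exchangeable normals under
#'   the null).
#' @param seed integer seed recorded in all outputs.
#' @return list of class `PlantingSpec`.
#' @export
planting_spec <- function(n_tissues = 40L, n_genes = 1000L,
                          transcripts_per_gene = 1L,
                          n_samples_per_tissue = 10L,
                          driver_tissue = "tissue01",
                          selective_gene_fraction = 0.4,
                          selective_effect = 5,
                          n_causal_genes = 10L, causal_overlap = 1,
                          variants_per_gene = 4L, ld_block_size = 4L,
                          ld_rho = 0.5, gwas_ncp = 2,
                          gene_length = 10000L, gene_gap = 20000L,
                          baseline_mean = 3, noise_sd = 1,
                          distribution = c("normal", "uniform"),
                          value_scale = c("tpm", "normal"),
                          seed = 1L) {
  distribution <- match.arg(distribution)
  value_scale <- match.arg(value_scale)
  stopifnot(selective_gene_fraction >= 0, selective_gene_fraction <= 1,
            causal_overlap >= 0, causal_overlap <= 1,
            selective_effect >= 0, ld_rho >= 0, ld_rho < 1,
            n_tissues >= 1, n_genes >= 1, n_samples_per_tissue >= 1)
  if (selective_effect == 0 && selective_gene_fraction > 0)
    warning("selective_effect = 0 with a positive selective fraction: planted truth is unidentifiable")
  spec <- list(n_tissues = as.integer(n_tissues), n_genes = as.integer(n_genes),
               transcripts_per_gene = as.integer(transcripts_per_gene),
               n_samples_per_tissue = as.integer(n_samples_per_tissue),
               driver_tissue = driver_tissue,
               selective_gene_fraction = selective_gene_fraction,
               selective_effect = selective_effect,
               n_causal_genes = as.integer(n_causal_genes),
               causal_overlap = causal_overlap,
               variants_per_gene = as.integer(variants_per_gene),
               ld_block_size = as.integer(ld_block_size), ld_rho = ld_rho,
               gwas_ncp = gwas_ncp, gene_length = as.integer(gene_length),
               gene_gap = as.integer(gene_gap), baseline_mean = baseline_mean,
               noise_sd = noise_sd, distribution = distribution,
               value_scale = value_scale, seed = as.integer(seed))
  class(spec) <- "PlantingSpec"
  spec
}

spec_tissues <- function(spec) sprintf("tissue%02d", seq_len(spec$n_tissues))
spec_genes <- function(spec) sprintf("gene%04d", seq_len(spec$n_genes))

# Deterministic partition of the selective genes across tissues: the first
# n_sel gene ids are split round-robin, so the truth is reproducible from
# the spec alone (no RNG involved).
planted_sets <- function(spec) {
  tissues <- spec_tissues(spec)
  genes <- spec_genes(spec)
  n_sel <- round(spec$selective_gene_fraction * spec$n_genes)
  per <- floor(n_sel / spec$n_tissues)
  sets <- stats::setNames(vector("list", spec$n_tissues), tissues)
  idx <- 0L
  for (t in tissues) {
    sets[[t]] <- if (per > 0) genes[idx + seq_len(per)] else character(0)
    idx <- idx + per
  }
  sets
}

#' Generate a synthetic multi-tissue expression matrix
#'
#' Per gene: a shared log2-scale baseline plus i.i.d. per-sample noise;
#' genes planted as selective in a tissue get a `selective_effect * noise_sd`
#' mean shift in that tissue's samples.  Values are exponentiated to
#' TPM-like positives.  With `transcripts_per_gene > 1` every transcript of
#' a gene shares the gene's (shifted) mean plus a small transcript offset.
#'
#' @param spec a [planting_spec()].
#' @return list: `matrix` (an [expression_matrix()] with sample-tissue map),
#'   `truth` (tissue -> planted selective gene ids),
#'   `transcript_gene_map` (named vector; `NULL` at gene level).
#' @export
make_expression <- function(spec) {
  stopifnot(inherits(spec, "PlantingSpec"))
  set.seed(spec$seed)
  tissues <- spec_tissues(spec)
  genes <- spec_genes(spec)
  truth <- planted_sets(spec)
  ntx <- spec$transcripts_per_gene
  feat <- if (ntx > 1) {
    as.vector(t(outer(genes, seq_len(ntx),
                      function(g, k) sprintf("%s.tx%d", g, k))))
  } else genes
  tx_gene <- if (ntx > 1) stats::setNames(rep(genes, each = ntx), feat) else NULL
  n_samp <- spec$n_samples_per_tissue
  samples <- as.vector(vapply(tissues, function(t)
    sprintf("%s_s%02d", t, seq_len(n_samp)), character(n_samp)))
  sample_tissue <- stats::setNames(rep(tissues, each = n_samp), samples)

  base_gene <- stats::rnorm(length(genes), spec$baseline_mean, 1)
  names(base_gene) <- genes
  tx_off <- if (ntx > 1) stats::rnorm(length(feat), 0, 0.25) else rep(0, length(feat))
  shift <- matrix(0, length(genes), length(tissues),
                  dimnames = list(genes, tissues))
  for (t in tissues) shift[truth[[t]], t] <- spec$selective_effect * spec$noise_sd

  gene_of_feat <- if (ntx > 1) tx_gene[feat] else feat
  vals <- matrix(NA_real_, length(feat), length(samples),
                 dimnames = list(feat, samples))
  for (ti in seq_along(tissues)) {
    cols <- which(sample_tissue == tissues[ti])
    mu <- base_gene[gene_of_feat] + tx_off + shift[gene_of_feat, ti]
    noise <- if (spec$distribution == "normal") {
      stats::rnorm(length(feat) * length(cols), 0, spec$noise_sd)
    } else {
      # uniform with the same SD
      stats::runif(length(feat) * length(cols), -sqrt(3) * spec$noise_sd,
                   sqrt(3) * spec$noise_sd)
    }
    vals[, cols] <- mu + matrix(noise, length(feat), length(cols))
  }
  m <- if (spec$value_scale == "tpm") {
    expression_matrix(2^vals, sample_tissue = sample_tissue,
                      level = if (ntx > 1) "transcript" else "gene")
  } else {
    expression_matrix(vals, sample_tissue = sample_tissue,
                      level = if (ntx > 1) "transcript" else "gene",
                      transformed = TRUE)
  }
  list(matrix = m, truth = truth, transcript_gene_map = tx_gene)
}

#' Generate a synthetic gene model
#'
#' Non-overlapping genes tiled along one synthetic chromosome with a fixed
#' intergenic gap; gaps below twice the assignment flank make adjacent genes
#' share boundary variants, gaps above keep assignments disjoint.
#'
#' @param spec a [planting_spec()].
#' @return gene-model data.frame (gene_id, symbol, chrom, strand, start, end).
#' @export
make_gene_model <- function(spec) {
  stopifnot(inherits(spec, "PlantingSpec"))
  genes <- spec_genes(spec)
  pitch <- spec$gene_length + spec$gene_gap
  start <- (seq_along(genes) - 1L) * pitch + 1L
  data.frame(gene_id = genes, symbol = toupper(genes), chrom = "chr1",
             strand = "+", start = start, end = start + spec$gene_length - 1L,
             stringsAsFactors = FALSE)
}

#' Pick the causal gene set for a spec
#'
#' `causal_overlap` of the causal genes come from the driver tissue's
#' planted selective set; the remainder from genes selective nowhere.
#' Deterministic given the spec (ordered picks, no RNG).
#'
#' @param spec a [planting_spec()].
#' @export
causal_genes <- function(spec) {
  truth <- planted_sets(spec)
  drv <- truth[[spec$driver_tissue]]
  n_from_driver <- min(round(spec$causal_overlap * spec$n_causal_genes),
                       length(drv))
  rest_n <- spec$n_causal_genes - n_from_driver
  nonsel <- setdiff(spec_genes(spec), unlist(truth))
  c(drv[seq_len(n_from_driver)],
    if (rest_n > 0) nonsel[seq_len(rest_n)] else character(0))
}

#' Generate LD-blocked GWAS summary statistics
#'
#' Variants are placed evenly inside each gene body and grouped, along the
#' genome, into exchangeable-correlation LD blocks of `ld_block_size`
#' variants (correlation `ld_rho` within, 0 across).  Marginal z-scores are
#' drawn from `MVN(R %*% delta, R)` per block where `delta` carries
#' `gwas_ncp` at the variants of causal genes — so variants of non-causal
#' genes sharing a block with a causal gene show genuinely inflated marginal
#' association (the LD-shadow effect the conditional analysis must undo).
#' P-values are `2 * (1 - Phi(|z|))`.
#'
#' @param spec a [planting_spec()].
#' @param model gene model from [make_gene_model()].
#' @param causal character vector of causal gene ids (default
#'   [causal_genes()]).
#' @param seed_offset added to `spec$seed` so the GWAS stream is independent
#'   of the expression stream.
#' @return list: `gwas` (data.frame variant_id, chrom, pos, pvalue), `ld`
#'   (an `ld_blocks` reference), `z` (named marginal z-scores),
#'   `causal` (the causal gene ids).
#' @export
make_gwas <- function(spec, model = make_gene_model(spec),
                      causal = causal_genes(spec), seed_offset = 500009L) {
  stopifnot(inherits(spec, "PlantingSpec"))
  if (!all(causal %in% model$gene_id))
    stop_input("causal genes absent from the gene model")
  set.seed(spec$seed + seed_offset)
  k <- spec$variants_per_gene
  pos <- as.vector(vapply(seq_len(nrow(model)), function(i) {
    as.integer(round(seq(model$start[i], model$end[i], length.out = k)))
  }, integer(k)))
  gene_of <- rep(model$gene_id, each = k)
  ids <- sprintf("rs_%s_%d", gene_of, rep(seq_len(k), times = nrow(model)))
  m <- length(ids)
  delta <- ifelse(gene_of %in% causal, spec$gwas_ncp, 0)

  bs <- spec$ld_block_size
  block_id <- (seq_len(m) - 1L) %/% bs + 1L
  blocks <- list()
  z <- numeric(m)
  for (b in unique(block_id)) {
    idx <- which(block_id == b)
    nb <- length(idx)
    R <- matrix(spec$ld_rho, nb, nb)
    diag(R) <- 1
    mu <- as.numeric(R %*% delta[idx])
    L <- chol(R)
    z[idx] <- mu + as.numeric(crossprod(L, stats::rnorm(nb)))
    blocks[[length(blocks) + 1]] <- list(ids = ids[idx], R = R)
  }
  p <- 2 * stats::pnorm(abs(z), lower.tail = FALSE)
  p[p < 1e-300] <- 1e-300
  gwas <- data.frame(variant_id = ids, chrom = rep(model$chrom, each = k),
                     pos = pos, pvalue = p, stringsAsFactors = FALSE)
  ld <- ld_from_blocks(blocks, chrom = stats::setNames(gwas$chrom, ids))
  list(gwas = gwas, ld = ld, z = stats::setNames(z, ids), causal = causal)
}

#' Generate a complete synthetic scenario
#'
#' Convenience wrapper tying [make_expression()], [make_gene_model()] and
#' [make_gwas()] together.
#'
#' @param spec a [planting_spec()].
#' @return list: `expression`, `truth`, `transcript_gene_map`, `model`,
#'   `gwas`, `ld`, `causal`, `spec`.
#' @export
make_scenario <- function(spec = planting_spec()) {
  ex <- make_expression(spec)
  model <- make_gene_model(spec)
  gw <- make_gwas(spec, model)
  list(expression = ex$matrix, truth = ex$truth,
       transcript_gene_map = ex$transcript_gene_map, model = model,
       gwas = gw$gwas, ld = gw$ld, causal = gw$causal, spec = spec)
}

#' Write a synthetic scenario to a directory
#'
#' Emits `expression.gct`, `sample_map.tsv`, `gene_model.tsv`, `gwas.tsv`,
#' `ld.tsv` and `truth.json` (planted sets, causal genes, seed).
#'
#' @param scenario output of [make_scenario()].
#' @param dir output directory (created if needed).
#' @export
write_scenario <- function(scenario, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  seed <- scenario$spec$seed
  write_gct(scenario$expression, file.path(dir, "expression.gct"))
  write_tsv_with_header(
    data.frame(sample = names(scenario$expression$sample_tissue),
               tissue = unname(scenario$expression$sample_tissue)),
    file.path(dir, "sample_map.tsv"), seed = seed)
  write_tsv_with_header(scenario$model, file.path(dir, "gene_model.tsv"),
                        seed = seed)
  gw <- scenario$gwas
  names(gw) <- c("SNP", "CHR", "BP", "P")
  write_tsv_with_header(gw, file.path(dir, "gwas.tsv"), seed = seed)
  write_ld_tsv(scenario$ld, file.path(dir, "ld.tsv"), seed = seed)
  jsonlite::write_json(list(seed = seed, driver_tissue = scenario$spec$driver_tissue,
                            causal_genes = scenario$causal,
                            selective_sets = scenario$truth),
                       file.path(dir, "truth.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(dir)
}
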