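# LD reference containers: pairwise variant correlations served either from
# stored block-correlation matrices (synthetic or precomputed panels) or
# from reference genotypes read out of a VCF.

#' Build an LD reference from block correlation matrices
#'
#' @param blocks list of blocks, each a list with `ids` (variant ids) and `R`
#'   (correlation matrix, dimnames optional).  Variants in different blocks
#'   are treated as uncorrelated; variants on different chromosomes always
#'   are.
#' @param chrom optional named character vector, variant id -> chromosome.
#' @return object of class `LdReference` (subtype `ld_blocks`).
#' @export
ld_from_blocks <- function(blocks, chrom = NULL) {
  ids <- unlist(lapply(blocks, `[[`, "ids"), use.names = FALSE)
  if (anyDuplicated(ids)) stop_input("variant ids repeated across LD blocks")
  block_of <- rep(seq_along(blocks), vapply(blocks, function(b) length(b$ids), 1L))
  names(block_of) <- ids
  for (b in seq_along(blocks)) {
    R <- as.matrix(blocks[[b]]$R)
    if (nrow(R) != length(blocks[[b]]$ids))
      stop_input("block %d: matrix size does not match id count", b)
    dimnames(R) <- list(blocks[[b]]$ids, blocks[[b]]$ids)
    blocks[[b]]$R <- R
  }
  structure(list(blocks = blocks, block_of = block_of, variant_ids = ids,
                 chrom = chrom),
            class = c("ld_blocks", "LdReference"))
}

#' Build an LD reference from a dosage matrix
#'
#' @param dosage numeric matrix, samples x variants, column names = variant
#'   ids (e.g. allele counts 0/1/2 from a reference panel).
#' @param chrom optional named character vector, variant id -> chromosome;
#'   cross-chromosome correlations are fixed at 0.
#' @export
ld_from_genotypes <- function(dosage, chrom = NULL) {
  if (is.null(colnames(dosage))) stop_input("dosage matrix needs variant ids as colnames")
  structure(list(dosage = dosage, variant_ids = colnames(dosage), chrom = chrom),
            class = c("ld_genotypes", "LdReference"))
}

#' Read reference genotypes from a VCF into an LD reference
#'
#' Biallelic variants only; genotypes are converted to ALT-allele dosages and
#' Pearson correlations are computed on demand.  Requires the `vcfR` package.
#'
#' @param path VCF file (plain or bgzipped).
#' @export
read_ld_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop_input("reading VCF LD references requires the 'vcfR' package")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  biallelic <- !grepl(",", fix[, "ALT"])
  gt <- vcfR::extract.gt(v, element = "GT")[biallelic, , drop = FALSE]
  fix <- fix[biallelic, , drop = FALSE]
  dos <- apply(gt, c(1, 2), function(g) {
    if (is.na(g)) return(NA_real_)
    sum(as.integer(strsplit(g, "[/|]")[[1]]) > 0)
  })
  ids <- fix[, "ID"]
  noid <- is.na(ids) | ids == "."
  ids[noid] <- paste0(fix[noid, "CHROM"], ":", fix[noid, "POS"])
  dos <- t(dos)            # samples x variants
  colnames(dos) <- ids
  ld_from_genotypes(dos, chrom = stats::setNames(fix[, "CHROM"], ids))
}

#' Pairwise variant correlations from an LD reference
#'
#' @param ld an `LdReference`.
#' @param ids_a,ids_b variant id vectors; `ids_b` defaults to `ids_a`.
#' @return matrix of Pearson correlations, `length(ids_a)` x `length(ids_b)`.
#' @export
ld_cor <- function(ld, ids_a, ids_b = ids_a) UseMethod("ld_cor")

#' @export
ld_cor.ld_blocks <- function(ld, ids_a, ids_b = ids_a) {
  unknown <- setdiff(c(ids_a, ids_b), ld$variant_ids)
  if (length(unknown))
    stop_input("variant(s) absent from LD reference: %s",
               paste(utils::head(unknown, 5), collapse = ", "))
  R <- matrix(0, length(ids_a), length(ids_b), dimnames = list(ids_a, ids_b))
  ba <- ld$block_of[ids_a]
  bb <- ld$block_of[ids_b]
  for (b in intersect(unique(ba), unique(bb))) {
    ia <- which(ba == b)
    ib <- which(bb == b)
    R[ia, ib] <- ld$blocks[[b]]$R[ids_a[ia], ids_b[ib], drop = FALSE]
  }
  if (length(ids_a) == length(ids_b) && all(ids_a == ids_b)) diag(R) <- 1
  R
}

#' @export
ld_cor.ld_genotypes <- function(ld, ids_a, ids_b = ids_a) {
  unknown <- setdiff(c(ids_a, ids_b), ld$variant_ids)
  if (length(unknown))
    stop_input("variant(s) absent from LD reference: %s",
               paste(utils::head(unknown, 5), collapse = ", "))
  R <- suppressWarnings(stats::cor(ld$dosage[, ids_a, drop = FALSE],
                                   ld$dosage[, ids_b, drop = FALSE],
                                   use = "pairwise.complete.obs"))
  R[!is.finite(R)] <- 0    # monomorphic reference variants
  if (!is.null(ld$chrom)) {
    cross <- outer(ld$chrom[ids_a], ld$chrom[ids_b], `!=`)
    R[cross] <- 0
  }
  dimnames(R) <- list(ids_a, ids_b)
  if (length(ids_a) == length(ids_b) && all(ids_a == ids_b)) diag(R) <- 1
  R
}

#' Write an LD block reference as a plain-text container
#'
#' Long TSV: block, variant_a, variant_b, r (upper triangle incl. diagonal).
#'
#' @param ld an `ld_blocks` reference.
#' @param path output file.
#' @param seed recorded in the provenance header.
#' @export
write_ld_tsv <- function(ld, path, seed = NA) {
  stopifnot(inherits(ld, "ld_blocks"))
  rows <- lapply(seq_along(ld$blocks), function(b) {
    R <- ld$blocks[[b]]$R
    idx <- which(upper.tri(R, diag = TRUE), arr.ind = TRUE)
    data.frame(block = b, variant_a = rownames(R)[idx[, 1]],
               variant_b = colnames(R)[idx[, 2]], r = R[idx],
               stringsAsFactors = FALSE)
  })
  write_tsv_with_header(do.call(rbind, rows), path, seed = seed)
}

#' Read an LD block reference written by [write_ld_tsv()]
#'
#' @param path TSV file.
#' @export
read_ld_tsv <- function(path) {
  df <- read_tsv_skip_comments(path)
  blocks <- lapply(split(df, df$block), function(d) {
    ids <- unique(c(d$variant_a, d$variant_b))
    R <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
    R[cbind(d$variant_a, d$variant_b)] <- d$r
    R[cbind(d$variant_b, d$variant_a)] <- d$r
    list(ids = ids, R = R)
  })
  ld_from_blocks(unname(blocks))
}
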