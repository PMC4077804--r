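#' Reads per kilobase per million mapped reads (RPKM)
#'
#' `rpkm()` computes `count * 1e9 / (length * library_size)`.
#' `rpkm_equivalent()` is the same quantity evaluated at a nominal read
#' count `k`; it is the "RPKM value equivalent to k reads" used by the
#' replacement floors.
#'
#' @param count non-negative read count(s).
#' @param length feature length(s) in bases, > 0.
#' @param library_size per-sample total mapped reads, > 0.
#' @return RPKM value(s); vectorized with the usual recycling.
#' @examples
#' rpkm(10, 2000, 1e6)   # 5
#' @export
rpkm <- function(count, length, library_size) {
  if (any(length <= 0)) stop("rpkm: length must be > 0")
  if (any(library_size <= 0)) stop("rpkm: library_size must be > 0")
  if (any(count < 0)) stop("rpkm: count must be >= 0")
  count * 1e9 / (length * library_size)
}

#' @rdname rpkm
#' @param k nominal read count whose RPKM equivalent is requested.
#' @export
rpkm_equivalent <- function(k, length, library_size) {
  rpkm(k, length, library_size)
}

#' Per-sample library sizes from a gene-level count matrix
#'
#' The normalization basis for every RPKM in the pipeline: the column sum of
#' gene-level counts over all annotated genes. One basis per sample is used
#' for both gene- and exon-level RPKM.
#'
#' @param gene_counts integer matrix, genes x samples.
#' @return Named numeric vector of column sums.
#' @export
library_sizes <- function(gene_counts) {
  colSums(gene_counts)
}

#' Sum exon counts to gene level
#'
#' Gene counts are defined as the sum of the counts of the gene's exons,
#' which keeps the gene and exon levels internally consistent (and makes
#' the length-weighted splicing-index identity exact).
#'
#' @param exon_counts integer matrix, exons x samples, rownames = exon ids.
#' @param gene_map named character vector mapping exon id -> gene id.
#' @return Integer matrix, genes x samples.
#' @export
sum_gene_counts <- function(exon_counts, gene_map) {
  missing <- setdiff(rownames(exon_counts), names(gene_map))
  if (length(missing) > 0L)
    stop("sum_gene_counts: exons with unknown gene: ",
         paste(utils::head(missing, 5L), collapse = ", "))
  rowsum(exon_counts, group = gene_map[rownames(exon_counts)])
}

#' Reliable Quantification Threshold filter
#'
#' A gene (or exon) is retained when it reaches at least `k_quant` reads in
#' one or more samples; everything else is reported as unquantified. The
#' default of 50 reads is the count at which RPKM values are expected to be
#' reproducible between technical replicates.
#'
#' @param counts integer matrix, entities x samples.
#' @param k_quant minimum read count required in at least one sample
#'   (inclusive; default 50).
#' @return Character vector of retained entity ids, with the dropped ids in
#'   attribute `"unquantified"`.
#' @export
filter_reliable <- function(counts, k_quant = 50) {
  stopifnot(is.matrix(counts), !is.null(rownames(counts)))
  keep <- apply(counts, 1L, max) >= k_quant
  retained <- rownames(counts)[keep]
  attr(retained, "unquantified") <- rownames(counts)[!keep]
  retained
}

#' Low-count replacement: floored RPKM abundances
#'
#' Converts counts to RPKM and replaces every cell whose count is at or
#' below `k_floor` by that entity's replacement floor: the RPKM equivalent
#' of `k_floor` reads averaged across all samples. This bounds fold changes
#' away from the large ratios that random variation of low counts would
#' otherwise produce. The defaults used by the pipeline are 10 reads per
#' gene and 1 read per exon.
#'
#' @param counts integer matrix (entities x samples) of the entities to
#'   quantify (normally those retained by [filter_reliable()]).
#' @param lengths named vector of entity lengths in bases covering every row.
#' @param lib_sizes named vector of per-sample library sizes (see
#'   [library_sizes()]); must cover every column.
#' @param k_floor replacement count threshold (cells with count <= `k_floor`
#'   are floored).
#' @return An `abundance_matrix`: a list with `rpkm` (numeric matrix),
#'   `flag` (character matrix, `"raw"` or `"floored"`), `floor` (per-entity
#'   replacement value), and the thresholds and normalization metadata.
#' @export
apply_replacement <- function(counts, lengths, lib_sizes, k_floor = 10) {
  stopifnot(is.matrix(counts), !is.null(rownames(counts)),
            !is.null(colnames(counts)))
  missing <- setdiff(rownames(counts), names(lengths))
  if (length(missing) > 0L)
    stop("apply_replacement: entities missing from annotation: ",
         paste(utils::head(missing, 5L), collapse = ", "))
  if (!all(colnames(counts) %in% names(lib_sizes)))
    stop("apply_replacement: library sizes missing for some samples")
  len <- lengths[rownames(counts)]
  ls <- lib_sizes[colnames(counts)]

  raw <- rpkm(counts, matrix(len, nrow(counts), ncol(counts)),
              matrix(ls, nrow(counts), ncol(counts), byrow = TRUE))
  # floor(g): the k_floor-read RPKM equivalent averaged over all samples
  floor_val <- rowMeans(outer(len, ls, function(l, s) rpkm_equivalent(k_floor, l, s)))
  floored <- counts <= k_floor
  out <- raw
  out[floored] <- matrix(floor_val, nrow(counts), ncol(counts))[floored]
  flag <- matrix("raw", nrow(counts), ncol(counts),
                 dimnames = dimnames(counts))
  flag[floored] <- "floored"
  structure(list(rpkm = out, flag = flag,
                 floor = stats::setNames(floor_val, rownames(counts)),
                 k_floor = k_floor, lengths = len, lib_sizes = ls),
            class = "abundance_matrix")
}

#' @export
print.abundance_matrix <- function(x, ...) {
  cat("abundance_matrix:", nrow(x$rpkm), "entities x", ncol(x$rpkm),
      "samples; k_floor =", x$k_floor, "\n")
  cat("floored cells:", sum(x$flag == "floored"), "of", length(x$flag), "\n")
  invisible(x)
}
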