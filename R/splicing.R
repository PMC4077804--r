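#' Two-step exon filter for splicing-index analysis
#'
#' Exons enter the splicing-index analysis only when (1) their gene reached
#' the Reliable Quantification Threshold (~50 reads) in at least one sample
#' and (2) the exon itself was detected — at least one read — in at least
#' one sample.
#'
#' @param exon_counts integer matrix, exons x samples.
#' @param gene_map named character vector exon id -> gene id (total on the
#'   exon set; unknown exons are an error).
#' @param reliable_genes character vector of genes passing
#'   [filter_reliable()].
#' @return Character vector of retained exon ids.
#' @export
filter_exons <- function(exon_counts, gene_map, reliable_genes) {
  unknown <- setdiff(rownames(exon_counts), names(gene_map))
  if (length(unknown) > 0L)
    stop("filter_exons: exons with unknown gene: ",
         paste(utils::head(unknown, 5L), collapse = ", "))
  g <- gene_map[rownames(exon_counts)]
  keep <- g %in% reliable_genes & apply(exon_counts, 1L, max) >= 1
  rownames(exon_counts)[keep]
}

#' Per-exon, per-sample splicing indexes
#'
#' SI(e, s) = exon RPKM / gene RPKM, computed from the floored exon
#' abundances (1-read floor) and the post-replacement gene abundances. The
#' SI is set to NA wherever the gene's raw count in that sample is below
#' `k_quant` reads — with an unreliably detected gene the denominator, and
#' hence the ratio, is meaningless.
#'
#' @param exon_abund exon-level `abundance_matrix` (floored at the 1-read
#'   equivalent).
#' @param gene_abund gene-level `abundance_matrix` (post-replacement).
#' @param gene_counts raw gene-level count matrix.
#' @param gene_map named character vector exon id -> gene id.
#' @param k_quant per-sample gene-count reliability cutoff (default 50;
#'   strict `<` triggers NA).
#' @return Numeric matrix of splicing indexes (exons x samples, NA allowed)
#'   with the exon -> gene map in attribute `gene_map`.
#' @export
splicing_index <- function(exon_abund, gene_abund, gene_counts, gene_map,
                           k_quant = 50) {
  stopifnot(inherits(exon_abund, "abundance_matrix"),
            inherits(gene_abund, "abundance_matrix"))
  er <- exon_abund$rpkm
  g <- unname(gene_map[rownames(er)])
  if (anyNA(g))
    stop("splicing_index: exons with unknown gene")
  missing <- setdiff(unique(g), rownames(gene_abund$rpkm))
  if (length(missing) > 0L)
    stop("splicing_index: genes missing from gene abundances: ",
         paste(utils::head(missing, 5L), collapse = ", "))
  gr <- gene_abund$rpkm[g, colnames(er), drop = FALSE]
  if (any(gr <= 0))
    stop("splicing_index: non-positive gene RPKM (internal inconsistency)")
  si <- er / gr
  low <- gene_counts[g, colnames(er), drop = FALSE] < k_quant
  si[low] <- NA_real_
  attr(si, "gene_map") <- stats::setNames(g, rownames(er))
  si
}

#' Per-exon ANOVA and Tukey test on splicing indexes
#'
#' For every exon, a one-way ANOVA across the two genotype groups on the
#' raw SI values, plus the Tukey HSD contrast for the group pair (with two
#' groups the Tukey-adjusted p equals the ANOVA p; the studentized-range
#' computation is kept so the output matches a generic post-hoc report).
#' Every statistic is NA when any sample's SI is NA. `significant` is
#' `p < p_cut`, or NA when p is NA.
#'
#' @param si splicing-index matrix from [splicing_index()].
#' @param groups named character vector sample id -> group label.
#' @param group_a,group_b group labels (difference is A - B).
#' @param p_cut significance cutoff (default 0.05).
#' @return Data frame `exon_id`, `gene_id`, `F`, `p`, `tukey_diff`,
#'   `tukey_p`, `significant` (logical, NA allowed).
#' @export
exon_anova_tukey <- function(si, groups,
                             group_a = unique(groups)[1],
                             group_b = unique(groups)[2],
                             p_cut = 0.05) {
  gene_map <- attr(si, "gene_map")
  sa <- names(groups)[groups == group_a]
  sb <- names(groups)[groups == group_b]
  A <- si[, sa, drop = FALSE]
  B <- si[, sb, drop = FALSE]
  has_na <- apply(is.na(A), 1L, any) | apply(is.na(B), 1L, any)

  f <- p <- diff <- tp <- rep(NA_real_, nrow(si))
  ok <- !has_na
  if (any(ok)) {
    av <- row_anova_two_group(A[ok, , drop = FALSE], B[ok, , drop = FALSE])
    f[ok] <- av$F
    p[ok] <- av$p
    diff[ok] <- rowMeans(A[ok, , drop = FALSE]) - rowMeans(B[ok, , drop = FALSE])
    # Tukey HSD for the single pair: studentized range q = sqrt(2 F)
    df2 <- length(sa) + length(sb) - 2L
    q <- sqrt(2 * av$F)
    tp[ok] <- stats::ptukey(q, nmeans = 2L, df = df2, lower.tail = FALSE)
    tp[ok][is.infinite(q)] <- 0
  }
  data.frame(exon_id = rownames(si),
             gene_id = unname(gene_map[rownames(si)]),
             F = f, p = p, tukey_diff = diff, tukey_p = tp,
             significant = ifelse(is.na(p), NA, p < p_cut),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Per-gene splicing summary and top-spliced ranking
#'
#' Summarizes [exon_anova_tukey()] records per gene (number of retained
#' exons, number significant, minimum exon p) and ranks genes by their
#' minimum exon p-value. The ranking can be restricted to genes with at
#' least `min_exons` retained exons, the selection used when plotting
#' exon-level profiles of the most significantly spliced genes.
#'
#' @param records data frame from [exon_anova_tukey()].
#' @param min_exons minimum retained exons for the ranked set (default 10);
#'   set to 0 to rank all genes.
#' @return Data frame `gene_id`, `n_exons`, `n_significant`, `min_p`,
#'   `ranked` (logical), ordered by `min_p` (NA last).
#' @export
splicing_gene_summary <- function(records, min_exons = 10) {
  sp <- split(records, records$gene_id)
  out <- data.frame(
    gene_id = names(sp),
    n_exons = vapply(sp, nrow, integer(1L)),
    n_significant = vapply(sp, function(d) sum(d$significant %in% TRUE), integer(1L)),
    min_p = vapply(sp, function(d) {
      if (all(is.na(d$p))) NA_real_ else min(d$p, na.rm = TRUE)
    }, numeric(1L)),
    row.names = NULL, stringsAsFactors = FALSE)
  out$ranked <- out$n_exons >= min_exons & !is.na(out$min_p)
  out[order(out$min_p, !out$ranked, na.last = TRUE), , drop = FALSE]
}
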