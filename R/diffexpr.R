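#' Two-group one-way ANOVA
#'
#' One-way fixed-effects ANOVA with df = (1, n_A + n_B - 2). When both
#' groups are constant and equal the statistic is defined as F = 0, p = 1
#' (no evidence of a difference rather than an error); constant unequal
#' groups give F = Inf, p = 0. For two groups, F is identical to the square
#' of the pooled-variance two-sample t statistic.
#'
#' @param values_a,values_b numeric vectors of length >= 2 (finite).
#' @return List with `F`, `p`, and `df = c(1, n_a + n_b - 2)`.
#' @examples
#' anova_two_group(c(1, 2, 3), c(4, 5, 6))   # F = 13.5
#' @export
anova_two_group <- function(values_a, values_b) {
  if (length(values_a) < 2L || length(values_b) < 2L)
    stop("anova_two_group: need at least 2 values per group")
  if (!all(is.finite(values_a)) || !all(is.finite(values_b)))
    stop("anova_two_group: values must be finite")
  r <- row_anova_two_group(rbind(values_a = values_a),
                           matrix(values_b, nrow = 1L))
  list(F = unname(r$F), p = unname(r$p),
       df = c(1L, length(values_a) + length(values_b) - 2L))
}

#' Row-wise two-group one-way ANOVA
#'
#' Vectorized version of [anova_two_group()] for a matrix of features: each
#' row is tested independently. Used by the gene- and exon-level stages so
#' that genome-scale designs need one call, not one model fit per feature.
#'
#' @param mat_a,mat_b numeric matrices with one row per feature and one
#'   column per replicate (same row count and order).
#' @return List of vectors `F` and `p` (one element per row) and `df`.
#' @export
row_anova_two_group <- function(mat_a, mat_b) {
  stopifnot(is.matrix(mat_a), is.matrix(mat_b), nrow(mat_a) == nrow(mat_b))
  na <- ncol(mat_a); nb <- ncol(mat_b)
  if (na < 2L || nb < 2L)
    stop("row_anova_two_group: need at least 2 replicates per group")
  ma <- rowMeans(mat_a); mb <- rowMeans(mat_b)
  gm <- (na * ma + nb * mb) / (na + nb)
  ssb <- na * (ma - gm)^2 + nb * (mb - gm)^2
  ssw <- rowSums((mat_a - ma)^2) + rowSums((mat_b - mb)^2)
  df2 <- na + nb - 2L
  f <- (ssb / 1) / (ssw / df2)
  # constant data: equal means carry no signal, unequal means are exact
  f[ssw == 0 & ssb == 0] <- 0
  f[ssw == 0 & ssb > 0] <- Inf
  p <- stats::pf(f, 1, df2, lower.tail = FALSE)
  p[is.infinite(f)] <- 0
  list(F = f, p = p, df = c(1L, df2))
}

#' Group fold changes with the low-abundance NA rule
#'
#' The fold change is the ratio of group-mean post-replacement RPKM
#' (A over B). It is reported as NA when the mean raw count of *both*
#' groups falls below the reliability threshold `k_quant`, since a ratio of
#' two unreliable abundances is not interpretable. Because both numerator
#' and denominator are bounded away from zero by the replacement floor, the
#' ratio is always finite when reported.
#'
#' @param rpkm_mat post-replacement RPKM matrix (entities x samples).
#' @param counts matching raw count matrix.
#' @param groups named character vector sample id -> group label.
#' @param group_a,group_b the two group labels (numerator / denominator).
#' @param k_quant reliability threshold in reads (default 50).
#' @return Data frame with `mean_a`, `mean_b`, `fold_change` (NA allowed).
#' @export
fold_change <- function(rpkm_mat, counts, groups, group_a, group_b,
                        k_quant = 50) {
  sa <- names(groups)[groups == group_a]
  sb <- names(groups)[groups == group_b]
  mean_a <- rowMeans(rpkm_mat[, sa, drop = FALSE])
  mean_b <- rowMeans(rpkm_mat[, sb, drop = FALSE])
  cnt_a <- rowMeans(counts[, sa, drop = FALSE])
  cnt_b <- rowMeans(counts[, sb, drop = FALSE])
  fc <- mean_a / mean_b
  fc[cnt_a < k_quant & cnt_b < k_quant] <- NA_real_
  data.frame(mean_a = mean_a, mean_b = mean_b, fold_change = fc)
}

#' Per-gene differential expression table
#'
#' Runs the two-group ANOVA on the analysis scale (log2 of post-replacement
#' RPKM by default) and combines it with [fold_change()]. A
#' Benjamini-Hochberg column (`p_adj_info`) is included for information
#' only; calls are made on the raw p-value, matching the p < 0.05
#' convention of the original analysis.
#'
#' @param abundance an `abundance_matrix` from [apply_replacement()].
#' @param counts matching raw count matrix (same entities).
#' @param groups named character vector sample id -> group label.
#' @param group_a,group_b numerator / denominator group labels; by default
#'   the first and second label in `unique(groups)`.
#' @param k_quant reliability threshold for the fold-change NA rule.
#' @param scale `"log2"` (default) or `"linear"`: scale on which the ANOVA
#'   is run.
#' @return Data frame with columns `gene_id`, `mean_a`, `mean_b`,
#'   `fold_change`, `F`, `p`, `p_adj_info`, `direction`.
#' @export
de_table <- function(abundance, counts, groups,
                     group_a = unique(groups)[1], group_b = unique(groups)[2],
                     k_quant = 50, scale = c("log2", "linear")) {
  scale <- match.arg(scale)
  stopifnot(inherits(abundance, "abundance_matrix"))
  rk <- abundance$rpkm
  counts <- counts[rownames(rk), colnames(rk), drop = FALSE]
  y <- if (scale == "log2") log2(rk) else rk
  sa <- names(groups)[groups == group_a]
  sb <- names(groups)[groups == group_b]
  av <- row_anova_two_group(y[, sa, drop = FALSE], y[, sb, drop = FALSE])
  fc <- fold_change(rk, counts, groups, group_a, group_b, k_quant)
  direction <- rep("none", nrow(rk))
  direction[!is.na(fc$fold_change) & fc$fold_change > 1] <- "up"
  direction[!is.na(fc$fold_change) & fc$fold_change < 1] <- "down"
  data.frame(gene_id = rownames(rk),
             mean_a = fc$mean_a, mean_b = fc$mean_b,
             fold_change = fc$fold_change,
             F = av$F, p = av$p,
             p_adj_info = stats::p.adjust(av$p, method = "BH"),
             direction = direction,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Call differentially expressed genes
#'
#' `de_set` contains every gene with p < `p_cut`. The fold-change-filtered
#' set additionally requires `fold_change >= fc_cut` or `<= 1/fc_cut`
#' (two-sided, so 1.5-fold covers both 1.5 and 0.667); NA fold changes
#' never pass the fold-change filter. `up_set` and `down_set` split the
#' filtered set by direction.
#'
#' @param records a [de_table()] data frame.
#' @param p_cut p-value cutoff (strict `<`; default 0.05).
#' @param fc_cut fold-change cutoff >= 1 (default 1.5).
#' @return List of character vectors `de_set`, `fc_set`, `up_set`,
#'   `down_set`.
#' @export
call_de <- function(records, p_cut = 0.05, fc_cut = 1.5) {
  stopifnot(fc_cut >= 1)
  de <- records$p < p_cut
  pass_fc <- !is.na(records$fold_change) &
    (records$fold_change >= fc_cut | records$fold_change <= 1 / fc_cut)
  list(de_set = records$gene_id[de],
       fc_set = records$gene_id[de & pass_fc],
       up_set = records$gene_id[de & pass_fc & records$fold_change > 1],
       down_set = records$gene_id[de & pass_fc & records$fold_change < 1])
}

#' Venn detection classification
#'
#' Classifies each gene by per-sample detection (count > `k_det`):
#' `common` when every sample in both groups is detected, `unique_A` when
#' all group-A samples are detected but at least one group-B sample is not
#' (`unique_B` symmetric), and `excluded` when at least one sample is
#' undetected in each group — such genes are left out of the Venn diagram.
#' The classes are disjoint and cover every gene.
#'
#' @param counts integer matrix, genes x samples.
#' @param groups named character vector sample id -> group label.
#' @param k_det detection threshold in reads: detected means count >
#'   `k_det`. The default 10 treats a cell that escaped the 10-read
#'   replacement floor as detected.
#' @param group_a,group_b group labels mapped to `unique_A` / `unique_B`.
#' @return Data frame `gene_id`, `venn_class` (factor with levels
#'   `unique_A`, `unique_B`, `common`, `excluded`); the thresholds and group
#'   mapping are stored in attributes `k_det`, `group_a`, `group_b`.
#' @export
classify_venn <- function(counts, groups,
                          group_a = unique(groups)[1],
                          group_b = unique(groups)[2],
                          k_det = 10) {
  detected <- counts > k_det
  all_a <- apply(detected[, names(groups)[groups == group_a], drop = FALSE], 1L, all)
  all_b <- apply(detected[, names(groups)[groups == group_b], drop = FALSE], 1L, all)
  cls <- ifelse(all_a & all_b, "common",
                ifelse(all_a, "unique_A",
                       ifelse(all_b, "unique_B", "excluded")))
  out <- data.frame(gene_id = rownames(counts),
                    venn_class = factor(cls, levels = c("unique_A", "unique_B",
                                                        "common", "excluded")),
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "k_det") <- k_det
  attr(out, "group_a") <- group_a
  attr(out, "group_b") <- group_b
  out
}
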