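#' Read a GMT gene-set collection
#'
#' Standard GMT dialect: one set per line,
#' `set_id <TAB> description <TAB> gene1 <TAB> gene2 ...`. Duplicate member
#' genes within a set are dropped.
#'
#' @param path path to a GMT file.
#' @return A `gene_set_collection`: named list of character vectors with a
#'   `description` attribute (named character vector).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(parts) < 3L)
  if (length(short) > 0L)
    stop("read_gmt: line ", short[1L], " has fewer than 3 fields")
  ids <- vapply(parts, `[[`, character(1L), 1L)
  if (anyDuplicated(ids))
    stop("read_gmt: duplicate set id: ", ids[duplicated(ids)][1L])
  sets <- lapply(parts, function(x) unique(x[-(1:2)]))
  names(sets) <- ids
  attr(sets, "description") <- stats::setNames(
    vapply(parts, `[[`, character(1L), 2L), ids)
  class(sets) <- "gene_set_collection"
  sets
}

#' Select focus genes for over-representation analysis
#'
#' Applies the differential-expression selection (p < `p_cut` and two-sided
#' fold change >= `fc_cut`) via [call_de()] and intersects the result with
#' the universe of annotated/detectable genes; genes passing the filters
#' but absent from the universe are dropped with a warning.
#'
#' @param records a [de_table()] data frame.
#' @param universe character vector of reference genes.
#' @param p_cut,fc_cut selection cutoffs (defaults 0.05 and 1.5).
#' @return Character vector of focus gene ids.
#' @export
select_focus <- function(records, universe, p_cut = 0.05, fc_cut = 1.5) {
  if (length(universe) == 0L)
    stop("select_focus: empty universe")
  fc_set <- call_de(records, p_cut = p_cut, fc_cut = fc_cut)$fc_set
  outside <- setdiff(fc_set, universe)
  if (length(outside) > 0L)
    warning("select_focus: ", length(outside),
            " selected gene(s) outside the universe were dropped")
  intersect(fc_set, universe)
}

#' Over-representation analysis (Fisher / hypergeometric)
#'
#' For each gene set, tests whether the focus list overlaps the set more
#' than expected under hypergeometric sampling from the universe:
#' p = P(X >= k) with N = |universe|, K = |set ∩ universe|, n = |focus|.
#' The one-sided upper tail (enrichment only) is the default; the
#' two-sided Fisher exact test is available via `alternative`. P-values
#' are adjusted across all tested sets (Benjamini-Hochberg by default) and
#' a set is called enriched when the adjusted p is below `alpha`. Sets with
#' no overlap with the universe are skipped with a warning.
#'
#' @param focus character vector of focus genes (must lie in `universe`).
#' @param sets a `gene_set_collection` or named list of character vectors.
#' @param universe character vector of reference genes.
#' @param alternative `"greater"` (default, enrichment-only upper tail) or
#'   `"two.sided"` (Fisher exact two-sided).
#' @param adjust multiple-testing method: `"BH"` (default) or
#'   `"bonferroni"`.
#' @param alpha adjusted-p cutoff for the `enriched` call (default 0.05).
#' @return Data frame `set_id`, `name`, `k`, `K`, `n`, `N`, `p`, `p_adj`,
#'   `enriched`, ordered by `p`.
#' @export
ora <- function(focus, sets, universe, alternative = c("greater", "two.sided"),
                adjust = c("BH", "bonferroni"), alpha = 0.05) {
  alternative <- match.arg(alternative)
  adjust <- match.arg(adjust)
  universe <- unique(universe)
  focus <- unique(focus)
  if (length(setdiff(focus, universe)) > 0L)
    stop("ora: focus genes must be a subset of the universe")
  N <- length(universe)
  n <- length(focus)
  desc <- attr(sets, "description")
  keep <- vapply(sets, function(s) length(intersect(s, universe)) > 0L, logical(1L))
  if (any(!keep))
    warning("ora: skipped ", sum(!keep), " set(s) with no universe overlap")
  sets <- sets[keep]
  if (length(sets) == 0L)
    return(data.frame(set_id = character(0), name = character(0),
                      k = integer(0), K = integer(0), n = integer(0),
                      N = integer(0), p = numeric(0), p_adj = numeric(0),
                      enriched = logical(0)))
  K <- vapply(sets, function(s) length(intersect(s, universe)), integer(1L))
  k <- vapply(sets, function(s) length(intersect(s, focus)), integer(1L))
  if (alternative == "greater") {
    p <- stats::phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
  } else {
    p <- mapply(function(ki, Ki) {
      tab <- matrix(c(ki, Ki - ki, n - ki, N - Ki - n + ki), 2L)
      stats::fisher.test(tab, alternative = "two.sided")$p.value
    }, k, K)
  }
  p_adj <- stats::p.adjust(p, method = adjust)
  out <- data.frame(set_id = names(sets),
                    name = if (is.null(desc)) names(sets)
                           else unname(desc[names(sets)]),
                    k = k, K = K, n = n, N = N,
                    p = p, p_adj = p_adj, enriched = p_adj < alpha,
                    row.names = NULL, stringsAsFactors = FALSE)
  out[order(out$p), , drop = FALSE]
}
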