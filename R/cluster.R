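#' Log2 transform and median-center rows for clustering
#'
#' Selects the requested genes, log2-transforms the post-replacement RPKM
#' values and centers each row by subtracting its median — the standard
#' preprocessing applied before hierarchical clustering of expression
#' profiles. Values must be strictly positive (guaranteed by the
#' replacement floors). The operation is applied exactly once; the returned
#' matrix carries a `preprocessed` attribute so callers can assert the
#' single-pass contract.
#'
#' @param rpkm_mat post-replacement RPKM matrix.
#' @param genes character vector of row ids to keep (e.g. the DE set).
#' @return Numeric matrix of centered log2 values, rows in `genes` order.
#' @export
preprocess_cluster <- function(rpkm_mat, genes) {
  if (!is.null(attr(rpkm_mat, "preprocessed")))
    stop("preprocess_cluster: input has already been preprocessed")
  missing <- setdiff(genes, rownames(rpkm_mat))
  if (length(missing) > 0L)
    stop("preprocess_cluster: genes not in matrix: ",
         paste(utils::head(missing, 5L), collapse = ", "))
  x <- rpkm_mat[genes, , drop = FALSE]
  bad <- rownames(x)[apply(x <= 0, 1L, any)]
  if (length(bad) > 0L)
    stop("preprocess_cluster: non-positive values for gene(s): ",
         paste(utils::head(bad, 5L), collapse = ", "))
  lx <- log2(x)
  out <- lx - apply(lx, 1L, stats::median)
  attr(out, "preprocessed") <- TRUE
  out
}

#' Centered (Pearson) correlation similarity
#'
#' The similarity metric used for clustering: ordinary mean-centered
#' Pearson correlation, in [-1, 1]. The distance used internally is
#' `1 - similarity`. A zero-variance vector has no defined correlation; its
#' similarity to anything is taken as 0 (with a warning) so that rows whose
#' cells were all floored still cluster rather than abort.
#'
#' @param x,y numeric vectors of equal length >= 2.
#' @return Similarity in [-1, 1].
#' @export
centered_correlation <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2L)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("centered_correlation: zero-variance vector; similarity set to 0")
    return(0)
  }
  stats::cor(x, y)
}

# pairwise centered-correlation distance (1 - r) between the rows of `mat`;
# zero-variance rows get similarity 0 to everything
.cor_dist_rows <- function(mat) {
  zv <- apply(mat, 1L, stats::sd) == 0
  sim <- matrix(0, nrow(mat), nrow(mat), dimnames = list(rownames(mat), rownames(mat)))
  if (any(!zv))
    sim[!zv, !zv] <- stats::cor(t(mat[!zv, , drop = FALSE]))
  if (any(zv)) {
    warning("zero-variance row(s); similarity to other rows set to 0")
    diag(sim) <- 1
  }
  1 - sim
}

#' Agglomerative average-linkage (UPGMA) clustering
#'
#' Unweighted average linkage: the distance between two clusters is the
#' mean distance over all inter-cluster leaf pairs, updated with the
#' Lance-Williams recurrence. Tie-breaking is deterministic: among merges
#' of equal distance the pair with the lexicographically smallest cluster
#' ids is chosen (leaves are numbered 1..n in input order; the k-th merge
#' creates cluster n + k). The leaf order is a depth-first traversal that
#' places, at every internal node, the child subtree containing the lowest
#' original leaf index first.
#'
#' @param d symmetric distance matrix (zero diagonal) or `dist` object.
#' @param labels optional leaf labels (default from `d`).
#' @return An object of class `hclust` with components `merge`, `height`,
#'   `order`, `labels` (so the standard `plot`/`cutree` tooling applies).
#' @export
average_linkage <- function(d, labels = NULL) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  stopifnot(is.matrix(d), nrow(d) == ncol(d))
  if (any(abs(d - t(d)) > 1e-12))
    stop("average_linkage: distance matrix is not symmetric")
  if (any(diag(d) != 0))
    stop("average_linkage: distance matrix diagonal must be zero")
  n <- nrow(d)
  if (is.null(labels)) labels <- rownames(d)
  if (n == 1L) {
    return(structure(list(merge = matrix(integer(0), 0, 2),
                          height = numeric(0), order = 1L, labels = labels,
                          method = "average", dist.method = "custom"),
                     class = "hclust"))
  }
  D <- d
  diag(D) <- Inf
  id <- seq_len(n)           # current cluster id per active row
  node <- -seq_len(n)        # hclust encoding: negative leaf, positive merge
  size <- rep(1L, n)
  active <- rep(TRUE, n)
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)
  # cached nearest neighbour per active row; valid because average linkage
  # is reducible (a merged cluster is never closer than its parts)
  nn_idx <- integer(n)
  nn_dist <- numeric(n)
  for (r in seq_len(n)) {
    nn_idx[r] <- which.min(D[r, ])
    nn_dist[r] <- D[r, nn_idx[r]]
  }

  for (k in seq_len(n - 1L)) {
    m <- min(nn_dist[active])
    rows <- which(active & nn_dist == m)
    cand <- do.call(rbind, lapply(rows, function(r) {
      js <- which(D[r, ] == m)
      cbind(r, js)
    }))
    cand <- cand[cand[, 1L] < cand[, 2L], , drop = FALSE]
    # deterministic tie-break on (min id, max id)
    key_lo <- pmin(id[cand[, 1L]], id[cand[, 2L]])
    key_hi <- pmax(id[cand[, 1L]], id[cand[, 2L]])
    pick <- order(key_lo, key_hi)[1L]
    i <- cand[pick, 1L]; j <- cand[pick, 2L]

    merge[k, ] <- sort(c(node[i], node[j]))
    height[k] <- m
    # Lance-Williams: unweighted mean over all leaf pairs
    upd <- which(active & seq_len(n) != i & seq_len(n) != j)
    D[i, upd] <- D[upd, i] <- (size[i] * D[i, upd] + size[j] * D[j, upd]) /
      (size[i] + size[j])
    size[i] <- size[i] + size[j]
    node[i] <- k
    id[i] <- n + k
    active[j] <- FALSE
    D[i, j] <- D[j, i] <- Inf
    D[j, upd] <- D[upd, j] <- Inf
    nn_dist[j] <- Inf

    if (k < n - 1L) {
      # rows pointing at a merged slot may hold a stale minimum: recompute;
      # every other row can only improve via the new cluster i
      stale <- which(active & (nn_idx == i | nn_idx == j) & seq_len(n) != i)
      for (r in c(i, stale)) {
        nn_idx[r] <- which.min(D[r, ])
        nn_dist[r] <- D[r, nn_idx[r]]
      }
      others <- setdiff(upd, stale)
      better <- others[D[others, i] < nn_dist[others]]
      nn_dist[better] <- D[better, i]
      nn_idx[better] <- i
    }
  }

  # depth-first leaf order, lower original index first
  min_leaf <- function(x) if (x < 0) -x else min_cache[[x]]
  min_cache <- integer(n - 1L)
  collect <- vector("list", n - 1L)
  for (k in seq_len(n - 1L)) {
    ch <- merge[k, ]
    mins <- vapply(ch, min_leaf, integer(1L))
    ord <- order(mins)
    min_cache[[k]] <- min(mins)
    collect[[k]] <- unlist(lapply(ch[ord], function(x) {
      if (x < 0) -x else collect[[x]]
    }))
  }
  structure(list(merge = merge, height = height,
                 order = as.integer(collect[[n - 1L]]), labels = labels,
                 method = "average", dist.method = "custom"),
            class = "hclust")
}

#' Hierarchically cluster differentially expressed genes and samples
#'
#' Reproduces the Cluster 3.0 configuration: log2 transform, median
#' centering per gene, centered correlation as the similarity metric
#' (distance = 1 - r) and average linkage, applied to both the gene and the
#' sample margins.
#'
#' @param rpkm_mat post-replacement RPKM matrix.
#' @param de_genes character vector of genes to cluster (>= 2).
#' @return A `cluster_result` list: `matrix` (preprocessed values in
#'   original row order), `gene_tree`, `sample_tree` (each an `hclust` from
#'   [average_linkage()]), `gene_order`, `sample_order` (label
#'   permutations).
#' @export
cluster_de_genes <- function(rpkm_mat, de_genes) {
  if (length(de_genes) < 2L)
    stop("cluster_de_genes: need at least 2 genes")
  x <- preprocess_cluster(rpkm_mat, de_genes)
  gene_tree <- average_linkage(.cor_dist_rows(x))
  sample_tree <- average_linkage(.cor_dist_rows(t(x)))
  structure(list(matrix = x,
                 gene_tree = gene_tree, sample_tree = sample_tree,
                 gene_order = rownames(x)[gene_tree$order],
                 sample_order = colnames(x)[sample_tree$order]),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat("cluster_result:", nrow(x$matrix), "genes x", ncol(x$matrix),
      "samples (average linkage, centered correlation)\n")
  invisible(x)
}

#' Write Cluster 3.0 / Java TreeView output files
#'
#' Emits `<prefix>.cdt` (the reordered matrix with GENE/ARRY ids),
#' `<prefix>.gtr` and `<prefix>.atr` (gene and array merge records; the
#' score column is the merge similarity, 1 - distance), plus
#' `<prefix>_matrix.tsv`, a plain reordered matrix.
#'
#' @param result a `cluster_result` from [cluster_de_genes()].
#' @param prefix output path prefix.
#' @return Named vector of written paths, invisibly.
#' @export
write_treeview <- function(result, prefix) {
  stopifnot(inherits(result, "cluster_result"))
  x <- result$matrix
  gid <- stats::setNames(sprintf("GENE%dX", seq_len(nrow(x))), rownames(x))
  aid <- stats::setNames(sprintf("ARRY%dX", seq_len(ncol(x))), colnames(x))

  tree_lines <- function(tree, ids, tag) {
    ref <- function(v, k) if (v < 0) ids[tree$labels[-v]] else sprintf("%s%dX", tag, v)
    vapply(seq_along(tree$height), function(k) {
      paste(sprintf("%s%dX", tag, k),
            ref(tree$merge[k, 1L]), ref(tree$merge[k, 2L]),
            format(1 - tree$height[k], digits = 10), sep = "\t")
    }, character(1L))
  }

  paths <- c(cdt = paste0(prefix, ".cdt"), gtr = paste0(prefix, ".gtr"),
             atr = paste0(prefix, ".atr"),
             matrix = paste0(prefix, "_matrix.tsv"))
  writeLines(tree_lines(result$gene_tree, gid, "NODE"), paths[["gtr"]])
  writeLines(tree_lines(result$sample_tree, aid, "NODE"), paths[["atr"]])

  ord_g <- result$gene_order
  ord_a <- result$sample_order
  hdr <- paste(c("GID", "UNIQID", "NAME", "GWEIGHT", ord_a), collapse = "\t")
  aid_row <- paste(c("AID", "", "", "", aid[ord_a]), collapse = "\t")
  ew_row <- paste(c("EWEIGHT", "", "", "", rep("1", length(ord_a))), collapse = "\t")
  rows <- vapply(ord_g, function(g) {
    paste(c(gid[g], g, g, "1", format(x[g, ord_a], digits = 10)), collapse = "\t")
  }, character(1L))
  writeLines(c(hdr, aid_row, ew_row, rows), paths[["cdt"]])

  reord <- data.frame(gene_id = ord_g, x[ord_g, ord_a, drop = FALSE],
                      check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv(reord, paths[["matrix"]])
  invisible(paths)
}
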