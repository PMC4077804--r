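# Independent oracles and small fixture builders shared across tests.

# brute-force average linkage: clusters as leaf-index sets; at every step the
# inter-cluster distance is recomputed as the mean over all original leaf
# pairs (no Lance-Williams update). Returns the sequence of merge heights.
brute_force_average_heights <- function(d) {
  n <- nrow(d)
  clusters <- as.list(seq_len(n))
  heights <- numeric(0)
  while (length(clusters) > 1L) {
    m <- length(clusters)
    best <- Inf; bi <- bj <- NA
    for (i in seq_len(m - 1L)) for (j in (i + 1L):m) {
      dist_ij <- mean(d[clusters[[i]], clusters[[j]]])
      if (dist_ij < best) { best <- dist_ij; bi <- i; bj <- j }
    }
    heights <- c(heights, best)
    clusters[[bi]] <- c(clusters[[bi]], clusters[[bj]])
    clusters[[bj]] <- NULL
  }
  heights
}

# exhaustive hypergeometric upper tail: enumerate all C(N, n) focus draws
# from a universe of size N containing K set members; P(overlap >= k).
enumerate_hyper_upper <- function(k, K, n, N) {
  draws <- utils::combn(N, n)
  in_set <- seq_len(K)   # wlog the first K universe elements are the set
  hits <- apply(draws, 2L, function(dr) sum(dr %in% in_set) >= k)
  mean(hits)
}

# minimal two-group fixture: one chromosome, disjoint exons, named samples
make_groups <- function(n_per_group = 3L) {
  samples <- c(paste0("mut_", seq_len(n_per_group)),
               paste0("ctl_", seq_len(n_per_group)))
  stats::setNames(rep(c("mutant", "control"), each = n_per_group), samples)
}

make_count_matrix <- function(rows, groups) {
  m <- do.call(rbind, rows)
  storage.mode(m) <- "integer"
  colnames(m) <- names(groups)
  m
}

# disjoint single-exon-per-row models: one exon per "gene" unless gene_ids
# repeats, lengths as given
make_models <- function(exon_ids, gene_ids, lengths) {
  start <- cumsum(c(1, utils::head(lengths + 100, -1)))
  gene_models(data.frame(exon_id = exon_ids, gene_id = gene_ids,
                         chrom = "chr1", start = as.integer(start),
                         end = as.integer(start + lengths - 1)))
}

# small simulated dataset used by several files
small_sim <- function(seed = 42, n_genes = 120, ...) {
  simulate_dataset(sim_params(n_genes = n_genes, seed = seed, ...))
}
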