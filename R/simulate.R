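#' Parameters for the two-group negative-binomial count simulator
#'
#' Defines the synthetic study: two genotype groups (mutant vs control) with
#' `n_per_group` replicates each, `n_genes` multi-exon genes, and exon-level
#' counts drawn from a negative binomial with mean
#' `baseline x group effect x exon multiplier x library factor` and
#' variance `mu + mu^2 * nb_dispersion`. A fraction of genes is planted as
#' differentially expressed (whole-gene fold change), a disjoint fraction as
#' differential exon usage (one exon scaled in the mutant group), and a
#' further fraction of null genes is placed so its expected maximum sample
#' count falls in [30, 70] reads, straddling the 50-read reliability
#' threshold.
#'
#' Defaults emulate the scale of an embryonic heart-valve RNA-seq
#' comparison: 3 replicates per genotype, ~19,000 genes averaging ~8 exons,
#' a wide log-normal spread of baseline expression, and modest library-size
#' variation.
#'
#' @param n_genes number of genes.
#' @param exons_per_gene integer range `c(min, max)` of exons per gene.
#' @param exon_length_bases integer range of exon lengths.
#' @param n_per_group replicates per group.
#' @param mean_expression_log2 `c(mu, sigma)` of the log2-normal baseline
#'   gene mean (expected reads per gene at library factor 1).
#' @param nb_dispersion negative-binomial dispersion (NB size = 1/dispersion).
#' @param library_size_factors per-sample positive multipliers of expected
#'   counts, length `2 * n_per_group`.
#' @param frac_de fraction of genes planted as differentially expressed.
#' @param de_log2fc `c(low, high)` magnitude range of planted log2 fold
#'   changes (sign random).
#' @param frac_deu fraction of genes planted with differential exon usage.
#' @param deu_exon_multiplier multiplier applied to one exon of each DEU gene
#'   in the mutant group (positive, != 1).
#' @param frac_boundary fraction of null genes rescaled so the expected
#'   maximum sample count lies in [30, 70] reads.
#' @param seed integer RNG seed.
#' @return A validated `sim_params` list.
#' @export
sim_params <- function(n_genes = 19000,
                       exons_per_gene = c(4L, 12L),
                       exon_length_bases = c(80L, 400L),
                       n_per_group = 3L,
                       mean_expression_log2 = c(7, 2.5),
                       nb_dispersion = 0.05,
                       library_size_factors = c(0.9, 1.0, 1.1, 0.95, 1.05, 1.0),
                       frac_de = 0.1,
                       de_log2fc = c(1, 3),
                       frac_deu = 0.05,
                       deu_exon_multiplier = 3,
                       frac_boundary = 0.05,
                       seed = 1L) {
  p <- list(n_genes = as.integer(n_genes),
            exons_per_gene = as.integer(exons_per_gene),
            exon_length_bases = as.integer(exon_length_bases),
            n_per_group = as.integer(n_per_group),
            mean_expression_log2 = as.numeric(mean_expression_log2),
            nb_dispersion = as.numeric(nb_dispersion),
            library_size_factors = as.numeric(library_size_factors),
            frac_de = as.numeric(frac_de),
            de_log2fc = as.numeric(de_log2fc),
            frac_deu = as.numeric(frac_deu),
            deu_exon_multiplier = as.numeric(deu_exon_multiplier),
            frac_boundary = as.numeric(frac_boundary),
            seed = as.integer(seed))
  if (p$n_genes < 1L) stop("sim_params: n_genes must be positive")
  if (p$n_per_group < 1L) stop("sim_params: n_per_group must be positive")
  for (rng in c("exons_per_gene", "exon_length_bases", "de_log2fc")) {
    v <- p[[rng]]
    if (length(v) != 2L || v[1] > v[2])
      stop("sim_params: ", rng, " must be a (min, max) range with min <= max")
  }
  if (p$exons_per_gene[1] < 1L) stop("sim_params: exons_per_gene must be >= 1")
  if (p$nb_dispersion <= 0) stop("sim_params: nb_dispersion must be positive")
  if (length(p$library_size_factors) != 2L * p$n_per_group)
    stop("sim_params: library_size_factors must have length 2 * n_per_group")
  if (any(p$library_size_factors <= 0))
    stop("sim_params: library_size_factors must be positive")
  for (fr in c("frac_de", "frac_deu", "frac_boundary")) {
    if (p[[fr]] < 0 || p[[fr]] > 1)
      stop("sim_params: ", fr, " must be in [0, 1]")
  }
  if (p$frac_de + p$frac_deu > 1)
    stop("sim_params: frac_de + frac_deu must be <= 1")
  if (p$deu_exon_multiplier <= 0 || p$deu_exon_multiplier == 1)
    stop("sim_params: deu_exon_multiplier must be positive and != 1")
  class(p) <- "sim_params"
  p
}

#' Simulate a two-group exon-level count dataset with known truth
#'
#' Draws exon counts as NB(mean = baseline x group effect x exon multiplier
#' x library factor, dispersion). Exons within a gene are disjoint, laid out
#' left to right with 100-bp gaps, and the gene-level baseline is split
#' across exons in proportion to exon length (uniform coverage). Gene-level
#' counts are obtained downstream by summing exon counts. The same
#' parameters and seed always reproduce the identical dataset.
#'
#' @param params a [sim_params()] object.
#' @return A `sim_dataset` list with elements `models` (a [gene_models()]
#'   object), `exon_counts` (integer matrix, exons x samples), `gene_map`
#'   (exon id -> gene id), `groups` (sample id -> `"mutant"`/`"control"`),
#'   and `truth` (list of per-gene and per-exon truth tables).
#' @export
simulate_dataset <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  set.seed(params$seed)
  n <- params$n_genes
  nrep <- params$n_per_group
  samples <- c(paste0("mut_", seq_len(nrep)), paste0("ctl_", seq_len(nrep)))
  groups <- stats::setNames(rep(c("mutant", "control"), each = nrep), samples)
  libf <- stats::setNames(params$library_size_factors, samples)

  # sample() on a scalar would draw from 1:x, so degenerate ranges need care
  draw_range <- function(lo, hi, m) {
    if (lo == hi) rep(lo, m) else sample(seq(lo, hi), m, replace = TRUE)
  }

  gene_id <- sprintf("G%05d", seq_len(n))
  n_exon <- draw_range(params$exons_per_gene[1], params$exons_per_gene[2], n)
  baseline <- 2^stats::rnorm(n, params$mean_expression_log2[1],
                             params$mean_expression_log2[2])

  # disjoint role assignment: DE, DEU, then boundary among the remaining nulls
  n_de <- round(params$frac_de * n)
  n_deu <- round(params$frac_deu * n)
  perm <- sample.int(n)
  de_idx <- perm[seq_len(n_de)]
  deu_idx <- perm[n_de + seq_len(n_deu)]
  null_idx <- if (n_de + n_deu > 0L) perm[-seq_len(n_de + n_deu)] else perm
  n_bnd <- min(round(params$frac_boundary * n), length(null_idx))
  bnd_idx <- null_idx[seq_len(n_bnd)]

  log2fc <- numeric(n)
  if (n_de > 0L) {
    mag <- stats::runif(n_de, params$de_log2fc[1], params$de_log2fc[2])
    log2fc[de_idx] <- mag * sample(c(-1, 1), n_de, replace = TRUE)
  }
  if (n_bnd > 0L) {
    # expected max sample count = baseline * max(libf); aim inside [30, 70]
    target <- stats::runif(n_bnd, 30, 70)
    baseline[bnd_idx] <- target / max(libf)
  }

  # exon layout: one chromosome, 100-bp intron gaps, 10-kb intergenic gaps
  exon_gene <- rep(gene_id, n_exon)
  exon_rank <- sequence(n_exon)
  exon_id <- paste0(exon_gene, ".E", exon_rank)
  exon_len <- draw_range(params$exon_length_bases[1],
                         params$exon_length_bases[2], length(exon_gene))
  step <- exon_len + 100L
  gene_span <- rowsum(step, exon_gene)[gene_id, 1L] + 10000L
  gene_offset <- c(0, cumsum(gene_span))[seq_len(n)]
  within_start <- unlist(lapply(split(step, factor(exon_gene, levels = gene_id)),
                                function(s) c(0L, cumsum(s))[seq_along(s)]),
                         use.names = FALSE)
  start <- as.integer(gene_offset[match(exon_gene, gene_id)] + within_start + 1L)
  end <- as.integer(start + exon_len - 1L)
  models <- gene_models(data.frame(exon_id = exon_id, gene_id = exon_gene,
                                   chrom = "chr1", start = start, end = end))

  # per-exon baseline: gene baseline split proportional to exon length
  len_sum <- rowsum(as.numeric(exon_len), exon_gene)[gene_id, 1L]
  g_of_e <- match(exon_gene, gene_id)
  exon_base <- baseline[g_of_e] * exon_len / len_sum[g_of_e]

  deu_exon <- rep(NA_character_, n)
  deu_flag_exon <- logical(length(exon_id))
  if (n_deu > 0L) {
    for (gi in deu_idx) {
      ids <- which(g_of_e == gi)
      pick <- ids[sample.int(length(ids), 1L)]
      deu_flag_exon[pick] <- TRUE
      deu_exon[gi] <- exon_id[pick]
    }
  }

  # expected count per exon and sample, then one NB draw per cell
  eff_mut <- 2^log2fc[g_of_e] *
    ifelse(deu_flag_exon, params$deu_exon_multiplier, 1)
  mu <- cbind(outer(exon_base * eff_mut, libf[seq_len(nrep)]),
              outer(exon_base, libf[nrep + seq_len(nrep)]))
  dimnames(mu) <- list(exon_id, samples)
  counts <- matrix(stats::rnbinom(length(mu), mu = as.vector(mu),
                                  size = 1 / params$nb_dispersion),
                   nrow = nrow(mu), dimnames = dimnames(mu))
  storage.mode(counts) <- "integer"

  truth_genes <- data.frame(
    gene_id = gene_id,
    is_de = seq_len(n) %in% de_idx,
    log2fc = log2fc,
    is_deu = seq_len(n) %in% deu_idx,
    deu_exon = deu_exon,
    deu_multiplier = ifelse(seq_len(n) %in% deu_idx,
                            params$deu_exon_multiplier, NA_real_),
    is_boundary = seq_len(n) %in% bnd_idx,
    baseline_mean = baseline,
    stringsAsFactors = FALSE)
  truth_exons <- data.frame(
    exon_id = exon_id,
    gene_id = exon_gene,
    baseline_mean = exon_base,
    is_deu_exon = deu_flag_exon,
    stringsAsFactors = FALSE)

  structure(list(models = models,
                 exon_counts = counts,
                 gene_map = stats::setNames(exon_gene, exon_id),
                 groups = groups,
                 truth = list(genes = truth_genes, exons = truth_exons),
                 params = params),
            class = "sim_dataset")
}

#' Write a simulated dataset as plain-text fixture files
#'
#' Emits the pipeline's input dialects: `exon_counts.tsv` (columns
#' `exon_id`, `gene_id`, then one column per sample), `sample_sheet.tsv`
#' (`sample_id`, `group`), `annotation.gtf` (exon features with `gene_id`
#' and `exon_id` attributes), and the truth tables `truth_genes.tsv` /
#' `truth_exons.tsv`. All files round-trip losslessly through the package's
#' readers.
#'
#' @param dataset a `sim_dataset` from [simulate_dataset()].
#' @param out_dir output directory (created if absent).
#' @return Named character vector of the written paths, invisibly.
#' @export
write_fixture <- function(dataset, out_dir) {
  stopifnot(inherits(dataset, "sim_dataset"))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  paths <- c(exon_counts = file.path(out_dir, "exon_counts.tsv"),
             sample_sheet = file.path(out_dir, "sample_sheet.tsv"),
             gtf = file.path(out_dir, "annotation.gtf"),
             truth_genes = file.path(out_dir, "truth_genes.tsv"),
             truth_exons = file.path(out_dir, "truth_exons.tsv"))
  cnt <- data.frame(exon_id = rownames(dataset$exon_counts),
                    gene_id = unname(dataset$gene_map[rownames(dataset$exon_counts)]),
                    dataset$exon_counts, check.names = FALSE,
                    stringsAsFactors = FALSE)
  write_tsv(cnt, paths[["exon_counts"]])
  write_tsv(data.frame(sample_id = names(dataset$groups),
                       group = unname(dataset$groups)),
            paths[["sample_sheet"]])
  write_gtf(dataset$models, paths[["gtf"]])
  write_tsv(dataset$truth$genes, paths[["truth_genes"]])
  write_tsv(dataset$truth$exons, paths[["truth_exons"]])
  invisible(paths)
}
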