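#' Write a table as tab-delimited UTF-8 text
#'
#' All pipeline outputs share one dialect: tab-delimited, header row,
#' no quoting, NA spelled `NA`.
#'
#' @param df data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, na = "NA",
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a count matrix from TSV
#'
#' Expects a header row, a first id column, optionally a `gene_id` second
#' column (exon-level files), then one integer column per sample. Duplicate
#' ids, non-integer or negative cells are parse errors reported with their
#' line number.
#'
#' @param path path to the TSV file.
#' @param gene_column does the file carry a `gene_id` second column?
#'   Default: autodetected from the header.
#' @return List with `counts` (integer matrix, ids x samples) and
#'   `gene_map` (named character vector, or NULL for gene-level files).
#' @export
read_counts <- function(path, gene_column = NULL) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character", check.names = FALSE)
  if (ncol(df) < 2L)
    stop("read_counts: ", path, ": need an id column plus sample columns")
  if (is.null(gene_column))
    gene_column <- ncol(df) >= 3L && names(df)[2L] == "gene_id"
  ids <- df[[1L]]
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0L)
    stop("read_counts: ", path, ": duplicate id '", dup[1L], "' at line ",
         which(ids == dup[1L])[2L] + 1L)
  gene_map <- NULL
  first_sample <- 2L
  if (gene_column) {
    gene_map <- stats::setNames(df[[2L]], ids)
    first_sample <- 3L
  }
  if (ncol(df) < first_sample)
    stop("read_counts: ", path, ": no sample columns")
  cells <- as.matrix(df[, first_sample:ncol(df), drop = FALSE])
  bad <- matrix(!grepl("^[0-9]+$", cells), nrow(cells))
  if (any(bad)) {
    at <- which(bad, arr.ind = TRUE)[1L, ]
    stop("read_counts: ", path, ": non-integer count '",
         cells[at[1L], at[2L]], "' at line ", at[1L] + 1L)
  }
  counts <- matrix(as.integer(cells), nrow = nrow(cells),
                   dimnames = list(ids, colnames(cells)))
  list(counts = counts, gene_map = gene_map)
}

#' Read a sample sheet
#'
#' TSV with header columns `sample_id` and `group`; exactly two groups are
#' required.
#'
#' @param path path to the sample sheet.
#' @return Named character vector, sample id -> group label.
#' @export
read_sample_sheet <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character")
  if (!all(c("sample_id", "group") %in% names(df)))
    stop("read_sample_sheet: ", path, ": need columns sample_id, group")
  if (anyDuplicated(df$sample_id))
    stop("read_sample_sheet: ", path, ": duplicate sample_id")
  groups <- stats::setNames(df$group, df$sample_id)
  if (length(unique(groups)) != 2L)
    stop("read_sample_sheet: ", path, ": exactly two groups required, got ",
         length(unique(groups)))
  groups
}

#' Pipeline configuration
#'
#' Collects every input path and threshold of the end-to-end analysis. The
#' defaults are the printed cut-offs of the original protocol: 50-read
#' reliable quantification threshold, 10-read gene replacement floor,
#' 1-read exon floor, 10-read Venn detection threshold, p < 0.05 and
#' 1.5-fold selection.
#'
#' @param exon_counts path to the exon-level count TSV.
#' @param sample_sheet path to the sample sheet TSV.
#' @param gtf path to the exon annotation GTF.
#' @param gmt optional path to a GMT gene-set collection (enrichment is
#'   skipped when NULL).
#' @param out_dir output directory.
#' @param group_a,group_b the fold-change numerator / denominator group
#'   labels; default: taken from the sample sheet in order of appearance.
#' @param k_quant,k_floor_gene,k_floor_exon,k_det count thresholds.
#' @param p_cut,fc_cut differential-expression cutoffs.
#' @param anova_scale `"log2"` or `"linear"` analysis scale for the
#'   gene-level ANOVA.
#' @param min_exons minimum retained exons for the top-spliced ranking.
#' @param seed integer recorded in the manifest (the analysis itself is
#'   deterministic).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(exon_counts, sample_sheet, gtf, gmt = NULL,
                            out_dir = ".",
                            group_a = NULL, group_b = NULL,
                            k_quant = 50, k_floor_gene = 10, k_floor_exon = 1,
                            k_det = 10, p_cut = 0.05, fc_cut = 1.5,
                            anova_scale = "log2", min_exons = 10,
                            seed = 1L) {
  cfg <- list(exon_counts = exon_counts, sample_sheet = sample_sheet,
              gtf = gtf, gmt = gmt, out_dir = out_dir,
              group_a = group_a, group_b = group_b,
              k_quant = k_quant, k_floor_gene = k_floor_gene,
              k_floor_exon = k_floor_exon, k_det = k_det,
              p_cut = p_cut, fc_cut = fc_cut,
              anova_scale = match.arg(anova_scale, c("log2", "linear")),
              min_exons = min_exons, seed = as.integer(seed))
  for (thr in c("k_quant", "k_floor_gene", "k_floor_exon", "k_det"))
    if (cfg[[thr]] < 0) stop("pipeline_config: ", thr, " must be non-negative")
  if (cfg$p_cut <= 0 || cfg$p_cut > 1)
    stop("pipeline_config: p_cut must be in (0, 1]")
  if (cfg$fc_cut < 1) stop("pipeline_config: fc_cut must be >= 1")
  class(cfg) <- "pipeline_config"
  cfg
}

#' Run the full analysis pipeline
#'
#' Executes quantification (RPKM + thresholds), differential expression
#' (ANOVA, fold change, Venn classification), hierarchical clustering of
#' the DE genes, splicing-index analysis, and (when a GMT is supplied)
#' over-representation analysis, writing every result table plus a JSON run
#' manifest into `out_dir`. The run is deterministic given the inputs.
#'
#' @param config a [pipeline_config()].
#' @return Invisibly, a list with every intermediate result plus `manifest`
#'   and `paths`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  if (!dir.exists(config$out_dir))
    dir.create(config$out_dir, recursive = TRUE)
  outfile <- function(x) file.path(config$out_dir, x)
  paths <- character(0)

  ## --- quantify ---
  rd <- read_counts(config$exon_counts)
  if (is.null(rd$gene_map))
    stop("quantify: exon count file must carry a gene_id column")
  groups <- read_sample_sheet(config$sample_sheet)
  if (!all(colnames(rd$counts) %in% names(groups)))
    stop("quantify: sample(s) missing from sample sheet: ",
         paste(setdiff(colnames(rd$counts), names(groups)), collapse = ", "))
  groups <- groups[colnames(rd$counts)]
  group_a <- if (is.null(config$group_a)) unique(groups)[1] else config$group_a
  group_b <- if (is.null(config$group_b)) unique(groups)[2] else config$group_b
  models <- read_gtf_models(config$gtf)

  gene_counts <- sum_gene_counts(rd$counts, rd$gene_map)
  lib <- library_sizes(gene_counts)
  reliable <- filter_reliable(gene_counts, config$k_quant)
  message("quantify: ", length(reliable), " of ", nrow(gene_counts),
          " genes pass the ", config$k_quant, "-read threshold")

  if (length(reliable) == 0L) {
    de <- data.frame(gene_id = character(0), mean_a = numeric(0),
                     mean_b = numeric(0), fold_change = numeric(0),
                     F = numeric(0), p = numeric(0), p_adj_info = numeric(0),
                     direction = character(0), venn_class = character(0))
    paths["de"] <- write_tsv(de, outfile("de_results.tsv"))
    manifest <- list(thresholds = config[c("k_quant", "k_floor_gene",
                                           "k_floor_exon", "k_det", "p_cut",
                                           "fc_cut")],
                     seed = config$seed,
                     package_version = as.character(utils::packageVersion("rpkmsplice")),
                     counts = list(n_genes_input = nrow(gene_counts),
                                   n_reliable_genes = 0L))
    jsonlite::write_json(manifest, outfile("manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    message("pipeline: no reliable genes; wrote empty DE table")
    return(invisible(list(de = de, manifest = manifest, paths = paths)))
  }

  glen <- gene_lengths(models)
  gene_abund <- apply_replacement(gene_counts[reliable, , drop = FALSE],
                                  glen, lib, config$k_floor_gene)
  paths["gene_rpkm"] <- write_tsv(
    data.frame(gene_id = rownames(gene_abund$rpkm), gene_abund$rpkm,
               check.names = FALSE),
    outfile("gene_rpkm.tsv"))

  ## --- diffexpr + venn ---
  de <- de_table(gene_abund, gene_counts[reliable, , drop = FALSE], groups,
                 group_a, group_b, k_quant = config$k_quant,
                 scale = config$anova_scale)
  venn <- classify_venn(gene_counts[reliable, , drop = FALSE], groups,
                        group_a, group_b, k_det = config$k_det)
  de$venn_class <- as.character(venn$venn_class[match(de$gene_id, venn$gene_id)])
  calls <- call_de(de, config$p_cut, config$fc_cut)
  message("diffexpr: ", length(calls$de_set), " DE genes (p < ", config$p_cut,
          "), ", length(calls$fc_set), " also pass the ", config$fc_cut,
          "-fold filter")
  paths["de"] <- write_tsv(de, outfile("de_results.tsv"))
  paths["venn"] <- write_tsv(venn, outfile("venn.tsv"))

  ## --- cluster ---
  clus <- NULL
  if (length(calls$de_set) >= 2L) {
    clus <- cluster_de_genes(gene_abund$rpkm, calls$de_set)
    paths <- c(paths, write_treeview(clus, outfile("cluster")))
    message("cluster: ", length(calls$de_set), " DE genes clustered")
  } else {
    message("cluster: fewer than 2 DE genes; skipped")
  }

  ## --- splicing ---
  retained_exons <- filter_exons(rd$counts, rd$gene_map, reliable)
  elen <- exon_lengths(models)
  exon_abund <- apply_replacement(rd$counts[retained_exons, , drop = FALSE],
                                  elen, lib, config$k_floor_exon)
  si <- splicing_index(exon_abund, gene_abund,
                       gene_counts[reliable, , drop = FALSE],
                       rd$gene_map, config$k_quant)
  sp <- exon_anova_tukey(si, groups, group_a, group_b, config$p_cut)
  sp_sum <- splicing_gene_summary(sp, config$min_exons)
  si_df <- data.frame(exon_id = rownames(si), gene_id = sp$gene_id, si,
                      check.names = FALSE)
  paths["splicing"] <- write_tsv(
    cbind(si_df, sp[, c("F", "p", "tukey_diff", "tukey_p", "significant")]),
    outfile("splicing_results.tsv"))
  paths["splicing_summary"] <- write_tsv(sp_sum,
                                         outfile("splicing_gene_summary.tsv"))
  n_spliced <- length(unique(sp$gene_id[sp$significant %in% TRUE]))
  message("splicing: ", length(retained_exons), " exons retained, ",
          sum(sp$significant %in% TRUE), " significant exons in ",
          n_spliced, " genes")

  ## --- enrichment ---
  enr <- NULL
  if (!is.null(config$gmt)) {
    sets <- read_gmt(config$gmt)
    focus <- select_focus(de, universe = reliable,
                          p_cut = config$p_cut, fc_cut = config$fc_cut)
    enr <- ora(focus, sets, universe = reliable)
    paths["enrichment"] <- write_tsv(enr, outfile("enrichment.tsv"))
    message("enrichment: ", sum(enr$enriched), " of ", nrow(enr),
            " sets enriched (adjusted p < 0.05)")
  }

  ## --- manifest ---
  vt <- table(venn$venn_class)
  dir_tab <- table(factor(de$direction[de$p < config$p_cut],
                          levels = c("up", "down", "none")))
  manifest <- list(
    thresholds = config[c("k_quant", "k_floor_gene", "k_floor_exon", "k_det",
                          "p_cut", "fc_cut", "anova_scale")],
    groups = list(group_a = group_a, group_b = group_b,
                  samples = as.list(groups)),
    seed = config$seed,
    package_version = as.character(utils::packageVersion("rpkmsplice")),
    counts = list(
      n_genes_input = nrow(gene_counts),
      n_exons_input = nrow(rd$counts),
      n_reliable_genes = length(reliable),
      n_de = length(calls$de_set),
      n_de_up = unname(dir_tab[["up"]]),
      n_de_down = unname(dir_tab[["down"]]),
      n_de_undirected = unname(dir_tab[["none"]]),
      n_fc_filtered = length(calls$fc_set),
      n_fc_up = length(calls$up_set),
      n_fc_down = length(calls$down_set),
      venn_unique_a = unname(vt[["unique_A"]]),
      venn_unique_b = unname(vt[["unique_B"]]),
      venn_common = unname(vt[["common"]]),
      venn_excluded = unname(vt[["excluded"]]),
      n_exons_retained = length(retained_exons),
      n_exons_tested = sum(!is.na(sp$p)),
      n_exons_significant = sum(sp$significant %in% TRUE),
      n_spliced_genes = n_spliced,
      n_sets_tested = if (is.null(enr)) 0L else nrow(enr),
      n_sets_enriched = if (is.null(enr)) 0L else sum(enr$enriched)))
  paths["manifest"] <- outfile("manifest.json")
  jsonlite::write_json(manifest, paths[["manifest"]],
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  invisible(list(models = models, gene_counts = gene_counts,
                 library_sizes = lib, reliable = reliable,
                 gene_abundance = gene_abund, de = de, venn = venn,
                 calls = calls, cluster = clus, exon_abundance = exon_abund,
                 splicing = sp, splicing_summary = sp_sum, si = si,
                 enrichment = enr, manifest = manifest, paths = paths))
}
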