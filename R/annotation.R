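#' Gene models: exon intervals and RPKM length denominators
#'
#' A `gene_models` object is a data frame with one row per exon and columns
#' `exon_id`, `gene_id`, `chrom`, `start`, `end` (1-based, inclusive, GTF
#' convention). It carries the per-kilobase denominators used for RPKM:
#' the exon length is `end - start + 1`, and the gene length is the length
#' of the union of its exon intervals, so overlapping exons are not counted
#' twice.
#'
#' @param exons data frame with columns `exon_id`, `gene_id`, `chrom`,
#'   `start`, `end`.
#' @return A `gene_models` object (a validated data frame).
#' @examples
#' gm <- gene_models(data.frame(
#'   exon_id = c("e1", "e2"), gene_id = "g1", chrom = "chr1",
#'   start = c(1L, 201L), end = c(100L, 300L)))
#' gene_lengths(gm)   # 200
#' @export
gene_models <- function(exons) {
  required <- c("exon_id", "gene_id", "chrom", "start", "end")
  missing_cols <- setdiff(required, names(exons))
  if (length(missing_cols) > 0L)
    stop("gene_models: missing columns: ", paste(missing_cols, collapse = ", "))
  exons <- as.data.frame(exons)[required]
  exons$exon_id <- as.character(exons$exon_id)
  exons$gene_id <- as.character(exons$gene_id)
  exons$chrom <- as.character(exons$chrom)
  exons$start <- as.integer(exons$start)
  exons$end <- as.integer(exons$end)
  if (anyNA(exons$start) || anyNA(exons$end))
    stop("gene_models: non-integer exon coordinates")
  if (any(exons$end < exons$start))
    stop("gene_models: exon end < start")
  if (anyDuplicated(exons$exon_id))
    stop("gene_models: duplicate exon_id: ",
         paste(unique(exons$exon_id[duplicated(exons$exon_id)]), collapse = ", "))
  class(exons) <- c("gene_models", "data.frame")
  exons
}

#' Per-exon lengths in bases
#'
#' @param models a `gene_models` object.
#' @return Named numeric vector of `end - start + 1`, one entry per exon.
#' @export
exon_lengths <- function(models) {
  stopifnot(inherits(models, "gene_models"))
  stats::setNames(as.numeric(models$end - models$start + 1L), models$exon_id)
}

#' Per-gene union lengths in bases
#'
#' The gene length is the number of bases covered by the union of the gene's
#' exon intervals (the convention used when reads are counted over exons at
#' the gene level): for disjoint exons it equals the sum of exon lengths,
#' and overlapping exons contribute each base once.
#'
#' @param models a `gene_models` object.
#' @return Named numeric vector of union lengths, one entry per gene.
#' @export
gene_lengths <- function(models) {
  stopifnot(inherits(models, "gene_models"))
  gr <- GenomicRanges::GRanges(
    seqnames = models$chrom,
    ranges = IRanges::IRanges(start = models$start, end = models$end))
  by_gene <- GenomicRanges::split(gr, models$gene_id)
  len <- sum(IRanges::width(GenomicRanges::reduce(by_gene)))
  stats::setNames(as.numeric(len), names(len))
}

#' Read exon gene models from a GTF file
#'
#' Only `exon` feature lines are used; the attributes `gene_id` and `exon_id`
#' are required and every other attribute is ignored. Coordinates are taken
#' as printed (1-based, inclusive).
#'
#' @param path path to a GTF file.
#' @return A [gene_models()] object.
#' @export
read_gtf_models <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  gr <- gr[tolower(as.character(gr$type)) == "exon"]
  if (length(gr) == 0L)
    stop("read_gtf_models: no exon features in ", path)
  meta <- GenomicRanges::mcols(gr)
  if (is.null(meta$gene_id))
    stop("read_gtf_models: missing gene_id attribute in ", path)
  exon_id <- meta$exon_id
  if (is.null(exon_id)) {
    # fall back to a positional id when the annotation carries none
    exon_id <- paste0(meta$gene_id, ":",
                      GenomicRanges::start(gr), "-", GenomicRanges::end(gr))
  }
  gene_models(data.frame(
    exon_id = as.character(exon_id),
    gene_id = as.character(meta$gene_id),
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr)))
}

#' Write gene models as a GTF file
#'
#' Emits one `exon` feature line per exon with `gene_id` and `exon_id`
#' attributes, suitable for [read_gtf_models()].
#'
#' @param models a `gene_models` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(models, path) {
  stopifnot(inherits(models, "gene_models"))
  lines <- sprintf(
    "%s\trpkmsplice\texon\t%d\t%d\t.\t+\t.\tgene_id \"%s\"; exon_id \"%s\";",
    models$chrom, models$start, models$end, models$gene_id, models$exon_id)
  writeLines(lines, path)
  invisible(path)
}
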