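#' Gene model tables
#'
#' Genes are tibbles with columns `gene_id`, `chrom`, `start`, `end` (gene
#' body, 0-based half-open) and `strand` (`"+"` or `"-"`). The TSS and TES
#' positions are derived from the strand: for `"+"` genes the TSS is the
#' first body base, for `"-"` genes the last. Expression values live in
#' separate tidy tables keyed by `gene_id`.
#'
#' @param x Data frame with `gene_id`, `chrom`, `strand` and either
#'   `start`/`end` or `tss`/`tes` (positions of the TSS and TES bases; for
#'   `"-"` genes `tss > tes`).
#' @return A validated gene tibble with `gene_id`, `chrom`, `start`, `end`,
#'   `strand`, `tss`, `tes`.
#' @export
gene_tbl <- function(x) {
  x <- as_tibble(x)
  if (!all(c("gene_id", "chrom", "strand") %in% names(x))) {
    abort("gene table needs gene_id, chrom and strand columns")
  }
  if (!all(x$strand %in% c("+", "-"))) abort("strand must be '+' or '-'")
  if (all(c("tss", "tes") %in% names(x)) && !all(c("start", "end") %in% names(x))) {
    flip <- x$strand == "-"
    if (any(flip & x$tss <= x$tes) || any(!flip & x$tss >= x$tes)) {
      abort("tss/tes orientation inconsistent with strand")
    }
    x$start <- pmin(x$tss, x$tes)
    x$end <- pmax(x$tss, x$tes) + 1
  }
  if (!all(c("start", "end") %in% names(x))) abort("gene table needs start/end or tss/tes")
  if (any(x$start < 0 | x$end <= x$start)) abort("gene body needs 0 <= start < end")
  x$tss <- ifelse(x$strand == "+", x$start, x$end - 1)
  x$tes <- ifelse(x$strand == "+", x$end - 1, x$start)
  arrange(x, .data$chrom, .data$start, .data$end)
}

#' TSS anchor table for a set of genes
#'
#' @param genes Gene tibble.
#' @return Tibble with `gene_id`, `chrom`, `pos` (TSS base), `strand`.
#' @export
gene_tss <- function(genes) {
  tibble(gene_id = genes$gene_id, chrom = genes$chrom, pos = genes$tss, strand = genes$strand)
}

#' Read a gene TSV (gene_id, chrom, tss, tes, strand, optional FPKM columns)
#'
#' @param path Path to a tab-separated file with a header.
#' @return A gene tibble; any extra columns (e.g. per-condition FPKM) are kept.
#' @export
read_gene_table <- function(path) {
  x <- readr::read_tsv(path, col_types = readr::cols(.default = "d", gene_id = "c",
                                                     chrom = "c", strand = "c"),
                       progress = FALSE)
  gene_tbl(x)
}

#' Read gene features from a GFF3 file
#'
#' Keeps only `type == "gene"` records and converts the 1-based inclusive GFF
#' coordinates to the package's 0-based half-open convention.
#'
#' @param path Path to a GFF3 file.
#' @return A gene tibble.
#' @export
read_gff_genes <- function(path) {
  gr <- rtracklayer::import(path)
  gr <- gr[!is.na(S4Vectors::mcols(gr)$type) & S4Vectors::mcols(gr)$type == "gene"]
  if (length(gr) == 0) abort("no 'gene' features found in GFF3 file")
  ids <- S4Vectors::mcols(gr)$ID
  if (is.null(ids) || anyNA(ids)) {
    alt <- S4Vectors::mcols(gr)$gene_id
    ids <- if (!is.null(alt)) alt else as.character(seq_along(gr))
  }
  gene_tbl(tibble(
    gene_id = as.character(ids),
    chrom = as.character(GenomeInfoDb::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1,
    end = as.numeric(GenomicRanges::end(gr)),
    strand = ifelse(as.character(GenomicRanges::strand(gr)) == "-", "-", "+")
  ))
}
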