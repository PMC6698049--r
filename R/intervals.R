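#' Genomic interval tables
#'
#' chromdyn represents genomic intervals as plain tibbles with columns
#' `chrom`, `start`, `end` (BED convention: 0-based, half-open) plus optional
#' `name`, `score` and `strand` columns. `interval_tbl()` validates such a
#' table, sorts it by (chrom, start, end) and, when a genome table is
#' supplied, checks every interval against its chromosome length and records
#' the genome in the `"genome"` attribute so downstream coverage statistics
#' can find it.
#'
#' @param x A data frame with at least `chrom`, `start`, `end`.
#' @param genome Optional genome table as returned by [genome_tbl()].
#' @return A sorted tibble of intervals, with the genome (if any) attached as
#'   the `"genome"` attribute.
#' @examples
#' g <- genome_tbl(c(chr1 = 1000))
#' interval_tbl(data.frame(chrom = "chr1", start = 0, end = 200), g)
#' @export
interval_tbl <- function(x, genome = NULL) {
  x <- as_tibble(x)
  need <- c("chrom", "start", "end")
  missing_cols <- setdiff(need, names(x))
  if (length(missing_cols) > 0) {
    abort(paste0("interval table lacks column(s): ", paste(missing_cols, collapse = ", ")))
  }
  x$chrom <- as.character(x$chrom)
  bad <- which(!(x$start >= 0 & x$end > x$start))
  if (length(bad) > 0) {
    abort(sprintf(
      "invalid interval coordinates (need 0 <= start < end) in %d row(s), first at row %d: %s:%s-%s",
      length(bad), bad[1], x$chrom[bad[1]], x$start[bad[1]], x$end[bad[1]]
    ))
  }
  if (!is.null(genome)) {
    genome <- as_genome_tbl(genome)
    unknown <- setdiff(unique(x$chrom), genome$chrom)
    if (length(unknown) > 0) {
      abort(paste0("interval(s) on chromosome(s) absent from the genome table: ",
                   paste(unknown, collapse = ", ")))
    }
    sz <- setNames(genome$size, genome$chrom)
    over <- which(x$end > sz[x$chrom])
    if (length(over) > 0) {
      abort(sprintf("interval end exceeds chromosome length in %d row(s), first at row %d",
                    length(over), over[1]))
    }
  }
  x <- arrange(x, .data$chrom, .data$start, .data$end)
  attr(x, "genome") <- genome
  x
}

#' Genome (chromosome size) tables
#'
#' @param sizes Named numeric vector of chromosome lengths, or a data frame
#'   with columns `chrom` and `size`.
#' @return A tibble with columns `chrom` and `size`.
#' @examples
#' genome_tbl(c(chr1 = 1e6, chr2 = 1e6))
#' @export
genome_tbl <- function(sizes) {
  as_genome_tbl(sizes)
}

as_genome_tbl <- function(genome) {
  if (is.numeric(genome) && !is.null(names(genome))) {
    genome <- tibble(chrom = names(genome), size = unname(as.numeric(genome)))
  }
  genome <- as_tibble(genome)
  if (!all(c("chrom", "size") %in% names(genome))) {
    abort("genome table needs columns 'chrom' and 'size'")
  }
  if (any(genome$size <= 0)) abort("chromosome sizes must be positive")
  genome$chrom <- as.character(genome$chrom)
  genome
}

#' Read a two-column chromosome-sizes file
#'
#' @param path Path to a TSV with chromosome name and length.
#' @return A genome tibble (`chrom`, `size`).
#' @export
read_chrom_sizes <- function(path) {
  x <- readr::read_tsv(path, col_names = c("chrom", "size"),
                       col_types = readr::cols(chrom = "c", size = "d"),
                       progress = FALSE)
  as_genome_tbl(x)
}

interval_genome <- function(x, genome = NULL) {
  g <- genome %||% attr(x, "genome")
  if (is.null(g)) abort("no genome table: pass `genome` or build the intervals with interval_tbl(x, genome)")
  as_genome_tbl(g)
}

check_shared_genome <- function(a, b) {
  ga <- attr(a, "genome"); gb <- attr(b, "genome")
  if (!is.null(ga) && !is.null(gb) && !identical(as.data.frame(ga), as.data.frame(gb))) {
    abort("the two interval sets carry different genome tables")
  }
  ga %||% gb
}

# tibble (0-based half-open) -> GRanges (1-based closed)
as_granges <- function(x, genome = NULL) {
  g <- genome %||% attr(x, "genome")
  sl <- if (!is.null(g)) setNames(as_genome_tbl(g)$size, as_genome_tbl(g)$chrom) else NULL
  lv <- if (!is.null(sl)) names(sl) else unique(x$chrom)
  gr <- GenomicRanges::GRanges(
    seqnames = factor(x$chrom, levels = lv),
    ranges = IRanges::IRanges(start = x$start + 1L, end = x$end)
  )
  if (!is.null(sl)) GenomeInfoDb::seqlengths(gr) <- sl
  gr
}

granges_to_tbl <- function(gr) {
  tibble(
    chrom = as.character(GenomeInfoDb::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1,
    end = as.numeric(GenomicRanges::end(gr))
  )
}

#' Read a BED3/BED6 file into an interval tibble
#'
#' Records on chromosomes absent from the genome table are rejected with an
#' error; malformed lines are reported with their line number. BED6 `name`,
#' `score` and `strand` columns are preserved.
#'
#' @param path Path to a BED file.
#' @param genome Genome table ([genome_tbl()]) covering all records.
#' @return An interval tibble with the genome attached.
#' @export
read_bed <- function(path, genome) {
  genome <- as_genome_tbl(genome)
  lines <- readr::read_lines(path, progress = FALSE)
  keep <- !grepl("^(#|track|browser)", lines) & nzchar(lines)
  lineno <- which(keep)
  parts <- strsplit(lines[keep], "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (length(nf) > 0 && any(nf < 3)) {
    i <- which(nf < 3)[1]
    abort(sprintf("malformed BED line %d: fewer than 3 fields", lineno[i]))
  }
  chrom <- vapply(parts, `[[`, "", 1)
  start <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 2)))
  end <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 3)))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad) > 0) {
    abort(sprintf("malformed BED line %d: non-numeric coordinates", lineno[bad[1]]))
  }
  inv <- which(start >= end | start < 0)
  if (length(inv) > 0) {
    abort(sprintf("invalid coordinates at BED line %d: start %s >= end %s",
                  lineno[inv[1]], start[inv[1]], end[inv[1]]))
  }
  out <- tibble(chrom = chrom, start = start, end = end)
  if (all(nf >= 4)) out$name <- vapply(parts, `[[`, "", 4)
  if (all(nf >= 5)) out$score <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 5)))
  if (all(nf >= 6)) out$strand <- vapply(parts, `[[`, "", 6)
  interval_tbl(out, genome)
}

#' Write an interval tibble as BED
#'
#' Coordinates round-trip bit-exactly through [read_bed()].
#'
#' @param x Interval tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path) {
  cols <- intersect(c("chrom", "start", "end", "name", "score", "strand"), names(x))
  # BED is positional: stop at the first absent optional column
  want <- c("chrom", "start", "end", "name", "score", "strand")
  upto <- max(which(cumsum(want %in% cols) == seq_along(want)))
  df <- as.data.frame(x[, want[seq_len(upto)]])
  df$start <- format(df$start, scientific = FALSE, trim = TRUE)
  df$end <- format(df$end, scientific = FALSE, trim = TRUE)
  readr::write_tsv(df, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Merge overlapping or bookended intervals
#'
#' @param x Interval tibble.
#' @return Interval tibble of maximal disjoint intervals covering the same bases.
#' @export
merge_intervals <- function(x) {
  out <- granges_to_tbl(GenomicRanges::reduce(as_granges(x)))
  attr(out, "genome") <- attr(x, "genome")
  out
}

#' Bases covered by both of two interval sets
#'
#' Total number of bases in the intersection of the merged coverage of `a`
#' and `b`; symmetric in its arguments.
#'
#' @param a,b Interval tibbles sharing a genome.
#' @return Number of shared bases (scalar).
#' @examples
#' g <- genome_tbl(c(chr1 = 1000))
#' a <- interval_tbl(data.frame(chrom = "chr1", start = 0, end = 100), g)
#' b <- interval_tbl(data.frame(chrom = "chr1", start = 50, end = 150), g)
#' overlap_bases(a, b) # 50
#' @export
overlap_bases <- function(a, b) {
  check_shared_genome(a, b)
  ga <- GenomicRanges::reduce(as_granges(a, genome = NULL))
  gb <- GenomicRanges::reduce(as_granges(b, genome = NULL))
  suppressWarnings(
    sum(as.numeric(GenomicRanges::width(GenomicRanges::intersect(ga, gb, ignore.strand = TRUE))))
  )
}

#' Fraction of peaks in one set overlapping another
#'
#' The peak-correlation of set `a` with set `b`: the number of intervals of
#' `a` sharing at least `min_overlap` bases with any interval of `b`, divided
#' by the number of intervals in `a`. Directional: swap the arguments for the
#' correlation of `b` with `a`.
#'
#' @param a,b Interval tibbles; `a` must be non-empty.
#' @param min_overlap Minimum shared bases for an interval to count as
#'   overlapping (default 1).
#' @return A proportion in \[0, 1\].
#' @export
peak_set_correlation <- function(a, b, min_overlap = 1) {
  if (nrow(a) == 0) abort("peak set `a` is empty; the correlation is undefined")
  check_shared_genome(a, b)
  ga <- as_granges(a, genome = NULL)
  gb <- as_granges(b, genome = NULL)
  hits <- suppressWarnings(
    GenomicRanges::countOverlaps(ga, gb, minoverlap = min_overlap, ignore.strand = TRUE)
  )
  mean(hits > 0)
}

#' Percentage of the genome covered by an interval set
#'
#' @param a Interval tibble.
#' @param genome Genome table; defaults to the one attached to `a`.
#' @return Merged coverage of `a` divided by total genome length, times 100.
#' @export
genome_coverage_pct <- function(a, genome = NULL) {
  g <- interval_genome(a, genome)
  cov <- sum(as.numeric(GenomicRanges::width(GenomicRanges::reduce(as_granges(a, genome = NULL)))))
  100 * cov / sum(g$size)
}

#' Distance from each peak to its nearest gene body
#'
#' Distance is 0 when the peak overlaps the gene body (TSS-to-TES span) and
#' otherwise the base-pair gap to the nearest gene body on the same
#' chromosome. Peaks on chromosomes without genes get `NA` with a warning.
#'
#' @param peaks Interval tibble.
#' @param genes Gene table ([gene_tbl()]).
#' @return The `peaks` tibble with added columns `distance` and
#'   `nearest_gene`.
#' @export
nearest_gene_distance <- function(peaks, genes) {
  gp <- as_granges(peaks, genome = NULL)
  gg <- as_granges(genes, genome = NULL)
  GenomeInfoDb::seqlevels(gp) <- union(GenomeInfoDb::seqlevels(gp), GenomeInfoDb::seqlevels(gg))
  GenomeInfoDb::seqlevels(gg) <- GenomeInfoDb::seqlevels(gp)
  hits <- suppressWarnings(GenomicRanges::distanceToNearest(gp, gg, ignore.strand = TRUE))
  distance <- rep(NA_real_, length(gp))
  nearest <- rep(NA_character_, length(gp))
  qh <- S4Vectors::queryHits(hits)
  distance[qh] <- S4Vectors::mcols(hits)$distance
  nearest[qh] <- genes$gene_id[S4Vectors::subjectHits(hits)]
  if (anyNA(distance)) {
    warn(sprintf("%d peak(s) lie on chromosomes with no genes; distance reported as NA",
                 sum(is.na(distance))))
  }
  out <- as_tibble(peaks)
  out$distance <- distance
  out$nearest_gene <- nearest
  out
}
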