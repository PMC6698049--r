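#' Base-pair state-transition accounting between two segmentations
#'
#' Cross-tabulates the two per-window state assignments on their shared grid,
#' weighting each window by its width, so the K x K matrix totals the
#' windowed genome length. Retention of state k is the diagonal entry divided
#' by its row sum (the fraction of the state's bases keeping the same state);
#' relative change is |after - before| coverage over before coverage.
#'
#' @param before,after Segmentation tibbles on identical grids.
#' @param n_states Number of states K; defaults to the largest state id seen.
#' @return A `transition_summary`: `bp_matrix` (K x K), `retention`,
#'   `relative_change`, `coverage_before`, `coverage_after`.
#' @export
state_transition_matrix <- function(before, after, n_states = NULL) {
  if (nrow(before) != nrow(after)) abort("segmentations have different window counts")
  b <- arrange(before, .data$chrom, .data$start)
  a <- arrange(after, .data$chrom, .data$start)
  if (!identical(b$chrom, a$chrom) || !identical(b$start, a$start) || !identical(b$end, a$end)) {
    abort("segmentations are not on the same window grid")
  }
  K <- n_states %||% max(b$state, a$state)
  w <- b$end - b$start
  bp <- matrix(0, K, K)
  tab <- tibble(from = b$state, to = a$state, w = w) %>%
    group_by(.data$from, .data$to) %>%
    summarise(bases = sum(.data$w), .groups = "drop")
  bp[cbind(tab$from, tab$to)] <- tab$bases
  rs <- rowSums(bp); cs <- colSums(bp)
  retention <- ifelse(rs > 0, diag(bp) / rs, NA_real_)
  structure(
    list(
      bp_matrix = bp,
      retention = retention,
      relative_change = ifelse(rs > 0, abs(cs - rs) / rs, NA_real_),
      coverage_before = rs, coverage_after = cs, n_states = K
    ),
    class = "transition_summary"
  )
}

#' @export
print.transition_summary <- function(x, ...) {
  cat(sprintf("<transition_summary> %d states over %s bp\n", x$n_states,
              format(sum(x$bp_matrix), big.mark = ",")))
  cat("retention:", paste(sprintf("%.3f", x$retention), collapse = " "), "\n")
  invisible(x)
}

#' Tidy a state-transition summary
#'
#' `tidy()` returns the long base-pair transition table; `glance()` the
#' per-state retention and relative-change summary.
#'
#' @param x A `transition_summary`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.transition_summary <- function(x, ...) {
  tidyr::expand_grid(from = seq_len(x$n_states), to = seq_len(x$n_states)) %>%
    mutate(bases = as.vector(t(x$bp_matrix)))
}

#' @rdname tidy.transition_summary
#' @export
glance.transition_summary <- function(x, ...) {
  tibble(
    state = seq_len(x$n_states),
    bases_before = x$coverage_before,
    bases_after = x$coverage_after,
    retention = x$retention,
    relative_change = x$relative_change
  )
}

#' State-transition heatmap
#'
#' @param object A `transition_summary`.
#' @param ... Unused.
#' @return A ggplot object (row-normalized transition fractions).
#' @export
autoplot.transition_summary <- function(object, ...) {
  tidy(object) %>%
    group_by(.data$from) %>%
    mutate(fraction = .data$bases / sum(.data$bases)) %>%
    ungroup() %>%
    ggplot2::ggplot(ggplot2::aes(x = factor(.data$to), y = factor(.data$from),
                                 fill = .data$fraction)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(low = "white", high = "#a50f15") +
    ggplot2::labs(x = "state after", y = "state before", fill = "fraction") +
    ggplot2::theme_minimal()
}

#' Relative proportion of a chromatin state changed between conditions
#'
#' The altered (increased or decreased) length of a state divided by its
#' total length before treatment.
#'
#' @param before,after Segmentation tibbles on the same grid.
#' @param states States to report; default all states present before.
#' @return Tibble `state`, `bases_before`, `bases_after`,
#'   `relative_change` (`NA` for states absent before).
#' @export
relative_proportion_changed <- function(before, after, states = NULL) {
  ts <- state_transition_matrix(before, after,
                                n_states = if (is.null(states)) NULL else max(states, before$state, after$state))
  out <- glance(ts) %>% select("state", "bases_before", "bases_after", "relative_change")
  if (!is.null(states)) out <- filter(out, .data$state %in% states)
  out
}

tss_flank_intervals <- function(genes, flank, genome, anchor = c("tss", "body")) {
  anchor <- match.arg(anchor)
  g <- as_genome_tbl(genome)
  sz <- setNames(g$size, g$chrom)
  known <- genes$chrom %in% g$chrom
  if (!all(known)) {
    warn(sprintf("%d gene(s) on chromosomes absent from the genome were skipped", sum(!known)))
    genes <- genes[known, , drop = FALSE]
  }
  if (nrow(genes) == 0) abort("empty anchor set")
  if (anchor == "tss") {
    start <- pmax(genes$tss - flank, 0)
    end <- pmin(genes$tss + flank, unname(sz[genes$chrom]))
    end <- pmax(end, pmin(start + 1, unname(sz[genes$chrom]))) # flank = 0: the TSS base itself
  } else {
    start <- pmax(genes$start - flank, 0)
    end <- pmin(genes$end + flank, unname(sz[genes$chrom]))
  }
  interval_tbl(tibble(chrom = genes$chrom, start = start, end = end,
                      name = genes$gene_id), g)
}

#' Chromatin-state enrichment in gene flanking regions
#'
#' Builds the union of windows around each gene (TSS +/- `flank` by default,
#' gene body +/- `flank` via `anchor = "body"`) and computes each state's
#' fold enrichment against that region set. Differencing the folds between
#' two conditions' segmentations gives the enrichment change of a gene set
#' (e.g. upregulated DEGs) under treatment.
#'
#' @param genes Gene tibble (e.g. the DEG subset).
#' @param seg Segmentation tibble.
#' @param genome Genome table.
#' @param flank Half-width in bp (default 20000).
#' @param anchor `"tss"` (default) or `"body"`.
#' @return Per-state tibble of fold-enrichment rows.
#' @export
gene_flank_state_enrichment <- function(genes, seg, genome, flank = 20000,
                                        anchor = c("tss", "body")) {
  region <- merge_intervals(tss_flank_intervals(genes, flank, genome, anchor))
  state_enrichment(seg, region, genome)
}

#' Genes whose flank contains a specified state transition
#'
#' Returns the genes having at least one window within their +/- `flank`
#' region whose state lies in `from_states` before and in `to_states` after
#' (e.g. bivalent-to-active-promoter transitions near upregulated DEGs).
#'
#' @param genes Gene tibble.
#' @param before,after Segmentation tibbles on the same grid.
#' @param from_states,to_states Disjoint integer state sets.
#' @param genome Genome table.
#' @param flank Half-width in bp (default 20000).
#' @param anchor `"tss"` (default) or `"body"`.
#' @return The subset of `genes` associated with the transition.
#' @export
transition_associated_genes <- function(genes, before, after, from_states, to_states,
                                        genome, flank = 20000,
                                        anchor = c("tss", "body")) {
  if (length(intersect(from_states, to_states)) > 0) {
    abort("from_states and to_states must be disjoint")
  }
  b <- arrange(before, .data$chrom, .data$start)
  a <- arrange(after, .data$chrom, .data$start)
  if (!identical(b$chrom, a$chrom) || !identical(b$start, a$start)) {
    abort("segmentations are not on the same window grid")
  }
  hit <- b$state %in% from_states & a$state %in% to_states
  if (!any(hit)) return(genes[0, , drop = FALSE])
  win <- tibble(chrom = b$chrom[hit], start = b$start[hit], end = b$end[hit])
  flanks <- tss_flank_intervals(genes, flank, genome, anchor)
  gr_f <- as_granges(flanks, genome = NULL)
  gr_w <- as_granges(win, genome = NULL)
  has <- suppressWarnings(GenomicRanges::countOverlaps(gr_f, gr_w)) > 0
  semi_join(genes, tibble(gene_id = flanks$name[has]), by = "gene_id")
}
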