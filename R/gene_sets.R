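#' Classify genes by promoter-proximal chromatin state
#'
#' A gene "has" state s when any window overlapping its body extended by
#' +/- `promoter_flank` is assigned s. The first category (active-promoter
#' genes by default) takes priority: genes with any of its states are
#' assigned there and excluded from every other category. The remaining
#' categories may overlap one another (a gene carrying both a poised-enhancer
#' and a Polycomb window, but no active promoter, is reported in both).
#'
#' @param genes Gene tibble.
#' @param seg Segmentation tibble covering the genes' chromosomes.
#' @param categories Named list mapping category name to the integer state
#'   id(s) defining it; the first entry is the priority category.
#' @param genome Genome table.
#' @param promoter_flank Body extension in bp (default 1000, matching a
#'   +/- 1 kb promoter definition).
#' @return Long tibble `gene_id`, `category`; genes on chromosomes not
#'   covered by the segmentation are left out with a message.
#' @export
classify_genes <- function(genes, seg, categories, genome, promoter_flank = 1000) {
  if (length(categories) < 1 || is.null(names(categories))) {
    abort("categories must be a named list of state ids")
  }
  covered <- genes$chrom %in% unique(seg$chrom)
  if (!all(covered)) {
    inform(sprintf("%d gene(s) on chromosomes without segmentation left unclassified",
                   sum(!covered)))
    genes <- genes[covered, , drop = FALSE]
  }
  ext <- tss_flank_intervals(genes, promoter_flank, genome, anchor = "body")
  gr_gene <- as_granges(ext, genome = NULL)
  # per gene, the set of states overlapping its extended body
  has_state <- function(states) {
    win <- filter(seg, .data$state %in% states)
    if (nrow(win) == 0) return(rep(FALSE, nrow(ext)))
    gr_w <- as_granges(win, genome = NULL)
    suppressWarnings(GenomicRanges::countOverlaps(gr_gene, gr_w)) > 0
  }
  flags <- purrr::map(categories, has_state)
  priority <- flags[[1]]
  out <- purrr::imap_dfr(flags, function(f, nm) {
    keep <- if (nm == names(categories)[1]) f else f & !priority
    tibble(gene_id = ext$name[keep], category = nm)
  })
  arrange(out, .data$category, .data$gene_id)
}

#' Expression summary of gene categories
#'
#' Per-category distribution of log2(FPKM+1) plus pairwise two-sample t-test
#' p-values between categories (tests skipped when a category has fewer than
#' two members with expression).
#'
#' @param categories Long tibble `gene_id`, `category` ([classify_genes()]).
#' @param expr Tibble `gene_id`, `fpkm`.
#' @return List with `summary` (per-category n, mean, median of
#'   log2(FPKM+1)) and `tests` (pairwise `category1`, `category2`,
#'   `statistic`, `p`).
#' @export
category_expression_summary <- function(categories, expr) {
  x <- inner_join(categories, expr, by = "gene_id") %>%
    mutate(log_expr = log2(.data$fpkm + 1))
  summary <- bind_rows(
    x %>% group_by(.data$category) %>%
      summarise(n = n(), mean = mean(.data$log_expr), median = median(.data$log_expr),
                .groups = "drop"),
    tibble(category = setdiff(unique(categories$category), unique(x$category))) %>%
      mutate(n = 0L, mean = NA_real_, median = NA_real_)
  )
  cats <- sort(unique(x$category))
  pairs <- if (length(cats) >= 2) utils::combn(cats, 2, simplify = FALSE) else list()
  tests <- purrr::map_dfr(pairs, function(pr) {
    a <- x$log_expr[x$category == pr[1]]
    b <- x$log_expr[x$category == pr[2]]
    if (length(a) < 2 || length(b) < 2) {
      return(tibble(category1 = pr[1], category2 = pr[2],
                    statistic = NA_real_, p = NA_real_))
    }
    tt <- tryCatch(t.test(a, b), error = function(e) NULL)
    tibble(category1 = pr[1], category2 = pr[2],
           statistic = if (is.null(tt)) 0 else unname(tt$statistic),
           p = if (is.null(tt)) 1 else tt$p.value)
  })
  list(summary = summary, tests = tests)
}

#' CG-density summary of gene categories
#'
#' Distribution summary of supplied per-gene GC fractions by category, with
#' pairwise Wilcoxon rank-sum tests.
#'
#' @param categories Long tibble `gene_id`, `category`.
#' @param gc Tibble `gene_id`, `gc` with GC fraction in \[0, 1\].
#' @return List with `summary` (per-category n, n_missing, mean, median) and
#'   `tests` (pairwise rank-test p-values).
#' @export
category_cg_density <- function(categories, gc) {
  if (nrow(gc) == 0) abort("empty GC table")
  if (any(gc$gc < 0 | gc$gc > 1, na.rm = TRUE)) abort("GC fractions must be in [0, 1]")
  x <- left_join(categories, gc, by = "gene_id")
  n_missing <- x %>% group_by(.data$category) %>%
    summarise(n_missing = sum(is.na(.data$gc)), .groups = "drop")
  x <- filter(x, !is.na(.data$gc))
  summary <- x %>% group_by(.data$category) %>%
    summarise(n = n(), mean = mean(.data$gc), median = median(.data$gc),
              .groups = "drop") %>%
    left_join(n_missing, by = "category")
  cats <- sort(unique(x$category))
  pairs <- if (length(cats) >= 2) utils::combn(cats, 2, simplify = FALSE) else list()
  tests <- purrr::map_dfr(pairs, function(pr) {
    a <- x$gc[x$category == pr[1]]
    b <- x$gc[x$category == pr[2]]
    if (length(a) < 1 || length(b) < 1) {
      return(tibble(category1 = pr[1], category2 = pr[2], p = NA_real_))
    }
    tibble(category1 = pr[1], category2 = pr[2],
           p = suppressWarnings(wilcox.test(a, b)$p.value))
  })
  list(summary = summary, tests = tests)
}
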