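#' Two-sided Fisher exact test for a 2x2 table, in log space
#'
#' The two-sided p-value is the sum of hypergeometric probabilities of all
#' tables with the observed margins whose probability does not exceed the
#' observed table's (the same rule as [stats::fisher.test()]). Probabilities
#' are accumulated in log space so that the log10 p-value remains usable when
#' p underflows at genome-scale base counts.
#'
#' @param table 2x2 non-negative integer matrix, or a length-4 vector
#'   (a, b, c, d filling the table by row).
#' @return Tibble with `p` and `log10p`.
#' @examples
#' fisher_exact(matrix(c(5, 5, 5, 5), 2)) # p = 1
#' @export
fisher_exact <- function(table) {
  x <- as.numeric(table)
  if (length(x) != 4) abort("need a 2x2 table")
  if (any(x < 0) || any(x != round(x))) abort("cell counts must be non-negative integers")
  if (sum(x) == 0) abort("table total must be positive")
  tb <- matrix(x, 2, 2)
  a <- tb[1, 1]
  r1 <- sum(tb[1, ]); r2 <- sum(tb[2, ]); c1 <- sum(tb[, 1])
  lo <- max(0, c1 - r2); hi <- min(r1, c1)
  support <- lo:hi
  lp <- dhyper(support, r1, r2, c1, log = TRUE)
  lp_obs <- dhyper(a, r1, r2, c1, log = TRUE)
  sel <- lp <= lp_obs + log(1 + 1e-7)
  m <- max(lp[sel])
  logp <- m + log(sum(exp(lp[sel] - m)))
  logp <- min(logp, 0)
  tibble(p = exp(logp), log10p = logp / log(10))
}

#' Base-level fold enrichment of a state for an annotation
#'
#' With A = bases in the state, B = bases in the annotation, C = bases in
#' both, and D = bases in the genome, the enrichment fold is (C/A)/(B/D);
#' significance comes from the two-sided Fisher exact test on the base-count
#' table \[\[C, A-C\], \[B-C, D-A-B+C\]\]. When A or B is 0 the fold is
#' undefined and reported as `NA` with a reason.
#'
#' @param state,annotation Interval tibbles on the same genome.
#' @param genome Genome table; defaults to the one attached to the inputs.
#' @return One-row tibble: `A`, `B`, `C`, `D`, `fold`, `p`, `log10p`,
#'   `note`.
#' @examples
#' g <- genome_tbl(c(chr1 = 1e6))
#' st <- interval_tbl(data.frame(chrom = "chr1", start = 0, end = 1000), g)
#' an <- interval_tbl(data.frame(chrom = "chr1", start = 900, end = 10900), g)
#' fold_enrichment(st, an) # C=100, fold = (100/1000)/(10000/1e6) = 10
#' @export
fold_enrichment <- function(state, annotation, genome = NULL) {
  g <- genome %||% check_shared_genome(state, annotation)
  g <- interval_genome(state, g)
  D <- sum(g$size)
  A <- sum(merge_intervals(state)$end - merge_intervals(state)$start)
  B <- sum(merge_intervals(annotation)$end - merge_intervals(annotation)$start)
  if (A == 0 || B == 0) {
    return(tibble(A = A, B = B, C = 0, D = D, fold = NA_real_, p = NA_real_,
                  log10p = NA_real_,
                  note = if (A == 0) "state covers no bases" else "annotation covers no bases"))
  }
  C <- overlap_bases(state, annotation)
  ft <- fisher_exact(c(C, A - C, B - C, D - A - B + C))
  tibble(A = A, B = B, C = C, D = D, fold = (C / A) / (B / D),
         p = ft$p, log10p = ft$log10p, note = NA_character_)
}

#' Fold enrichment of every chromatin state for an annotation
#'
#' @param seg Segmentation tibble.
#' @param annotation Interval tibble.
#' @param genome Genome table.
#' @return Per-state tibble of [fold_enrichment()] rows with a leading
#'   `state` column.
#' @export
state_enrichment <- function(seg, annotation, genome) {
  iv <- segmentation_to_intervals(seg)
  purrr::map_dfr(sort(unique(iv$state)), function(k) {
    dplyr::bind_cols(
      tibble(state = k),
      fold_enrichment(filter(iv, .data$state == k), annotation, genome = genome)
    )
  })
}

#' Positional enrichment profile of a state around anchors
#'
#' For each strand-oriented bin offset in \[-flank, +flank) the profile is
#' the fraction of anchors whose bin overlaps the state, divided by the
#' state's genome-wide coverage fraction. Bins truncated by a chromosome
#' edge are excluded from that offset's denominator.
#'
#' @param state Interval tibble (one chromatin state's intervals).
#' @param anchors Tibble with `chrom`, `pos`, `strand` (e.g. [gene_tss()]).
#' @param genome Genome table.
#' @param flank Half-width in bp (default 2000); must be a multiple of `bin`.
#' @param bin Bin width in bp (default 200).
#' @return Tibble with `offset` (bin start relative to anchor, strand
#'   oriented), `n_anchors`, `fraction`, `ratio`.
#' @export
positional_profile <- function(state, anchors, genome, flank = 2000, bin = 200) {
  if (nrow(anchors) == 0) abort("anchor set is empty")
  if (flank %% bin != 0) abort("flank must be a multiple of bin")
  g <- interval_genome(state, genome)
  sz <- setNames(g$size, g$chrom)
  cov_frac <- genome_coverage_pct(state, g) / 100
  if (cov_frac == 0) abort("state covers no bases")
  offsets <- seq(-flank, flank - bin, by = bin)
  gr_state <- GenomicRanges::reduce(as_granges(state, genome = NULL))
  minus <- anchors$strand == "-"
  purrr::map_dfr(offsets, function(off) {
    # strand-oriented: offset `off` is downstream-positive along the gene
    s <- ifelse(minus, anchors$pos - off - bin + 1, anchors$pos + off)
    e <- s + bin
    ok <- s >= 0 & e <= sz[anchors$chrom] & !is.na(sz[anchors$chrom])
    n <- sum(ok)
    if (n == 0) return(tibble(offset = off, n_anchors = 0L, fraction = NA_real_, ratio = NA_real_))
    gr_bin <- GenomicRanges::GRanges(anchors$chrom[ok], IRanges::IRanges(s[ok] + 1, e[ok]))
    frac <- mean(suppressWarnings(GenomicRanges::countOverlaps(gr_bin, gr_state)) > 0)
    tibble(offset = off, n_anchors = n, fraction = frac, ratio = frac / cov_frac)
  })
}

#' Plot a positional enrichment profile
#'
#' @param profile Output of [positional_profile()] (optionally with extra
#'   grouping columns, e.g. `state`).
#' @return A ggplot object.
#' @export
plot_positional_profile <- function(profile) {
  p <- ggplot2::ggplot(profile, ggplot2::aes(x = .data$offset, y = .data$ratio))
  if ("state" %in% names(profile)) {
    p <- p + ggplot2::geom_line(ggplot2::aes(colour = factor(.data$state)))
  } else {
    p <- p + ggplot2::geom_line()
  }
  p + ggplot2::geom_hline(yintercept = 1, linetype = "dashed") +
    ggplot2::labs(x = "distance from anchor (bp)", y = "enrichment ratio",
                  colour = "state") +
    ggplot2::theme_minimal()
}

# ---- GWAS marker-set test ---------------------------------------------------

check_effects <- function(effects) {
  if (!all(c("chrom", "pos", "b") %in% names(effects))) {
    abort("marker-effect table needs chrom, pos and b columns")
  }
  if (any(!is.finite(effects$b))) abort("SNP effects must be finite")
  arrange(as_tibble(effects), .data$chrom, .data$pos)
}

#' Add a feature-membership mask to a marker-effect table
#'
#' A SNP belongs to the feature when its position falls inside any feature
#' interval (0-based, half-open).
#'
#' @param effects Tibble with `chrom`, `pos`, `b`.
#' @param feature Interval tibble.
#' @param name Name of the logical mask column to add.
#' @return `effects` with the new logical column.
#' @export
add_feature_mask <- function(effects, feature, name = "feature") {
  effects <- check_effects(effects)
  gr_snp <- GenomicRanges::GRanges(effects$chrom, IRanges::IRanges(effects$pos + 1, effects$pos + 1))
  gr_feat <- as_granges(feature, genome = NULL)
  effects[[name]] <- suppressWarnings(GenomicRanges::countOverlaps(gr_snp, gr_feat)) > 0
  effects
}

#' Marker-set summary statistic: sum of squared SNP effects
#'
#' T_sum for a genomic feature is the sum of squared single-marker GWAS
#' effects over the SNPs inside the feature.
#'
#' @param effects Marker-effect tibble with `b` and a logical mask column.
#' @param feature Name of the mask column (default `"feature"`).
#' @return Scalar T_sum.
#' @export
gwas_tsum <- function(effects, feature = "feature") {
  effects <- check_effects(effects)
  mask <- effects[[feature]]
  if (is.null(mask)) abort(sprintf("no mask column '%s'", feature))
  if (!any(mask)) abort(sprintf("feature '%s' contains no SNPs", feature))
  sum(effects$b[mask]^2)
}

#' Circular-permutation test for GWAS signal enrichment in a feature
#'
#' Each permutation rotates the genome-ordered effect vector by a random
#' offset k in 1..(m-1) against the fixed feature mask and recomputes T_sum;
#' by default one circle spans the whole genome (per-chromosome rotation by
#' flag). The empirical p-value is reported both with the (r+1)/(n+1)
#' correction (`p_emp`, avoiding exact zeros) and as the literal proportion
#' of permuted T_sum exceeding the observed (`p_literal`). Ties use strict
#' `>` by default.
#'
#' @param effects Marker-effect tibble with a logical mask column.
#' @param feature Mask column name.
#' @param n_perm Number of rotations (the study design this mirrors used
#'   10,000).
#' @param seed Integer seed; results are reproducible given the seed.
#' @param tie `">"` (strict, default) or `">="` when comparing permuted to
#'   observed T_sum.
#' @param per_chromosome Rotate within each chromosome instead of one
#'   genome-wide circle.
#' @return A `gwas_perm_test` object (see [tidy.gwas_perm_test()]).
#' @export
circular_permutation_test <- function(effects, feature = "feature", n_perm = 10000L,
                                      seed = 1L, tie = c(">", ">="),
                                      per_chromosome = FALSE) {
  tie <- match.arg(tie)
  effects <- check_effects(effects)
  mask <- effects[[feature]]
  if (is.null(mask)) abort(sprintf("no mask column '%s'", feature))
  m <- nrow(effects)
  if (m < 2) abort("need at least 2 SNPs")
  if (n_perm < 1) abort("n_perm must be >= 1")
  if (!any(mask)) abort(sprintf("feature '%s' contains no SNPs", feature))
  if (all(mask)) warn("feature covers every SNP; the permutation null is degenerate")
  b2 <- effects$b^2
  t_obs <- sum(b2[mask])
  set.seed(seed)
  if (per_chromosome) {
    groups <- split(seq_len(m), effects$chrom)
    null_t <- vapply(seq_len(n_perm), function(i) {
      s <- 0
      for (idx in groups) {
        mm <- length(idx)
        k <- if (mm > 1) sample.int(mm - 1, 1) else 0
        rot <- b2[idx][((seq_len(mm) - 1 + k) %% mm) + 1]
        s <- s + sum(rot[mask[idx]])
      }
      s
    }, numeric(1))
  } else {
    pos <- which(mask)
    offs <- sample.int(m - 1, n_perm, replace = TRUE)
    # rotated b^2 at mask position p for offset k is b2[((p-1+k) mod m)+1]
    idx <- outer(pos - 1, offs, `+`) %% m + 1
    null_t <- colSums(matrix(b2[idx], nrow = length(pos)))
  }
  exceed <- if (tie == ">") sum(null_t > t_obs) else sum(null_t >= t_obs)
  structure(
    list(
      t_obs = t_obs, null_t = null_t, n_perm = as.integer(n_perm),
      p_emp = (exceed + 1) / (n_perm + 1), p_literal = exceed / n_perm,
      n_snps = m, n_feature = sum(mask), feature = feature,
      seed = as.integer(seed), tie = tie, per_chromosome = per_chromosome
    ),
    class = "gwas_perm_test"
  )
}

#' @export
print.gwas_perm_test <- function(x, ...) {
  cat(sprintf("<gwas_perm_test> feature '%s': %d of %d SNPs\n", x$feature, x$n_feature, x$n_snps))
  cat(sprintf("T_sum = %.4g; empirical p = %.4g (literal %.4g) from %d rotations\n",
              x$t_obs, x$p_emp, x$p_literal, x$n_perm))
  invisible(x)
}

#' Tidy a circular-permutation test
#'
#' `tidy()` returns the permutation null as a tibble; `glance()` the one-row
#' summary.
#'
#' @param x A `gwas_perm_test`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.gwas_perm_test <- function(x, ...) {
  tibble(permutation = seq_along(x$null_t), t_sum = x$null_t)
}

#' @rdname tidy.gwas_perm_test
#' @export
glance.gwas_perm_test <- function(x, ...) {
  tibble(feature = x$feature, t_obs = x$t_obs, p_emp = x$p_emp,
         p_literal = x$p_literal, n_perm = x$n_perm,
         n_snps = x$n_snps, n_feature = x$n_feature, seed = x$seed)
}

#' Null T_sum distribution plot for a permutation test
#'
#' @param object A `gwas_perm_test`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.gwas_perm_test <- function(object, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(x = .data$t_sum)) +
    ggplot2::geom_histogram(bins = 50, fill = "grey70") +
    ggplot2::geom_vline(xintercept = object$t_obs, colour = "red") +
    ggplot2::labs(x = "permuted T_sum", y = "count",
                  subtitle = sprintf("observed T_sum (red); empirical p = %.3g", object$p_emp)) +
    ggplot2::theme_minimal()
}

# ---- gene-set enrichment ----------------------------------------------------

#' Upper-tail hypergeometric gene-set enrichment
#'
#' Probability of observing at least `|query intersect target|` target genes
#' in a draw of `|query|` genes from the universe.
#'
#' @param query,target,universe Character vectors of gene ids; `query` and
#'   `target` must be subsets of `universe`.
#' @return Tibble with `overlap`, `expected` and `p`.
#' @export
hypergeom_enrichment <- function(query, target, universe) {
  universe <- unique(universe)
  query <- unique(query); target <- unique(target)
  if (length(universe) == 0) abort("universe is empty")
  if (!all(query %in% universe) || !all(target %in% universe)) {
    abort("query and target must be subsets of the universe")
  }
  q <- length(intersect(query, target))
  p <- phyper(q - 1, length(target), length(universe) - length(target),
              length(query), lower.tail = FALSE)
  tibble(overlap = q,
         expected = length(query) * length(target) / length(universe),
         p = p)
}

#' Top tissue-specific genes from an expression matrix
#'
#' Scores each gene's specificity for the target tissue as the z-score of
#' log2(FPKM+1) in that tissue against the gene's across-tissue mean and SD,
#' and returns the top `ceiling(top_frac * n)` genes. Genes with constant
#' expression score 0 and rank last.
#'
#' @param expr Tibble with `gene_id` and one numeric FPKM column per tissue.
#' @param tissue Target tissue column name.
#' @param top_frac Fraction of genes to return (default 0.05, the usual
#'   top-5% rule).
#' @return Tibble `gene_id`, `score`, ordered by decreasing specificity.
#' @export
tissue_specific_genes <- function(expr, tissue, top_frac = 0.05) {
  if (top_frac <= 0 || top_frac >= 1) abort("top_frac must be in (0, 1)")
  tissues <- setdiff(names(expr), "gene_id")
  if (length(tissues) < 2) abort("need at least two tissue columns")
  if (!tissue %in% tissues) abort(sprintf("no tissue column '%s'", tissue))
  L <- log2(as.matrix(expr[tissues]) + 1)
  mu <- rowMeans(L)
  s <- apply(L, 1, sd)
  z <- (L[, tissue] - mu) / s
  constant <- s == 0
  z[constant] <- 0
  ord <- order(constant, -z)
  n_top <- ceiling(top_frac * nrow(expr))
  tibble(gene_id = expr$gene_id[ord], score = z[ord])[seq_len(n_top), ]
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment (delegates to
#' [stats::p.adjust()]); the pluggable q-value used throughout the DMR
#' pipeline.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values, same length and order.
#' @export
benjamini_hochberg <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) abort("p-values must be in [0, 1]")
  p.adjust(p, method = "BH")
}
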