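#' Differential-expression filter (Bonferroni + fold-change)
#'
#' Applies the published DEG rule to a per-gene statistics table: a gene is
#' differentially expressed when its Bonferroni-corrected p-value
#' (min(1, p * n_tests)) is strictly below `p_threshold` and |log2 fold
#' change| is strictly above `lfc_threshold`. Genes with missing statistics
#' are excluded and counted.
#'
#' @param stats Tibble with `gene_id`, `p`, `log2fc` (treated vs control).
#' @param n_tests Number of tests for the Bonferroni correction; defaults to
#'   the number of genes with complete statistics.
#' @param p_threshold Corrected-p cutoff (default 0.05).
#' @param lfc_threshold |log2FC| cutoff (default 2).
#' @return Tibble of passing genes with `p_bonf` and `direction`
#'   (`"up"`/`"down"`); the number of genes dropped for missing values is in
#'   attribute `"n_missing"`.
#' @export
deg_filter <- function(stats, n_tests = NULL, p_threshold = 0.05, lfc_threshold = 2) {
  if (p_threshold <= 0 || lfc_threshold <= 0) abort("thresholds must be positive")
  ok <- !is.na(stats$p) & !is.na(stats$log2fc)
  n_missing <- sum(!ok)
  if (n_missing > 0) inform(sprintf("%d gene(s) with missing statistics excluded", n_missing))
  x <- stats[ok, , drop = FALSE]
  n_tests <- n_tests %||% nrow(x)
  out <- x %>%
    mutate(p_bonf = pmin(1, .data$p * n_tests)) %>%
    filter(.data$p_bonf < p_threshold, abs(.data$log2fc) > lfc_threshold) %>%
    mutate(direction = ifelse(.data$log2fc > 0, "up", "down"))
  attr(out, "n_missing") <- n_missing
  out
}

#' Simple per-gene differential-expression test for synthetic data
#'
#' Welch two-sample t-test on log2(FPKM+1) between conditions, with log2 fold
#' change as the difference of condition means on that scale. This is the
#' pipeline's pluggable stand-in DE test for simulated expression tables; it
#' feeds [deg_filter()].
#'
#' @param expr Long tibble with `gene_id`, `condition`, `replicate`, `fpkm`.
#' @param treatment,control The two condition labels (fold change is
#'   treatment minus control).
#' @return Tibble `gene_id`, `log2fc`, `p`.
#' @export
simple_de_test <- function(expr, treatment = "treated", control = "control") {
  need <- c("gene_id", "condition", "fpkm")
  if (!all(need %in% names(expr))) abort("expression table needs gene_id, condition, fpkm")
  x <- filter(expr, .data$condition %in% c(treatment, control)) %>%
    mutate(log_expr = log2(.data$fpkm + 1))
  counts <- x %>% count(.data$gene_id, .data$condition)
  if (any(counts$n < 2)) abort("need at least 2 replicates per condition for every gene")
  x %>%
    group_by(.data$gene_id) %>%
    summarise(
      log2fc = mean(.data$log_expr[.data$condition == treatment]) -
        mean(.data$log_expr[.data$condition == control]),
      p = {
        a <- .data$log_expr[.data$condition == treatment]
        b <- .data$log_expr[.data$condition == control]
        if (sd(a) == 0 && sd(b) == 0) {
          if (mean(a) == mean(b)) 1 else 0
        } else {
          t.test(a, b)$p.value
        }
      },
      .groups = "drop"
    )
}

#' Aggregate per-CpG methylation counts into fixed windows
#'
#' Loci are first filtered on coverage: with the per-sample rule (default), a
#' CpG is dropped when any sample covers it with fewer than `min_coverage`
#' reads; with the per-condition rule, when either condition's pooled
#' coverage is below the threshold. Surviving per-CpG counts are then summed
#' per sample within windows of `window` bp placed every `step` bp from
#' position 0 (the published setting uses window = step = 500). Windows with
#' no surviving CpG are omitted.
#'
#' @param cpgs Long tibble with `chrom`, `pos`, `sample`, `condition`,
#'   `meth`, `total`.
#' @param window Window size in bp (default 500).
#' @param step Step size in bp (default 500).
#' @param min_coverage Minimum reads per locus (default 10).
#' @param coverage_rule `"per_sample"` (default) or `"per_condition"`.
#' @return Tibble `chrom`, `start`, `end`, `sample`, `condition`, `meth`,
#'   `total`.
#' @export
window_methylation <- function(cpgs, window = 500, step = 500, min_coverage = 10,
                               coverage_rule = c("per_sample", "per_condition")) {
  coverage_rule <- match.arg(coverage_rule)
  if (any(cpgs$meth < 0 | cpgs$total < 0)) abort("negative methylation counts")
  if (any(cpgs$meth > cpgs$total)) abort("methylated count exceeds total at some locus")
  keep <- if (coverage_rule == "per_sample") {
    cpgs %>% group_by(.data$chrom, .data$pos) %>%
      summarise(ok = all(.data$total >= min_coverage), .groups = "drop")
  } else {
    cpgs %>% group_by(.data$chrom, .data$pos, .data$condition) %>%
      summarise(cov = sum(.data$total), .groups = "drop_last") %>%
      summarise(ok = all(.data$cov >= min_coverage), .groups = "drop")
  }
  x <- cpgs %>%
    inner_join(filter(keep, .data$ok) %>% select("chrom", "pos"), by = c("chrom", "pos"))
  if (nrow(x) == 0) return(tibble(chrom = character(), start = numeric(), end = numeric(),
                                  sample = character(), condition = character(),
                                  meth = numeric(), total = numeric()))
  # every window start s (multiple of step) with s <= pos < s + window
  k_max <- floor(x$pos / step)
  k_min <- ceiling((x$pos - window + 1) / step)
  reps <- pmax(k_max - pmax(k_min, 0) + 1, 0)
  idx <- rep(seq_len(nrow(x)), reps)
  offs <- unlist(purrr::map2(pmax(k_min, 0), k_max, function(a, b) if (b >= a) a:b else integer(0)))
  x[idx, ] %>%
    mutate(start = offs * step, end = .data$start + window) %>%
    group_by(.data$chrom, .data$start, .data$end, .data$sample, .data$condition) %>%
    summarise(meth = sum(.data$meth), total = sum(.data$total), .groups = "drop") %>%
    arrange(.data$chrom, .data$start, .data$sample)
}

#' Binomial logistic-regression test for one methylation window
#'
#' Replicates are pooled within condition and a two-level binomial logistic
#' regression of methylated/total on condition is fit by iteratively
#' reweighted least squares ([stats::glm()]); the p-value is the 1-df
#' likelihood-ratio chi-square of the treatment model against the
#' intercept-only model. The methylation difference is the treatment pooled
#' proportion minus the control pooled proportion, in percentage points.
#' Complete separation (0% vs 100%) is flagged; the LRT deviance remains
#' well defined.
#'
#' @param meth,total Per-sample methylated and total counts for the window.
#' @param condition Per-sample condition labels.
#' @param treatment,control The two condition labels.
#' @return One-row tibble `p`, `meth_diff`, `statistic`, `separated`.
#' @export
dmr_test <- function(meth, total, condition, treatment = "treated", control = "control") {
  pool <- tibble(meth = meth, total = total, condition = condition) %>%
    filter(.data$condition %in% c(treatment, control)) %>%
    group_by(.data$condition) %>%
    summarise(meth = sum(.data$meth), total = sum(.data$total), .groups = "drop")
  if (nrow(pool) != 2 || any(pool$total == 0)) {
    abort("both conditions need positive total counts in the window")
  }
  pool$condition <- factor(pool$condition, levels = c(control, treatment))
  fit <- suppressWarnings(
    glm(cbind(meth, total - meth) ~ condition, family = binomial(), data = pool)
  )
  lrt <- max(fit$null.deviance - fit$deviance, 0)
  prop <- pool$meth / pool$total
  separated <- any(prop %in% c(0, 1)) && abs(diff(prop)) == 1
  tibble(
    p = pchisq(lrt, df = 1, lower.tail = FALSE),
    meth_diff = 100 * (prop[pool$condition == treatment] - prop[pool$condition == control]),
    statistic = lrt,
    separated = separated
  )
}

#' Test every methylation window for differential methylation
#'
#' @param windows Output of [window_methylation()].
#' @param treatment,control Condition labels.
#' @return Tibble with one row per window: `chrom`, `start`, `end`, `p`,
#'   `meth_diff`, `statistic`, `separated`. Windows lacking coverage in
#'   either condition are dropped with a message.
#' @export
dmr_test_all <- function(windows, treatment = "treated", control = "control") {
  pooled <- windows %>%
    group_by(.data$chrom, .data$start, .data$end, .data$condition) %>%
    summarise(meth = sum(.data$meth), total = sum(.data$total), .groups = "drop")
  wide <- tidyr::pivot_wider(pooled, names_from = "condition",
                             values_from = c("meth", "total"), values_fill = 0)
  mt <- paste0("meth_", treatment); tt <- paste0("total_", treatment)
  mc <- paste0("meth_", control); tc <- paste0("total_", control)
  if (!all(c(mt, tt, mc, tc) %in% names(wide))) {
    abort("windows must contain both condition labels")
  }
  usable <- wide[[tt]] > 0 & wide[[tc]] > 0
  if (any(!usable)) {
    inform(sprintf("%d window(s) lacking coverage in one condition dropped", sum(!usable)))
    wide <- wide[usable, , drop = FALSE]
  }
  m1 <- wide[[mt]]; t1 <- wide[[tt]]; m0 <- wide[[mc]]; t0 <- wide[[tc]]
  # closed-form 1-df LRT for the saturated two-group binomial model (what the
  # per-window glm converges to); identical to dmr_test() on pooled counts
  ll <- function(m, t, p) {
    p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
    m * log(p) + (t - m) * log(1 - p)
  }
  p1 <- m1 / t1; p0 <- m0 / t0; pn <- (m1 + m0) / (t1 + t0)
  lrt <- 2 * (ll(m1, t1, p1) + ll(m0, t0, p0) - ll(m1, t1, pn) - ll(m0, t0, pn))
  lrt <- pmax(lrt, 0)
  tibble(
    chrom = wide$chrom, start = wide$start, end = wide$end,
    p = pchisq(lrt, df = 1, lower.tail = FALSE),
    meth_diff = 100 * (p1 - p0),
    statistic = lrt,
    separated = abs(p1 - p0) == 1
  ) %>% arrange(.data$chrom, .data$start)
}

#' Filter tested windows into differentially methylated regions
#'
#' Adjusts the per-window p-values to q-values (Benjamini-Hochberg by
#' default; pluggable) and returns windows with q strictly below
#' `q_threshold` and |methylation difference| strictly above
#' `diff_threshold` percentage points.
#'
#' @param tested Output of [dmr_test_all()].
#' @param q_threshold q-value cutoff (default 0.05).
#' @param diff_threshold |difference| cutoff in percentage points (default 10).
#' @param q_fun Multiple-testing adjustment function (default
#'   [benjamini_hochberg()]).
#' @return The DMR subset with a `q` column; the full table with `q` added is
#'   in attribute `"tested"`.
#' @export
dmr_filter <- function(tested, q_threshold = 0.05, diff_threshold = 10,
                       q_fun = benjamini_hochberg) {
  tested$q <- q_fun(tested$p)
  out <- filter(tested, .data$q < q_threshold, abs(.data$meth_diff) > diff_threshold)
  attr(out, "tested") <- tested
  out
}
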