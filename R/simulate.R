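#' Configuration for the synthetic two-condition epigenome study
#'
#' Bundles every tunable of the simulators with defaults emulating the design
#' of a two-condition (control vs 24-h treated), three-replicate epigenome
#' study at desk scale: 2 chromosomes of 1 Mb tiled by 200-bp windows
#' (10,000 windows), 6 marks, 8 chromatin states, 500 genes, 20,000 SNPs and
#' 50,000 CpGs. All sub-generators derive their seeds from the single `seed`
#' by fixed small offsets, so a config is reproducible end to end.
#'
#' @param seed Master seed (integer).
#' @param genome Named vector of chromosome lengths or genome table.
#' @param window_size Window width in bp.
#' @param n_states,n_marks Hidden-state and mark counts of the true model.
#' @param hmm Optional `chromatin_hmm` to use as the truth; by default a
#'   well-separated sticky model is built (each state turns on its own subset
#'   of marks with probability `emission_on`, others at `emission_off`;
#'   self-transition `self_prob`).
#' @param emission_on,emission_off,self_prob Parameters of the default truth.
#' @param lambda_signal,lambda_background Poisson read-count rates inside and
#'   outside mark-on windows.
#' @param n_changed_regions,changed_region_windows Number and width (in
#'   windows) of regions whose states are re-drawn in condition 2, planting
#'   localized state transitions.
#' @param n_genes Gene count; bodies are placed uniformly with log-normal
#'   lengths.
#' @param n_replicates Replicates per condition.
#' @param de_fraction,de_log2fc Fraction of genes differentially expressed in
#'   condition 2 and the planted |log2 fold change|.
#' @param expr_log2_mean,expr_log2_sd,expr_noise_sd Baseline log2-FPKM
#'   distribution and replicate noise (log2 scale).
#' @param n_snps,snp_effect_sd,snp_inflation SNP count, null effect SD, and
#'   the variance-inflation factor applied inside enriched features.
#' @param n_cpgs,coverage_mu,coverage_size Negative-binomial CpG coverage.
#' @param dmr_n_windows,dmr_shift Number of planted DMR windows (on the
#'   500-bp grid) and the methylation-proportion shift in condition 2.
#' @param meth_window DMR window size in bp.
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       genome = c(chr1 = 1e6, chr2 = 1e6),
                       window_size = 200,
                       n_states = 8, n_marks = 6,
                       hmm = NULL,
                       emission_on = 0.9, emission_off = 0.05, self_prob = 0.9,
                       lambda_signal = 15, lambda_background = 0.5,
                       n_changed_regions = 40, changed_region_windows = 10,
                       n_genes = 500, n_replicates = 3,
                       de_fraction = 0.05, de_log2fc = 3,
                       expr_log2_mean = 3, expr_log2_sd = 2, expr_noise_sd = 0.2,
                       n_snps = 20000, snp_effect_sd = 0.1, snp_inflation = 5,
                       n_cpgs = 50000, coverage_mu = 30, coverage_size = 5,
                       dmr_n_windows = 20, dmr_shift = 0.3, meth_window = 500) {
  cfg <- list(
    seed = as.integer(seed), genome = as_genome_tbl(genome), window_size = window_size,
    n_states = n_states, n_marks = n_marks, hmm = hmm,
    emission_on = emission_on, emission_off = emission_off, self_prob = self_prob,
    lambda_signal = lambda_signal, lambda_background = lambda_background,
    n_changed_regions = n_changed_regions, changed_region_windows = changed_region_windows,
    n_genes = n_genes, n_replicates = n_replicates,
    de_fraction = de_fraction, de_log2fc = de_log2fc,
    expr_log2_mean = expr_log2_mean, expr_log2_sd = expr_log2_sd,
    expr_noise_sd = expr_noise_sd,
    n_snps = n_snps, snp_effect_sd = snp_effect_sd, snp_inflation = snp_inflation,
    n_cpgs = n_cpgs, coverage_mu = coverage_mu, coverage_size = coverage_size,
    dmr_n_windows = dmr_n_windows, dmr_shift = dmr_shift, meth_window = meth_window
  )
  if (de_fraction < 0 || de_fraction >= 1) abort("de_fraction must be in [0, 1)")
  if (snp_inflation < 1) abort("snp_inflation must be >= 1")
  structure(cfg, class = "sim_config")
}

# deterministic sub-seeds: one fixed offset per generator
sim_seed <- function(config, offset) (config$seed + offset) %% .Machine$integer.max

default_true_hmm <- function(config) {
  K <- config$n_states; M <- config$n_marks
  em <- matrix(config$emission_off, K, M)
  # state k switches on marks (k-1) mod M and k mod M so profiles overlap
  # between neighbouring states but remain separable
  for (k in seq_len(K)) {
    em[k, ((k - 1) %% M) + 1] <- config$emission_on
    em[k, (k %% M) + 1] <- config$emission_on
  }
  A <- matrix((1 - config$self_prob) / max(K - 1, 1), K, K)
  diag(A) <- if (K > 1) config$self_prob else 1
  chromatin_hmm(rep(1 / K, K), A, em, marks = paste0("mark", seq_len(M)))
}

sample_hmm_path <- function(model, n) {
  K <- model$n_states
  s <- integer(n)
  s[1] <- sample.int(K, 1, prob = model$initial)
  for (t in seq_len(n - 1)) {
    s[t + 1] <- sample.int(K, 1, prob = model$transition[s[t], ])
  }
  s
}

emit_calls <- function(model, states) {
  p <- model$emission[states, , drop = FALSE]
  calls <- matrix(rbinom(length(p), 1, as.vector(p)), nrow = length(states))
  colnames(calls) <- model$marks
  calls
}

#' Simulate a two-condition binarized epigenome with known state paths
#'
#' Samples a hidden state path from the true HMM along each chromosome's
#' 200-bp window grid and emits per-mark Bernoulli presence calls, plus
#' Poisson read counts (rate `lambda_signal` where the mark is on,
#' `lambda_background` elsewhere, with a control track at the background
#' rate). Condition 2 ("treated") re-draws the states of
#' `n_changed_regions` random regions and re-emits calls/counts only there,
#' so planted transitions are localized and countable; everything else is
#' shared between conditions.
#'
#' @param config A [sim_config()].
#' @return List with `truth` (the generating `chromatin_hmm`), `grid`,
#'   per-condition `states` (true segmentations), `calls`, `counts`, and
#'   `changed_regions` (interval tibble of the planted reassignments).
#' @export
simulate_epigenome <- function(config) {
  model <- config$hmm %||% default_true_hmm(config)
  if (model$n_states != config$n_states || length(model$marks) != config$n_marks) {
    abort("config hmm dimensions disagree with n_states/n_marks")
  }
  grid <- window_grid(config$genome, config$window_size)
  set.seed(sim_seed(config, 11L))
  n <- nrow(grid)
  states1 <- integer(n)
  for (i in split(seq_len(n), grid$chrom)) {
    states1[i] <- sample_hmm_path(model, length(i))
  }
  calls1 <- emit_calls(model, states1)

  # condition 2: re-draw designated regions
  states2 <- states1
  calls2 <- calls1
  changed <- grid[0, c("chrom", "start", "end")]
  if (config$n_changed_regions > 0) {
    w <- config$changed_region_windows
    starts <- sort(sample.int(max(n - w, 1), config$n_changed_regions))
    for (s in starts) {
      idx <- s:min(s + w - 1, n)
      idx <- idx[grid$chrom[idx] == grid$chrom[s]] # stay on one chromosome
      new_state <- sample.int(model$n_states, 1)
      states2[idx] <- new_state
      calls2[idx, ] <- emit_calls(model, states2[idx])
      changed <- bind_rows(changed, tibble(chrom = grid$chrom[s],
                                           start = grid$start[idx[1]],
                                           end = grid$end[idx[length(idx)]]))
    }
  }

  mk_counts <- function(calls) {
    cnt <- matrix(rpois(length(calls),
                        ifelse(calls == 1, config$lambda_signal, config$lambda_background)),
                  nrow = nrow(calls))
    colnames(cnt) <- model$marks
    out <- bind_cols(grid[c("chrom", "start", "end")], as_tibble(cnt))
    out$control <- rpois(nrow(out), config$lambda_background)
    out
  }
  counts1 <- mk_counts(calls1)
  counts2 <- counts1
  if (nrow(changed) > 0) {
    gr_changed <- as_granges(changed, genome = NULL)
    gr_grid <- as_granges(grid, genome = NULL)
    in_changed <- suppressWarnings(GenomicRanges::countOverlaps(gr_grid, gr_changed)) > 0
    repl <- mk_counts(calls2)
    counts2[in_changed, c(model$marks, "control")] <- repl[in_changed, c(model$marks, "control")]
  }

  seg_tbl <- function(states) bind_cols(grid[c("chrom", "start", "end")], tibble(state = states))
  calls_tbl <- function(calls) bind_cols(grid[c("chrom", "start", "end")], as_tibble(calls))
  list(
    truth = model,
    grid = grid,
    states = list(control = seg_tbl(states1), treated = seg_tbl(states2)),
    calls = list(control = calls_tbl(calls1), treated = calls_tbl(calls2)),
    counts = list(control = counts1, treated = counts2),
    changed_regions = merge_intervals(interval_tbl(changed, config$genome))
  )
}

#' Simulate gene models on the synthetic genome
#'
#' Gene bodies are placed uniformly with log-normal lengths (median ~3 kb)
#' and random strands.
#'
#' @param config A [sim_config()].
#' @return A gene tibble.
#' @export
simulate_genes <- function(config) {
  set.seed(sim_seed(config, 23L))
  g <- config$genome
  chrom <- sample(g$chrom, config$n_genes, replace = TRUE, prob = g$size / sum(g$size))
  sz <- setNames(g$size, g$chrom)
  len <- pmin(pmax(round(rlnorm(config$n_genes, log(3000), 0.6)), 200), 50000)
  start <- unname(floor(runif(config$n_genes) * pmax(sz[chrom] - len, 1)))
  gene_tbl(tibble(
    gene_id = sprintf("gene%04d", seq_len(config$n_genes)),
    chrom = chrom, start = start, end = start + len,
    strand = sample(c("+", "-"), config$n_genes, replace = TRUE)
  ))
}

#' Simulate a two-condition FPKM table with planted DE genes
#'
#' Baseline expression is log-normal (log2 scale); a `de_fraction` subset is
#' shifted by +/- `de_log2fc` in the treated condition, with log-normal
#' replicate noise.
#'
#' @param config A [sim_config()].
#' @param genes Gene tibble ([simulate_genes()]).
#' @return List with `expr` (long tibble `gene_id`, `condition`, `replicate`,
#'   `fpkm`) and `truth` (`gene_id`, `is_de`, `true_log2fc`).
#' @export
simulate_expression <- function(config, genes) {
  set.seed(sim_seed(config, 37L))
  n <- nrow(genes)
  base <- rnorm(n, config$expr_log2_mean, config$expr_log2_sd)
  n_de <- round(config$de_fraction * n)
  de_idx <- if (n_de > 0) sample.int(n, n_de) else integer(0)
  lfc <- numeric(n)
  lfc[de_idx] <- sample(c(-1, 1), n_de, replace = TRUE) * config$de_log2fc
  expr <- tidyr::expand_grid(
    gene_id = genes$gene_id,
    condition = c("control", "treated"),
    replicate = seq_len(config$n_replicates)
  ) %>%
    left_join(tibble(gene_id = genes$gene_id, base = base, lfc = lfc), by = "gene_id") %>%
    mutate(
      log2_mean = .data$base + ifelse(.data$condition == "treated", .data$lfc, 0),
      fpkm = 2^(.data$log2_mean + rnorm(dplyr::n(), 0, config$expr_noise_sd))
    ) %>%
    select("gene_id", "condition", "replicate", "fpkm")
  list(
    expr = expr,
    truth = tibble(gene_id = genes$gene_id, is_de = seq_len(n) %in% de_idx,
                   true_log2fc = lfc)
  )
}

#' Simulate genome-ordered SNP effects with feature-localized inflation
#'
#' SNP positions are uniform over the genome; effects are normal with SD
#' `snp_effect_sd` outside the feature intervals and SD
#' `sqrt(snp_inflation)` times larger inside, so the exchangeable null holds
#' exactly when `snp_inflation = 1`.
#'
#' @param config A [sim_config()].
#' @param features Interval tibble of enriched features (may be empty).
#' @return Marker-effect tibble with a logical `feature` mask column.
#' @export
simulate_gwas_effects <- function(config, features) {
  set.seed(sim_seed(config, 53L))
  g <- config$genome
  chrom <- sample(g$chrom, config$n_snps, replace = TRUE, prob = g$size / sum(g$size))
  sz <- setNames(g$size, g$chrom)
  pos <- unname(floor(runif(config$n_snps) * sz[chrom]))
  eff <- tibble(chrom = chrom, pos = pos, b = 0) %>%
    arrange(.data$chrom, .data$pos)
  eff <- add_feature_mask(eff, features, "feature")
  sd_vec <- ifelse(eff$feature, config$snp_effect_sd * sqrt(config$snp_inflation),
                   config$snp_effect_sd)
  eff$b <- rnorm(config$n_snps, 0, sd_vec)
  eff
}

#' Simulate a two-condition bisulfite count table with planted DMRs
#'
#' CpGs are placed uniformly; coverage per CpG and sample is negative
#' binomial; methylated counts are binomial with a per-CpG baseline
#' proportion drawn uniform(0.2, 0.6), shifted upward by `dmr_shift` in the
#' treated condition inside the planted DMR windows (on the `meth_window`
#' grid).
#'
#' @param config A [sim_config()].
#' @return List with `cpgs` (long tibble `chrom`, `pos`, `sample`,
#'   `condition`, `meth`, `total`) and `dmr_truth` (interval tibble of
#'   planted windows).
#' @export
simulate_methylome <- function(config) {
  if (config$dmr_shift < 0 || config$dmr_shift > 0.4) {
    abort("dmr_shift must keep proportions in [0, 1] (baseline is uniform(0.2, 0.6))")
  }
  set.seed(sim_seed(config, 71L))
  g <- config$genome
  chrom <- sample(g$chrom, config$n_cpgs, replace = TRUE, prob = g$size / sum(g$size))
  sz <- setNames(g$size, g$chrom)
  pos <- unname(floor(runif(config$n_cpgs) * sz[chrom]))
  base_pi <- runif(config$n_cpgs, 0.2, 0.6)
  loci <- tibble(chrom = chrom, pos = pos, base_pi = base_pi) %>%
    distinct(.data$chrom, .data$pos, .keep_all = TRUE) %>%
    arrange(.data$chrom, .data$pos)

  # plant DMR windows on the meth_window grid
  w <- config$meth_window
  grid <- window_grid(g, w)
  dmr_rows <- if (config$dmr_n_windows > 0) sort(sample.int(nrow(grid), config$dmr_n_windows)) else integer(0)
  dmr <- grid[dmr_rows, c("chrom", "start", "end")]
  in_dmr <- rep(FALSE, nrow(loci))
  if (nrow(dmr) > 0) {
    gr_cpg <- GenomicRanges::GRanges(loci$chrom, IRanges::IRanges(loci$pos + 1, loci$pos + 1))
    gr_dmr <- as_granges(dmr, genome = NULL)
    in_dmr <- suppressWarnings(GenomicRanges::countOverlaps(gr_cpg, gr_dmr)) > 0
  }

  samples <- tidyr::expand_grid(condition = c("control", "treated"),
                                replicate = seq_len(config$n_replicates)) %>%
    mutate(sample = paste0(.data$condition, "_rep", .data$replicate))
  cpgs <- tidyr::expand_grid(i = seq_len(nrow(loci)), s = seq_len(nrow(samples))) %>%
    mutate(
      chrom = loci$chrom[.data$i], pos = loci$pos[.data$i],
      sample = samples$sample[.data$s], condition = samples$condition[.data$s],
      pi = loci$base_pi[.data$i] +
        ifelse(.data$condition == "treated" & in_dmr[.data$i], config$dmr_shift, 0),
      total = rnbinom(dplyr::n(), mu = config$coverage_mu, size = config$coverage_size),
      meth = rbinom(dplyr::n(), .data$total, .data$pi)
    ) %>%
    select("chrom", "pos", "sample", "condition", "meth", "total") %>%
    arrange(.data$chrom, .data$pos, .data$sample)
  list(cpgs = cpgs, dmr_truth = interval_tbl(dmr, g))
}
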