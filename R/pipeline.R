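#' End-to-end pipeline configuration
#'
#' Collects the analysis thresholds around a [sim_config()] (or around
#' externally supplied inputs). Defaults mirror the published study design:
#' 200-bp windows, Poisson binarization threshold 1e-4, 10,000 circular
#' permutations, promoter flank +/- 1 kb, TSS/TES profile flank +/- 2 kb, DEG
#' flank +/- 20 kb, DEG thresholds Bonferroni p < 0.05 and |log2FC| > 2, DMR
#' thresholds q < 0.05, |difference| > 10 percentage points, coverage >= 10.
#'
#' @param sim A [sim_config()]; its seed drives every stochastic stage.
#' @param n_states States for the fitted model (defaults to the simulation
#'   truth's).
#' @param binarize_threshold Poisson tail threshold for [binarize_counts()].
#' @param n_perm Circular permutations for the GWAS marker-set test.
#' @param promoter_flank,profile_flank,deg_flank Flank widths in bp.
#' @param deg_p,deg_lfc,dmr_q,dmr_diff,dmr_coverage Filter thresholds.
#' @param categories Named list of state ids for [classify_genes()]; the
#'   first is the priority (active-promoter-like) category.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(sim = sim_config(),
                            n_states = sim$n_states,
                            binarize_threshold = 1e-4,
                            n_perm = 10000L,
                            promoter_flank = 1000,
                            profile_flank = 2000,
                            deg_flank = 20000,
                            deg_p = 0.05, deg_lfc = 2,
                            dmr_q = 0.05, dmr_diff = 10, dmr_coverage = 10,
                            categories = list(TssA = 1L, EnhPois = 2L,
                                              BivFlnk = 3L, ReprPC = 4L)) {
  structure(
    list(sim = sim, n_states = n_states, binarize_threshold = binarize_threshold,
         n_perm = as.integer(n_perm), promoter_flank = promoter_flank,
         profile_flank = profile_flank, deg_flank = deg_flank,
         deg_p = deg_p, deg_lfc = deg_lfc, dmr_q = dmr_q, dmr_diff = dmr_diff,
         dmr_coverage = dmr_coverage, categories = categories),
    class = "pipeline_config"
  )
}

#' Run the full simulate-to-report chain
#'
#' Simulates a two-condition epigenome study, binarizes the read counts, fits
#' one joint chromatin-state HMM across both conditions, decodes each
#' condition, and runs every downstream statistic: state coverages and
#' annotation enrichment, TSS positional profiles, GWAS marker-set
#' enrichment, state-transition dynamics, DEG detection and flank-enrichment
#' change, gene classification, and the windowed DMR pipeline. Every
#' stochastic stage is seeded from `seed`, so reruns are byte-identical; the
#' computation is single-threaded, hence independent of any thread setting.
#'
#' @param config A [pipeline_config()].
#' @param seed Master seed; overrides the seed in `config$sim`.
#' @param out_dir Optional directory; when given, all result tables are
#'   written as TSVs with a version/seed/config-hash header, plus
#'   segmentation BEDs and the model files.
#' @return Named list of result objects and tibbles, including `summary`
#'   (one row per headline quantity).
#' @export
run_pipeline <- function(config = pipeline_config(), seed = NULL, out_dir = NULL) {
  if (!is.null(seed)) config$sim$seed <- as.integer(seed)
  seed <- config$sim$seed
  cfg_for_hash <- config
  cfg_for_hash$sim$genome <- as.data.frame(cfg_for_hash$sim$genome)
  config_hash <- rlang::hash(cfg_for_hash)
  genome <- config$sim$genome

  inform("simulating epigenome ...")
  sim <- simulate_epigenome(config$sim)
  genes <- simulate_genes(config$sim)
  exprsim <- simulate_expression(config$sim, genes)

  inform("binarizing and fitting the chromatin-state model ...")
  bin <- purrr::map(sim$counts, binarize_counts, p_threshold = config$binarize_threshold)
  fit <- fit_chromatin_hmm(unname(bin), n_states = config$n_states,
                           seed = sim_seed(config$sim, 101L))
  seg <- purrr::map(bin, ~ decode_states(fit, .x))

  coverage <- purrr::imap_dfr(seg, ~ mutate(state_coverage(.x), condition = .y))

  # annotation enrichment: gene bodies as the external annotation
  gene_bodies <- interval_tbl(genes[c("chrom", "start", "end")], genome)
  enrichment <- state_enrichment(seg$control, gene_bodies, genome)

  # positional profile of each state around TSS
  anchors <- gene_tss(genes)
  seg_iv <- segmentation_to_intervals(seg$control)
  profile <- purrr::map_dfr(sort(unique(seg_iv$state)), function(k) {
    mutate(positional_profile(filter(seg_iv, .data$state == k), anchors, genome,
                              flank = config$profile_flank,
                              bin = config$sim$window_size),
           state = k)
  })

  inform("differential expression ...")
  de_stats <- simple_de_test(exprsim$expr)
  degs <- deg_filter(de_stats, p_threshold = config$deg_p, lfc_threshold = config$deg_lfc)
  up_genes <- semi_join(genes, filter(degs, .data$direction == "up"), by = "gene_id")
  flank_enrich <- NULL
  if (nrow(up_genes) > 0) {
    flank_enrich <- purrr::imap_dfr(seg, function(s, nm) {
      mutate(gene_flank_state_enrichment(up_genes, s, genome, flank = config$deg_flank),
             condition = nm)
    })
  }

  inform("state dynamics ...")
  transitions <- state_transition_matrix(seg$control, seg$treated,
                                         n_states = config$n_states)
  assoc <- transition_associated_genes(
    if (nrow(up_genes) > 0) up_genes else genes,
    seg$control, seg$treated,
    from_states = config$categories[[3]] %||% 3L,
    to_states = config$categories[[1]] %||% 1L,
    genome = genome, flank = config$deg_flank
  )

  inform("gene classification ...")
  cats <- classify_genes(genes, seg$control, config$categories, genome,
                         promoter_flank = config$promoter_flank)
  expr_control <- exprsim$expr %>%
    filter(.data$condition == "control") %>%
    group_by(.data$gene_id) %>%
    summarise(fpkm = mean(.data$fpkm), .groups = "drop")
  cat_expr <- category_expression_summary(cats, expr_control)

  inform("GWAS marker-set enrichment ...")
  feature_iv <- filter(seg_iv, .data$state == (config$categories[[1]] %||% 1L))
  effects <- simulate_gwas_effects(config$sim, feature_iv)
  perm <- circular_permutation_test(effects, "feature", n_perm = config$n_perm,
                                    seed = sim_seed(config$sim, 131L))

  inform("differential methylation ...")
  methsim <- simulate_methylome(config$sim)
  meth_windows <- window_methylation(methsim$cpgs, window = config$sim$meth_window,
                                     step = config$sim$meth_window,
                                     min_coverage = config$dmr_coverage)
  tested <- dmr_test_all(meth_windows)
  dmrs <- dmr_filter(tested, q_threshold = config$dmr_q, diff_threshold = config$dmr_diff)

  summary <- tibble(
    quantity = c("windows", "states", "em_iterations", "loglik",
                 "deg_total", "deg_up", "deg_down",
                 "transition_assoc_genes", "gwas_t_obs", "gwas_p_emp",
                 "dmr_windows_tested", "dmr_count", "max_retention_pct"),
    value = c(nrow(sim$grid), config$n_states, fit$n_iter, fit$loglik,
              nrow(degs), sum(degs$direction == "up"), sum(degs$direction == "down"),
              nrow(assoc), perm$t_obs, perm$p_emp,
              nrow(tested), nrow(dmrs),
              100 * max(transitions$retention, na.rm = TRUE))
  )

  results <- list(
    seed = seed, config_hash = config_hash,
    model = fit, segmentation = seg, coverage = coverage,
    enrichment = enrichment, profile = profile,
    de_stats = de_stats, degs = degs, flank_enrichment = flank_enrich,
    transitions = transitions, transition_genes = assoc,
    categories = cats, category_expression = cat_expr,
    gwas = perm, dmr_tested = attr(dmrs, "tested"), dmrs = dmrs,
    truth = list(states = sim$states, changed_regions = sim$changed_regions,
                 de = exprsim$truth, dmr = methsim$dmr_truth),
    summary = summary
  )

  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    wt <- function(x, name) write_result_tsv(x, file.path(out_dir, name), seed, config_hash)
    wt(coverage, "state_coverage.tsv")
    wt(enrichment, "state_enrichment.tsv")
    wt(profile, "tss_profile.tsv")
    wt(de_stats, "de_stats.tsv")
    wt(as_tibble(degs), "degs.tsv")
    if (!is.null(flank_enrich)) wt(flank_enrich, "deg_flank_enrichment.tsv")
    wt(glance(transitions), "state_dynamics.tsv")
    wt(tidy(transitions), "transition_matrix.tsv")
    wt(cats, "gene_categories.tsv")
    wt(glance(perm), "gwas_enrichment.tsv")
    wt(attr(dmrs, "tested"), "dmr_tested.tsv")
    wt(as_tibble(dmrs), "dmrs.tsv")
    wt(summary, "summary.tsv")
    write_hmm_model(fit, file.path(out_dir, "model"))
    write_segmentation_bed(seg$control, file.path(out_dir, "segmentation_control.bed"))
    write_segmentation_bed(seg$treated, file.path(out_dir, "segmentation_treated.bed"))
  }
  results
}
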