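test_that("fisher_exact matches stats::fisher.test and the enumeration oracle", {
  frozen <- fisher_exact(matrix(c(0, 10, 10, 0), 2, byrow = TRUE))
  expect_equal(frozen$p, 2 / choose(20, 10), tolerance = 1e-12)
  expect_equal(fisher_exact(c(5, 5, 5, 5))$p, 1, tolerance = 1e-12)

  set.seed(31)
  for (rep in 1:25) {
    tb <- matrix(rpois(4, 6), 2)
    if (sum(tb) == 0) tb[1, 1] <- 1
    got <- fisher_exact(tb)
    expect_equal(got$p, fisher_enum(tb), tolerance = 1e-9)
    expect_equal(got$p, stats::fisher.test(tb)$p.value, tolerance = 1e-7)
    expect_equal(got$log10p, log10(got$p), tolerance = 1e-9)
  }

  # log10p survives underflow of p itself
  big <- fisher_exact(c(5e5, 5e5, 1e5, 9e5))
  expect_equal(big$p, 0)
  expect_lt(big$log10p, -1000)
  expect_true(is.finite(big$log10p))

  expect_error(fisher_exact(c(1, 2, 3)), "2x2")
  expect_error(fisher_exact(c(-1, 2, 3, 4)), "non-negative")
})

test_that("fold_enrichment matches the per-base boolean computation", {
  g <- genome_tbl(c(chr1 = 1e6))
  st <- interval_tbl(data.frame(chrom = "chr1", start = 0, end = 1000), g)
  an <- interval_tbl(data.frame(chrom = "chr1", start = 900, end = 10900), g)
  fe <- fold_enrichment(st, an)
  expect_equal(fe$C, 100)
  expect_equal(fe$fold, (100 / 1000) / (10000 / 1e6))

  set.seed(13)
  g10 <- toy_genome(10000)
  for (rep in 1:10) {
    st <- random_intervals(15, g10)
    an <- random_intervals(15, g10)
    cs <- base_cover(st, "chr1", 10000)
    ca <- base_cover(an, "chr1", 10000)
    fe <- fold_enrichment(st, an)
    expect_equal(fe$A, sum(cs))
    expect_equal(fe$B, sum(ca))
    expect_equal(fe$C, sum(cs & ca))
    expect_equal(fe$D, 10000)
    expect_equal(fe$fold, (sum(cs & ca) / sum(cs)) / (sum(ca) / 10000))
  }

  # undefined fold reported as NA with a reason, not an error
  empty_state <- interval_tbl(data.frame(chrom = "chr1", start = 0, end = 1)[0, ], g10)
  fe0 <- fold_enrichment(empty_state, random_intervals(3, g10), genome = g10)
  expect_true(is.na(fe0$fold))
  expect_match(fe0$note, "state")
})

test_that("positional_profile is strand-aware and normalizes by coverage", {
  g <- genome_tbl(c(chr1 = 100000))
  # state occupies [10000, 11000); coverage fraction 0.01
  st <- interval_tbl(data.frame(chrom = "chr1", start = 10000, end = 11000), g)
  # plus-strand anchor with the state starting exactly at the anchor
  anchors <- tibble::tibble(chrom = "chr1", pos = 10000, strand = "+")
  pr <- positional_profile(st, anchors, g, flank = 2000, bin = 200)
  expect_equal(nrow(pr), 20)
  expect_equal(pr$fraction[pr$offset >= 0 & pr$offset < 1000], rep(1, 5))
  expect_equal(pr$fraction[pr$offset < 0 | pr$offset >= 1000], rep(0, 15))
  expect_equal(pr$ratio, pr$fraction / 0.01)

  # the mirrored minus-strand anchor sees the same oriented profile:
  # state upstream of a minus-strand TSS at 9999 lies at negative offsets
  anchors_m <- tibble::tibble(chrom = "chr1", pos = 9999, strand = "-")
  pr_m <- positional_profile(st, anchors_m, g, flank = 2000, bin = 200)
  expect_equal(pr_m$fraction[pr_m$offset %in% seq(-1000, -200, 200)], rep(1, 5))
  expect_equal(sum(pr_m$fraction), 5)

  # anchors near the chromosome edge are dropped from affected offsets only
  anchors_e <- tibble::tibble(chrom = "chr1", pos = c(500, 50000), strand = "+")
  pr_e <- positional_profile(st, anchors_e, g, flank = 2000, bin = 200)
  expect_equal(pr_e$n_anchors[pr_e$offset == -2000], 1L)
  expect_equal(pr_e$n_anchors[pr_e$offset == 0], 2L)

  expect_error(positional_profile(st, anchors, g, flank = 2100, bin = 200), "multiple")
  expect_error(positional_profile(st, anchors[0, ], g), "empty")
  expect_s3_class(plot_positional_profile(pr), "ggplot")
})

test_that("gwas_tsum and the circular permutation test match hand computation", {
  # m = 5, b = (3,0,0,0,0), single-SNP feature at position 1:
  # the 4 possible rotations give T in {0,0,0,9}; with 9 > 9 false for the
  # aligned rotation, p_literal over exhaustive offsets would be 0 and
  # p_emp with all 4 offsets sampled = (0+1)/(4+1)
  eff <- tibble::tibble(chrom = "chr1", pos = 0:4, b = c(3, 0, 0, 0, 0),
                        feature = c(TRUE, FALSE, FALSE, FALSE, FALSE))
  expect_equal(gwas_tsum(eff), 9)
  pt <- circular_permutation_test(eff, n_perm = 400, seed = 3)
  expect_true(all(pt$null_t == 0))
  expect_equal(pt$p_literal, 0)
  expect_equal(pt$p_emp, 1 / 401)

  # rotation preserves the multiset of b^2 values
  set.seed(17)
  eff2 <- tibble::tibble(chrom = "chr1", pos = sort(sample.int(10000, 200)) - 1,
                         b = rnorm(200))
  feat <- interval_tbl(data.frame(chrom = "chr1", start = 2000, end = 4000),
                       genome_tbl(c(chr1 = 10000)))
  eff2 <- add_feature_mask(eff2, feat)
  # oracle: recompute one rotation by hand for every sampled offset
  pt2 <- circular_permutation_test(eff2, n_perm = 50, seed = 5)
  set.seed(5)
  offs <- sample.int(199, 50, replace = TRUE)
  b2 <- eff2$b^2
  oracle <- vapply(offs, function(k) {
    sum((b2[((seq_len(200) - 1 + k) %% 200) + 1])[eff2$feature])
  }, numeric(1))
  expect_equal(pt2$null_t, oracle)
  expect_equal(pt2$t_obs, sum(eff2$b[eff2$feature]^2))
  expect_equal(pt2$p_emp, (sum(oracle > pt2$t_obs) + 1) / 51)
  # ">=" tie rule can only raise the p-value
  pt3 <- circular_permutation_test(eff2, n_perm = 50, seed = 5, tie = ">=")
  expect_gte(pt3$p_emp, pt2$p_emp)
  # per-chromosome rotation keeps the same T_obs
  eff3 <- dplyr::mutate(eff2, chrom = ifelse(pos < 5000, "chr1", "chr2"))
  pt4 <- circular_permutation_test(eff3, n_perm = 20, seed = 5,
                                   per_chromosome = TRUE)
  expect_equal(pt4$t_obs, pt2$t_obs)

  gl <- glance(pt2)
  expect_equal(gl$n_feature, sum(eff2$feature))
  expect_equal(nrow(tidy(pt2)), 50)
  expect_s3_class(autoplot(pt2), "ggplot")
  expect_output(print(pt2), "gwas_perm_test")
  expect_error(gwas_tsum(dplyr::mutate(eff, feature = FALSE)), "no SNPs")
})

test_that("hypergeometric enrichment matches pmf summation and frozen values", {
  # universe 20, target 10, query 5, overlap 5: p = C(10,5)/C(20,5)
  uni <- paste0("g", 1:20)
  p <- hypergeom_enrichment(uni[1:5], uni[1:10], uni)
  expect_equal(p$overlap, 5)
  expect_equal(p$expected, 2.5)
  expect_equal(p$p, choose(10, 5) / choose(20, 5), tolerance = 1e-12)
  expect_equal(p$p, 252 / 15504, tolerance = 1e-12)

  set.seed(19)
  for (rep in 1:10) {
    n_uni <- sample(10:40, 1)
    uni <- paste0("g", seq_len(n_uni))
    target <- sample(uni, sample.int(n_uni, 1))
    query <- sample(uni, sample.int(n_uni, 1))
    got <- hypergeom_enrichment(query, target, uni)
    expect_equal(got$p,
                 hypergeom_enum(length(intersect(query, target)),
                                length(target), n_uni, length(query)),
                 tolerance = 1e-9)
  }
  expect_error(hypergeom_enrichment(c("x"), uni[1:2], uni), "subsets")
})

test_that("tissue_specific_genes ranks by z-score and takes the top fraction", {
  expr <- tibble::tibble(
    gene_id = paste0("g", 1:40),
    liver = c(1000, rep(1, 39)),
    brain = rep(1, 40),
    muscle = rep(1, 40)
  )
  top <- tissue_specific_genes(expr, "liver", top_frac = 0.05)
  expect_equal(nrow(top), 2) # ceiling(0.05 * 40)
  expect_equal(top$gene_id[1], "g1")
  expect_gt(top$score[1], top$score[2])
  # constant genes score 0 and rank last
  expect_equal(top$score[2], 0)
  expect_error(tissue_specific_genes(expr["gene_id"], "liver"), "two tissue")
  expect_error(tissue_specific_genes(expr, "kidney"), "kidney")
})

test_that("benjamini_hochberg reproduces the step-up adjustment", {
  expect_equal(benjamini_hochberg(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  set.seed(23)
  p <- runif(50)
  expect_equal(benjamini_hochberg(p), p.adjust(p, "BH"))
  expect_error(benjamini_hochberg(c(0.5, 1.2)), "\\[0, 1\\]")
})
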