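test_that("window_grid tiles each chromosome exactly once", {
  g <- genome_tbl(c(chr1 = 1000, chr2 = 450))
  grid <- window_grid(g, 200)
  expect_equal(nrow(grid), 5 + 3)
  # last window truncated to the chromosome length
  expect_equal(max(grid$end[grid$chrom == "chr2"]), 450)
  # contiguous, non-overlapping tiling
  by_chr <- split(grid, grid$chrom)
  for (x in by_chr) {
    expect_equal(x$start[1], 0)
    expect_equal(x$start[-1], x$end[-nrow(x)])
  }
  expect_equal(sum(grid$end - grid$start), sum(g$size))
  expect_error(window_grid(g, 0), "positive")
})

test_that("binarize_counts matches a direct Poisson-tail computation", {
  set.seed(21)
  n <- 400
  counts <- tibble::tibble(
    chrom = "chr1", start = (seq_len(n) - 1) * 200, end = seq_len(n) * 200,
    m1 = rpois(n, 1), m2 = rpois(n, c(rep(20, 40), rep(0.5, n - 40))),
    control = rpois(n, 2)
  )
  calls <- binarize_counts(counts, p_threshold = 1e-4)
  for (m in c("m1", "m2")) {
    lam <- mean(counts[[m]]) * counts$control / mean(counts$control)
    oracle <- as.integer(counts[[m]] > 0 &
                           ppois(counts[[m]] - 1, pmax(lam, 1e-12), lower.tail = FALSE) < 1e-4)
    expect_equal(calls[[m]], oracle)
  }
  expect_false("control" %in% names(calls))
  # without a control the background is flat
  c2 <- binarize_counts(counts[setdiff(names(counts), "control")])
  lam <- mean(counts$m2)
  expect_equal(c2$m2, as.integer(counts$m2 > 0 &
                                   ppois(counts$m2 - 1, lam, lower.tail = FALSE) < 1e-4))
  # all-zero mark warns and yields zeros
  counts$m3 <- 0L
  expect_warning(c3 <- binarize_counts(counts), "all-zero")
  expect_true(all(c3$m3 == 0L))
  expect_error(binarize_counts(counts, p_threshold = 1.5), "p_threshold")
})

test_that("chromatin_hmm constructor enforces stochasticity invariants", {
  A <- matrix(c(0.9, 0.1, 0.2, 0.8), 2, byrow = TRUE)
  em <- matrix(c(0.9, 0.1, 0.1, 0.9), 2, byrow = TRUE)
  m <- chromatin_hmm(c(0.5, 0.5), A, em, marks = c("a", "b"))
  expect_s3_class(m, "chromatin_hmm")
  expect_error(chromatin_hmm(c(0.6, 0.5), A, em), "sum to 1")
  expect_error(chromatin_hmm(c(0.5, 0.5), A * 2, em), "rows must sum")
  expect_error(chromatin_hmm(c(0.5, 0.5), A, em * 2), "emission")
})

test_that("posterior marginals and loglik match exhaustive path enumeration", {
  set.seed(5)
  for (rep in 1:5) {
    K <- sample(2:3, 1)
    M <- sample(2:3, 1)
    T_ <- sample(4:7, 1)
    A <- matrix(rgamma(K * K, 1), K); A <- A / rowSums(A)
    em <- matrix(runif(K * M, 0.05, 0.95), K, M)
    pi0 <- rgamma(K, 1); pi0 <- pi0 / sum(pi0)
    model <- chromatin_hmm(pi0, A, em)
    X <- matrix(rbinom(T_ * M, 1, 0.5), T_, M)
    calls <- dplyr::bind_cols(
      tibble::tibble(chrom = "chr1", start = (seq_len(T_) - 1) * 200, end = seq_len(T_) * 200),
      tibble::as_tibble(`colnames<-`(X, model$marks))
    )
    truth <- enumerate_hmm(pi0, A, pmin(pmax(em, 1e-6), 1 - 1e-6), X)
    got <- posterior_marginals(model, calls)
    expect_lt(abs(got$loglik - truth$loglik), 1e-9)
    expect_lt(max(abs(got$gamma - truth$gamma)), 1e-9)
    expect_equal(rowSums(got$gamma), rep(1, T_), tolerance = 1e-12)
  }
})

test_that("viterbi decoding finds the maximum-probability path on toys", {
  set.seed(6)
  for (rep in 1:3) {
    K <- 3; M <- 2; T_ <- 6
    A <- matrix(rgamma(K * K, 1), K); A <- A / rowSums(A)
    em <- matrix(runif(K * M, 0.1, 0.9), K, M)
    pi0 <- rep(1 / K, K)
    model <- chromatin_hmm(pi0, A, em)
    X <- matrix(rbinom(T_ * M, 1, 0.5), T_, M)
    calls <- dplyr::bind_cols(
      tibble::tibble(chrom = "chr1", start = (seq_len(T_) - 1) * 200, end = seq_len(T_) * 200),
      tibble::as_tibble(`colnames<-`(X, model$marks))
    )
    # brute force over all K^T paths
    emc <- pmin(pmax(em, 1e-6), 1 - 1e-6)
    paths <- as.matrix(expand.grid(rep(list(seq_len(K)), T_)))
    lp <- apply(paths, 1, function(s) {
      v <- log(pi0[s[1]]) + sum(X[1, ] * log(emc[s[1], ]) + (1 - X[1, ]) * log(1 - emc[s[1], ]))
      for (t in seq_len(T_ - 1)) {
        v <- v + log(A[s[t], s[t + 1]]) +
          sum(X[t + 1, ] * log(emc[s[t + 1], ]) + (1 - X[t + 1, ]) * log(1 - emc[s[t + 1], ]))
      }
      v
    })
    best <- unname(paths[which.max(lp), ])
    got <- decode_states(model, calls, method = "viterbi")$state
    expect_equal(got, best)
  }
})

test_that("EM log-likelihood is non-decreasing and the fit is seed-deterministic", {
  cfg <- sim_config(seed = 4, genome = c(chr1 = 6e4), n_states = 3, n_marks = 4)
  sim <- simulate_epigenome(cfg)
  fit1 <- fit_chromatin_hmm(sim$calls$control, n_states = 3, seed = 7, max_iter = 40)
  fit2 <- fit_chromatin_hmm(sim$calls$control, n_states = 3, seed = 7, max_iter = 40)
  expect_identical(fit1$emission, fit2$emission)
  expect_identical(fit1$transition, fit2$transition)
  expect_true(all(diff(fit1$loglik_trace) >= -1e-8))
  expect_equal(sum(fit1$initial), 1, tolerance = 1e-9)
  expect_equal(rowSums(fit1$transition), rep(1, 3), tolerance = 1e-9)
})

test_that("segmentation round-trips through run-length intervals", {
  set.seed(9)
  g <- genome_tbl(c(chr1 = 4000, chr2 = 2000))
  grid <- window_grid(g, 200)
  seg <- dplyr::mutate(grid[c("chrom", "start", "end")],
                       state = sample(1:3, nrow(grid), replace = TRUE))
  iv <- segmentation_to_intervals(seg)
  # intervals tile the windowed genome exactly once
  expect_equal(sum(iv$end - iv$start), sum(g$size))
  expect_equal(genome_coverage_pct(interval_tbl(iv, g)), 100)
  # adjacent intervals on a chromosome never share a state
  for (x in split(iv, iv$chrom)) {
    if (nrow(x) > 1) expect_true(all(x$state[-1] != x$state[-nrow(x)]))
  }
  # expanding intervals back to windows recovers the segmentation
  back <- purrr::pmap_dfr(iv, function(chrom, start, end, state) {
    s <- seq(start, end - 1, by = 200)
    tibble::tibble(chrom = chrom, start = s, end = pmin(s + 200, end), state = state)
  }) %>% dplyr::arrange(chrom, start)
  expect_equal(back, dplyr::arrange(seg, chrom, start))
  # state labels
  iv2 <- segmentation_to_intervals(seg, state_names = c("TssA", "Enh", "Quies"))
  expect_true(all(grepl("^[123]_(TssA|Enh|Quies)$", iv2$name)))
  # coverage percentages total 100
  cov <- state_coverage(seg)
  expect_equal(sum(cov$coverage_pct), 100)
  expect_equal(sum(cov$bases), sum(g$size))
})

test_that("tidy/glance/autoplot methods return well-formed objects", {
  m <- chromatin_hmm(c(0.5, 0.5),
                     matrix(c(0.9, 0.1, 0.2, 0.8), 2, byrow = TRUE),
                     matrix(c(0.9, 0.1, 0.1, 0.9), 2, byrow = TRUE),
                     marks = c("H3K4me3", "H3K27me3"))
  td <- tidy(m, "emission")
  expect_equal(nrow(td), 4)
  expect_equal(td$probability[td$state == 1 & td$mark == "H3K4me3"], 0.9)
  tt <- tidy(m, "transition")
  expect_equal(tt$probability[tt$from == 1 & tt$to == 2], 0.1)
  expect_equal(tidy(m, "initial")$probability, c(0.5, 0.5))
  gl <- glance(m)
  expect_equal(gl$n_states, 2)
  expect_s3_class(autoplot(m), "ggplot")
  expect_output(print(m), "chromatin_hmm")
})
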