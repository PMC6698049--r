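# Brute-force oracles and fixture builders, independent of the package's
# implementation paths.

toy_genome <- function(len = 10000, chroms = "chr1") {
  genome_tbl(setNames(rep(len, length(chroms)), chroms))
}

random_intervals <- function(n, genome, max_len = 500) {
  g <- as.data.frame(genome)
  chrom <- sample(g$chrom, n, replace = TRUE)
  sz <- setNames(g$size, g$chrom)
  len <- sample.int(max_len, n, replace = TRUE)
  start <- floor(runif(n) * (sz[chrom] - len))
  interval_tbl(tibble::tibble(chrom = chrom, start = start, end = start + len), genome)
}

# per-base boolean coverage of one chromosome
base_cover <- function(iv, chrom, len) {
  v <- logical(len)
  x <- iv[iv$chrom == chrom, , drop = FALSE]
  for (i in seq_len(nrow(x))) v[(x$start[i] + 1):x$end[i]] <- TRUE
  v
}

# exhaustive enumeration over all K^T hidden paths of a Bernoulli-product HMM
enumerate_hmm <- function(initial, transition, emission, X) {
  K <- length(initial)
  T_ <- nrow(X)
  paths <- as.matrix(expand.grid(rep(list(seq_len(K)), T_)))
  emis_p <- function(k, t) prod(ifelse(X[t, ] == 1, emission[k, ], 1 - emission[k, ]))
  probs <- apply(paths, 1, function(s) {
    p <- initial[s[1]] * emis_p(s[1], 1)
    for (t in seq_len(T_ - 1)) {
      p <- p * transition[s[t], s[t + 1]] * emis_p(s[t + 1], t + 1)
    }
    p
  })
  lik <- sum(probs)
  gamma <- matrix(0, T_, K)
  for (t in seq_len(T_)) {
    for (k in seq_len(K)) gamma[t, k] <- sum(probs[paths[, t] == k]) / lik
  }
  list(loglik = log(lik), gamma = gamma)
}

# two-sided Fisher p by enumerating all tables with the observed margins,
# probabilities from factorials (independent of dhyper)
fisher_enum <- function(tb) {
  tb <- matrix(as.numeric(tb), 2, 2)
  r1 <- sum(tb[1, ]); r2 <- sum(tb[2, ]); c1 <- sum(tb[, 1])
  lo <- max(0, c1 - r2); hi <- min(r1, c1)
  lp <- vapply(lo:hi, function(a) {
    b <- r1 - a; cc <- c1 - a; d <- r2 - cc
    -(lfactorial(a) + lfactorial(b) + lfactorial(cc) + lfactorial(d))
  }, numeric(1))
  w <- exp(lp - max(lp))
  probs <- w / sum(w)
  p_obs <- probs[tb[1, 1] - lo + 1]
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# upper-tail hypergeometric p by direct pmf summation
hypergeom_enum <- function(overlap, n_target, n_universe, n_query) {
  ks <- overlap:min(n_target, n_query)
  sum(vapply(ks, function(k) {
    exp(lchoose(n_target, k) + lchoose(n_universe - n_target, n_query - k) -
          lchoose(n_universe, n_query))
  }, numeric(1)))
}

# best state relabeling (exhaustive over permutations; fine for K <= 6)
match_states <- function(est_emission, true_emission) {
  K <- nrow(true_emission)
  perms <- gtools_permutations(K)
  errs <- apply(perms, 1, function(p) sum(abs(est_emission[p, , drop = FALSE] - true_emission)))
  perms[which.min(errs), ]
}

gtools_permutations <- function(K) {
  if (K == 1) return(matrix(1, 1, 1))
  sub <- gtools_permutations(K - 1)
  out <- NULL
  for (i in seq_len(K)) {
    rest <- setdiff(seq_len(K), i)
    out <- rbind(out, cbind(i, matrix(rest[sub], nrow(sub), K - 1)))
  }
  unname(out)
}
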