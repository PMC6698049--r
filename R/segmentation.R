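#' Tile a genome into fixed-width windows
#'
#' Windows tile each chromosome contiguously from position 0; the last window
#' of a chromosome may be truncated.
#'
#' @param genome Genome table ([genome_tbl()]).
#' @param window_size Window width in bp (default 200).
#' @return Tibble with `chrom`, `start`, `end`, `window` (1-based index
#'   within chromosome).
#' @export
window_grid <- function(genome, window_size = 200) {
  genome <- as_genome_tbl(genome)
  if (window_size <= 0) abort("window_size must be positive")
  purrr::map_dfr(seq_len(nrow(genome)), function(i) {
    n <- ceiling(genome$size[i] / window_size)
    start <- (seq_len(n) - 1) * window_size
    tibble(
      chrom = genome$chrom[i],
      start = start,
      end = pmin(start + window_size, genome$size[i]),
      window = seq_len(n)
    )
  })
}

mark_columns <- function(x) {
  setdiff(names(x), c("chrom", "start", "end", "window", "control"))
}

#' Binarize per-window mark read counts against a Poisson background
#'
#' Each mark is called present (1) in a window when its count is significantly
#' above a Poisson background: the mark's genome-wide mean rate, optionally
#' scaled window-by-window by a control track (control count divided by the
#' control's genome-wide mean). A window is called when the Poisson
#' upper-tail probability P(X >= count) falls below `p_threshold`.
#'
#' @param counts Tibble with `chrom`, `start`, `end` and one non-negative
#'   integer column per mark; an optional `control` column (or the
#'   `control` argument) carries the background read counts.
#' @param control Optional numeric vector of per-window control counts,
#'   overriding a `control` column.
#' @param p_threshold Poisson tail threshold in (0, 1); default 1e-4.
#' @return The input tibble with mark columns replaced by 0/1 calls (the
#'   control column is dropped).
#' @export
binarize_counts <- function(counts, control = NULL, p_threshold = 1e-4) {
  if (p_threshold <= 0 || p_threshold >= 1) abort("p_threshold must be in (0, 1)")
  marks <- mark_columns(counts)
  if (length(marks) == 0) abort("no mark columns found")
  ctl <- control %||% counts[["control"]]
  scale <- if (!is.null(ctl)) {
    if (any(ctl < 0)) abort("control counts must be non-negative")
    if (mean(ctl) <= 0) rep(1, nrow(counts)) else ctl / mean(ctl)
  } else {
    rep(1, nrow(counts))
  }
  out <- counts[c("chrom", "start", "end", intersect("window", names(counts)))]
  for (m in marks) {
    x <- counts[[m]]
    if (any(x < 0)) abort(sprintf("negative counts in mark '%s'", m))
    lambda <- mean(x)
    if (lambda == 0) {
      warn(sprintf("mark '%s' has all-zero counts; calls set to 0", m))
      out[[m]] <- rep(0L, length(x))
      next
    }
    lam <- pmax(lambda * scale, 1e-12)
    # P(X >= x | Poisson(lam)) < threshold
    tail_p <- ppois(x - 1, lam, lower.tail = FALSE)
    out[[m]] <- as.integer(x > 0 & tail_p < p_threshold)
  }
  out
}

calls_matrix <- function(calls) {
  marks <- mark_columns(calls)
  X <- as.matrix(calls[marks])
  if (!all(X %in% c(0, 1))) abort("binarized calls must be 0/1")
  storage.mode(X) <- "double"
  list(X = X, marks = marks, chrom = calls$chrom)
}

emission_lik <- function(X, p, log = FALSE) {
  pe <- pmin(pmax(p, 1e-6), 1 - 1e-6)
  lB <- X %*% t(log(pe)) + (1 - X) %*% t(log(1 - pe))
  if (log) lB else exp(lB)
}

new_chromatin_hmm <- function(initial, transition, emission, marks,
                              loglik = NA_real_, loglik_trace = numeric(),
                              n_iter = NA_integer_, converged = NA) {
  structure(
    list(
      n_states = length(initial), marks = marks,
      initial = initial, transition = transition, emission = emission,
      loglik = loglik, loglik_trace = loglik_trace,
      n_iter = n_iter, converged = converged
    ),
    class = "chromatin_hmm"
  )
}

#' Construct a Bernoulli-product hidden Markov model
#'
#' The model underlying ChromHMM-style chromatin-state discovery: `K` hidden
#' states, a row-stochastic transition matrix, and per-state conditionally
#' independent Bernoulli emission probabilities for each of `M` marks.
#'
#' @param initial Length-K initial state distribution (sums to 1).
#' @param transition K x K row-stochastic matrix.
#' @param emission K x M matrix of Bernoulli success probabilities.
#' @param marks Character vector of M mark names.
#' @return A `chromatin_hmm` object.
#' @export
chromatin_hmm <- function(initial, transition, emission,
                          marks = colnames(emission) %||% paste0("mark", seq_len(ncol(emission)))) {
  initial <- as.numeric(initial)
  transition <- as.matrix(transition)
  emission <- as.matrix(emission)
  K <- length(initial)
  if (abs(sum(initial) - 1) > 1e-9) abort("initial distribution must sum to 1")
  if (!all(dim(transition) == c(K, K))) abort("transition must be K x K")
  if (any(abs(rowSums(transition) - 1) > 1e-9)) abort("transition rows must sum to 1")
  if (nrow(emission) != K) abort("emission must have one row per state")
  if (any(emission < 0 | emission > 1)) abort("emission probabilities must be in [0, 1]")
  colnames(emission) <- marks
  new_chromatin_hmm(initial, transition, emission, marks)
}

#' Fit a chromatin-state HMM by Baum-Welch
#'
#' Expectation-maximization for the Bernoulli-product HMM on one binarized
#' track (or a list of tracks sharing the same marks). Chromosomes are
#' treated as independent sequences: the chain restarts from the initial
#' distribution at each chromosome boundary. The log-likelihood is
#' non-decreasing across iterations and the fit is deterministic given
#' `seed`.
#'
#' Initialization: emission probabilities drawn uniform(0.2, 0.8) from the
#' seed; transitions 0.5 on the diagonal with the rest uniform; initial
#' distribution uniform.
#'
#' @param calls A binarized-track tibble (`chrom` plus 0/1 mark columns), or
#'   a list of such tibbles (e.g. two conditions fit jointly).
#' @param n_states Number of hidden states K (>= 1); the study design this
#'   mirrors used 15.
#' @param seed Integer seed for the random initialization.
#' @param max_iter Maximum EM iterations.
#' @param tol Stop when the total log-likelihood improves by less than this.
#' @param verbose Print the log-likelihood each iteration.
#' @return A `chromatin_hmm` fit with `loglik_trace`, `n_iter`, `converged`.
#' @examples
#' sim <- simulate_epigenome(sim_config(genome = c(chr1 = 4e4), n_states = 3, n_marks = 4))
#' fit <- fit_chromatin_hmm(sim$calls$control, n_states = 3, seed = 1)
#' glance(fit)
#' @export
fit_chromatin_hmm <- function(calls, n_states, seed = 1L, max_iter = 200L,
                              tol = 1e-4, verbose = FALSE) {
  tracks <- if (is.data.frame(calls)) list(calls) else calls
  parsed <- purrr::map(tracks, calls_matrix)
  marks <- parsed[[1]]$marks
  if (!all(purrr::map_lgl(parsed, ~ identical(.x$marks, marks)))) {
    abort("all tracks must share the same mark columns in the same order")
  }
  # chromosome = independent sequence
  seqs <- purrr::map(parsed, function(p) {
    lapply(split(seq_len(nrow(p$X)), p$chrom), function(i) p$X[i, , drop = FALSE])
  })
  seqs <- unlist(seqs, recursive = FALSE)
  Ttot <- sum(purrr::map_int(seqs, nrow))
  K <- as.integer(n_states)
  M <- length(marks)
  if (K < 1) abort("n_states must be >= 1")
  if (K > Ttot) abort("n_states exceeds the number of windows")

  set.seed(seed)
  p <- matrix(runif(K * M, 0.2, 0.8), K, M)
  A <- matrix(if (K > 1) 0.5 / (K - 1) else 0, K, K)
  diag(A) <- if (K > 1) 0.5 else 1
  pi0 <- rep(1 / K, K)

  ll_trace <- numeric(0)
  ll_prev <- -Inf
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    pi_acc <- numeric(K)
    xi_acc <- matrix(0, K, K)
    wx_acc <- matrix(0, K, M)
    w_acc <- numeric(K)
    ll <- 0
    for (X in seqs) {
      B <- emission_lik(X, p)
      fb <- fb_scaled(B, pi0, A)
      if (anyNA(fb$gamma)) abort("NaN posterior in E-step; aborting")
      ll <- ll + fb$loglik
      pi_acc <- pi_acc + fb$gamma[1, ]
      xi_acc <- xi_acc + fb$xi_sum
      wx_acc <- wx_acc + t(fb$gamma) %*% X
      w_acc <- w_acc + colSums(fb$gamma)
    }
    ll_trace <- c(ll_trace, ll)
    if (verbose) inform(sprintf("iter %d: loglik %.6f", it, ll))
    # M-step
    pi0 <- pi_acc / sum(pi_acc)
    if (K > 1) {
      rs <- rowSums(xi_acc)
      ok <- rs > 0
      A[ok, ] <- xi_acc[ok, , drop = FALSE] / rs[ok]
      A[!ok, ] <- 1 / K
    }
    p <- wx_acc / w_acc
    p[!is.finite(p)] <- 0.5
    if (is.finite(ll_prev) && abs(ll - ll_prev) < tol) {
      converged <- TRUE
      break
    }
    ll_prev <- ll
  }
  fit <- new_chromatin_hmm(pi0, A, p, marks,
                           loglik = ll_trace[length(ll_trace)],
                           loglik_trace = ll_trace, n_iter = it, converged = converged)
  fit
}

#' @export
print.chromatin_hmm <- function(x, ...) {
  cat(sprintf("<chromatin_hmm> %d states x %d marks", x$n_states, length(x$marks)))
  if (!is.na(x$loglik)) {
    cat(sprintf("; loglik %.3f after %d EM iteration(s)%s", x$loglik, x$n_iter,
                if (isTRUE(x$converged)) " (converged)" else ""))
  }
  cat("\nmarks:", paste(x$marks, collapse = ", "), "\n")
  invisible(x)
}

#' @rdname tidy.chromatin_hmm
#' @export
glance.chromatin_hmm <- function(x, ...) {
  tibble(
    n_states = x$n_states, n_marks = length(x$marks),
    loglik = x$loglik, n_iter = x$n_iter, converged = x$converged
  )
}

#' Tidy a fitted chromatin-state HMM
#'
#' `tidy()` returns the model parameters as a long tibble; `glance()` returns
#' a one-row fit summary.
#'
#' @param x A `chromatin_hmm`.
#' @param matrix Which parameter block to return.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.chromatin_hmm <- function(x, matrix = c("emission", "transition", "initial"), ...) {
  matrix <- match.arg(matrix)
  if (matrix == "emission") {
    tidyr::pivot_longer(
      dplyr::bind_cols(tibble(state = seq_len(x$n_states)),
                       as_tibble(x$emission, .name_repair = "minimal")),
      -"state", names_to = "mark", values_to = "probability"
    )
  } else if (matrix == "transition") {
    tidyr::expand_grid(from = seq_len(x$n_states), to = seq_len(x$n_states)) %>%
      mutate(probability = as.vector(t(x$transition)))
  } else {
    tibble(state = seq_len(x$n_states), probability = x$initial)
  }
}

#' Forward-backward posterior state marginals
#'
#' @param model A `chromatin_hmm`.
#' @param calls Binarized-track tibble with the model's marks.
#' @return List with `gamma` (windows x K posterior matrix, rows sum to 1)
#'   and `loglik` (total log-likelihood across chromosomes).
#' @export
posterior_marginals <- function(model, calls) {
  pc <- calls_matrix(calls)
  if (!identical(pc$marks, model$marks)) abort("track marks do not match the model")
  gamma <- matrix(NA_real_, nrow(pc$X), model$n_states)
  ll <- 0
  for (i in split(seq_len(nrow(pc$X)), pc$chrom)) {
    B <- emission_lik(pc$X[i, , drop = FALSE], model$emission)
    fb <- fb_scaled(B, model$initial, model$transition)
    gamma[i, ] <- fb$gamma
    ll <- ll + fb$loglik
  }
  list(gamma = gamma, loglik = ll)
}

#' Decode a binarized track into a chromatin-state segmentation
#'
#' `"posterior"` (the default, matching ChromHMM's segmentation) assigns each
#' window the state maximizing its forward-backward marginal; `"viterbi"`
#' assigns the jointly most probable path. Chromosomes are decoded
#' independently.
#'
#' @param model A `chromatin_hmm`.
#' @param calls Binarized-track tibble.
#' @param method `"posterior"` or `"viterbi"`.
#' @return A segmentation tibble: `chrom`, `start`, `end`, `state` (1..K).
#' @export
decode_states <- function(model, calls, method = c("posterior", "viterbi")) {
  method <- match.arg(method)
  pc <- calls_matrix(calls)
  if (!identical(pc$marks, model$marks)) abort("track marks do not match the model")
  state <- integer(nrow(pc$X))
  if (method == "posterior") {
    gamma <- posterior_marginals(model, calls)$gamma
    state <- max.col(gamma, ties.method = "first")
  } else {
    lpi <- log(pmax(model$initial, 1e-300))
    lA <- log(pmax(model$transition, 1e-300))
    for (i in split(seq_len(nrow(pc$X)), pc$chrom)) {
      lB <- emission_lik(pc$X[i, , drop = FALSE], model$emission, log = TRUE)
      state[i] <- viterbi_path(lB, lpi, lA)
    }
  }
  tibble(chrom = calls$chrom, start = calls$start, end = calls$end, state = state)
}

#' Collapse a segmentation into per-state intervals
#'
#' Maximal runs of the same state become one interval; the union of all
#' state intervals tiles the windowed genome exactly once.
#'
#' @param seg Segmentation tibble (`chrom`, `start`, `end`, `state`).
#' @param state_names Optional character vector naming states 1..K; stored in
#'   a `name` column as `"<k>_<label>"`.
#' @return Interval tibble with a `state` column (and `name` if labelled).
#' @export
segmentation_to_intervals <- function(seg, state_names = NULL) {
  out <- seg %>%
    group_by(.data$chrom) %>%
    arrange(.data$start, .by_group = TRUE) %>%
    mutate(new_run = .data$state != dplyr::lag(.data$state, default = -1L) |
             .data$start != dplyr::lag(.data$end, default = -1)) %>%
    mutate(run = cumsum(.data$new_run)) %>%
    group_by(.data$chrom, .data$run) %>%
    summarise(start = min(.data$start), end = max(.data$end),
              state = first(.data$state), .groups = "drop") %>%
    select(-"run") %>%
    arrange(.data$chrom, .data$start)
  if (!is.null(state_names)) {
    out$name <- paste0(out$state, "_", state_names[out$state])
  }
  out
}

#' Per-state genomic coverage of a segmentation
#'
#' @param seg Segmentation tibble.
#' @return Tibble with `state`, `bases`, `coverage_pct` (percent of the
#'   windowed genome); percentages sum to 100.
#' @export
state_coverage <- function(seg) {
  seg %>%
    mutate(len = .data$end - .data$start) %>%
    group_by(.data$state) %>%
    summarise(bases = sum(.data$len), .groups = "drop") %>%
    mutate(coverage_pct = 100 * .data$bases / sum(.data$bases)) %>%
    arrange(.data$state)
}

#' Emission-probability heatmap for a fitted HMM
#'
#' @param object A `chromatin_hmm`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.chromatin_hmm <- function(object, ...) {
  tidy(object, "emission") %>%
    ggplot2::ggplot(ggplot2::aes(x = .data$mark, y = factor(.data$state),
                                 fill = .data$probability)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(low = "white", high = "#08519c", limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = "state", fill = "emission\nprobability") +
    ggplot2::theme_minimal()
}
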