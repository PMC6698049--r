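#' Write binarized tracks in the per-chromosome ChromHMM dialect
#'
#' One tab-separated file per chromosome named `<cell>_<chrom>_binary.txt`,
#' with a two-line header (`cell<TAB>chrom`, then the mark names) followed by
#' one 0/1 row per window.
#'
#' @param calls Binarized-track tibble (`chrom`, `start`, `end` + mark
#'   columns).
#' @param dir Output directory (created if needed).
#' @param cell Cell/condition label for the header and file names.
#' @return Character vector of file paths, invisibly.
#' @export
write_binarized_track <- function(calls, dir, cell = "cell") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  marks <- mark_columns(calls)
  paths <- purrr::map_chr(split(calls, calls$chrom), function(x) {
    chrom <- x$chrom[1]
    path <- file.path(dir, sprintf("%s_%s_binary.txt", cell, chrom))
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c(paste(cell, chrom, sep = "\t"), paste(marks, collapse = "\t")), con)
    utils::write.table(arrange(x, .data$start)[marks], con, sep = "\t",
                       row.names = FALSE, col.names = FALSE, quote = FALSE)
    path
  })
  invisible(unname(paths))
}

#' Read per-chromosome binarized tracks (ChromHMM dialect)
#'
#' @param paths Files written by [write_binarized_track()].
#' @param window_size Window width used when the tracks were built.
#' @param genome Optional genome table, used to truncate each chromosome's
#'   last window to the chromosome length.
#' @return Binarized-track tibble (`chrom`, `start`, `end` + mark columns).
#' @export
read_binarized_track <- function(paths, window_size = 200, genome = NULL) {
  out <- purrr::map_dfr(paths, function(path) {
    hdr <- readr::read_lines(path, n_max = 2, progress = FALSE)
    chrom <- strsplit(hdr[1], "\t", fixed = TRUE)[[1]][2]
    marks <- strsplit(hdr[2], "\t", fixed = TRUE)[[1]]
    x <- readr::read_tsv(path, skip = 2, col_names = marks,
                         col_types = readr::cols(.default = "i"), progress = FALSE)
    n <- nrow(x)
    start <- (seq_len(n) - 1) * window_size
    end <- start + window_size
    if (!is.null(genome)) {
      g <- as_genome_tbl(genome)
      sz <- setNames(g$size, g$chrom)
      if (chrom %in% names(sz)) end <- pmin(end, sz[chrom])
    }
    bind_cols(tibble(chrom = chrom, start = start, end = end), x)
  })
  arrange(out, .data$chrom, .data$start)
}

#' Write a fitted HMM as plain-text matrices with a JSON sidecar
#'
#' Writes `<prefix>_emission.tsv`, `<prefix>_transition.tsv`,
#' `<prefix>_initial.tsv` and `<prefix>_model.json` (state count, marks, fit
#' metadata).
#'
#' @param model A `chromatin_hmm`.
#' @param prefix Output path prefix.
#' @return `prefix`, invisibly.
#' @export
write_hmm_model <- function(model, prefix) {
  em <- as.data.frame(model$emission)
  names(em) <- model$marks
  utils::write.table(cbind(state = seq_len(model$n_states), em),
                     paste0(prefix, "_emission.tsv"), sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(model$transition, paste0(prefix, "_transition.tsv"),
                     sep = "\t", row.names = FALSE, col.names = FALSE, quote = FALSE)
  utils::write.table(data.frame(initial = model$initial), paste0(prefix, "_initial.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  jsonlite::write_json(
    list(n_states = model$n_states, marks = model$marks, loglik = model$loglik,
         n_iter = model$n_iter, converged = model$converged),
    paste0(prefix, "_model.json"), auto_unbox = TRUE, digits = NA
  )
  invisible(prefix)
}

#' Read a fitted HMM written by [write_hmm_model()]
#'
#' @param prefix Path prefix used when writing.
#' @return A `chromatin_hmm`.
#' @export
read_hmm_model <- function(prefix) {
  meta <- jsonlite::read_json(paste0(prefix, "_model.json"), simplifyVector = TRUE)
  em <- utils::read.table(paste0(prefix, "_emission.tsv"), sep = "\t", header = TRUE,
                          check.names = FALSE)
  A <- as.matrix(utils::read.table(paste0(prefix, "_transition.tsv"), sep = "\t"))
  dimnames(A) <- NULL
  init <- utils::read.table(paste0(prefix, "_initial.tsv"), sep = "\t", header = TRUE)$initial
  m <- chromatin_hmm(init, A, as.matrix(em[meta$marks]), marks = meta$marks)
  m$loglik <- meta$loglik; m$n_iter <- meta$n_iter; m$converged <- meta$converged
  m
}

#' Write a segmentation as BED4
#'
#' @param seg Segmentation tibble.
#' @param path Output path.
#' @param state_names Optional labels for states 1..K (name column becomes
#'   `"<k>_<label>"`, else `"<k>"`).
#' @return `path`, invisibly.
#' @export
write_segmentation_bed <- function(seg, path, state_names = NULL) {
  iv <- segmentation_to_intervals(seg, state_names = state_names)
  if (is.null(state_names)) iv$name <- as.character(iv$state)
  write_bed(iv[c("chrom", "start", "end", "name")], path)
}

# TSV with a provenance header (version, seed, config hash); deterministic,
# so identical runs produce byte-identical files.
write_result_tsv <- function(x, path, seed, config_hash) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# chromdyn %s", as.character(utils::packageVersion("chromdyn"))),
    sprintf("# seed: %d", as.integer(seed)),
    sprintf("# config: %s", config_hash)
  ), con)
  utils::write.table(as.data.frame(x), con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
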