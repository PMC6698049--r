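test_that("read_bed parses, validates and round-trips BED records", {
  g <- genome_tbl(c(chr1 = 1000))
  path <- withr::local_tempfile(fileext = ".bed")

  writeLines("chr1\t0\t200", path)
  iv <- read_bed(path, g)
  expect_equal(nrow(iv), 1)
  expect_equal(iv$end - iv$start, 200)

  writeLines("chr1\t200\t100", path)
  expect_error(read_bed(path, g), "line 1")

  writeLines(c("chr1\t0\t200", "chr2\t0\t100"), path)
  expect_error(read_bed(path, g), "chr2")

  # BED6 strand preserved and coordinates round-trip bit-exactly
  writeLines(c("chr1\t0\t200\tpk1\t5\t+", "chr1\t300\t450\tpk2\t7\t-"), path)
  iv <- read_bed(path, g)
  expect_equal(iv$strand, c("+", "-"))
  out <- withr::local_tempfile(fileext = ".bed")
  write_bed(iv, out)
  expect_identical(read_bed(out, g)[c("chrom", "start", "end", "strand")],
                   iv[c("chrom", "start", "end", "strand")])
})

test_that("overlap_bases matches a per-base oracle and is symmetric", {
  g <- genome_tbl(c(chr1 = 1000))
  a <- interval_tbl(data.frame(chrom = "chr1", start = 0, end = 100), g)
  b <- interval_tbl(data.frame(chrom = "chr1", start = 50, end = 150), g)
  expect_equal(overlap_bases(a, b), 50)
  expect_equal(overlap_bases(a, a), 100)

  set.seed(42)
  g10 <- toy_genome(10000)
  for (rep in 1:5) {
    x <- random_intervals(20, g10)
    y <- random_intervals(20, g10)
    oracle <- sum(base_cover(x, "chr1", 10000) & base_cover(y, "chr1", 10000))
    expect_equal(overlap_bases(x, y), oracle)
    expect_equal(overlap_bases(x, y), overlap_bases(y, x))
    expect_equal(overlap_bases(x, x), sum(base_cover(x, "chr1", 10000)))
  }

  # disjoint sets share nothing
  d1 <- interval_tbl(data.frame(chrom = "chr1", start = 0, end = 100), g)
  d2 <- interval_tbl(data.frame(chrom = "chr1", start = 100, end = 200), g)
  expect_equal(overlap_bases(d1, d2), 0)
  expect_equal(peak_set_correlation(d1, d2), 0)
})

test_that("peak_set_correlation matches an all-pairs scan and is asymmetric", {
  g <- genome_tbl(c(chr1 = 1000))
  a <- interval_tbl(data.frame(chrom = "chr1",
                               start = c(0, 100, 300, 500),
                               end = c(50, 150, 350, 550)), g)
  b <- interval_tbl(data.frame(chrom = "chr1", start = c(40, 520), end = c(60, 560)), g)
  expect_equal(peak_set_correlation(a, b), 0.5)

  inside <- interval_tbl(data.frame(chrom = "chr1", start = c(10, 110), end = c(20, 120)), g)
  outer_set <- interval_tbl(data.frame(chrom = "chr1", start = 0, end = 200), g)
  expect_equal(peak_set_correlation(inside, outer_set), 1.0)
  expect_error(peak_set_correlation(outer_set[0, ], inside), "empty")

  set.seed(7)
  g10 <- toy_genome(10000)
  for (rep in 1:3) {
    x <- random_intervals(50, g10, max_len = 300)
    y <- random_intervals(50, g10, max_len = 300)
    # O(n^2) oracle: a peak counts if any y interval intersects it
    hit <- vapply(seq_len(nrow(x)), function(i) {
      any(pmax(x$start[i], y$start) < pmin(x$end[i], y$end))
    }, logical(1))
    expect_equal(peak_set_correlation(x, y), mean(hit))
    # invariant to splitting y intervals (of length >= 2) at internal points
    long <- y$end - y$start >= 2
    mid <- floor((y$start[long] + y$end[long]) / 2)
    y_split <- interval_tbl(
      tibble::tibble(chrom = c(y$chrom[!long], rep(y$chrom[long], 2)),
                     start = c(y$start[!long], y$start[long], mid),
                     end = c(y$end[!long], mid, y$end[long])),
      g10
    )
    expect_equal(peak_set_correlation(x, y_split), mean(hit))
  }
})

test_that("genome coverage percentage uses merged coverage", {
  g <- genome_tbl(c(chr1 = 10000))
  a <- interval_tbl(data.frame(chrom = "chr1", start = 0, end = 100), g)
  expect_equal(genome_coverage_pct(a), 1.0)
  whole <- interval_tbl(data.frame(chrom = "chr1", start = 0, end = 10000), g)
  expect_equal(genome_coverage_pct(whole), 100.0)
  g1k <- genome_tbl(c(chr1 = 1000))
  ov <- interval_tbl(data.frame(chrom = "chr1", start = c(0, 50), end = c(100, 150)), g1k)
  expect_equal(genome_coverage_pct(ov), 15.0)
})

test_that("nearest gene distance is 0 on overlap and matches brute force", {
  g <- genome_tbl(c(chr1 = 50000))
  genes <- gene_tbl(data.frame(gene_id = c("g1", "g2"), chrom = "chr1",
                               start = c(100, 20000), end = c(900, 25000),
                               strand = c("+", "-")))
  peaks <- interval_tbl(data.frame(chrom = "chr1",
                                   start = c(200, 1000), end = c(300, 1100)), g)
  d <- nearest_gene_distance(peaks, genes)
  expect_equal(d$distance, c(0, 100))

  set.seed(11)
  peaks <- random_intervals(30, g, max_len = 400)
  genes5 <- gene_tbl(data.frame(
    gene_id = paste0("g", 1:5), chrom = "chr1",
    start = c(1000, 9000, 18000, 30000, 42000),
    end = c(3000, 12000, 20000, 33000, 45000), strand = "+"
  ))
  d <- nearest_gene_distance(peaks, genes5)$distance
  oracle <- vapply(seq_len(nrow(peaks)), function(i) {
    gaps <- pmax(genes5$start - peaks$end[i], peaks$start[i] - genes5$end, 0)
    min(gaps)
  }, numeric(1))
  expect_equal(d, oracle)

  # peak on a chromosome with no genes -> NA with a warning
  g2 <- genome_tbl(c(chr1 = 50000, chr2 = 50000))
  lonely <- interval_tbl(data.frame(chrom = "chr2", start = 10, end = 20), g2)
  expect_warning(d2 <- nearest_gene_distance(lonely, genes5), "no genes")
  expect_true(is.na(d2$distance))
})

test_that("gene tables accept tss/tes input and reject bad strand orientation", {
  ge <- gene_tbl(data.frame(gene_id = "g1", chrom = "chr1",
                            tss = 500, tes = 100, strand = "-"))
  expect_equal(ge$start, 100)
  expect_equal(ge$end, 501)
  expect_equal(ge$tss, 500)
  expect_error(
    gene_tbl(data.frame(gene_id = "g1", chrom = "chr1", tss = 100, tes = 500, strand = "-")),
    "orientation"
  )
})

test_that("GFF3 gene reading converts to 0-based half-open coordinates", {
  path <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "chr1\tsrc\tgene\t101\t500\t.\t+\t.\tID=geneA",
    "chr1\tsrc\texon\t101\t200\t.\t+\t.\tParent=geneA",
    "chr1\tsrc\tgene\t1001\t2000\t.\t-\t.\tID=geneB"
  ), path)
  genes <- read_gff_genes(path)
  expect_equal(genes$gene_id, c("geneA", "geneB"))
  expect_equal(genes$start, c(100, 1000))
  expect_equal(genes$end, c(500, 2000))
  expect_equal(genes$tss, c(100, 1999))
})
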