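make_genome <- function(...) {
  seqs <- c(...)
  setNames(vapply(seqs, function(L) {
    paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
  }, character(1)), names(seqs))
}

test_that("noncoding extraction complements gene spans and exon unions", {
  set.seed(1)
  genome <- make_genome(s1 = 1000L)
  genes <- data.frame(gene_id = "g1", scaffold = "s1", start = 200L,
                      end = 500L, strand = "+")
  exons <- data.frame(gene_id = "g1", scaffold = "s1",
                      start = c(200L, 400L), end = c(300L, 500L))
  nc <- extract_noncoding(genome, genes, exons)
  ig <- nc[nc$kind == "intergenic", ]
  expect_equal(ig$start, c(0L, 500L))
  expect_equal(ig$end, c(200L, 1000L))
  intr <- nc[nc$kind == "intronic", ]
  expect_equal(intr$start, 300L)
  expect_equal(intr$end, 400L)
  expect_equal(intr$source_gene, "g1")
})

test_that("a scaffold without genes is one intergenic region", {
  set.seed(2)
  genome <- make_genome(s1 = 640L)
  nc <- extract_noncoding(genome,
                          data.frame(gene_id = character(),
                                     scaffold = character(),
                                     start = integer(), end = integer(),
                                     strand = character()))
  expect_equal(nrow(nc), 1L)
  expect_equal(c(nc$start, nc$end), c(0L, 640L))
})

test_that("overlapping genes: intergenic is the complement of the union", {
  set.seed(3)
  L <- 800L
  genome <- make_genome(s1 = L)
  genes <- data.frame(gene_id = c("g1", "g2"), scaffold = "s1",
                      start = c(100L, 250L), end = c(300L, 600L),
                      strand = "+")
  nc <- extract_noncoding(genome, genes)
  ig <- nc[nc$kind == "intergenic", ]
  # brute-force per-base labelling
  genic <- rep(FALSE, L)
  for (r in seq_len(nrow(genes))) {
    genic[(genes$start[r] + 1):genes$end[r]] <- TRUE
  }
  lab <- rep(FALSE, L)
  for (r in seq_len(nrow(ig))) lab[(ig$start[r] + 1):ig$end[r]] <- TRUE
  expect_identical(lab, !genic)
})

test_that("gene validation fails loudly", {
  set.seed(4)
  genome <- make_genome(s1 = 500L)
  expect_error(extract_noncoding(
    genome, data.frame(gene_id = "gx", scaffold = "nope", start = 0L,
                       end = 10L, strand = "+")), "unknown scaffold.*gx")
  expect_error(extract_noncoding(
    genome, data.frame(gene_id = "gy", scaffold = "s1", start = 400L,
                       end = 600L, strand = "+")), "outside scaffold")
  genes <- data.frame(gene_id = "g1", scaffold = "s1", start = 100L,
                      end = 200L, strand = "+")
  exons <- data.frame(gene_id = "g1", scaffold = "s1", start = 150L,
                      end = 250L)
  expect_error(extract_noncoding(genome, genes, exons), "exon outside")
})

test_that("fragmentation follows the 120/20 windowing with backward last window", {
  set.seed(5)
  genome <- make_genome(s1 = 2200L)
  cfg <- window_config()
  frag_starts <- function(L) {
    region <- data.frame(scaffold = "s1", start = 0L, end = L,
                         kind = "intergenic")
    fragment_region(region, genome, cfg)$start
  }
  expect_equal(frag_starts(120L), 0L)
  expect_equal(frag_starts(250L), c(0L, 100L, 130L))
  # backward window coinciding with an existing start is emitted once
  expect_equal(frag_starts(220L), c(0L, 100L))
  # fragment sequences equal the genome slices
  region <- data.frame(scaffold = "s1", start = 37L, end = 417L,
                       kind = "intergenic")
  fr <- fragment_region(region, genome, cfg)
  expect_true(all(nchar(fr$sequence) == 120L))
  expect_identical(fr$sequence[2],
                   substring(genome[["s1"]], fr$start[2] + 1, fr$end[2]))
})

test_that("windowing count law and full coverage hold for all lengths 120-2000", {
  cfg <- window_config()
  for (L in 120:2000) {
    starts <- premirscan:::window_starts(L, cfg)
    n_expected <- if (L == cfg$window_length) 1L else
      1L + as.integer(ceiling((L - cfg$window_length) / cfg$step))
    expect_identical(length(starts), as.integer(n_expected))
    # per-base coverage by difference marking (independent of the formula)
    cov <- integer(L)
    for (s in starts) cov[(s + 1):(s + cfg$window_length)] <-
        cov[(s + 1):(s + cfg$window_length)] + 1L
    if (any(cov == 0L)) fail(sprintf("uncovered base at L=%d", L))
  }
  succeed()
})

test_that("short regions are skipped with a message; N-rich fragments dropped", {
  set.seed(6)
  genome <- make_genome(s1 = 400L)
  region <- data.frame(scaffold = "s1", start = 0L, end = 80L,
                       kind = "intergenic")
  expect_message(fr <- fragment_region(region, genome, window_config()),
                 "skipping region")
  expect_equal(nrow(fr), 0L)
  # a window_config with a lowered floor emits the whole region unpadded
  cfg2 <- window_config(min_region_length = 50L)
  fr2 <- suppressMessages(fragment_region(region, genome, cfg2))
  expect_equal(nrow(fr2), 1L)
  expect_equal(fr2$end - fr2$start, 80L)
  # N handling
  genomeN <- c(s1 = paste0(strrep("N", 60),
                           substring(genome[["s1"]], 61, 400)))
  regionN <- data.frame(scaffold = "s1", start = 0L, end = 240L,
                        kind = "intergenic")
  expect_message(frN <- fragment_region(regionN, genomeN, window_config()),
                 "dropped")
  expect_true(all(frN$start >= 60 - 12))  # >10% N windows removed
})
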