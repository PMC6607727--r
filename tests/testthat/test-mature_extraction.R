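test_that("find_stems recovers designed stem geometry", {
  set.seed(91)
  arm <- paste(sample(c("A", "C", "G", "T"), 18, TRUE), collapse = "")
  f <- fold_rna(make_hairpin(arm, loop = "AAAAA"))
  st <- find_stems(f)
  expect_length(st, 1)
  expect_equal(nrow(st[[1]]$pairs), 18)
  expect_equal(st[[1]]$arm5, c(0L, 18L))
  expect_equal(st[[1]]$loop, c(18L, 23L))
  expect_equal(st[[1]]$arm3, c(23L, 41L))
  # unpaired sequence: no stems
  expect_length(find_stems(fold_rna(strrep("A", 30))), 0)
})

test_that("two tandem hairpins give two stems with disjoint arms", {
  set.seed(92)
  a1 <- "GCGCGGCCGGCG"; a2 <- "CGGCGCCGCGGC"
  seq2 <- paste0(make_hairpin(a1, "AAAA"), strrep("A", 15),
                 make_hairpin(a2, "AAAA"))
  st <- find_stems(fold_rna(seq2))
  expect_length(st, 2)
  expect_lt(st[[1]]$arm3[2], st[[2]]$arm5[1] + 1)
})

test_that("extract_duplex matches hand-built stems and criteria boundaries", {
  # perfect 18-pair stem: full duplex, 0 mismatches, 0 bulges
  s <- make_stem(18)
  d <- extract_duplex(s, stem_cover_seq(s))
  expect_equal(d$n_pairs, 18)
  expect_equal(d$mismatch_total, 0L)
  expect_equal(nrow(d$bulges), 0L)
  expect_equal(d$arm5_interval, s$arm5)
  expect_equal(d$arm3_interval, s$arm3)
  # 20-pair stem with one 3-vs-0 bulge in the middle: no window long
  # enough satisfies the asymmetry rule
  s2 <- make_stem(20, gaps5 = c(rep(0L, 9), 3L, rep(0L, 9)))
  expect_null(extract_duplex(s2, stem_cover_seq(s2)))
  # 22-pair stem with 4 scattered symmetric mismatches: boundary accept
  g5 <- integer(21); g3 <- integer(21)
  at <- c(4L, 9L, 14L, 18L)
  g5[at] <- 1L; g3[at] <- 1L
  s3 <- make_stem(22, g5, g3)
  d3 <- extract_duplex(s3, stem_cover_seq(s3))
  expect_equal(d3$n_pairs, 22)
  expect_equal(d3$mismatch_total, 4L)
  # 5 mismatches: the full window is rejected, a sub-window wins
  g5b <- g5; g3b <- g3; g5b[11] <- 1L; g3b[11] <- 1L
  s4 <- make_stem(22, g5b, g3b)
  d4 <- extract_duplex(s4, stem_cover_seq(s4))
  expect_true(is.null(d4) || d4$mismatch_total <= 4L)
  expect_identical(extract_duplex(s4, stem_cover_seq(s4))$n_pairs,
                   oracle_duplex(s4)$n_pairs)
})

test_that("extract_duplex agrees with the exhaustive window oracle", {
  set.seed(93)
  for (i in 1:150) {
    st <- random_stem(30L)
    got <- extract_duplex(st, stem_cover_seq(st))
    want <- oracle_duplex(st)
    if (is.null(want)) {
      expect_null(got)
    } else {
      expect_equal(got$arm5_interval, want$arm5_interval)
      expect_equal(got$arm3_interval, want$arm3_interval)
      expect_equal(got$mismatch_total, want$mismatch_total)
    }
  }
})

test_that("returned duplexes always satisfy the criteria re-checked post hoc", {
  set.seed(94)
  crit <- duplex_criteria()
  for (i in 1:100) {
    st <- random_stem(35L)
    d <- extract_duplex(st, stem_cover_seq(st), crit)
    if (is.null(d)) next
    expect_gte(d$arm5_interval[2] - d$arm5_interval[1],
               crit$min_strand_length)
    expect_gte(d$arm3_interval[2] - d$arm3_interval[1],
               crit$min_strand_length)
    expect_lte(d$mismatch_total, crit$max_mismatch)
    if (nrow(d$bulges)) {
      expect_true(all(abs(d$bulges$size5 - d$bulges$size3) <=
                        crit$max_asym_bulge))
    }
  }
})

test_that("end extension recovers straddling hairpins and clamps at bounds", {
  set.seed(95)
  hp <- plant_hairpin(simulation_config(seed = 95, arm_length = c(18L, 18L),
                                        mismatches = c(0L, 0L),
                                        bulge_events = c(0L, 0L)))
  # assembly-gap flanks (N never pairs): the truncated locus can only fold
  # the partial stem, so the success extension is fully determined
  bg <- function(n) strrep("N", n)
  # place the hairpin so its stem pokes 8 nt beyond the locus end
  left <- 150L
  genome <- c(s1 = paste0(bg(left), hp$sequence, bg(160L)))
  hp_start <- left
  stem_g <- hp_start + hp$record$stem_interval
  locus <- data.frame(locus_id = "L1", scaffold = "s1",
                      start = stem_g[1] - 30L, end = stem_g[2] - 8L)
  res <- extract_locus_duplex(locus, genome)
  expect_false(is.null(res))
  expect_equal(res$extension, 10L)
  expect_equal(res$interval[1] + res$duplex$arm5_interval,
               hp_start + hp$record$arm5_interval)
  # locus at scaffold start: extension clamps without failure
  genome2 <- c(s1 = paste0(hp$sequence, bg(150L)))
  locus2 <- data.frame(locus_id = "L2", scaffold = "s1", start = 0L,
                       end = nchar(hp$sequence) - 6L)
  res2 <- extract_locus_duplex(locus2, genome2)
  expect_false(is.null(res2))
  expect_gte(res2$interval[1], 0L)
  # no hairpin anywhere within +-20: none
  genome3 <- c(s1 = strrep("A", 400))
  locus3 <- data.frame(locus_id = "L3", scaffold = "s1", start = 100L,
                       end = 220L)
  expect_null(extract_locus_duplex(locus3, genome3))
})

test_that("mature enumeration yields two deterministic arm products", {
  set.seed(96)
  hp <- plant_hairpin(simulation_config(seed = 96))
  st <- find_stems(fold_rna(hp$sequence))
  d <- NULL
  for (s in st) {
    cand <- extract_duplex(s, hp$sequence)
    if (!is.null(cand) && (is.null(d) || cand$n_pairs > d$n_pairs)) d <- cand
  }
  m <- enumerate_matures(d, "locusX", locus_start = 1000L)
  expect_equal(nrow(m), 2L)
  expect_equal(m$arm, c("5p", "3p"))
  expect_true(all(nchar(m$sequence) > 15))
  expect_equal(m$sequence[1], d$arm5_seq)
  expect_equal(m$sequence[2], revcomp(d$arm3_seq))
  expect_equal(m$start[1], 1000L + d$arm5_interval[1])
  # forward-strand 3p reading behind the flag
  m2 <- enumerate_matures(d, "locusX", threep_revcomp = FALSE)
  expect_equal(m2$sequence[2], d$arm3_seq)
  # determinism of ids
  expect_identical(enumerate_matures(d, "locusX")$mature_id,
                   c("locusX-5p", "locusX-3p"))
})
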