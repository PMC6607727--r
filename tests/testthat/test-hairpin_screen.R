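test_that("a designed perfect hairpin fragment passes at the strictest cut-off", {
  set.seed(81)
  arm <- paste(sample(c("A", "C", "G", "T"), 40, TRUE), collapse = "")
  hp <- make_hairpin(arm, loop = "AACAAA")
  pad <- strrep("A", (120 - nchar(hp)) %/% 2)
  frag <- substr(paste0(pad, hp, pad, "AAAA"), 1, 120)
  r <- screen_fragment(frag)
  expect_equal(r$score, 1)
  expect_true(r$passed)
  expect_gte(r$features$longest_stem_pairs, 40)
})

test_that("a poly-A fragment fails with zero pairing", {
  r <- screen_fragment(strrep("A", 120))
  expect_equal(r$features$paired_fraction, 0)
  expect_lt(r$score, 1)
  expect_false(r$passed)
})

test_that("dinucleotide-shuffled hairpins fail more often than they pass", {
  set.seed(82)
  hp <- plant_hairpin(simulation_config(seed = 82))
  pad_n <- 120 - nchar(hp$sequence)
  frag <- paste0(hp$sequence,
                 paste(sample(c("A", "C", "G", "T"), pad_n, TRUE),
                       collapse = ""))
  expect_true(screen_fragment(frag)$passed)
  passes <- 0L
  for (i in 1:100) {
    shuf <- dinucleotide_shuffle(frag)
    if (screen_fragment(shuf)$passed) passes <- passes + 1L
  }
  expect_lt(passes, 50L)
})

test_that("structural-RNA exclusion follows the seeded 90%/60nt rule", {
  set.seed(83)
  trna <- paste(sample(c("A", "C", "G", "T"), 75, TRUE), collapse = "")
  frag_tbl <- function(seqs) data.frame(
    fragment_id = paste0("f", seq_along(seqs)), scaffold = "s",
    start = 0L, end = nchar(seqs), kind = "intergenic", sequence = seqs,
    stringsAsFactors = FALSE)
  # verbatim 70-nt slice -> excluded
  emb <- paste0(paste(sample(c("A", "C", "G", "T"), 30, TRUE), collapse = ""),
                substring(trna, 1, 70),
                paste(sample(c("A", "C", "G", "T"), 20, TRUE), collapse = ""))
  res <- filter_structural_rna(frag_tbl(emb), trna)
  expect_equal(nrow(res$excluded), 1L)
  expect_equal(nrow(res$retained), 0L)
  # disjoint alphabets share no 16-mer -> retained
  frA <- paste(sample(c("A", "C"), 120, TRUE), collapse = "")
  refGT <- paste(sample(c("G", "T"), 80, TRUE), collapse = "")
  res2 <- filter_structural_rna(frag_tbl(frA), refGT)
  expect_equal(nrow(res2$excluded), 0L)
  # 65-nt slice with 5 substitutions (92.3% identity) -> excluded
  slice <- strsplit(substring(trna, 1, 65), "")[[1]]
  subs_at <- c(50, 54, 58, 61, 64)  # leaves an intact 16-mer seed up front
  for (p in subs_at) slice[p] <- setdiff(c("A", "C", "G", "T"), slice[p])[1]
  emb3 <- paste0(strrep("A", 25), paste(slice, collapse = ""), strrep("A", 30))
  res3 <- filter_structural_rna(frag_tbl(emb3), trna)
  expect_equal(nrow(res3$excluded), 1L)
  # empty reference fails loudly
  expect_error(filter_structural_rna(frag_tbl(frA), character()), "empty")
})

test_that("locus merging is transitive, strict on touching, ordered", {
  fr <- function(starts, ends, sc = "s1") data.frame(
    fragment_id = sprintf("%s:%d-%d", sc, starts, ends), scaffold = sc,
    start = starts, end = ends, kind = "intergenic",
    stringsAsFactors = FALSE)
  m1 <- merge_predicted_loci(fr(c(0L, 100L), c(120L, 220L)))
  expect_equal(nrow(m1), 1L)
  expect_equal(c(m1$start, m1$end), c(0L, 220L))
  # half-open touch is not overlap
  m2 <- merge_predicted_loci(fr(c(0L, 120L), c(120L, 240L)))
  expect_equal(nrow(m2), 2L)
  # transitive closure
  m3 <- merge_predicted_loci(fr(c(0L, 100L, 130L, 400L),
                                c(120L, 220L, 250L, 520L)))
  expect_equal(m3$start, c(0L, 400L))
  expect_equal(m3$end, c(250L, 520L))
  expect_equal(m3$n_fragments, c(3L, 1L))
})

test_that("merging is idempotent and order-independent", {
  set.seed(84)
  starts <- sample(0:2000, 40) %/% 10 * 10
  df <- data.frame(fragment_id = paste0("f", seq_along(starts)),
                   scaffold = sample(c("s1", "s2"), 40, TRUE),
                   start = starts, end = starts + 120L,
                   kind = "intergenic", stringsAsFactors = FALSE)
  m <- merge_predicted_loci(df)
  # idempotence: merging the merged loci (as pseudo-fragments) is a no-op
  again <- m
  again$fragment_id <- again$locus_id
  m2 <- merge_predicted_loci(again)
  expect_equal(m2[, c("scaffold", "start", "end")],
               m[, c("scaffold", "start", "end")])
  # order independence
  for (i in 1:5) {
    perm <- df[sample(nrow(df)), ]
    mp <- merge_predicted_loci(perm)
    expect_equal(mp[, c("scaffold", "start", "end", "n_fragments")],
                 m[, c("scaffold", "start", "end", "n_fragments")])
  }
})

test_that("externally supplied screening scores drive the pass decision", {
  df <- data.frame(fragment_id = c("a", "b"), sequence = c("x", "y"),
                   stringsAsFactors = FALSE)
  sc <- data.frame(fragment_id = c("b", "a"), score = c(1, 0.5))
  out <- screen_fragments_external(df, sc)
  expect_identical(out$passed, c(FALSE, TRUE))
  expect_error(screen_fragments_external(
    data.frame(fragment_id = "z", sequence = "q"), sc), "missing")
})
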