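antisense_site <- function(mature) revcomp(mature)

test_that("site scoring: perfect, wobble and seed arithmetic", {
  set.seed(121)
  mature <- "TGGAGCTCCCTTCATTCCAAT"  # 21 nt
  tx <- paste0("AAAAA", antisense_site(mature), "CCCCC")
  hits <- score_target_site(mature, tx)
  expect_equal(hits$score[1], 0)
  expect_equal(hits$site_start[1], 5L)
  # one G:U at mature position 5 (inside the 2-13 seed): 0.5 * 2 = 1.0
  site <- strsplit(antisense_site(mature), "")[[1]]
  # mature position 5 faces site position L + 1 - 5
  p <- length(site) + 1 - 5
  expect_equal(substr(mature, 5, 5), "G")
  site[p] <- "T"  # G:C becomes G:U
  tx_gu <- paste0("AAAAA", paste(site, collapse = ""), "CCCCC")
  expect_equal(score_target_site(mature, tx_gu)$score[1], 1.0)
  # three seed mismatches score 6.0: above both preset cutoffs
  site3 <- strsplit(antisense_site(mature), "")[[1]]
  for (mp in c(3, 7, 11)) {
    q <- length(site3) + 1 - mp
    m_base <- substr(mature, mp, mp)
    bad <- setdiff(c("A", "C", "G", "T"),
                   c(chartr("ACGT", "TGCA", m_base),
                     if (m_base == "G") "T", if (m_base == "T") "G"))
    site3[q] <- bad[1]
  }
  tx3 <- paste0("AAAAA", paste(site3, collapse = ""), "CCCCC")
  expect_equal(nrow(score_target_site(mature, tx3,
                                      target_scheme(cutoff = 4))), 0L)
})

test_that("consensus keeps only pairs passing both presets", {
  set.seed(122)
  m <- "GCATCGATCGGATTCACGGCT"
  tx_perfect <- paste0("TT", antisense_site(m), "AA")
  # a site with one seed mismatch (score 2.0): passes 3.0 and 4.0
  s1 <- strsplit(antisense_site(m), "")[[1]]
  q <- length(s1) + 1 - 6
  s1[q] <- setdiff(c("A", "C", "G", "T"),
                   c(chartr("ACGT", "TGCA", substr(m, 6, 6)),
                     if (substr(m, 6, 6) == "G") "T",
                     if (substr(m, 6, 6) == "T") "G"))[1]
  # a site with a 3.5-ish score: one seed mismatch (2.0) + two non-seed
  # mismatches (1.0 each) = 4.0 -> passes preset B only at cutoff 4
  s2 <- s1
  for (mp in c(15, 18)) {
    q2 <- length(s2) + 1 - mp
    s2[q2] <- setdiff(c("A", "C", "G", "T"),
                      c(chartr("ACGT", "TGCA", substr(m, mp, mp)),
                        if (substr(m, mp, mp) == "G") "T",
                        if (substr(m, mp, mp) == "T") "G"))[1]
  }
  mats <- data.frame(mature_id = "m1", sequence = m, stringsAsFactors = FALSE)
  txs <- c(t1 = tx_perfect, t2 = paste0("TT", paste(s1, collapse = ""), "AA"),
           t3 = paste0("TT", paste(s2, collapse = ""), "AA"))
  cons <- consensus_targets(mats, txs)
  expect_setequal(cons$transcript_id, c("t1", "t2"))
  expect_true(all(cons$consensus))
  # empty transcript set
  expect_equal(nrow(consensus_targets(mats, character())), 0L)
  # lowering a cutoff never adds consensus interactions
  consA <- consensus_targets(mats, txs, target_scheme(cutoff = 2),
                             target_scheme(cutoff = 4))
  expect_true(all(paste(consA$mature_id, consA$transcript_id) %in%
                    paste(cons$mature_id, cons$transcript_id)))
})

test_that("binding groups take the outer deciles with lexical tie-breaks", {
  inter <- do.call(rbind, lapply(1:100, function(i) data.frame(
    mature_id = paste0("mir", seq_len(i)),
    transcript_id = sprintf("t%03d", i), stringsAsFactors = FALSE)))
  bg <- classify_binding_groups(inter)
  expect_equal(sum(bg$group == "LMBG"), 10L)
  expect_equal(sum(bg$group == "HMBG"), 10L)
  expect_setequal(bg$transcript_id[bg$group == "LMBG"], sprintf("t%03d", 1:10))
  expect_setequal(bg$transcript_id[bg$group == "HMBG"],
                  sprintf("t%03d", 91:100))
  expect_lte(max(bg$binding_mirna_count[bg$group == "LMBG"]),
             min(bg$binding_mirna_count[bg$group == "HMBG"]))
  # all counts equal: deciles filled lexically, deterministic
  flat <- data.frame(mature_id = "m1",
                     transcript_id = sprintf("x%02d", 1:20))
  bf <- classify_binding_groups(flat)
  expect_equal(bf$transcript_id[bf$group == "LMBG"], c("x01", "x02"))
  expect_equal(bf$transcript_id[bf$group == "HMBG"], c("x19", "x20"))
  # seeded subsample is reproducible
  b1 <- classify_binding_groups(inter, subsample_fraction = 0.5, seed = 9L)
  b2 <- classify_binding_groups(inter, subsample_fraction = 0.5, seed = 9L)
  expect_identical(b1$sampled, b2$sampled)
  expect_error(classify_binding_groups(flat[1:5, ]), "at least 10")
})

test_that("enrichment matches exact tail arithmetic and shares the kernel", {
  background <- sprintf("g%02d", 1:20)
  term_map <- data.frame(gene_id = background[1:5], term_id = "T1")
  gene_set <- c(background[1:3], background[6:7])
  e <- hypergeom_enrichment(gene_set, term_map, background)
  expect_equal(e$p_value, 1126 / 15504, tolerance = 1e-12)
  expect_equal(e$p_value,
               overlap_significance(20, 5, 5, 3)$p_tail, tolerance = 1e-15)
  # set = all term members, term = background -> p = 1
  tm_all <- data.frame(gene_id = background, term_id = "Tall")
  e2 <- hypergeom_enrichment(background[1:4], tm_all, background)
  expect_equal(e2$p_value, 1)
  # zero overlap with a tiny term: p close to 1, never above
  tm3 <- data.frame(gene_id = background[19:20], term_id = "T3")
  e3 <- hypergeom_enrichment(background[1:5], tm3, background)
  expect_lte(e3$p_value, 1)
  expect_gt(e3$p_value, 0.4)
  # BH column appears on request
  e4 <- hypergeom_enrichment(gene_set, rbind(term_map, tm3), background,
                             adjust = "BH")
  expect_true("p_adjust" %in% names(e4))
  expect_error(hypergeom_enrichment(c("nope"), term_map, background),
               "subset")
})

test_that("degree classes close the published gaps at 15 and 81", {
  mk <- function(id, n) data.frame(mature_id = id,
                                   transcript_id = paste0(id, "_t", seq_len(n)))
  inter <- rbind(mk("a", 15), mk("b", 16), mk("c", 30), mk("d", 31),
                 mk("e", 80), mk("f", 81), mk("g", 200), mk("h", 3))
  cls <- degree_class_summary(inter)$classes
  expect_equal(cls$n_matures, c(2L, 2L, 2L, 2L))
  expect_equal(cls$mean_targets, c((15 + 3) / 2, 23, 55.5, 140.5))
})

test_that("co-regulation counts are plain set intersections", {
  inter <- data.frame(
    mature_id = c(rep("m1", 10), rep("m2", 9)),
    transcript_id = c(paste0("t", 1:10), paste0("t", 4:12)))
  out <- degree_class_summary(inter)
  sh <- out$shared[["1-15"]]
  expect_equal(nrow(sh), 1L)
  expect_equal(sh$shared_targets, 7L)
})
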