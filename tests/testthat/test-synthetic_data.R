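small_cfg <- function(seed = 5L, ...) {
  simulation_config(seed = seed, genome_length = 60000L, n_scaffolds = 1L,
                    n_genes = 6L, n_planted = 8L, ...)
}

test_that("hairpin construction is deterministic and self-consistent", {
  cfg <- simulation_config(seed = 131)
  set.seed(1); h1 <- plant_hairpin(cfg)
  set.seed(1); h2 <- plant_hairpin(cfg)
  expect_identical(h1, h2)
  r <- h1$record
  expect_equal(substring(h1$sequence, r$arm5_interval[1] + 1,
                         r$arm5_interval[2]), r$mature5p)
  expect_equal(revcomp(substring(h1$sequence, r$arm3_interval[1] + 1,
                                 r$arm3_interval[2])), r$mature3p)
})

test_that("non-decoy records satisfy the duplex criteria directly", {
  crit <- duplex_criteria()
  set.seed(132)
  for (i in 1:25) {
    hp <- plant_hairpin(simulation_config(seed = 132))
    r <- hp$record
    expect_gt(r$arm5_interval[2] - r$arm5_interval[1],
              crit$min_strand_length - 1L)
    expect_gt(r$arm3_interval[2] - r$arm3_interval[1],
              crit$min_strand_length - 1L)
    expect_lte(r$mismatches, crit$max_mismatch)
    if (nrow(r$bulges)) {
      expect_true(all(abs(r$bulges$size5 - r$bulges$size3) <=
                        crit$max_asym_bulge))
    }
    expect_gte(r$arm_pairs, 16L)
  }
})

test_that("decoys plant criteria violations and extraction never accepts them", {
  set.seed(133)
  for (i in 1:10) {
    type <- if (i %% 2) "mismatch" else "asym"
    hp <- plant_hairpin(simulation_config(seed = 133), is_decoy = TRUE,
                        decoy_type = type)
    r <- hp$record
    if (type == "mismatch") expect_gte(r$mismatches, 5L)
    else expect_gte(max(abs(r$bulges$size5 - r$bulges$size3)), 3L)
    st <- find_stems(fold_rna(hp$sequence))
    duplexes <- Filter(Negate(is.null),
                       lapply(st, extract_duplex, sequence = hp$sequence))
    expect_length(duplexes, 0)
  }
})

test_that("the synthetic genome is reproducible and bookkept correctly", {
  sim1 <- simulate_genome(small_cfg())
  sim2 <- simulate_genome(small_cfg())
  expect_identical(as.character(sim1$genome), as.character(sim2$genome))
  expect_identical(sim1$truth, sim2$truth)
  tr <- sim1$truth
  expect_equal(nrow(tr), 8L)
  expect_setequal(unique(tr$region_kind), c("intergenic", "intronic"))
  # planted hairpins sit inside noncoding regions of the recorded kind and
  # never overlap exons
  for (i in seq_len(nrow(tr))) {
    reg <- sim1$regions
    hosts <- reg[reg$scaffold == tr$scaffold[i] & reg$start <= tr$start[i] &
                   reg$end >= tr$end[i], ]
    expect_gte(nrow(hosts), 1L)
    expect_true(tr$region_kind[i] %in% hosts$kind)
    ex <- sim1$exons[sim1$exons$scaffold == tr$scaffold[i], ]
    expect_false(any(ex$start < tr$end[i] & ex$end > tr$start[i]))
  }
  # the genome slice equals the recorded mature sequences
  i <- 1L
  expect_equal(premirscan:::genome_slice(sim1$genome, tr$scaffold[i],
                                         tr$arm5_start[i], tr$arm5_end[i]),
               tr$mature5p[i])
})

test_that("simulated reads flip expression support exactly at depth 10", {
  sim <- simulate_genome(small_cfg(seed = 6L))
  rd <- simulate_reads(sim, n_background = 10L)
  expect_identical(rd$reads, simulate_reads(sim, n_background = 10L)$reads)
  tr <- sim$truth[!sim$truth$is_decoy, ]
  mats <- data.frame(mature_id = paste0(tr$planted_id, "-5p"),
                     sequence = tr$mature5p, stringsAsFactors = FALSE)
  sup <- support_small_rna(mats, rd$reads$sequence)
  for (i in seq_len(nrow(sup))) {
    d <- rd$depths[[sup$mature_id[i]]]
    expect_gte(sup$read_depth[i], d)  # background may add coincidental hits
    if (d >= 10L) expect_true(sup$supported[i])
  }
  # alignments carry the true coordinates
  al <- rd$alignments[rd$alignments$read_id == rd$reads$read_id[1], ]
  expect_equal(al$end - al$start, nchar(rd$reads$sequence[1]))
})

test_that("reference sets, conserved catalog and term map behave as planted", {
  # the enrichment check needs a reasonable gene universe
  sim <- simulate_genome(simulation_config(seed = 6L, genome_length = 90000L,
                                           n_scaffolds = 1L, n_genes = 16L,
                                           n_planted = 8L))
  refs <- simulate_reference_sets(sim)
  tr <- sim$truth[!sim$truth$is_decoy, ]
  expect_equal(nrow(refs$references), nrow(tr))
  expect_true(all(refs$references$end - refs$references$start ==
                    nchar(refs$references$sequence)))
  # a zero-substitution catalog gives every 5p mature a conservation hit
  mats <- data.frame(mature_id = tr$planted_id, sequence = tr$mature5p,
                     stringsAsFactors = FALSE)
  hits <- match_conserved(mats, refs$plant_matures)
  expect_true(all(mats$mature_id %in% hits$mature_id))
  expect_true(all(hits$mismatches[paste0("pln-", hits$mature_id) ==
                                    hits$plant_mirna_id] == 0L))
  # the planted enriched term is significant for the designated gene set
  e <- hypergeom_enrichment(refs$enriched$gene_set, refs$term_map,
                            refs$background)
  expect_lt(e$p_value[e$term_id == refs$enriched$term], 0.05)
})
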