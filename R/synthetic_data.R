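#' Simulation configuration for the synthetic genome
#'
#' The generator emulates the statistical structure the pipeline assumes:
#' a genome with annotated protein-coding genes (introns included), hairpin
#' loci planted in intronic and intergenic space with fully known duplexes,
#' and a truth table recording every planted feature. A stated fraction of
#' planted hairpins are decoys that deliberately violate the duplex
#' criteria (5-6 mismatches, or one bulge of asymmetry 3-4) and must never
#' be recovered.
#'
#' Two structural guarantees shape the construction (see the methods
#' vignette): planted stems keep at least 16 paired columns so every
#' non-decoy carries a screenable helix, and events plus flank/loop
#' alphabets are chosen so the planted pairing is the unique maximum-weight
#' fold, making exact arm-interval recovery well defined.
#'
#' @param seed integer; fully determines the output.
#' @param genome_length total genome size in nt.
#' @param n_scaffolds number of scaffolds.
#' @param n_genes number of protein-coding genes.
#' @param exons_per_gene integer range (min, max).
#' @param exon_length,intron_length integer ranges in nt.
#' @param n_planted number of planted hairpins.
#' @param planted_split ratio intergenic:genic, e.g. c(2, 1).
#' @param arm_length stem arm length range in nt (18-24).
#' @param loop_length hairpin loop length range in nt (4-15).
#' @param mismatches mismatch count range (0-4; capped at arm_length - 16).
#' @param bulge_events bulge event count range (0-2).
#' @param bulge_asym asymmetry per bulge event (1-2 nt).
#' @param decoy_fraction fraction of planted hairpins that are decoys.
#' @param background_gc background GC fraction.
#' @param buffer_length pairing-inert flank placed on each side of a
#'   planted stem, in nt; must exceed the stem-walk gap limit.
#' @param min_spacing minimum genomic distance between planted hairpins.
#' @param read_depth read-depth range for simulated mature reads.
#' @param read_error_rate per-base substitution rate in simulated reads.
#' @return a `simulation_config` list.
#' @export
simulation_config <- function(seed = 1L, genome_length = 200000L,
                              n_scaffolds = 2L, n_genes = 20L,
                              exons_per_gene = c(2L, 4L),
                              exon_length = c(200L, 600L),
                              intron_length = c(200L, 500L),
                              n_planted = 30L, planted_split = c(2, 1),
                              arm_length = c(18L, 24L),
                              loop_length = c(4L, 15L),
                              mismatches = c(0L, 4L),
                              bulge_events = c(0L, 2L),
                              bulge_asym = c(1L, 2L),
                              decoy_fraction = 0.2,
                              background_gc = 0.36,
                              buffer_length = 12L,
                              min_spacing = 400L,
                              read_depth = c(5L, 20L),
                              read_error_rate = 0) {
  structure(as.list(environment()), class = "simulation_config")
}

sample_range <- function(rng) {
  if (length(rng) == 1) return(as.integer(rng))
  v <- seq.int(rng[1], rng[2])
  v[sample.int(length(v), 1L)]
}

# sample n values from a vector without the scalar-x surprise of sample()
sample_vec <- function(x, n) x[sample.int(length(x), n)]

COMP <- c(A = "T", C = "G", G = "C", T = "A")

# Alphabet for a pairing-inert segment adjacent to the pair (x, y):
# {A, C} minus any base that could pair with x or y. Because y is the
# Watson-Crick complement of x this always leaves exactly one base.
inert_base <- function(x) {
  if (x %in% c("G", "C")) "A" else "C"
}

#' Construct one planted hairpin
#'
#' Builds a random 5' arm, an inert loop, and a 3' arm as the reverse
#' complement of the 5' arm with the prescribed events applied: mismatch
#' columns are set to A on both arms (A:A cannot pair), bulge events insert
#' C bases on one arm. Inert buffers flank the stem so the stem walk cannot
#' extend into genomic context. Decoys violate the duplex criteria by
#' construction: `"mismatch"` decoys place 5-6 mismatches so that every
#' pair window with arms > 15 nt contains more than 4 of them;
#' `"asym"` decoys place one central bulge of asymmetry 3-4 so that no
#' qualifying window exists on either side.
#'
#' Each candidate is verified in isolation before being accepted: the
#' built-in fold of the hairpin must yield, for a non-decoy, exactly the
#' planted arm intervals under [extract_duplex()], and for a decoy no
#' qualifying duplex at all; otherwise the arm bases are resampled
#' (bounded retries).
#'
#' @param cfg a [simulation_config()] (only the hairpin fields are used).
#' @param is_decoy logical.
#' @param decoy_type "mismatch" or "asym".
#' @param fold_cfg the [fold_config()] used for the verification fold.
#' @param criteria the [duplex_criteria()] used for verification.
#' @param max_tries bounded resampling attempts.
#' @return list with `sequence` and `record` (local 0-based coordinates:
#'   stem/arm5/arm3 intervals, mature sequences, event bookkeeping).
#' @export
plant_hairpin <- function(cfg = simulation_config(), is_decoy = FALSE,
                          decoy_type = c("mismatch", "asym"),
                          fold_cfg = fold_config(),
                          criteria = duplex_criteria(), max_tries = 50L) {
  decoy_type <- match.arg(decoy_type)
  for (try in seq_len(max_tries)) {
    hp <- plant_hairpin_once(cfg, is_decoy, decoy_type)
    if (hairpin_verifies(hp, is_decoy, fold_cfg, criteria)) return(hp)
  }
  stop("plant_hairpin: no verifiable hairpin after ", max_tries,
       " attempts for this event combination")
}

# Fold the isolated hairpin and check that duplex extraction returns
# exactly the planted arms (non-decoy) or nothing (decoy).
hairpin_verifies <- function(hp, is_decoy, fold_cfg, criteria) {
  struct <- fold_rna(hp$sequence, fold_cfg)
  stems <- find_stems(struct)
  duplexes <- Filter(Negate(is.null), lapply(stems, extract_duplex,
                                             sequence = hp$sequence,
                                             criteria = criteria))
  if (is_decoy) return(length(duplexes) == 0L)
  if (!length(duplexes)) return(FALSE)
  best <- duplexes[[which.max(vapply(duplexes, function(d) d$n_pairs,
                                     numeric(1)))]]
  identical(as.integer(best$arm5_interval),
            as.integer(hp$record$arm5_interval)) &&
    identical(as.integer(best$arm3_interval),
              as.integer(hp$record$arm3_interval)) &&
    best$mismatch_total == hp$record$mismatches
}

plant_hairpin_once <- function(cfg, is_decoy, decoy_type) {
  arm <- sample_range(cfg$arm_length)
  loop_len <- sample_range(cfg$loop_length)
  if (!is_decoy) {
    # events live in the outer event zone [5, arm - 12]: far enough from
    # both helix ends that bridging an event is always worthwhile for the
    # folder, and leaving the 12 loop-proximal columns as a clean helical
    # core (the screen's contiguous-run rule keys on it)
    zone <- seq.int(5L, arm - 12L)
    max_mm <- min(cfg$mismatches[2], arm - 16L, length(zone))
    min_mm <- min(cfg$mismatches[1], max_mm)
    n_mm <- if (max_mm >= min_mm) sample_range(c(min_mm, max_mm)) else 0L
    mm_cols <- sort(sample_vec(zone, n_mm))
    n_bulge <- min(sample_range(cfg$bulge_events), length(zone))
    bulge_gaps <- if (n_bulge > 0) {
      sort(sample_vec(zone, n_bulge))
    } else integer()
    bulge_sizes <- vapply(seq_len(n_bulge), function(i)
      sample_range(cfg$bulge_asym), integer(1))
  } else if (decoy_type == "mismatch") {
    zone <- seq.int(max(3L, arm - 15L), min(16L, arm - 2L))
    n_mm <- min(length(zone), sample_range(c(5L, 6L)))
    stopifnot(n_mm >= 5L)
    mm_cols <- sort(sample_vec(zone, n_mm))
    bulge_gaps <- integer(); bulge_sizes <- integer()
  } else {
    n_mm <- 0L; mm_cols <- integer()
    bulge_gaps <- as.integer(floor(arm / 2))
    bulge_sizes <- sample(3:4, 1L)
  }
  bulge_sides <- if (length(bulge_gaps)) {
    sample(c("5p", "3p"), length(bulge_gaps), replace = TRUE)
  } else character()

  arm5_cols <- sample(DNA_BASES, arm, replace = TRUE)
  arm5_cols[mm_cols] <- "A"
  arm3_cols <- unname(COMP[arm5_cols])
  arm3_cols[mm_cols] <- "A"

  # assemble the 5' arm with its inserted bulge bases
  arm5_parts <- character()
  for (c in seq_len(arm)) {
    arm5_parts <- c(arm5_parts, arm5_cols[c])
    bi <- which(bulge_gaps == c & bulge_sides == "5p")
    if (length(bi)) arm5_parts <- c(arm5_parts, rep("C", bulge_sizes[bi]))
  }
  # the 3' arm runs innermost -> outermost in sequence order
  arm3_parts <- character()
  for (c in seq.int(arm, 1L)) {
    arm3_parts <- c(arm3_parts, arm3_cols[c])
    bi <- which(bulge_gaps == c - 1L & bulge_sides == "3p")
    if (length(bi)) arm3_parts <- c(arm3_parts, rep("C", bulge_sizes[bi]))
  }
  loop_base <- inert_base(arm5_cols[arm])
  buffer_base <- inert_base(arm5_cols[1])
  buf <- strrep(buffer_base, cfg$buffer_length)
  arm5_seq <- paste(arm5_parts, collapse = "")
  arm3_seq <- paste(arm3_parts, collapse = "")
  loop_seq <- strrep(loop_base, loop_len)
  sequence <- paste0(buf, arm5_seq, loop_seq, arm3_seq, buf)

  b <- cfg$buffer_length
  arm5_iv <- c(b, b + nchar(arm5_seq))
  loop_iv <- c(arm5_iv[2], arm5_iv[2] + loop_len)
  arm3_iv <- c(loop_iv[2], loop_iv[2] + nchar(arm3_seq))
  bulges <- data.frame(
    gap_after_column = bulge_gaps,
    size5 = ifelse(bulge_sides == "5p", bulge_sizes, 0L),
    size3 = ifelse(bulge_sides == "3p", bulge_sizes, 0L))
  list(sequence = sequence,
       record = list(
         arm_pairs = arm - n_mm,
         arm5_interval = arm5_iv, arm3_interval = arm3_iv,
         loop_interval = loop_iv,
         stem_interval = c(arm5_iv[1], arm3_iv[2]),
         mature5p = arm5_seq, mature3p = revcomp(arm3_seq),
         mismatches = n_mm, bulges = bulges,
         is_decoy = is_decoy,
         decoy_type = if (is_decoy) decoy_type else NA_character_))
}

# Build the exon layout of one gene; returns list(length, exons_rel) where
# exons_rel are 0-based intervals relative to the gene start.
build_gene_structure <- function(cfg) {
  k <- sample_range(cfg$exons_per_gene)
  ex_len <- vapply(seq_len(k), function(i) sample_range(cfg$exon_length),
                   integer(1))
  in_len <- if (k > 1) vapply(seq_len(k - 1), function(i)
    sample_range(cfg$intron_length), integer(1)) else integer()
  starts <- cumsum(c(0L, ex_len[-k] + in_len))
  list(length = sum(ex_len) + sum(in_len),
       exons_rel = cbind(starts, starts + ex_len))
}

# Window starts of the fragment grid for a region [rs, re), genomic coords.
region_window_starts <- function(rs, re, window = 120L, step = 100L) {
  L <- re - rs
  if (L < window) return(integer())
  rs + window_starts(L, list(window_length = window, step = step))
}

#' Generate a synthetic genome with planted hairpins
#'
#' Places non-overlapping genes (with introns) on i.i.d. background
#' sequence at the configured GC, then embeds planted hairpins into
#' intronic and intergenic space in the configured ratio, none overlapping
#' exons, each stem positioned inside at least one scanning window of its
#' region's fragment grid, and writes a truth table.
#'
#' @param cfg a [simulation_config()].
#' @return list with `genome` (DNAStringSet), `genes`, `exons`, `regions`,
#'   `truth` (one row per planted hairpin, genomic 0-based coordinates) and
#'   `config`.
#' @export
simulate_genome <- function(cfg = simulation_config()) {
  with_seed(cfg$seed, simulate_genome_impl(cfg))
}

simulate_genome_impl <- function(cfg) {
  n_sc <- cfg$n_scaffolds
  sc_len <- rep(cfg$genome_length %/% n_sc, n_sc)
  sc_names <- sprintf("scf%02d", seq_len(n_sc))
  p_gc <- cfg$background_gc
  probs <- c(A = (1 - p_gc) / 2, C = p_gc / 2, G = p_gc / 2,
             T = (1 - p_gc) / 2)
  chars <- lapply(sc_len, function(L) {
    sample(DNA_BASES, L, replace = TRUE, prob = probs)
  })
  names(chars) <- sc_names

  # gene placement: evenly slotted with jitter, never overlapping
  genes <- list(); exons <- list()
  per_sc <- diff(round(seq(0, cfg$n_genes, length.out = n_sc + 1)))
  gid <- 0L
  for (s in seq_len(n_sc)) {
    ng <- per_sc[s]
    if (ng == 0) next
    slot <- sc_len[s] %/% ng
    for (g in seq_len(ng)) {
      st <- build_gene_structure(cfg)
      margin <- slot - st$length - 200L
      if (margin < 1L) stop("simulate_genome: scaffold too small for genes; ",
                            "increase genome_length or shrink genes")
      start <- (g - 1L) * slot + 100L + sample.int(margin, 1L)
      gid <- gid + 1L
      gene_id <- sprintf("gene%03d", gid)
      genes[[gid]] <- data.frame(
        gene_id = gene_id, scaffold = sc_names[s], start = start,
        end = start + st$length, strand = sample(c("+", "-"), 1L),
        stringsAsFactors = FALSE)
      exons[[gid]] <- data.frame(
        gene_id = gene_id, scaffold = sc_names[s],
        start = start + st$exons_rel[, 1], end = start + st$exons_rel[, 2],
        stringsAsFactors = FALSE)
    }
  }
  genes <- do.call(rbind, genes)
  exons <- do.call(rbind, exons)
  genome0 <- setNames(vapply(chars, paste, character(1), collapse = ""),
                      sc_names)
  regions <- extract_noncoding(genome0, genes, exons)

  # planted hairpins
  n_pl <- cfg$n_planted
  w_ig <- cfg$planted_split[1] / sum(cfg$planted_split)
  n_ig <- round(n_pl * w_ig)
  kinds <- c(rep("intergenic", n_ig), rep("intronic", n_pl - n_ig))
  n_decoy <- round(cfg$decoy_fraction * n_pl)
  decoy_flags <- rep(FALSE, n_pl)
  if (n_decoy > 0) decoy_flags[sample.int(n_pl, n_decoy)] <- TRUE
  decoy_types <- rep(c("mismatch", "asym"), length.out = n_decoy)

  truth <- list()
  placed <- data.frame(scaffold = character(), start = integer(),
                       end = integer(), stringsAsFactors = FALSE)
  di <- 0L
  for (i in seq_len(n_pl)) {
    if (decoy_flags[i]) di <- di + 1L
    hp <- plant_hairpin(cfg, is_decoy = decoy_flags[i],
                        decoy_type = if (decoy_flags[i])
                          decoy_types[di] else "mismatch")
    hp_len <- nchar(hp$sequence)
    cand <- regions[regions$kind == kinds[i] &
                      (regions$end - regions$start) >= hp_len + 20L, ,
                    drop = FALSE]
    if (!nrow(cand)) stop("simulate_genome: no ", kinds[i],
                          " region can host a hairpin; enlarge the genome")
    ok <- FALSE
    for (try in seq_len(500L)) {
      r <- cand[sample.int(nrow(cand), 1L,
                           prob = cand$end - cand$start), , drop = FALSE]
      pos <- r$start + sample.int(r$end - r$start - hp_len + 1L, 1L) - 1L
      stem_g <- pos + hp$record$stem_interval
      # spacing from previously placed hairpins
      near <- placed[placed$scaffold == r$scaffold, , drop = FALSE]
      if (nrow(near) && any(near$end + cfg$min_spacing > pos &
                            near$start - cfg$min_spacing < pos + hp_len)) next
      # stem must sit inside at least one scanning window of this region
      ws <- region_window_starts(r$start, r$end)
      if (!length(ws)) next
      win <- ws[ws <= stem_g[1] & stem_g[2] <= ws + 120L]
      if (!length(win)) next
      # verify recoverability in the actual window context: the window
      # must pass the default screen and duplex extraction must return
      # exactly the planted arms (decoys: no duplex at all)
      v <- chars[[r$scaffold]]
      v[(pos + 1L):(pos + hp_len)] <- strsplit(hp$sequence, "")[[1]]
      wseq <- paste(v[(win[1] + 1L):(win[1] + 120L)], collapse = "")
      d <- fold_and_extract(wseq, fold_config(), duplex_criteria())
      if (decoy_flags[i]) {
        if (!is.null(d)) next
      } else {
        if (is.null(d) || d$strand != "+") next
        if (!identical(win[1] + d$arm5_interval,
                       c(pos + hp$record$arm5_interval[1],
                         pos + hp$record$arm5_interval[2])) ||
            !identical(win[1] + d$arm3_interval,
                       c(pos + hp$record$arm3_interval[1],
                         pos + hp$record$arm3_interval[2]))) next
        if (!screen_fragment(wseq)$passed) next
      }
      ok <- TRUE
      break
    }
    if (!ok) stop("simulate_genome: hairpin placement failed after ",
                  "bounded retries; enlarge the genome or lower n_planted")
    sc <- r$scaffold
    chars[[sc]] <- v  # already carries the hairpin from the verification
    placed <- rbind(placed, data.frame(scaffold = sc, start = pos,
                                       end = pos + hp_len,
                                       stringsAsFactors = FALSE))
    rec <- hp$record
    truth[[i]] <- data.frame(
      planted_id = sprintf("planted%03d", i), scaffold = sc,
      start = pos, end = pos + hp_len,
      stem_start = pos + rec$stem_interval[1],
      stem_end = pos + rec$stem_interval[2],
      arm5_start = pos + rec$arm5_interval[1],
      arm5_end = pos + rec$arm5_interval[2],
      arm3_start = pos + rec$arm3_interval[1],
      arm3_end = pos + rec$arm3_interval[2],
      mature5p = rec$mature5p, mature3p = rec$mature3p,
      arm_pairs = rec$arm_pairs, mismatches = rec$mismatches,
      n_bulges = nrow(rec$bulges),
      region_kind = kinds[i], is_decoy = rec$is_decoy,
      decoy_type = rec$decoy_type,
      family = sprintf("MIR9%02d", ((i - 1) %% 12) + 1),
      stringsAsFactors = FALSE)
  }
  truth <- do.call(rbind, truth)
  genome <- Biostrings::DNAStringSet(
    setNames(vapply(chars, paste, character(1), collapse = ""), sc_names))
  list(genome = genome, genes = genes, exons = exons, regions = regions,
       truth = truth, config = cfg)
}

#' Simulate small-RNA reads from planted matures
#'
#' For each non-decoy planted mature (both arms) `d` reads are emitted
#' (exact copies with a per-base substitution rate), `d` drawn from the
#' configured depth range, plus background reads sliced at random from the
#' genome. True coordinates are recorded as a minimal alignment table.
#'
#' @param sim output of [simulate_genome()].
#' @param seed seed for the read simulation (defaults to config seed + 1).
#' @param n_background number of random background reads.
#' @return list with `reads` (read_id, sequence), `alignments` (read_id,
#'   scaffold, start, end, strand) and `depths` (per mature_id).
#' @export
simulate_reads <- function(sim, seed = sim$config$seed + 1L,
                           n_background = 50L) {
  cfg <- sim$config
  with_seed(seed, {
    tr <- sim$truth[!sim$truth$is_decoy, , drop = FALSE]
    reads <- list(); aligns <- list(); depths <- integer()
    rid <- 0L
    for (i in seq_len(nrow(tr))) {
      for (arm in c("5p", "3p")) {
        mat_seq <- if (arm == "5p") tr$mature5p[i] else tr$mature3p[i]
        iv <- if (arm == "5p") c(tr$arm5_start[i], tr$arm5_end[i]) else
          c(tr$arm3_start[i], tr$arm3_end[i])
        d <- sample_range(cfg$read_depth)
        depths[paste0(tr$planted_id[i], "-", arm)] <- d
        for (r in seq_len(d)) {
          rid <- rid + 1L
          s <- strsplit(mat_seq, "")[[1]]
          err <- runif(length(s)) < cfg$read_error_rate
          if (any(err)) {
            s[err] <- vapply(s[err], function(b)
              sample(setdiff(DNA_BASES, b), 1L), character(1))
          }
          reads[[rid]] <- data.frame(
            read_id = sprintf("read%06d", rid),
            sequence = paste(s, collapse = ""), stringsAsFactors = FALSE)
          aligns[[rid]] <- data.frame(
            read_id = sprintf("read%06d", rid), scaffold = tr$scaffold[i],
            start = iv[1], end = iv[2],
            strand = if (arm == "5p") "+" else "-",
            stringsAsFactors = FALSE)
        }
      }
    }
    lens <- genome_lengths(sim$genome)
    for (b in seq_len(n_background)) {
      rid <- rid + 1L
      sc <- sample(names(lens), 1L)
      L <- 21L
      st <- sample.int(lens[[sc]] - L, 1L) - 1L
      reads[[rid]] <- data.frame(
        read_id = sprintf("read%06d", rid),
        sequence = genome_slice(sim$genome, sc, st, st + L),
        stringsAsFactors = FALSE)
      aligns[[rid]] <- data.frame(
        read_id = sprintf("read%06d", rid), scaffold = sc, start = st,
        end = st + L, strand = "+", stringsAsFactors = FALSE)
    }
    list(reads = do.call(rbind, reads), alignments = do.call(rbind, aligns),
         depths = depths)
  })
}

#' Simulate reference sets, a conserved catalog and a term map
#'
#' Samples fractions of the non-decoy planted stems as "known pre-miRNA"
#' reference sets (one per source label), derives a plant mature catalog
#' from planted matures with up to `conserved_max_sub` substitutions and
#' family tags, and builds a random gene-to-term map with one genuinely
#' enriched term planted into a designated gene set.
#'
#' @param sim output of [simulate_genome()].
#' @param fractions named numeric vector: fraction of non-decoy planted
#'   stems per reference source label.
#' @param conserved_max_sub substitutions applied to catalog entries (0-3).
#' @param seed seed (defaults to config seed + 2).
#' @return list with `references`, `plant_matures`, `term_map`,
#'   `enriched` (term id and the designated gene set) and `background`
#'   (all gene ids).
#' @export
simulate_reference_sets <- function(sim, fractions = c(synthetic = 1),
                                    conserved_max_sub = 0L,
                                    seed = sim$config$seed + 2L) {
  with_seed(seed, {
    tr <- sim$truth[!sim$truth$is_decoy, , drop = FALSE]
    refs <- list()
    for (lb in names(fractions)) {
      n_take <- max(1L, round(fractions[[lb]] * nrow(tr)))
      take <- sort(sample.int(nrow(tr), n_take))
      for (i in take) {
        refs[[length(refs) + 1L]] <- data.frame(
          ref_id = paste0(lb, "-", tr$planted_id[i]),
          scaffold = tr$scaffold[i], start = tr$stem_start[i],
          end = tr$stem_end[i],
          sequence = genome_slice(sim$genome, tr$scaffold[i],
                                  tr$stem_start[i], tr$stem_end[i]),
          family = tr$family[i], source_label = lb,
          stringsAsFactors = FALSE)
      }
    }
    references <- do.call(rbind, refs)

    plant <- lapply(seq_len(nrow(tr)), function(i) {
      s <- strsplit(tr$mature5p[i], "")[[1]]
      n_sub <- if (conserved_max_sub > 0)
        sample(0:conserved_max_sub, 1L) else 0L
      if (n_sub > 0) {
        pos <- sample(seq_along(s), n_sub)
        s[pos] <- vapply(s[pos], function(b)
          sample(setdiff(DNA_BASES, b), 1L), character(1))
      }
      data.frame(mirna_id = paste0("pln-", tr$planted_id[i]),
                 family = tr$family[i],
                 sequence = paste(s, collapse = ""),
                 stringsAsFactors = FALSE)
    })
    plant_matures <- do.call(rbind, plant)

    background <- sim$genes$gene_id
    terms <- sprintf("T%02d", 1:10)
    rows <- lapply(background, function(g) {
      data.frame(gene_id = g,
                 term_id = sample(terms, sample(1:3, 1L)),
                 stringsAsFactors = FALSE)
    })
    term_map <- do.call(rbind, rows)
    enr_members <- sample(background, max(4L, round(0.25 * length(background))))
    term_map <- rbind(term_map,
                      data.frame(gene_id = enr_members,
                                 term_id = "T_enriched",
                                 stringsAsFactors = FALSE))
    n_set <- max(5L, round(0.3 * length(background)))
    n_from <- round(0.8 * n_set)
    gene_set <- unique(c(sample(enr_members, min(n_from, length(enr_members))),
                         sample(setdiff(background, enr_members),
                                n_set - n_from)))
    list(references = references, plant_matures = plant_matures,
         term_map = term_map,
         enriched = list(term = "T_enriched", gene_set = gene_set),
         background = background)
  })
}
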