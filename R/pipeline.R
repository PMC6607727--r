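#' Pipeline configuration
#'
#' Bundles every stage's configuration with the run seed. Each component
#' defaults to the package defaults, so `pipeline_config()` reproduces the
#' standard identification settings (120/20 windowing, strictest screen
#' cut-off, duplex criteria > 15 / <= 2 / <= 4, 20-nt extension retry).
#'
#' @param seed run seed (used by any stage that randomises).
#' @param window a [window_config()].
#' @param fold a [fold_config()].
#' @param screen a [screen_rules()].
#' @param criteria a [duplex_criteria()].
#' @param max_extension,ext_step end-extension retry schedule in nt.
#' @param min_overlap_fraction,max_ref_mismatch reference-matching rules.
#' @param density_mode "summation" or "union", see
#'   [genomic_partition_lengths()].
#' @param presetA,presetB target-predictor presets ([target_scheme()]s).
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(seed = 1L,
                            window = window_config(),
                            fold = fold_config(),
                            screen = screen_rules(),
                            criteria = duplex_criteria(),
                            max_extension = 20L, ext_step = 5L,
                            min_overlap_fraction = 0.60,
                            max_ref_mismatch = 2L,
                            density_mode = "summation",
                            presetA = target_scheme(cutoff = 3),
                            presetB = target_scheme(cutoff = 4)) {
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the full identification pipeline
#'
#' Executes region extraction, windowing, hairpin screening, optional
#' structural-RNA exclusion, locus merging, folding with duplex extraction
#' (plus end-extension retry) and mature enumeration, then the optional
#' downstream analyses for whichever inputs are supplied: reference
#' matching with the hypergeometric overlap test, small-RNA and total-RNA
#' expression support, conservation, per-region-class density, and
#' consensus target prediction. The run is deterministic for a fixed
#' configuration and inputs.
#'
#' @param genome genome container (DNAStringSet or named character).
#' @param genes,exons gene model tables (0-based half-open).
#' @param cfg a [pipeline_config()].
#' @param references optional reference pre-miRNA table (see
#'   [match_reference_loci()]).
#' @param reads optional character vector of small-RNA reads.
#' @param alignments optional alignment table for total-RNA support.
#' @param plant_matures optional plant mature catalog.
#' @param transcripts optional named character vector for target
#'   prediction.
#' @param structural_ref optional rRNA/tRNA sequences for exclusion.
#' @param out_dir optional directory; when given, artifacts are written
#'   (BED/TSV/FASTA/JSON plus a MANIFEST).
#' @return list with `summary` (stage counts) and the per-stage tables:
#'   regions, fragments, loci, duplexes, matures, fold_failed,
#'   overlap_tests, evidence, density, targets.
#' @export
run_pipeline <- function(genome, genes, exons, cfg = pipeline_config(),
                         references = NULL, reads = NULL,
                         alignments = NULL, plant_matures = NULL,
                         transcripts = NULL, structural_ref = NULL,
                         out_dir = NULL) {
  regions <- extract_noncoding(genome, genes, exons)
  fragments <- fragment_noncoding(regions, genome, cfg$window)
  screened <- screen_fragments(fragments, cfg$fold, cfg$screen)
  n_investigated <- nrow(screened)
  passed <- screened[screened$passed, , drop = FALSE]
  excluded_structural <- 0L
  if (!is.null(structural_ref)) {
    flt <- filter_structural_rna(passed, structural_ref)
    excluded_structural <- nrow(flt$excluded)
    passed <- flt$retained
  }
  loci <- merge_predicted_loci(passed)

  duplexes <- list(); matures <- list(); fold_failed <- character()
  for (i in seq_len(nrow(loci))) {
    locus <- loci[i, ]
    res <- extract_locus_duplex(locus, genome, cfg$fold, cfg$criteria,
                                max_extension = cfg$max_extension,
                                ext_step = cfg$ext_step,
                                max_gap = cfg$screen$max_gap,
                                scan_reverse = cfg$screen$scan_reverse)
    if (is.null(res)) {
      fold_failed <- c(fold_failed, locus$locus_id)
      next
    }
    d <- res$duplex
    duplexes[[length(duplexes) + 1L]] <- data.frame(
      locus_id = locus$locus_id, scaffold = locus$scaffold,
      strand = d$strand,
      arm5_start = res$interval[1] + d$arm5_interval[1],
      arm5_end = res$interval[1] + d$arm5_interval[2],
      arm3_start = res$interval[1] + d$arm3_interval[1],
      arm3_end = res$interval[1] + d$arm3_interval[2],
      n_pairs = d$n_pairs, mismatch_total = d$mismatch_total,
      n_bulges = nrow(d$bulges), extension = res$extension,
      region_kind = locus$kind, stringsAsFactors = FALSE)
    m <- enumerate_matures(d, locus$locus_id, locus_start = res$interval[1])
    m$scaffold <- locus$scaffold
    m$region_kind <- locus$kind
    matures[[length(matures) + 1L]] <- m
  }
  duplexes <- if (length(duplexes)) do.call(rbind, duplexes) else
    data.frame(locus_id = character(), scaffold = character(),
               strand = character(), arm5_start = integer(),
               arm5_end = integer(), arm3_start = integer(),
               arm3_end = integer(), n_pairs = integer(),
               mismatch_total = integer(), n_bulges = integer(),
               extension = integer(), region_kind = character(),
               stringsAsFactors = FALSE)
  matures <- if (length(matures)) do.call(rbind, matures) else
    data.frame(mature_id = character(), locus_id = character(),
               arm = character(), sequence = character(),
               start = integer(), end = integer(), scaffold = character(),
               region_kind = character(), stringsAsFactors = FALSE)

  overlap_tests <- NULL
  if (!is.null(references)) {
    mt <- match_reference_loci(loci, references, genome,
                               cfg$min_overlap_fraction,
                               cfg$max_ref_mismatch)
    k <- vapply(split(references$ref_id, references$source_label),
                function(x) length(unique(x)), integer(1))
    overlap_tests <- list(
      matches = mt$matches,
      tests = overlap_test_table(mt$found, k, N = n_investigated,
                                 n = nrow(passed)))
  }

  evidence <- list()
  if (!is.null(reads) && nrow(matures)) {
    evidence$small_rna <- support_small_rna(matures, reads)
  }
  if (!is.null(alignments) && nrow(matures)) {
    evidence$total_rna <- support_total_rna(matures, alignments)
  }
  if (!is.null(plant_matures) && nrow(matures)) {
    evidence$conserved <- match_conserved(matures, plant_matures)
  }

  density <- if (nrow(loci)) density_report(loci, genome, genes,
                                            cfg$density_mode) else NULL

  targets <- NULL
  if (!is.null(transcripts) && nrow(matures)) {
    targets <- consensus_targets(matures, transcripts, cfg$presetA,
                                 cfg$presetB)
  }

  summary <- list(
    n_regions = nrow(regions),
    n_regions_by_kind = as.list(table(regions$kind)),
    n_fragments = n_investigated,
    n_fragments_by_kind = as.list(table(fragments$kind)),
    n_passed_fragments = sum(screened$passed),
    n_excluded_structural = excluded_structural,
    n_loci = nrow(loci),
    n_loci_by_kind = as.list(table(loci$kind)),
    n_duplexes = nrow(duplexes),
    n_fold_failed = length(fold_failed),
    n_matures = nrow(matures),
    n_matures_5p = sum(matures$arm == "5p"),
    n_matures_3p = sum(matures$arm == "3p"),
    n_reference_matched = if (!is.null(overlap_tests))
      as.list(setNames(overlap_tests$tests$X,
                       overlap_tests$tests$source_label)) else NULL,
    n_supported_small_rna = if (!is.null(evidence$small_rna))
      sum(evidence$small_rna$supported) else NULL,
    n_supported_total_rna = if (!is.null(evidence$total_rna))
      sum(evidence$total_rna$supported) else NULL,
    n_conserved = if (!is.null(evidence$conserved))
      length(unique(evidence$conserved$mature_id)) else NULL,
    n_consensus_interactions = if (!is.null(targets)) nrow(targets) else NULL
  )
  out <- list(summary = summary, regions = regions, fragments = screened,
              loci = loci, duplexes = duplexes, matures = matures,
              fold_failed = fold_failed, overlap_tests = overlap_tests,
              evidence = evidence, density = density, targets = targets,
              config = cfg)
  if (!is.null(out_dir)) write_pipeline_artifacts(out, out_dir)
  out
}

# Write the standard artifact set with stable filenames plus a MANIFEST.
write_pipeline_artifacts <- function(run, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character()
  w <- function(fn, writer) {
    p <- file.path(out_dir, fn)
    writer(p)
    paths[[length(paths) + 1L]] <<- p
    p
  }
  w("regions.bed", function(p) write_bed(
    cbind(run$regions, name = paste0(run$regions$kind, ":",
                                     seq_len(nrow(run$regions)))), p))
  w("fragments.tsv", function(p) write_tsv(run$fragments, p))
  w("loci.bed", function(p) write_bed(run$loci, p))
  w("loci.gff3", function(p) write_loci_gff3(run$loci, p))
  w("loci.tsv", function(p) write_tsv(run$loci, p))
  w("duplexes.tsv", function(p) write_tsv(run$duplexes, p))
  w("matures.tsv", function(p) write_tsv(run$matures, p))
  if (nrow(run$matures)) {
    w("matures.fasta", function(p) write_fasta(
      setNames(run$matures$sequence, run$matures$mature_id), p))
  }
  if (!is.null(run$overlap_tests)) {
    w("overlap_tests.tsv", function(p) write_tsv(run$overlap_tests$tests, p))
  }
  if (!is.null(run$density)) {
    w("density.tsv", function(p) write_tsv(run$density, p))
  }
  if (!is.null(run$targets)) {
    w("targets.tsv", function(p) write_tsv(run$targets, p))
  }
  w("summary.json", function(p) jsonlite::write_json(
    run$summary, p, auto_unbox = TRUE, digits = NA, pretty = TRUE))
  manifest <- data.frame(
    file = basename(unlist(paths)),
    md5 = vapply(unlist(paths), function(p) unname(tools::md5sum(p)),
                 character(1)),
    stringsAsFactors = FALSE)
  jsonlite::write_json(manifest, file.path(out_dir, "MANIFEST.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(out_dir)
}
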