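#' Penalty scheme for complementarity-based target scoring
#'
#' One configurable expectation-style scorer emulates the usual plant
#' target predictors: every ungapped antisense placement of the mature on
#' the transcript is scored per position (perfect complement 0, G:U wobble
#' `gu_penalty`, anything else `mismatch_penalty`), penalties inside the
#' seed region (mature positions `seed_start`..`seed_end` from the 5' end)
#' multiplied by `seed_multiplier`. Two presets differing in cutoff stand
#' in for two independent predictors whose consistent calls are kept.
#'
#' @param mismatch_penalty penalty per mismatched position (default 1).
#' @param gu_penalty penalty per G:U wobble (default 0.5).
#' @param gap_penalty declared for completeness; the scorer is ungapped so
#'   it is not consumed (default 2).
#' @param seed_start,seed_end seed region bounds on the mature, 1-based
#'   inclusive (defaults 2 and 13).
#' @param seed_multiplier penalty multiplier inside the seed (default 2).
#' @param cutoff maximum reported score.
#' @return a `target_scheme` list.
#' @export
target_scheme <- function(mismatch_penalty = 1, gu_penalty = 0.5,
                          gap_penalty = 2, seed_start = 2L, seed_end = 13L,
                          seed_multiplier = 2, cutoff = 3) {
  if (any(c(mismatch_penalty, gu_penalty, gap_penalty) < 0)) {
    stop("target_scheme: penalties must be >= 0")
  }
  if (cutoff <= 0) stop("target_scheme: cutoff must be > 0")
  structure(list(mismatch_penalty = mismatch_penalty,
                 gu_penalty = gu_penalty, gap_penalty = gap_penalty,
                 seed_start = as.integer(seed_start),
                 seed_end = as.integer(seed_end),
                 seed_multiplier = seed_multiplier, cutoff = cutoff),
            class = "target_scheme")
}

# Score one ungapped antisense placement: mature position p (5'->3') faces
# transcript position site_start + L - p (antiparallel binding).
site_score <- function(mature_chars, window_chars_rev, scheme) {
  L <- length(mature_chars)
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  t_b <- window_chars_rev
  m_b <- mature_chars
  pen <- ifelse(comp[m_b] == t_b, 0,
                ifelse((m_b == "G" & t_b == "T") | (m_b == "T" & t_b == "G"),
                       scheme$gu_penalty, scheme$mismatch_penalty))
  seed <- seq_along(m_b) >= scheme$seed_start &
    seq_along(m_b) <= scheme$seed_end
  pen[seed] <- pen[seed] * scheme$seed_multiplier
  sum(pen)
}

#' Score target sites of one mature on one transcript
#'
#' @param mature_seq mature sequence, 16-28 nt.
#' @param transcript_seq transcript sequence (at least as long).
#' @param scheme a [target_scheme()].
#' @return data.frame of sites with score <= cutoff (site_start is 0-based
#'   on the transcript), best site first; zero rows when none qualify.
#' @export
score_target_site <- function(mature_seq, transcript_seq,
                              scheme = target_scheme()) {
  mature_seq <- normalize_seq(mature_seq)
  transcript_seq <- normalize_seq(transcript_seq)
  L <- nchar(mature_seq)
  Tn <- nchar(transcript_seq)
  if (L > Tn) {
    return(data.frame(site_start = integer(), score = numeric()))
  }
  m_chars <- strsplit(mature_seq, "")[[1]]
  t_chars <- strsplit(transcript_seq, "")[[1]]
  scores <- vapply(0:(Tn - L), function(s) {
    site_score(m_chars, rev(t_chars[(s + 1):(s + L)]), scheme)
  }, numeric(1))
  keep <- which(scores <= scheme$cutoff)
  df <- data.frame(site_start = keep - 1L, score = scores[keep])
  df[order(df$score, df$site_start), , drop = FALSE]
}

#' Best qualifying site per (mature, transcript) pair under one scheme
#'
#' @param matures data.frame with mature_id, sequence.
#' @param transcripts named character vector of transcript sequences.
#' @param scheme a [target_scheme()].
#' @return data.frame: mature_id, transcript_id, site_start, score.
#' @export
predict_targets <- function(matures, transcripts,
                            scheme = target_scheme()) {
  rows <- list()
  for (i in seq_len(nrow(matures))) {
    for (tx in names(transcripts)) {
      sites <- score_target_site(matures$sequence[i], transcripts[[tx]],
                                 scheme)
      if (nrow(sites)) {
        rows[[length(rows) + 1L]] <- data.frame(
          mature_id = matures$mature_id[i], transcript_id = tx,
          site_start = sites$site_start[1], score = sites$score[1],
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(mature_id = character(), transcript_id = character(),
                      site_start = integer(), score = numeric(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

#' Consensus interactions of two predictor presets
#'
#' Only (mature, transcript) pairs predicted under both presets are kept
#' (the consistent predictions); the site and score reported come from
#' preset A.
#'
#' @param matures data.frame with mature_id, sequence.
#' @param transcripts named character vector.
#' @param presetA,presetB two [target_scheme()]s (defaults: cutoffs 3 and 4).
#' @return interaction data.frame with consensus = TRUE rows.
#' @export
consensus_targets <- function(matures, transcripts,
                              presetA = target_scheme(cutoff = 3),
                              presetB = target_scheme(cutoff = 4)) {
  a <- predict_targets(matures, transcripts, presetA)
  b <- predict_targets(matures, transcripts, presetB)
  keyA <- paste(a$mature_id, a$transcript_id)
  keyB <- paste(b$mature_id, b$transcript_id)
  out <- a[keyA %in% keyB, , drop = FALSE]
  if (nrow(out)) out$consensus <- TRUE
  else out$consensus <- logical(0)
  rownames(out) <- NULL
  out
}

#' Classify target transcripts into binding groups
#'
#' Transcripts are ranked by the number of distinct matures predicted to
#' bind them; the lowest decile forms the LMBG (low miRNA-bound genes)
#' group, the highest the HMBG group (decile size `floor(0.1 * count)`,
#' at least 1; ties broken by transcript id, lexically).
#'
#' @param interactions interaction table (mature_id, transcript_id).
#' @param subsample_fraction optional fraction of each group to subsample
#'   (seeded) for enrichment input.
#' @param seed seed for the subsample.
#' @return data.frame: transcript_id, binding_mirna_count, group, and
#'   (when subsampling) `sampled`.
#' @export
classify_binding_groups <- function(interactions, subsample_fraction = NULL,
                                    seed = 1L) {
  counts <- vapply(split(interactions$mature_id, interactions$transcript_id),
                   function(x) length(unique(x)), integer(1))
  if (length(counts) < 10) {
    stop("classify_binding_groups: need at least 10 targeted transcripts")
  }
  df <- data.frame(transcript_id = names(counts),
                   binding_mirna_count = as.integer(counts),
                   stringsAsFactors = FALSE)
  df <- df[order(df$binding_mirna_count, df$transcript_id), , drop = FALSE]
  dec <- max(1L, floor(0.1 * nrow(df)))
  df$group <- "middle"
  df$group[seq_len(dec)] <- "LMBG"
  df$group[seq.int(nrow(df) - dec + 1L, nrow(df))] <- "HMBG"
  if (!is.null(subsample_fraction)) {
    df$sampled <- FALSE
    with_seed(seed, {
      for (g in c("LMBG", "HMBG")) {
        idx <- which(df$group == g)
        take <- sort(sample(idx, max(1L, round(subsample_fraction *
                                                 length(idx)))))
        df$sampled[take] <- TRUE
      }
    })
  }
  rownames(df) <- NULL
  df
}

#' Hypergeometric GO-term enrichment
#'
#' One-sided upper-tail hypergeometric test per term, sharing the kernel of
#' [overlap_significance()]: the population is the background gene set, the
#' successes the term's members, the draws the query set. No correction is
#' applied by default (`adjust = "BH"` adds Benjamini-Hochberg values).
#'
#' @param gene_set character vector, a subset of `background`.
#' @param term_map data.frame with gene_id, term_id.
#' @param background character vector of background gene ids.
#' @param adjust "none" (default) or "BH".
#' @return data.frame per term: overlap, term_size, set_size,
#'   background_size, p_value (and p_adjust when requested), ordered by
#'   p_value.
#' @export
hypergeom_enrichment <- function(gene_set, term_map, background,
                                 adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  if (!all(gene_set %in% background)) {
    stop("hypergeom_enrichment: gene_set must be a subset of background")
  }
  term_map <- term_map[term_map$gene_id %in% background, , drop = FALSE]
  terms <- unique(term_map$term_id)
  rows <- list()
  for (tm in terms) {
    members <- unique(term_map$gene_id[term_map$term_id == tm])
    if (!length(members)) {
      message("term ", tm, " has no background members; skipped")
      next
    }
    t <- overlap_significance(N = length(background), k = length(members),
                              n = length(gene_set),
                              X = length(intersect(gene_set, members)))
    rows[[length(rows) + 1L]] <- data.frame(
      term_id = tm, overlap = t$X, term_size = t$k,
      set_size = t$n, background_size = t$N, p_value = t$p_tail,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$p_value, out$term_id), , drop = FALSE]
  if (adjust == "BH") out$p_adjust <- stats::p.adjust(out$p_value, "BH")
  rownames(out) <- NULL
  out
}

#' Degree-class summary of the miRNA-target network
#'
#' Matures are binned by their number of targets into the classes
#' \[1, 15\], \[16, 30\], \[31, 80\] and \[81, Inf) (the published open
#' boundaries 15 and 81 are closed into the adjacent bins). Per class the
#' summary reports the mature count and mean target count, plus a
#' co-regulation summary: for each class, the pairwise shared-target
#' counts between its matures.
#'
#' @param interactions interaction table (mature_id, transcript_id).
#' @return list with `classes` (data.frame) and `shared` (per-class list of
#'   pairwise shared-target count data.frames).
#' @export
degree_class_summary <- function(interactions) {
  tgt <- split(interactions$transcript_id, interactions$mature_id)
  tgt <- lapply(tgt, unique)
  n_tgt <- lengths(tgt)
  breaks <- c(1, 16, 31, 81, Inf)
  labels <- c("1-15", "16-30", "31-80", ">=81")
  cls <- cut(n_tgt, breaks = breaks, labels = labels, right = FALSE)
  classes <- data.frame(
    class = labels,
    n_matures = as.integer(table(cls)[labels]),
    mean_targets = vapply(labels, function(lb) {
      v <- n_tgt[cls == lb]
      if (length(v)) mean(v) else NA_real_
    }, numeric(1)),
    stringsAsFactors = FALSE)
  shared <- lapply(labels, function(lb) {
    ids <- names(tgt)[which(cls == lb)]
    if (length(ids) < 2) {
      return(data.frame(mature_a = character(), mature_b = character(),
                        shared_targets = integer(),
                        stringsAsFactors = FALSE))
    }
    pairs <- utils::combn(ids, 2)
    data.frame(mature_a = pairs[1, ], mature_b = pairs[2, ],
               shared_targets = vapply(seq_len(ncol(pairs)), function(i) {
                 length(intersect(tgt[[pairs[1, i]]], tgt[[pairs[2, i]]]))
               }, integer(1)), stringsAsFactors = FALSE)
  })
  names(shared) <- labels
  rownames(classes) <- NULL
  list(classes = classes, shared = shared)
}
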