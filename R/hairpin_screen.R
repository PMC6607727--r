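#' Screening rules for hairpin-bearing fragments
#'
#' The built-in screen is a transparent rule set standing in for an external
#' pre-miRNA classifier: each fragment is folded (both strands when
#' `scan_reverse`; the better-scoring strand is kept) and scored as the mean
#' of four indicator subscores: (1) at least `min_paired_fraction` of
#' bases paired, (2) a stem of at least `min_stem_pairs` pairs, (3) the
#' longest stem is a clean single-loop stem-loop, (4) a contiguous helix
#' run of at least `min_helix_block` stacked pairs. The helix-run rule
#' carries most of the specificity: opportunistic folds of random sequence
#' chain short helices through bulges but rarely stack more than ~10 pairs
#' without interruption, while a miRNA duplex keeps a long clean helical
#' core. A fragment passes when its score reaches `threshold` (default 1,
#' the strictest cut-off).
#' Externally computed scores can be used instead via
#' [screen_fragments_external()].
#'
#' @param threshold pass threshold on the score in \[0, 1\].
#' @param min_paired_fraction minimum fraction of paired bases.
#' @param min_stem_pairs minimum pairs in the longest stem.
#' @param min_helix_block minimum contiguous stacked run, in pairs.
#' @param scan_reverse fold the reverse complement too.
#' @param max_gap stem-walk gap limit, see [find_stems()].
#' @return a `screen_rules` list.
#' @export
screen_rules <- function(threshold = 1, min_paired_fraction = 0.40,
                         min_stem_pairs = 16L, min_helix_block = 12L,
                         scan_reverse = TRUE, max_gap = 10L) {
  structure(list(threshold = threshold,
                 min_paired_fraction = min_paired_fraction,
                 min_stem_pairs = as.integer(min_stem_pairs),
                 min_helix_block = as.integer(min_helix_block),
                 scan_reverse = scan_reverse, max_gap = as.integer(max_gap)),
            class = "screen_rules")
}

# Longest contiguous stacked run within one stem, in pairs.
longest_helix_block <- function(stem) {
  pr <- stem$pairs
  m <- nrow(pr)
  if (m == 1) return(1L)
  run <- 1L; best <- 1L
  for (t in seq_len(m - 1)) {
    stacked <- (pr[t + 1, 1] - pr[t, 1] == 1L) &&
      (pr[t, 2] - pr[t + 1, 2] == 1L)
    run <- if (stacked) run + 1L else 1L
    if (run > best) best <- run
  }
  best
}

#' Screen one fragment for hairpin potential
#'
#' @param sequence fragment sequence (window length).
#' @param fold_cfg a [fold_config()].
#' @param rules a [screen_rules()].
#' @return list with `score`, `passed` and a `features` list
#'   (paired_fraction, longest_stem_pairs, loop_count, gc_fraction).
#' @export
screen_fragment <- function(sequence, fold_cfg = fold_config(),
                            rules = screen_rules()) {
  sequence <- normalize_seq(sequence)
  structs <- list(fold_rna(sequence, fold_cfg))
  if (rules$scan_reverse) {
    structs <- c(structs, list(fold_rna(revcomp(sequence), fold_cfg)))
  }
  scores <- vapply(structs, function(s) s$score, numeric(1))
  struct <- structs[[which.max(scores)]]
  pt <- struct$pair_table
  n <- length(pt)
  paired_fraction <- sum(pt >= 0) / n
  stems <- find_stems(struct, max_gap = rules$max_gap)
  longest <- if (length(stems)) max(vapply(stems, function(s) nrow(s$pairs),
                                           numeric(1))) else 0L
  block <- if (length(stems)) max(vapply(stems, longest_helix_block,
                                         integer(1))) else 0L
  # every stem from find_stems encloses exactly one hairpin loop; 0 records
  # the absence of any stem-loop
  loop_count <- if (length(stems)) 1L else 0L
  s <- strsplit(sequence, "")[[1]]
  features <- list(paired_fraction = paired_fraction,
                   longest_stem_pairs = as.integer(longest),
                   helix_block = as.integer(block),
                   loop_count = loop_count,
                   gc_fraction = mean(s %in% c("G", "C")))
  sub <- c(paired_fraction >= rules$min_paired_fraction,
           longest >= rules$min_stem_pairs,
           loop_count == 1L,
           block >= rules$min_helix_block)
  score <- mean(sub)
  list(score = score, passed = score >= rules$threshold, features = features)
}

#' Screen a table of fragments
#'
#' @param fragments data.frame from [fragment_noncoding()].
#' @param fold_cfg a [fold_config()].
#' @param rules a [screen_rules()].
#' @return the fragments with score, passed and feature columns appended.
#' @export
screen_fragments <- function(fragments, fold_cfg = fold_config(),
                             rules = screen_rules()) {
  res <- lapply(fragments$sequence, screen_fragment, fold_cfg = fold_cfg,
                rules = rules)
  fragments$score <- vapply(res, function(r) r$score, numeric(1))
  fragments$passed <- vapply(res, function(r) r$passed, logical(1))
  fragments$paired_fraction <-
    vapply(res, function(r) r$features$paired_fraction, numeric(1))
  fragments$longest_stem_pairs <-
    vapply(res, function(r) r$features$longest_stem_pairs, integer(1))
  fragments
}

#' Apply externally computed screening scores
#'
#' @param fragments fragment table.
#' @param scores data.frame with fragment_id and score (in \[0, 1\]).
#' @param threshold pass threshold.
#' @return fragments with score and passed columns.
#' @export
screen_fragments_external <- function(fragments, scores, threshold = 1) {
  idx <- match(fragments$fragment_id, scores$fragment_id)
  if (anyNA(idx)) {
    stop("missing external score for fragment(s): ",
         paste(head(fragments$fragment_id[is.na(idx)]), collapse = ", "))
  }
  fragments$score <- scores$score[idx]
  fragments$passed <- fragments$score >= threshold
  fragments
}

#' Exclude fragments matching structural RNAs (rRNA/tRNA)
#'
#' A deterministic seeded matcher replaces a similarity-search tool: a
#' fragment is excluded when a shared exact `seed_k`-mer extends (ungapped,
#' on the same diagonal) to a window of at least `min_length` nt with at
#' least `min_identity` identity, on either strand.
#'
#' @param fragments fragment table with `sequence`.
#' @param structural_ref character vector (or DNAStringSet) of rRNA/tRNA
#'   sequences; must be non-empty.
#' @param seed_k exact seed length (default 16).
#' @param min_identity identity threshold (default 0.90).
#' @param min_length minimum alignment length (default 60).
#' @return list with `retained` and `excluded` fragment tables (a
#'   partition of the input).
#' @export
filter_structural_rna <- function(fragments, structural_ref, seed_k = 16L,
                                  min_identity = 0.90, min_length = 60L) {
  if (is(structural_ref, "DNAStringSet")) {
    structural_ref <- as.character(structural_ref)
  }
  if (length(structural_ref) == 0) {
    stop("filter_structural_rna: structural reference set is empty")
  }
  structural_ref <- normalize_seq(structural_ref)
  seed_index <- build_seed_index(structural_ref, seed_k)
  hit <- vapply(fragments$sequence, function(fr) {
    matches_structural(fr, structural_ref, seed_index, seed_k,
                       min_identity, min_length) ||
      matches_structural(revcomp(fr), structural_ref, seed_index, seed_k,
                         min_identity, min_length)
  }, logical(1))
  list(retained = fragments[!hit, , drop = FALSE],
       excluded = fragments[hit, , drop = FALSE])
}

build_seed_index <- function(refs, k) {
  idx <- new.env(parent = emptyenv(), hash = TRUE)
  for (r in seq_along(refs)) {
    L <- nchar(refs[r])
    if (L < k) next
    starts <- seq_len(L - k + 1L)
    kmers <- substring(refs[r], starts, starts + k - 1L)
    for (p in seq_along(kmers)) {
      key <- kmers[p]
      idx[[key]] <- rbind(idx[[key]], c(r, p))
    }
  }
  idx
}

matches_structural <- function(frag, refs, seed_index, k, min_identity,
                               min_length) {
  L <- nchar(frag)
  if (L < k) return(FALSE)
  starts <- seq_len(L - k + 1L)
  kmers <- substring(frag, starts, starts + k - 1L)
  seen_diag <- character()
  for (p in seq_along(kmers)) {
    hits <- seed_index[[kmers[p]]]
    if (is.null(hits)) next
    for (h in seq_len(nrow(hits))) {
      r <- hits[h, 1]; rp <- hits[h, 2]
      diag_id <- paste0(r, ":", p - rp)
      if (diag_id %in% seen_diag) next
      seen_diag <- c(seen_diag, diag_id)
      if (diagonal_hit(frag, refs[r], p, rp, min_identity, min_length)) {
        return(TRUE)
      }
    }
  }
  FALSE
}

# Test all ungapped windows of length >= min_length on the diagonal through
# (frag pos fp, ref pos rp), 1-based.
diagonal_hit <- function(frag, ref, fp, rp, min_identity, min_length) {
  off <- fp - rp  # frag position = ref position + off
  r1 <- max(1L, 1L - off)
  r2 <- min(nchar(ref), nchar(frag) - off)
  if (r2 - r1 + 1L < min_length) return(FALSE)
  f <- strsplit(substring(frag, r1 + off, r2 + off), "")[[1]]
  r <- strsplit(substring(ref, r1, r2), "")[[1]]
  match <- as.integer(f == r)
  cs <- c(0L, cumsum(match))
  n <- length(match)
  for (w in seq.int(min_length, n)) {
    wins <- cs[(w + 1L):(n + 1L)] - cs[1:(n - w + 1L)]
    if (any(wins / w >= min_identity)) return(TRUE)
  }
  FALSE
}

#' Merge screened fragments into predicted loci
#'
#' Per scaffold, fragment intervals sharing at least one base are
#' transitively merged; touching end-to-start intervals are not merged
#' (half-open convention). Loci are returned sorted by scaffold and start.
#'
#' @param passed_fragments fragment table (typically the rows with
#'   `passed == TRUE`).
#' @return data.frame of loci: locus_id, scaffold, start, end, kind,
#'   n_fragments, member_fragments (comma-separated ids).
#' @export
merge_predicted_loci <- function(passed_fragments) {
  if (!nrow(passed_fragments)) {
    return(data.frame(locus_id = character(), scaffold = character(),
                      start = integer(), end = integer(), kind = character(),
                      n_fragments = integer(), member_fragments = character(),
                      stringsAsFactors = FALSE))
  }
  out <- list()
  for (sc in sort(unique(passed_fragments$scaffold))) {
    fr <- passed_fragments[passed_fragments$scaffold == sc, , drop = FALSE]
    ir <- to_iranges(fr$start, fr$end)
    merged <- IRanges::reduce(ir, min.gapwidth = 0L)
    ov <- IRanges::findOverlaps(ir, merged)
    grp <- S4Vectors::subjectHits(ov)[order(S4Vectors::queryHits(ov))]
    for (g in seq_along(merged)) {
      members <- fr[grp == g, , drop = FALSE]
      members <- members[order(members$start), , drop = FALSE]
      kind <- names(sort(table(members$kind), decreasing = TRUE))[1]
      out[[length(out) + 1L]] <- data.frame(
        scaffold = sc, start = from_iranges_start(merged[g]),
        end = from_iranges_end(merged[g]), kind = kind,
        n_fragments = nrow(members),
        member_fragments = paste(members$fragment_id, collapse = ","),
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  res <- res[order(res$scaffold, res$start), , drop = FALSE]
  res <- cbind(locus_id = sprintf("locus%05d", seq_len(nrow(res))), res,
               stringsAsFactors = FALSE)
  rownames(res) <- NULL
  res
}
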