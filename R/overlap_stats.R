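#' Match predicted loci against reference pre-miRNA sets
#'
#' A reference pre-miRNA counts as found when some predicted locus (1)
#' shares its scaffold, (2) overlaps it over more than
#' `min_overlap_fraction` of the reference length (or of the shorter
#' sequence, see `denominator`), and (3) shows at most `max_mismatch`
#' substitutions between the overlapping segments, compared ungapped and
#' position-wise.
#'
#' @param loci predicted-locus table from [merge_predicted_loci()].
#' @param references data.frame with ref_id, scaffold, start, end, sequence,
#'   source_label (and optionally family); coordinates 0-based half-open.
#' @param genome genome container supplying the locus-side sequence.
#' @param min_overlap_fraction overlap threshold, exceeded strictly
#'   (default 0.60).
#' @param max_mismatch substitution cap in the overlap (default 2).
#' @param denominator "reference" (default) or "shorter".
#' @return list with `matches` (ref_id, locus_id, overlap_fraction,
#'   mismatches_in_overlap) and `found` (X per source_label: distinct
#'   references matched).
#' @export
match_reference_loci <- function(loci, references, genome,
                                 min_overlap_fraction = 0.60,
                                 max_mismatch = 2L,
                                 denominator = c("reference", "shorter")) {
  denominator <- match.arg(denominator)
  lens <- genome_lengths(genome)
  matches <- list()
  for (i in seq_len(nrow(references))) {
    ref <- references[i, ]
    if (!ref$scaffold %in% names(lens)) {
      message("reference ", ref$ref_id, " on unknown scaffold ",
              ref$scaffold, "; counted unfound")
      next
    }
    cand <- loci[loci$scaffold == ref$scaffold, , drop = FALSE]
    if (!nrow(cand)) next
    os <- pmax(cand$start, ref$start)
    oe <- pmin(cand$end, ref$end)
    ov <- pmax(0L, oe - os)
    denom <- if (denominator == "reference") ref$end - ref$start else
      pmin(ref$end - ref$start, cand$end - cand$start)
    frac <- ov / denom
    for (j in which(frac > min_overlap_fraction)) {
      ref_seg <- substring(ref$sequence, os[j] - ref$start + 1L,
                           oe[j] - ref$start)
      locus_seg <- genome_slice(genome, ref$scaffold, os[j], oe[j])
      mm <- hamming(toupper(ref_seg), toupper(locus_seg))
      if (mm <= max_mismatch) {
        matches[[length(matches) + 1L]] <- data.frame(
          ref_id = ref$ref_id, locus_id = cand$locus_id[j],
          source_label = ref$source_label,
          overlap_fraction = frac[j], mismatches_in_overlap = mm,
          stringsAsFactors = FALSE)
      }
    }
  }
  matches <- if (length(matches)) do.call(rbind, matches) else
    data.frame(ref_id = character(), locus_id = character(),
               source_label = character(), overlap_fraction = numeric(),
               mismatches_in_overlap = integer(), stringsAsFactors = FALSE)
  found <- vapply(split(matches$ref_id, matches$source_label),
                  function(x) length(unique(x)), integer(1))
  all_labels <- unique(references$source_label)
  X <- setNames(integer(length(all_labels)), all_labels)
  X[names(found)] <- found
  list(matches = matches, found = X)
}

#' Hypergeometric overlap test
#'
#' Probability model for recovering known pre-miRNAs among predicted loci:
#' drawing `n` loci without replacement from `N` investigated fragments of
#' which `k` carry a known pre-miRNA, and observing `X` known ones. Both
#' the point probability P(x = X) and the upper tail P(x >= X) are
#' returned; the point probability is what published per-study overlap
#' tables of this form print, while the upper tail is the significance of
#' "X or more".
#'
#' @param N total investigated fragments.
#' @param k known pre-miRNAs (successes in the population).
#' @param n predicted loci drawn.
#' @param X known pre-miRNAs recovered.
#' @return an `overlap_test` list: N, k, n, X, p_point, p_tail.
#' @export
overlap_significance <- function(N, k, n, X) {
  if (k < 0 || k > N || n < 0 || n > N) {
    stop("overlap_significance: need 0 <= k <= N and 0 <= n <= N")
  }
  if (X < 0 || X > min(n, k)) {
    stop("overlap_significance: impossible X (must lie in [0, min(n, k)])")
  }
  structure(list(
    N = N, k = k, n = n, X = X,
    p_point = dhyper(X, k, N - k, n),
    p_tail = phyper(X - 1, k, N - k, n, lower.tail = FALSE)),
    class = "overlap_test")
}

#' @export
print.overlap_test <- function(x, ...) {
  cat(sprintf(
    "hypergeometric overlap test: X = %d of k = %d references among n = %d draws from N = %d\n",
    x$X, x$k, x$n, x$N))
  cat(sprintf("  P(x = X)  = %.6g\n  P(x >= X) = %.6g\n", x$p_point, x$p_tail))
  invisible(x)
}

#' Overlap tests for every reference source
#'
#' @param found named integer vector of X per source_label (from
#'   [match_reference_loci()]).
#' @param k named integer vector of reference-set sizes per source_label.
#' @param N total investigated fragments.
#' @param n predicted loci drawn.
#' @return data.frame with one row per source_label: k, X, p_point, p_tail.
#' @export
overlap_test_table <- function(found, k, N, n) {
  labels <- names(found)
  rows <- lapply(labels, function(lb) {
    t <- overlap_significance(N, k[[lb]], n, found[[lb]])
    data.frame(source_label = lb, N = N, n = n, k = t$k, X = t$X,
               p_point = t$p_point, p_tail = t$p_tail,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
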