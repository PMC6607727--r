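# Minimum Hamming distance over all ungapped placements of `query` inside
# `subject`; optionally also against the reverse complement of the query.
# Returns +Inf when the query is longer than the subject.
min_hamming_placement <- function(query, subject, both_strands = TRUE) {
  lq <- nchar(query); ls <- nchar(subject)
  if (lq > ls) return(Inf)
  qs <- if (both_strands) c(query, revcomp(query)) else query
  best <- Inf
  sub_chars <- strsplit(subject, "")[[1]]
  for (q in qs) {
    q_chars <- strsplit(q, "")[[1]]
    for (s in 0:(ls - lq)) {
      d <- sum(q_chars != sub_chars[(s + 1):(s + lq)])
      if (d < best) best <- d
    }
  }
  best
}

#' Expression support from small-RNA reads
#'
#' A read counts for a mature candidate when it covers 100% of the
#' candidate's length (the full candidate occurs ungapped within the read)
#' with at most `max_mismatch` substitutions, on either strand. A candidate
#' is supported when at least `min_reads` reads count.
#'
#' @param matures data.frame with mature_id and sequence.
#' @param reads character vector of read sequences (a multiset; duplicates
#'   count separately).
#' @param max_mismatch substitution cap per read (default 3).
#' @param min_reads depth threshold (default 10).
#' @param both_strands match reads on both strands.
#' @return data.frame: mature_id, read_depth, max_mismatch_seen,
#'   coverage_fraction (1 for counting reads by construction), supported.
#' @export
support_small_rna <- function(matures, reads, max_mismatch = 3L,
                              min_reads = 10L, both_strands = TRUE) {
  rows <- lapply(seq_len(nrow(matures)), function(i) {
    m <- matures$sequence[i]
    dists <- vapply(reads, function(r) {
      min_hamming_placement(m, r, both_strands = both_strands)
    }, numeric(1), USE.NAMES = FALSE)
    counting <- dists <= max_mismatch
    data.frame(mature_id = matures$mature_id[i],
               read_depth = sum(counting),
               max_mismatch_seen = if (any(counting))
                 as.integer(max(dists[counting])) else NA_integer_,
               coverage_fraction = if (any(counting)) 1 else 0,
               supported = sum(counting) >= min_reads,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Expression support from aligned total-RNA reads
#'
#' Alignments are consumed as interval records (an external aligner's
#' output or the synthetic exact-matcher). A candidate is supported when at
#' least `min_coverage` of its genomic positions are covered by at least
#' one read and at least `min_reads` reads overlap it.
#'
#' @param matures data.frame with mature_id, scaffold, start, end (0-based
#'   half-open genomic coordinates).
#' @param alignments data.frame with read_id, scaffold, start, end.
#' @param min_coverage covered-position fraction threshold (default 0.60).
#' @param min_reads overlapping-read threshold (default 10).
#' @return data.frame: mature_id, read_depth, coverage_fraction, supported.
#' @export
support_total_rna <- function(matures, alignments, min_coverage = 0.60,
                              min_reads = 10L) {
  need <- c("scaffold", "start", "end")
  if (!all(need %in% names(matures)) || !all(need %in% names(alignments))) {
    stop("support_total_rna: matures and alignments need scaffold/start/end")
  }
  rows <- lapply(seq_len(nrow(matures)), function(i) {
    m <- matures[i, ]
    al <- alignments[alignments$scaffold == m$scaffold &
                       alignments$end > m$start &
                       alignments$start < m$end, , drop = FALSE]
    L <- m$end - m$start
    depth <- integer(L)
    for (j in seq_len(nrow(al))) {
      a <- max(al$start[j], m$start) - m$start + 1L
      b <- min(al$end[j], m$end) - m$start
      depth[a:b] <- depth[a:b] + 1L
    }
    cov <- mean(depth >= 1L)
    data.frame(mature_id = m$mature_id, read_depth = nrow(al),
               coverage_fraction = cov,
               supported = cov >= min_coverage && nrow(al) >= min_reads,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Conservation against known plant mature miRNAs
#'
#' A hit requires the plant mature to align ungapped within the candidate
#' with 100% of the plant mature covered and at most `max_mismatch` total
#' substitutions (best placement wins). All qualifying (candidate, plant)
#' pairs are reported with the family taken from the plant record.
#'
#' @param matures data.frame with mature_id and sequence.
#' @param plant_matures data.frame with mirna_id, family, sequence (e.g.
#'   from [read_mature_catalog()]).
#' @param max_mismatch substitution cap (default 3).
#' @param both_strands also match the reverse complement.
#' @return data.frame: mature_id, plant_mirna_id, family, mismatches.
#' @export
match_conserved <- function(matures, plant_matures, max_mismatch = 3L,
                            both_strands = TRUE) {
  rows <- list()
  for (i in seq_len(nrow(matures))) {
    cand <- matures$sequence[i]
    for (j in seq_len(nrow(plant_matures))) {
      d <- min_hamming_placement(plant_matures$sequence[j], cand,
                                 both_strands = both_strands)
      if (d <= max_mismatch) {
        rows[[length(rows) + 1L]] <- data.frame(
          mature_id = matures$mature_id[i],
          plant_mirna_id = plant_matures$mirna_id[j],
          family = plant_matures$family[j],
          mismatches = as.integer(d), stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(mature_id = character(), plant_mirna_id = character(),
                      family = character(), mismatches = integer(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}
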