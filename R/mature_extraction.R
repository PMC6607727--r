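#' Duplex acceptance criteria
#'
#' The three stem criteria for a miRNA duplex: both strands longer than 15
#' nt, asymmetric bulges of at most 2 nt, and at most 4 nt of mismatch.
#' Mismatches are counted as `min(a, b)` per internal loop (opposed
#' unpaired bases on the two arms), summed over the stem window; the bulge
#' constraint applies per event as `|a - b| <= max_asym_bulge`
#' (`asym_mode = "total"` instead bounds the summed asymmetry).
#'
#' @param min_strand_length minimum arm length in nt (16, i.e. "> 15").
#' @param max_asym_bulge maximum asymmetry of a bulge event in nt.
#' @param max_mismatch maximum total mismatch in nt.
#' @param asym_mode "per_event" (default) or "total".
#' @return a `duplex_criteria` list.
#' @export
duplex_criteria <- function(min_strand_length = 16L, max_asym_bulge = 2L,
                            max_mismatch = 4L,
                            asym_mode = c("per_event", "total")) {
  asym_mode <- match.arg(asym_mode)
  if (min_strand_length < 0 || max_asym_bulge < 0 || max_mismatch < 0) {
    stop("duplex_criteria: thresholds must be non-negative")
  }
  structure(list(min_strand_length = as.integer(min_strand_length),
                 max_asym_bulge = as.integer(max_asym_bulge),
                 max_mismatch = as.integer(max_mismatch),
                 asym_mode = asym_mode),
            class = "duplex_criteria")
}

#' Find stem-loops in a secondary structure
#'
#' A stem is a maximal run of nested pairs enclosing a single hairpin loop:
#' starting from each hairpin-closing pair the run is extended outwards
#' through interior loops and bulges of at most `max_gap` unpaired bases per
#' side, stopping at branch points (multiloops) or larger gaps.
#'
#' @param struct a `secondary_structure` from [fold_rna()].
#' @param max_gap largest unpaired run (per side) bridged within one stem.
#' @return list of stems, each with `pairs` (two-column 0-based matrix,
#'   outermost to innermost), `arm5`, `arm3`, `loop` intervals (0-based
#'   half-open, local coordinates), ordered 5' to 3' by arm5 start.
#' @export
find_stems <- function(struct, max_gap = 10L) {
  pt <- struct$pair_table
  n <- length(pt)
  if (!any(pt >= 0)) return(list())
  # hairpin-closing pairs: (i, j) paired with everything strictly inside
  # unpaired
  closing <- integer()
  for (i in which(pt > seq_len(n) - 1L)) {
    j <- pt[i] + 1L
    inner <- if (i + 1L <= j - 1L) seq.int(i + 1L, j - 1L) else integer()
    if (all(pt[inner] == -1L)) closing <- c(closing, i)
  }
  stems <- lapply(closing, function(i1) {
    j1 <- pt[i1] + 1L
    pairs <- matrix(c(i1 - 1L, j1 - 1L), ncol = 2)  # innermost first
    ci <- i1; cj <- j1
    repeat {
      # scan outwards over unpaired bases on both sides
      i2 <- ci - 1L
      while (i2 >= 1L && pt[i2] == -1L && (ci - i2) <= max_gap + 1L) {
        i2 <- i2 - 1L
      }
      j2 <- cj + 1L
      while (j2 <= n && pt[j2] == -1L && (j2 - cj) <= max_gap + 1L) {
        j2 <- j2 + 1L
      }
      if (i2 < 1L || j2 > n) break
      gap5 <- ci - i2 - 1L
      gap3 <- j2 - cj - 1L
      if (gap5 > max_gap || gap3 > max_gap) break
      if (pt[i2] != j2 - 1L) break  # branch point or foreign helix
      pairs <- rbind(pairs, c(i2 - 1L, j2 - 1L))
      ci <- i2; cj <- j2
    }
    pairs <- pairs[rev(seq_len(nrow(pairs))), , drop = FALSE]  # outermost first
    m <- nrow(pairs)
    list(pairs = pairs,
         arm5 = c(pairs[1, 1], pairs[m, 1] + 1L),
         arm3 = c(pairs[m, 2], pairs[1, 2] + 1L),
         loop = c(pairs[m, 1] + 1L, pairs[m, 2]))
  })
  stems[order(vapply(stems, function(s) s$arm5[1], numeric(1)))]
}

# Gap sizes between consecutive pairs of a stem: for pairs t and t+1
# (outermost to innermost), a = unpaired bases on the 5' arm, b = on the 3'
# arm.
stem_gaps <- function(stem) {
  p <- stem$pairs
  m <- nrow(p)
  if (m < 2) return(data.frame(a = integer(), b = integer()))
  data.frame(a = p[-1, 1] - p[-m, 1] - 1L,
             b = p[-m, 2] - p[-1, 2] - 1L)
}

# Criteria bookkeeping for the pair window [p, q] of a stem.
window_stats <- function(stem, p, q, gaps) {
  pr <- stem$pairs
  idx <- if (q > p) seq.int(p, q - 1L) else integer()
  a <- gaps$a[idx]; b <- gaps$b[idx]
  list(npairs = q - p + 1L,
       arm5_len = pr[q, 1] - pr[p, 1] + 1L,
       arm3_len = pr[p, 2] - pr[q, 2] + 1L,
       mismatch = sum(pmin(a, b)),
       asym = abs(a - b),
       bulges = data.frame(size5 = a, size3 = b)[a != b, , drop = FALSE])
}

window_ok <- function(st, criteria) {
  asym_ok <- if (criteria$asym_mode == "per_event") {
    all(st$asym <= criteria$max_asym_bulge)
  } else {
    sum(st$asym) <= criteria$max_asym_bulge
  }
  st$arm5_len >= criteria$min_strand_length &&
    st$arm3_len >= criteria$min_strand_length &&
    st$mismatch <= criteria$max_mismatch && asym_ok
}

#' Extract the miRNA duplex from a stem
#'
#' Walks consecutive pairs outermost to innermost, accounting mismatches
#' and bulge events between pairs, and returns the longest contiguous
#' pair-window whose induced arms satisfy the criteria (ties resolved
#' towards the loop). Returns NULL when no window qualifies.
#'
#' @param stem a stem from [find_stems()].
#' @param sequence the folded sequence (local coordinates of the stem).
#' @param criteria a [duplex_criteria()].
#' @return a `duplex` list (arm sequences and local intervals, mismatch
#'   total, bulges, pair count) or NULL.
#' @export
extract_duplex <- function(stem, sequence, criteria = duplex_criteria()) {
  m <- nrow(stem$pairs)
  gaps <- stem_gaps(stem)
  best <- NULL
  for (p in seq_len(m)) {
    for (q in seq.int(p, m)) {
      st <- window_stats(stem, p, q, gaps)
      if (!window_ok(st, criteria)) next
      if (is.null(best) || st$npairs > best$st$npairs ||
          (st$npairs == best$st$npairs &&
           (q > best$q || (q == best$q && p > best$p)))) {
        best <- list(p = p, q = q, st = st)
      }
    }
  }
  if (is.null(best)) return(NULL)
  pr <- stem$pairs
  arm5 <- c(pr[best$p, 1], pr[best$q, 1] + 1L)
  arm3 <- c(pr[best$q, 2], pr[best$p, 2] + 1L)
  structure(list(
    arm5_interval = arm5, arm3_interval = arm3,
    arm5_seq = substring(sequence, arm5[1] + 1L, arm5[2]),
    arm3_seq = substring(sequence, arm3[1] + 1L, arm3[2]),
    mismatch_total = best$st$mismatch,
    bulges = best$st$bulges,
    n_pairs = best$st$npairs), class = "duplex")
}

# Fold a locus sequence and pick the best stem-wise duplex. The forward
# strand is folded first; the reverse complement is consulted only when
# the forward fold yields no qualifying duplex (so a minus-strand
# precursor is still found, but a forward hit is never overridden by an
# opportunistic reverse-strand structure). Reverse-strand coordinates are
# mapped back to the forward strand.
fold_and_extract <- function(sequence, fold_cfg, criteria, max_gap = 10L,
                             scan_reverse = TRUE) {
  L <- nchar(sequence)
  strands <- if (scan_reverse) c("+", "-") else "+"
  best <- NULL
  for (strand in strands) {
    seq_s <- if (strand == "+") sequence else revcomp(sequence)
    struct <- fold_rna(seq_s, fold_cfg)
    stems <- find_stems(struct, max_gap = max_gap)
    for (stem in stems) {
      d <- extract_duplex(stem, struct$sequence, criteria)
      if (!is.null(d) && (is.null(best) || d$n_pairs > best$n_pairs)) best <- d
    }
    if (!is.null(best)) {
      best$strand <- strand
      break
    }
  }
  if (is.null(best)) return(NULL)
  if (best$strand == "-") {
    # map [s, e) on the reverse strand to forward coordinates
    flip <- function(iv) c(L - iv[2], L - iv[1])
    a5 <- flip(best$arm5_interval)
    a3 <- flip(best$arm3_interval)
    best$arm5_interval <- a3  # 5' arm of the reverse read lies 3' on forward
    best$arm3_interval <- a5
    tmp <- best$arm5_seq
    best$arm5_seq <- best$arm3_seq
    best$arm3_seq <- tmp
  }
  best
}

#' Extract a duplex from a predicted locus, retrying with end extension
#'
#' When the unextended locus yields no duplex, both ends are extended
#' symmetrically in 5-nt increments up to `max_extension` nt (clamped at
#' scaffold bounds), refolding and re-extracting each time; the first
#' success is returned with coordinates on the extended interval.
#'
#' @param locus one-row data.frame (locus_id, scaffold, start, end).
#' @param genome genome container.
#' @param fold_cfg a [fold_config()].
#' @param criteria a [duplex_criteria()].
#' @param max_extension largest end extension in nt (default 20).
#' @param ext_step extension increment in nt (default 5).
#' @param max_gap stem-walk gap limit, see [find_stems()].
#' @param scan_reverse also fold the reverse complement.
#' @return list(duplex, interval, extension) or NULL; `interval` is the
#'   (possibly extended) locus interval the duplex coordinates refer to.
#' @export
extract_locus_duplex <- function(locus, genome, fold_cfg = fold_config(),
                                 criteria = duplex_criteria(),
                                 max_extension = 20L, ext_step = 5L,
                                 max_gap = 10L, scan_reverse = TRUE) {
  lens <- genome_lengths(genome)
  L <- lens[[locus$scaffold]]
  for (ext in seq.int(0L, max_extension, by = ext_step)) {
    s <- max(0L, locus$start - ext)
    e <- min(L, locus$end + ext)
    seq <- genome_slice(genome, locus$scaffold, s, e)
    d <- fold_and_extract(seq, fold_cfg, criteria, max_gap, scan_reverse)
    if (!is.null(d)) {
      return(list(duplex = d, interval = c(s, e), extension = ext))
    }
  }
  NULL
}

#' Enumerate putative mature miRNAs from a duplex
#'
#' Exactly two candidates are produced: the 5p arm read on the forward
#' strand and the 3p arm read, by default, as the reverse-complement strand
#' 5'->3' (the biological convention; set `threep_revcomp = FALSE` for the
#' forward-strand substring).
#'
#' @param duplex a `duplex`, e.g. from [extract_locus_duplex()].
#' @param locus_id locus identifier used to build deterministic mature ids.
#' @param locus_start genomic start (0-based) of the interval the duplex
#'   coordinates refer to.
#' @param threep_revcomp report the 3p product on the reverse strand.
#' @return data.frame with mature_id, locus_id, arm, sequence, scaffold
#'   columns absent, genomic start/end (0-based half-open).
#' @export
enumerate_matures <- function(duplex, locus_id, locus_start = 0L,
                              threep_revcomp = TRUE) {
  seq3 <- if (threep_revcomp) revcomp(duplex$arm3_seq) else duplex$arm3_seq
  data.frame(
    mature_id = paste0(locus_id, "-", c("5p", "3p")),
    locus_id = locus_id,
    arm = c("5p", "3p"),
    sequence = c(duplex$arm5_seq, seq3),
    start = locus_start + c(duplex$arm5_interval[1], duplex$arm3_interval[1]),
    end = locus_start + c(duplex$arm5_interval[2], duplex$arm3_interval[2]),
    stringsAsFactors = FALSE)
}
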