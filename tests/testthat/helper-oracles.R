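# Independent oracles and small constructors used across the suite.
# These re-derive expected values through separate code paths from the
# package implementation.

# --- designed hairpin: arm + loop + reverse complement of arm ------------
make_hairpin <- function(arm, loop = "AAAA", pad5 = "", pad3 = "") {
  paste0(pad5, arm, loop, revcomp(arm), pad3)
}

# --- brute-force scorer for the stem-loop folding objective --------------
# Recursive with memoisation; written independently of the C++ tables
# (top-down instead of bottom-up, same objective definition).
oracle_fold_score <- function(seq, cfg = fold_config()) {
  s <- strsplit(seq, "")[[1]]
  n <- length(s)
  w <- function(a, b) {
    key <- paste0(a, b)
    if (key %in% c("GC", "CG")) cfg$pair_weights[["GC"]]
    else if (key %in% c("AT", "TA")) cfg$pair_weights[["AU"]]
    else if (key %in% c("GT", "TG")) cfg$pair_weights[["GU"]]
    else 0
  }
  Cmemo <- matrix(NA_real_, n, n)
  closed <- function(i, j) {  # score of [i,j] given (i,j) paired; -Inf if not pairable
    if (j - i - 1 < cfg$min_loop) return(-Inf)
    wij <- w(s[i], s[j])
    if (wij == 0) return(-Inf)
    if (!is.na(Cmemo[i, j])) return(Cmemo[i, j])
    best <- -cfg$hairpin_penalty
    for (k in (i + 1):(j - 1)) {
      for (l in (k + 1):(j - 1)) {
        g <- (k - i - 1) + (j - l - 1)
        if (g > cfg$max_interior) next
        inner <- closed(k, l)
        if (!is.finite(inner)) next
        adj <- if (g == 0) cfg$stack_bonus else
          -(cfg$interior_open + cfg$interior_per_nt * g)
        if (inner + adj > best) best <- inner + adj
      }
    }
    Cmemo[i, j] <<- wij + best
    wij + best
  }
  E <- numeric(n + 1)  # E[j+1]: best for prefix 1..j
  for (j in seq_len(n)) {
    best <- E[j]
    for (i in seq_len(j)) {
      cv <- closed(i, j)
      if (is.finite(cv)) best <- max(best, E[i] + cv)
    }
    E[j + 1] <- best
  }
  E[n + 1]
}

# --- synthetic stems and an exhaustive duplex oracle ---------------------
# Build a stem object directly from per-junction gap sizes, bypassing
# folding entirely: gaps5/gaps3 give the unpaired bases between
# consecutive pairs (outermost to innermost).
make_stem <- function(n_pairs, gaps5 = integer(n_pairs - 1),
                      gaps3 = integer(n_pairs - 1), start5 = 0L,
                      loop_len = 4L) {
  i <- start5
  pos5 <- integer(n_pairs)
  for (t in seq_len(n_pairs)) {
    pos5[t] <- i
    i <- i + 1L + if (t < n_pairs) gaps5[t] else 0L
  }
  j <- pos5[n_pairs] + loop_len + 1L
  pos3 <- integer(n_pairs)
  for (t in rev(seq_len(n_pairs))) {
    pos3[t] <- j
    j <- j + 1L + if (t > 1) gaps3[t - 1] else 0L
  }
  pairs <- cbind(pos5, pos3)
  m <- n_pairs
  list(pairs = pairs,
       arm5 = c(pairs[1, 1], pairs[m, 1] + 1L),
       arm3 = c(pairs[m, 2], pairs[1, 2] + 1L),
       loop = c(pairs[m, 1] + 1L, pairs[m, 2]))
}

random_stem <- function(max_pairs = 40L) {
  m <- sample(2:max_pairs, 1)
  # mixture of clean junctions and small/large gaps
  g5 <- sample(0:4, m - 1, replace = TRUE, prob = c(.6, .15, .1, .1, .05))
  g3 <- sample(0:4, m - 1, replace = TRUE, prob = c(.6, .15, .1, .1, .05))
  make_stem(m, g5, g3, start5 = sample(0:5, 1), loop_len = sample(3:8, 1))
}

# A dummy sequence long enough to cover a stem's coordinates (base content
# is irrelevant to window selection; only intervals matter).
stem_cover_seq <- function(stem) {
  strrep("A", stem$arm3[2] + 2L)
}

# Exhaustive oracle: enumerate every contiguous pair-window, re-derive arm
# lengths, mismatch and bulge accounting directly from the pair
# coordinates, apply the criteria, and pick the winner under the declared
# rule (most pairs; ties towards the loop: larger end, then larger start).
oracle_duplex <- function(stem, criteria = duplex_criteria()) {
  pr <- stem$pairs
  m <- nrow(pr)
  best <- NULL
  for (p in seq_len(m)) {
    for (q in p:m) {
      ok <- TRUE
      mism <- 0L
      if (q > p) {
        for (t in p:(q - 1)) {
          a <- pr[t + 1, 1] - pr[t, 1] - 1L
          b <- pr[t, 2] - pr[t + 1, 2] - 1L
          mism <- mism + min(a, b)
          if (criteria$asym_mode == "per_event") {
            if (a != b && abs(a - b) > criteria$max_asym_bulge) ok <- FALSE
          }
        }
        if (criteria$asym_mode == "total") {
          asum <- 0L
          for (t in p:(q - 1)) {
            a <- pr[t + 1, 1] - pr[t, 1] - 1L
            b <- pr[t, 2] - pr[t + 1, 2] - 1L
            asum <- asum + abs(a - b)
          }
          if (asum > criteria$max_asym_bulge) ok <- FALSE
        }
      }
      len5 <- pr[q, 1] - pr[p, 1] + 1L
      len3 <- pr[p, 2] - pr[q, 2] + 1L
      if (len5 < criteria$min_strand_length) ok <- FALSE
      if (len3 < criteria$min_strand_length) ok <- FALSE
      if (mism > criteria$max_mismatch) ok <- FALSE
      if (!ok) next
      cand <- list(p = p, q = q, npairs = q - p + 1L, mismatch = mism)
      if (is.null(best) || cand$npairs > best$npairs ||
          (cand$npairs == best$npairs &&
           (cand$q > best$q || (cand$q == best$q && cand$p > best$p)))) {
        best <- cand
      }
    }
  }
  if (is.null(best)) return(NULL)
  list(arm5_interval = c(pr[best$p, 1], pr[best$q, 1] + 1L),
       arm3_interval = c(pr[best$q, 2], pr[best$p, 2] + 1L),
       mismatch_total = best$mismatch, n_pairs = best$npairs)
}

# --- dinucleotide shuffle (Euler-path walk, bounded retries) -------------
dinucleotide_shuffle <- function(seq, max_tries = 100L) {
  s <- strsplit(seq, "")[[1]]
  n <- length(s)
  if (n < 3) return(seq)
  edges <- split(s[-1], s[-n])  # outgoing edges per node
  for (try in seq_len(max_tries)) {
    pool <- lapply(edges, sample)
    out <- character(n)
    out[1] <- s[1]
    ok <- TRUE
    for (i in 2:n) {
      u <- out[i - 1]
      if (!length(pool[[u]])) { ok <- FALSE; break }
      out[i] <- pool[[u]][1]
      pool[[u]] <- pool[[u]][-1]
    }
    if (ok && !any(lengths(pool) > 0)) return(paste(out, collapse = ""))
  }
  # fall back to the identity permutation of edges (original sequence)
  seq
}

# --- exhaustive hypergeometric by draw enumeration (N <= 20) -------------
enum_hyper <- function(N, k, n, X) {
  draws <- utils::combn(N, n)
  succ <- seq_len(k)  # first k items are the successes
  counts <- apply(draws, 2, function(d) sum(d %in% succ))
  c(p_point = mean(counts == X), p_tail = mean(counts >= X))
}
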