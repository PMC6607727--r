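#' Folding configuration
#'
#' The built-in folder computes the best-scoring chain of nested
#' stem-loops under a lightweight additive model: pair weights
#' (GC > AU > GU by default) plus a helix-stacking bonus, minus penalties
#' for opening hairpin and interior loops. Loop penalties are what let a
#' genuine stem-loop out-compete scattered opportunistic pairings in
#' flanking sequence; multiloops and pseudoknots are outside the model.
#' The traceback is fixed and deterministic. The folder is an
#' engine-agnostic structure contract: set `backend = "external"` and
#' supply `structures` (a dot-bracket lookup, see [read_dotbracket()]) to
#' inject structures computed elsewhere.
#'
#' @param min_loop minimum number of unpaired positions in a hairpin loop
#'   (default 3).
#' @param pair_weights named numeric weights for GC, AU and GU pairs.
#' @param stack_bonus extra weight for each pair stacked directly on the
#'   previous one (default 1).
#' @param hairpin_penalty cost of closing a hairpin loop (default 8).
#' @param interior_open,interior_per_nt cost of an interior loop or bulge
#'   within a stem: `interior_open + interior_per_nt * total_gap`
#'   (defaults 2 and 1.5). Small symmetric mismatches and 1-2 nt bulges
#'   stay cheap; the larger gaps needed to chain unrelated helices are
#'   priced out.
#' @param max_interior largest total unpaired gap (both sides summed) an
#'   interior loop may bridge, in nt (default 30).
#' @param backend "builtin" or "external".
#' @param structures for the external backend: a named list of
#'   `list(sequence, dotbracket)` records; lookup is by sequence.
#' @return a `fold_config` list.
#' @export
fold_config <- function(min_loop = 3L,
                        pair_weights = c(GC = 3, AU = 2, GU = 1),
                        stack_bonus = 1,
                        hairpin_penalty = 8,
                        interior_open = 2,
                        interior_per_nt = 1.5,
                        max_interior = 30L,
                        backend = c("builtin", "external"),
                        structures = NULL) {
  backend <- match.arg(backend)
  if (min_loop < 3L) stop("fold_config: min_loop must be >= 3")
  if (any(pair_weights <= 0)) stop("fold_config: pair weights must be > 0")
  if (stack_bonus < 0) stop("fold_config: stack_bonus must be >= 0")
  if (hairpin_penalty < 0 || interior_open < 0 || interior_per_nt < 0) {
    stop("fold_config: loop penalties must be >= 0")
  }
  structure(list(min_loop = as.integer(min_loop),
                 pair_weights = pair_weights, stack_bonus = stack_bonus,
                 hairpin_penalty = hairpin_penalty,
                 interior_open = interior_open,
                 interior_per_nt = interior_per_nt,
                 max_interior = as.integer(max_interior),
                 backend = backend, structures = structures),
            class = "fold_config")
}

#' Fold a sequence into a secondary structure
#'
#' @param sequence nucleotide string (A/C/G/T/U; U is mapped to T
#'   internally). Must be at least 10 nt.
#' @param cfg a [fold_config()].
#' @return a `secondary_structure` list with `sequence`, `dotbracket`,
#'   `pair_table` (0-based partner index, -1 when unpaired) and `score`.
#' @export
fold_rna <- function(sequence, cfg = fold_config()) {
  sequence <- normalize_seq(sequence, allow_n = TRUE)
  if (nchar(sequence) < 10) stop("fold_rna: sequence shorter than 10 nt")
  if (cfg$backend == "external") {
    key <- which(vapply(cfg$structures, function(r) r$sequence == sequence,
                        logical(1)))
    if (!length(key)) {
      stop("fold_rna: no external structure recorded for this sequence")
    }
    rec <- cfg$structures[[key[1]]]
    pt <- dotbracket_to_pairs(rec$dotbracket)
    return(new_structure(sequence, rec$dotbracket, pt, score = NA_real_))
  }
  res <- .fold_stemloop(sequence, cfg$pair_weights[["GC"]],
                        cfg$pair_weights[["AU"]], cfg$pair_weights[["GU"]],
                        cfg$min_loop, cfg$stack_bonus, cfg$hairpin_penalty,
                        cfg$interior_open, cfg$interior_per_nt,
                        cfg$max_interior)
  pt <- res$pair_table
  new_structure(sequence, pairs_to_dotbracket(pt), pt, res$score)
}

new_structure <- function(sequence, dotbracket, pair_table, score) {
  structure(list(sequence = sequence, dotbracket = dotbracket,
                 pair_table = pair_table, score = score),
            class = "secondary_structure")
}

#' Convert a dot-bracket string to a pair table
#'
#' @param db dot-bracket string over `(`, `)`, `.`.
#' @return integer vector of 0-based partner positions (-1 unpaired).
#' @export
dotbracket_to_pairs <- function(db) {
  chars <- strsplit(db, "")[[1]]
  pt <- rep(-1L, length(chars))
  stack <- integer()
  for (i in seq_along(chars)) {
    if (chars[i] == "(") {
      stack <- c(stack, i)
    } else if (chars[i] == ")") {
      if (!length(stack)) stop("unbalanced dot-bracket string")
      j <- stack[length(stack)]
      stack <- stack[-length(stack)]
      pt[i] <- j - 1L
      pt[j] <- i - 1L
    } else if (chars[i] != ".") {
      stop("dot-bracket characters must be one of ( ) .")
    }
  }
  if (length(stack)) stop("unbalanced dot-bracket string")
  pt
}

#' @rdname dotbracket_to_pairs
#' @param pt 0-based pair table.
#' @export
pairs_to_dotbracket <- function(pt) {
  chars <- rep(".", length(pt))
  paired <- which(pt >= 0) - 1L
  open <- paired[pt[paired + 1L] > paired]
  chars[open + 1L] <- "("
  chars[pt[open + 1L] + 1L] <- ")"
  paste(chars, collapse = "")
}

#' Validate a secondary structure against its invariants
#'
#' Checks that the pair table is a self-inverse matching the dot-bracket,
#' that pairs are canonical (A:U, G:C) or wobble (G:U), and that hairpin
#' loops respect the minimum loop size.
#'
#' @param struct a `secondary_structure`.
#' @param cfg a [fold_config()] supplying `min_loop`.
#' @return TRUE invisibly; errors describe the violated invariant.
#' @export
validate_structure <- function(struct, cfg = fold_config()) {
  pt <- struct$pair_table
  n <- length(pt)
  if (nchar(struct$dotbracket) != n || nchar(struct$sequence) != n) {
    stop("structure fields disagree in length")
  }
  paired <- which(pt >= 0)
  if (any(pt[paired] < 0 | pt[pt[paired] + 1L] != paired - 1L)) {
    stop("pair table is not an involution")
  }
  if (!identical(dotbracket_to_pairs(struct$dotbracket), as.integer(pt))) {
    stop("pair table does not round-trip through the dot-bracket string")
  }
  s <- strsplit(struct$sequence, "")[[1]]
  open <- which(pt > seq_along(pt) - 1L)  # 1-based positions of '(' side
  if (length(open)) {
    j <- pt[open] + 1L
    if (!all(bases_pair(s[open], s[j]))) stop("non-canonical base pair present")
    for (o in open) {
      jj <- pt[o] + 1L
      inner <- if (o + 1L <= jj - 1L) seq.int(o + 1L, jj - 1L) else integer()
      if (all(pt[inner] == -1L) && length(inner) < cfg$min_loop) {
        stop("hairpin loop smaller than min_loop")
      }
    }
  }
  invisible(TRUE)
}
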