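#' @useDynLib premirscan, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom methods is
#' @importFrom stats dhyper phyper runif setNames
#' @importFrom utils read.delim write.table head
NULL

# All genomic coordinates inside the package are 0-based half-open
# [start, end); GFF3 (1-based closed) is converted at the I/O boundary.

DNA_BASES <- c("A", "C", "G", "T")

#' Reverse complement of plain character sequences
#'
#' @param x character vector of DNA sequences (A/C/G/T/N, U tolerated).
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  comp <- chartr("ACGTUNacgtun", "TGCAANtgcaan", x)
  vapply(strsplit(comp, "", fixed = TRUE),
         function(s) paste(rev(s), collapse = ""), character(1))
}

#' Hamming distance between equal-length strings
#' @param a,b equal-length character scalars.
#' @return integer count of mismatching positions.
#' @export
hamming <- function(a, b) {
  if (nchar(a) != nchar(b)) stop("hamming() requires equal-length strings")
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

# TRUE where the two bases can pair (Watson-Crick or G:U wobble).
bases_pair <- function(a, b) {
  (a == "A" & b == "T") | (a == "T" & b == "A") |
    (a == "G" & b == "C") | (a == "C" & b == "G") |
    (a == "G" & b == "T") | (a == "T" & b == "G")
}

# Normalise a nucleotide string: uppercase, U -> T; error on other letters.
normalize_seq <- function(x, allow_n = TRUE) {
  x <- chartr("u", "t", x)
  x <- toupper(x)
  x <- chartr("U", "T", x)
  ok <- if (allow_n) grepl("^[ACGTN]*$", x) else grepl("^[ACGT]*$", x)
  if (!all(ok)) {
    stop("sequence contains characters outside the A/C/G/T/U(/N) alphabet")
  }
  x
}

# Extract genome slice [start, end) (0-based half-open) from a DNAStringSet
# or a named character vector of scaffold sequences.
genome_slice <- function(genome, scaffold, start, end) {
  seqs <- genome_as_character(genome, scaffold)
  unname(substring(seqs, start + 1L, end))
}

genome_as_character <- function(genome, scaffold) {
  if (is(genome, "DNAStringSet")) {
    if (!all(scaffold %in% names(genome))) {
      stop("unknown scaffold: ",
           paste(setdiff(scaffold, names(genome)), collapse = ", "))
    }
    as.character(genome[scaffold])
  } else {
    if (!all(scaffold %in% names(genome))) {
      stop("unknown scaffold: ",
           paste(setdiff(scaffold, names(genome)), collapse = ", "))
    }
    unname(genome[scaffold])
  }
}

genome_lengths <- function(genome) {
  if (is(genome, "DNAStringSet")) {
    setNames(Biostrings::width(genome), names(genome))
  } else {
    setNames(nchar(genome), names(genome))
  }
}

# Run code with a locally-set RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# 0-based half-open data.frame columns (start, end) -> IRanges
to_iranges <- function(start, end) {
  IRanges::IRanges(start = start + 1L, end = end)
}
from_iranges_start <- function(ir) IRanges::start(ir) - 1L
from_iranges_end <- function(ir) IRanges::end(ir)
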