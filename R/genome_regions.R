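#' Windowing configuration
#'
#' Noncoding regions are chopped into fixed-length windows that overlap by
#' `overlap` nucleotides; the step between window starts is
#' `window_length - overlap`. Regions shorter than `min_region_length` are
#' skipped (lower it to emit short regions whole).
#'
#' @param window_length window size in nt (default 120).
#' @param overlap overlap between consecutive windows in nt (default 20).
#' @param min_region_length minimum region length to fragment; defaults to
#'   `window_length`.
#' @param max_n_fraction windows with more than this fraction of N bases are
#'   dropped (assembly gaps).
#' @return a `window_config` list.
#' @export
window_config <- function(window_length = 120L, overlap = 20L,
                          min_region_length = window_length,
                          max_n_fraction = 0.10) {
  window_length <- as.integer(window_length)
  overlap <- as.integer(overlap)
  if (overlap <= 0L || overlap >= window_length) {
    stop("window_config: need 0 < overlap < window_length")
  }
  structure(list(window_length = window_length, overlap = overlap,
                 step = window_length - overlap,
                 min_region_length = as.integer(min_region_length),
                 max_n_fraction = max_n_fraction),
            class = "window_config")
}

validate_genes <- function(genome, genes, exons = NULL) {
  lens <- genome_lengths(genome)
  unknown <- setdiff(genes$scaffold, names(lens))
  if (length(unknown) > 0) {
    bad <- genes$gene_id[genes$scaffold %in% unknown]
    stop("gene(s) on unknown scaffold: ", paste(bad, collapse = ", "))
  }
  out <- genes$end > lens[genes$scaffold] | genes$start < 0
  if (any(out)) {
    stop("gene span outside scaffold bounds: ",
         paste(genes$gene_id[out], collapse = ", "))
  }
  if (!is.null(exons) && nrow(exons) > 0) {
    key <- match(exons$gene_id, genes$gene_id)
    if (anyNA(key)) {
      stop("exon references unknown gene: ",
           paste(unique(exons$gene_id[is.na(key)]), collapse = ", "))
    }
    bad <- exons$start < genes$start[key] | exons$end > genes$end[key]
    if (any(bad)) {
      stop("exon outside its gene span: ",
           paste(unique(exons$gene_id[bad]), collapse = ", "))
    }
  }
  invisible(TRUE)
}

#' Extract intergenic and intronic noncoding regions
#'
#' Intergenic space is the per-scaffold complement of the union of gene
#' spans (so bases inside any gene, including overlapping genes, are never
#' intergenic). Intronic space is, per gene, the gaps between consecutive
#' exons after taking the union of that gene's exons.
#'
#' @param genome DNAStringSet or named character vector of scaffolds.
#' @param genes data.frame with gene_id, scaffold, start, end (0-based
#'   half-open), strand.
#' @param exons data.frame with gene_id, scaffold, start, end; may be NULL
#'   (no intronic regions are then produced).
#' @return data.frame with scaffold, start, end, kind
#'   (intergenic/intronic), source_gene (NA for intergenic).
#' @export
extract_noncoding <- function(genome, genes, exons = NULL) {
  validate_genes(genome, genes, exons)
  lens <- genome_lengths(genome)
  out <- list()
  for (sc in names(lens)) {
    g <- genes[genes$scaffold == sc, , drop = FALSE]
    full <- IRanges::IRanges(1L, lens[[sc]])
    spans <- if (nrow(g)) IRanges::reduce(to_iranges(g$start, g$end)) else
      IRanges::IRanges()
    inter <- IRanges::setdiff(full, spans)
    if (length(inter)) {
      out[[length(out) + 1L]] <- data.frame(
        scaffold = sc, start = from_iranges_start(inter),
        end = from_iranges_end(inter), kind = "intergenic",
        source_gene = NA_character_, stringsAsFactors = FALSE)
    }
  }
  if (!is.null(exons) && nrow(exons) > 0) {
    for (gid in unique(exons$gene_id)) {
      ge <- exons[exons$gene_id == gid, , drop = FALSE]
      ex <- IRanges::reduce(to_iranges(ge$start, ge$end))
      if (length(ex) < 2) next
      gaps <- IRanges::gaps(ex, start = min(IRanges::start(ex)),
                            end = max(IRanges::end(ex)))
      if (!length(gaps)) next
      out[[length(out) + 1L]] <- data.frame(
        scaffold = ge$scaffold[1], start = from_iranges_start(gaps),
        end = from_iranges_end(gaps), kind = "intronic",
        source_gene = gid, stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    return(data.frame(scaffold = character(), start = integer(),
                      end = integer(), kind = character(),
                      source_gene = character(), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res <- res[order(res$scaffold, res$start, res$kind), , drop = FALSE]
  rownames(res) <- NULL
  res
}

# Window start offsets for a region of length L: 0, step, 2*step, ... while
# start + window <= L; a final backward window [L - window, L) is appended
# when residual bases remain, and deduplicated if it coincides with an
# existing start.
window_starts <- function(L, cfg) {
  if (L < cfg$window_length) return(integer())
  starts <- seq.int(0L, L - cfg$window_length, by = cfg$step)
  last <- L - cfg$window_length
  if (starts[length(starts)] != last) starts <- c(starts, last)
  starts
}

#' Fragment one noncoding region into overlapping windows
#'
#' @param region one-row data.frame (or list) with scaffold, start, end,
#'   kind.
#' @param genome genome container.
#' @param cfg a [window_config()].
#' @return data.frame of fragments (fragment_id, scaffold, start, end, kind,
#'   sequence), 5'->3'; empty for regions shorter than
#'   `cfg$min_region_length`.
#' @export
fragment_region <- function(region, genome, cfg = window_config()) {
  L <- region$end - region$start
  empty <- data.frame(fragment_id = character(), scaffold = character(),
                      start = integer(), end = integer(), kind = character(),
                      sequence = character(), stringsAsFactors = FALSE)
  if (L < cfg$min_region_length) {
    message("skipping region ", region$scaffold, ":", region$start, "-",
            region$end, " shorter than ", cfg$min_region_length, " nt")
    return(empty)
  }
  if (L < cfg$window_length) {
    # only reachable when min_region_length was lowered: emit whole region
    starts <- 0L
    ends <- L
  } else {
    starts <- window_starts(L, cfg)
    ends <- starts + cfg$window_length
  }
  abs_start <- region$start + starts
  abs_end <- region$start + ends
  seqs <- genome_slice(genome, rep(region$scaffold, length(starts)),
                       abs_start, abs_end)
  df <- data.frame(
    fragment_id = sprintf("%s:%d-%d:%s", region$scaffold, abs_start, abs_end,
                          region$kind),
    scaffold = region$scaffold, start = abs_start, end = abs_end,
    kind = region$kind, sequence = seqs, stringsAsFactors = FALSE)
  nfrac <- vapply(strsplit(df$sequence, ""), function(s) mean(s == "N"),
                  numeric(1))
  drop <- nfrac > cfg$max_n_fraction
  if (any(drop)) {
    message(sum(drop), " fragment(s) dropped for >",
            round(100 * cfg$max_n_fraction), "% N content")
    df <- df[!drop, , drop = FALSE]
  }
  rownames(df) <- NULL
  df
}

#' Fragment all noncoding regions
#'
#' @param regions data.frame from [extract_noncoding()].
#' @param genome genome container.
#' @param cfg a [window_config()].
#' @return data.frame of all fragments, ordered by scaffold and start.
#' @export
fragment_noncoding <- function(regions, genome, cfg = window_config()) {
  parts <- lapply(seq_len(nrow(regions)), function(i) {
    fragment_region(regions[i, , drop = FALSE], genome, cfg)
  })
  df <- do.call(rbind, parts)
  if (is.null(df) || !nrow(df)) {
    return(data.frame(fragment_id = character(), scaffold = character(),
                      start = integer(), end = integer(), kind = character(),
                      sequence = character(), stringsAsFactors = FALSE))
  }
  df <- df[order(df$scaffold, df$start, df$kind), , drop = FALSE]
  rownames(df) <- NULL
  df
}
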