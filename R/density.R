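#' Genic and intergenic partition lengths
#'
#' `summation` mode takes the genic length as the plain sum of gene-span
#' lengths (the literal rule of summing the nucleotide bases of all
#' protein-coding genes); overlapping genes are then double-counted, so a
#' loud warning is emitted and `union` mode (merged-interval length) is
#' recommended whenever genes overlap.
#'
#' @param genome genome container.
#' @param genes gene table (gene_id, scaffold, start, end).
#' @param mode "summation" (default) or "union".
#' @return named list: genic, intergenic (base counts).
#' @export
genomic_partition_lengths <- function(genome, genes,
                                      mode = c("summation", "union")) {
  mode <- match.arg(mode)
  validate_genes(genome, genes)
  total <- sum(genome_lengths(genome))
  if (!nrow(genes)) return(list(genic = 0L, intergenic = total))
  union_len <- sum(vapply(split(genes, genes$scaffold), function(g) {
    sum(IRanges::width(IRanges::reduce(to_iranges(g$start, g$end))))
  }, numeric(1)))
  sum_len <- sum(genes$end - genes$start)
  if (mode == "summation") {
    if (sum_len != union_len) {
      warning("overlapping gene spans are double-counted in summation mode; ",
              "consider mode = \"union\"", call. = FALSE)
    }
    genic <- sum_len
  } else {
    genic <- union_len
  }
  intergenic <- total - genic
  if (intergenic < 0) {
    stop("summation-mode genic length exceeds the genome; ",
         "use mode = \"union\"")
  }
  list(genic = genic, intergenic = intergenic)
}

#' miRNA population density
#'
#' Density is the miRNA count per gigabase of the observed region:
#' `count * 1e9 / length_bases`.
#'
#' @param count number of miRNAs (or loci) in the region class.
#' @param length_bases region length in bases; must be positive.
#' @return density per gigabase.
#' @export
population_density <- function(count, length_bases) {
  if (any(length_bases <= 0)) {
    stop("population_density: region length must be positive")
  }
  count * 1e9 / length_bases
}

#' Per-region-class density report
#'
#' A locus is classed genic when its midpoint lies inside a gene span,
#' intergenic otherwise.
#'
#' @param loci locus table (scaffold, start, end).
#' @param genome genome container.
#' @param genes gene table.
#' @param mode partition mode, see [genomic_partition_lengths()].
#' @return data.frame with region_class, mirna_count, region_length_bases,
#'   density_per_gb.
#' @export
density_report <- function(loci, genome, genes,
                           mode = c("summation", "union")) {
  mode <- match.arg(mode)
  lens <- genomic_partition_lengths(genome, genes, mode)
  mid <- (loci$start + loci$end) %/% 2L
  genic <- logical(nrow(loci))
  for (sc in unique(loci$scaffold)) {
    g <- genes[genes$scaffold == sc, , drop = FALSE]
    i <- which(loci$scaffold == sc)
    if (!nrow(g)) next
    genic[i] <- vapply(mid[i], function(p) any(p >= g$start & p < g$end),
                       logical(1))
  }
  counts <- c(genic = sum(genic), intergenic = sum(!genic))
  data.frame(
    region_class = c("genic", "intergenic"),
    mirna_count = as.integer(counts),
    region_length_bases = c(lens$genic, lens$intergenic),
    density_per_gb = c(population_density(counts[["genic"]], lens$genic),
                       population_density(counts[["intergenic"]],
                                          lens$intergenic)),
    stringsAsFactors = FALSE)
}
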