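#' Read a multi-record genome FASTA
#'
#' Sequences are uppercased; record names are truncated at the first
#' whitespace, following common FASTA usage.
#'
#' @param path path to a FASTA file.
#' @return a [Biostrings::DNAStringSet] named by scaffold id.
#' @export
read_genome_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  names(x) <- sub("\\s.*$", "", names(x))
  x
}

#' Write named sequences as FASTA
#'
#' @param seqs named character vector or DNAStringSet.
#' @param path output path.
#' @export
write_fasta <- function(seqs, path) {
  if (!is(seqs, "DNAStringSet")) {
    seqs <- Biostrings::DNAStringSet(unlist(seqs))
  }
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Read gene models from GFF3
#'
#' Consumes `gene` and `exon` features, linking exons to genes through
#' `Parent` attributes (via mRNA features when present). Coordinates are
#' converted to the package's 0-based half-open convention.
#'
#' @param path path to a GFF3 file.
#' @return list with elements `genes` (gene_id, scaffold, start, end, strand)
#'   and `exons` (gene_id, scaffold, start, end).
#' @export
read_gene_models <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  type <- as.character(gr$type)
  genes_gr <- gr[type == "gene"]
  mrna_gr <- gr[type == "mRNA"]
  exons_gr <- gr[type == "exon"]
  genes <- data.frame(
    gene_id = as.character(genes_gr$ID),
    scaffold = as.character(GenomicRanges::seqnames(genes_gr)),
    start = GenomicRanges::start(genes_gr) - 1L,
    end = GenomicRanges::end(genes_gr),
    strand = as.character(GenomicRanges::strand(genes_gr)),
    stringsAsFactors = FALSE
  )
  # map exon Parent -> gene (directly, or through an mRNA)
  mrna_parent <- setNames(
    vapply(mrna_gr$Parent, function(p) as.character(p)[1], character(1)),
    as.character(mrna_gr$ID)
  )
  exon_parent <- vapply(exons_gr$Parent, function(p) as.character(p)[1],
                        character(1))
  exon_gene <- ifelse(exon_parent %in% names(mrna_parent),
                      mrna_parent[exon_parent], exon_parent)
  exons <- data.frame(
    gene_id = unname(exon_gene),
    scaffold = as.character(GenomicRanges::seqnames(exons_gr)),
    start = GenomicRanges::start(exons_gr) - 1L,
    end = GenomicRanges::end(exons_gr),
    stringsAsFactors = FALSE
  )
  exons <- exons[order(exons$gene_id, exons$start), , drop = FALSE]
  rownames(exons) <- NULL
  list(genes = genes, exons = exons)
}

#' Write gene models as GFF3
#'
#' @param models list with `genes` and `exons` as from [read_gene_models()].
#' @param path output path.
#' @export
write_gene_models <- function(models, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  g <- models$genes
  e <- models$exons
  for (i in seq_len(nrow(g))) {
    writeLines(sprintf("%s\tpremirscan\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                       g$scaffold[i], g$start[i] + 1L, g$end[i], g$strand[i],
                       g$gene_id[i]), con)
    writeLines(sprintf("%s\tpremirscan\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s.1;Parent=%s",
                       g$scaffold[i], g$start[i] + 1L, g$end[i], g$strand[i],
                       g$gene_id[i], g$gene_id[i]), con)
    ge <- e[e$gene_id == g$gene_id[i], , drop = FALSE]
    for (j in seq_len(nrow(ge))) {
      writeLines(sprintf("%s\tpremirscan\texon\t%d\t%d\t.\t%s\t.\tID=%s.exon%d;Parent=%s.1",
                         ge$scaffold[j], ge$start[j] + 1L, ge$end[j],
                         g$strand[i], g$gene_id[i], j, g$gene_id[i]), con)
    }
  }
  invisible(path)
}

#' Write intervals as BED
#'
#' @param df data.frame with columns scaffold, start, end (0-based half-open)
#'   and optionally a `name` column.
#' @param path output path.
#' @export
write_bed <- function(df, path) {
  name <- if ("name" %in% names(df)) df$name else
    if ("locus_id" %in% names(df)) df$locus_id else
      if ("fragment_id" %in% names(df)) df$fragment_id else "."
  out <- data.frame(df$scaffold, df$start, df$end, name)
  write.table(out, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write predicted loci as GFF3
#'
#' Emits one `predicted_miRNA_locus` feature per locus (1-based closed
#' coordinates in the file, as GFF3 requires).
#'
#' @param loci locus table from [merge_predicted_loci()].
#' @param path output path.
#' @export
write_loci_gff3 <- function(loci, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  for (i in seq_len(nrow(loci))) {
    writeLines(sprintf(
      "%s\tpremirscan\tpredicted_miRNA_locus\t%d\t%d\t.\t.\t.\tID=%s;n_fragments=%d",
      loci$scaffold[i], loci$start[i] + 1L, loci$end[i], loci$locus_id[i],
      loci$n_fragments[i]), con)
  }
  invisible(path)
}

#' Read/write Vienna-style dot-bracket records
#'
#' The text format is three lines per record: `>name`, sequence, structure.
#' This allows structures computed by an external folding engine to be
#' injected bit-exactly as a folding backend.
#'
#' @param path file path.
#' @return named list of `list(sequence, dotbracket)` records.
#' @export
read_dotbracket <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) %% 3 != 0) {
    stop("dot-bracket file must hold three lines per record (>name/seq/structure)")
  }
  idx <- seq(1, length(lines), by = 3)
  out <- lapply(idx, function(i) {
    list(sequence = normalize_seq(lines[i + 1]), dotbracket = lines[i + 2])
  })
  names(out) <- sub("^>", "", lines[idx])
  out
}

#' @rdname read_dotbracket
#' @param records named list of `list(sequence, dotbracket)`.
#' @export
write_dotbracket <- function(records, path) {
  lines <- unlist(lapply(names(records), function(nm) {
    c(paste0(">", nm), records[[nm]]$sequence, records[[nm]]$dotbracket)
  }))
  writeLines(lines, path)
  invisible(path)
}

#' Read a reference pre-miRNA set (TSV)
#'
#' Columns: ref_id, scaffold, start, end, sequence, family, source_label.
#' Coordinates in the file are 0-based half-open.
#'
#' @param path TSV path.
#' @return data.frame of references.
#' @export
read_reference_tsv <- function(path) {
  read.delim(path, stringsAsFactors = FALSE)
}

#' Write a TSV table
#' @param df data.frame.
#' @param path output path.
#' @export
write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a plant mature-miRNA catalog FASTA
#'
#' Headers are parsed tolerantly: `id|family` takes the family from the
#' second field; miRBase-style ids (`ath-miR169a`) fall back to the
#' `miR<number>` family stem; otherwise family is NA.
#'
#' @param path FASTA path.
#' @return data.frame with mirna_id, family, sequence.
#' @export
read_mature_catalog <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  hdr <- names(x)
  first <- sub("\\s.*$", "", hdr)
  has_pipe <- grepl("|", first, fixed = TRUE)
  id <- ifelse(has_pipe, sub("\\|.*$", "", first), first)
  fam <- ifelse(has_pipe, sub("^[^|]*\\|", "", first), NA_character_)
  m <- regexpr("[mM][iI][rR]-?[0-9]+", id)
  hit <- !has_pipe & m > 0
  fam[hit] <- substring(id[hit], m[hit], m[hit] + attr(m, "match.length")[hit] - 1L)
  data.frame(mirna_id = id, family = fam,
             sequence = normalize_seq(as.character(x)),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Read small-RNA reads from FASTA or FASTQ
#'
#' @param path FASTA/FASTQ path (format chosen by extension; `.fq`/`.fastq`
#'   read as FASTQ).
#' @return character vector of read sequences.
#' @export
read_reads <- function(path) {
  fmt <- if (grepl("\\.f(ast)?q$", path, ignore.case = TRUE)) "fastq" else "fasta"
  x <- Biostrings::readDNAStringSet(path, format = fmt)
  unname(normalize_seq(as.character(x)))
}

#' Read a minimal alignment table
#'
#' A deliberately small SAM surrogate: TSV with read_id, scaffold, start,
#' end, strand (0-based half-open coordinates).
#'
#' @param path TSV path.
#' @return data.frame of alignments.
#' @export
read_alignments_tsv <- function(path) {
  read.delim(path, stringsAsFactors = FALSE)
}

#' Read a flat gene-to-term map
#'
#' @param path TSV with columns gene_id, term_id (one pair per line).
#' @return data.frame with gene_id, term_id.
#' @export
read_term_map <- function(path) {
  read.delim(path, stringsAsFactors = FALSE)
}
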