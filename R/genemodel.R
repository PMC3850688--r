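#' Validate a gene-model table
#'
#' The package represents annotation as a flat table with one row per
#' exon/CDS interval: columns `gene_id`, `transcript_id`, `chrom`, `strand`
#' (`+`/`-`), `feature` (`"exon"` or `"CDS"`) and 0-based half-open
#' `start`/`end`. Exons within a transcript must be sorted and
#' non-overlapping; every transcript needs at least one exon; introns are
#' the gaps between consecutive exons.
#'
#' @param genes gene-model `data.frame`.
#' @param genome optional `cyto_genome` for bounds checking.
#' @return the validated table as a `data.table` (invisibly usable onward).
#' @export
validate_gene_model <- function(genes, genome = NULL) {
  genes <- data.table::as.data.table(genes)
  need <- c("gene_id", "transcript_id", "chrom", "strand", "feature",
            "start", "end")
  miss <- setdiff(need, names(genes))
  if (length(miss)) stopf("gene model lacks column(s): %s",
                          paste(miss, collapse = ", "))
  if (nrow(genes) == 0L) return(genes[])
  if (!all(genes$strand %in% c("+", "-"))) stopf("strand must be '+' or '-'")
  if (!all(genes$feature %in% c("exon", "CDS")))
    stopf("feature must be 'exon' or 'CDS'")
  if (any(genes$start < 0L) || any(genes$end <= genes$start))
    stopf("intervals must satisfy 0 <= start < end")
  if (!is.null(genome)) {
    lens <- genome_lengths(genome)
    if (!all(genes$chrom %in% names(lens)))
      stopf("gene model refers to chromosomes absent from the genome")
    if (any(genes$end > lens[genes$chrom]))
      stopf("gene interval exceeds chromosome bounds")
  }
  ex <- genes[feature == "exon"]
  if (nrow(ex) == 0L || !all(unique(genes$transcript_id) %in%
                             unique(ex$transcript_id)))
    stopf("every transcript must have at least one exon")
  chk <- ex[order(transcript_id, start),
            .(bad = any(start < data.table::shift(end, fill = -1L))),
            by = transcript_id]
  if (any(chk$bad))
    stopf("overlapping exons within transcript '%s'",
          chk$transcript_id[which(chk$bad)[1]])
  data.table::setorder(genes, gene_id, transcript_id, feature, start)
  genes[]
}

#' Transcript spans of a gene model
#' @param genes validated gene-model table.
#' @return `data.table` with one row per transcript: `gene_id`,
#'   `transcript_id`, `chrom`, `strand`, `start`, `end` (span including
#'   introns).
#' @export
transcript_spans <- function(genes) {
  genes <- data.table::as.data.table(genes)
  genes[feature == "exon",
        .(chrom = chrom[1], strand = strand[1], start = min(start),
          end = max(end)),
        by = .(gene_id, transcript_id)]
}

#' Gene spans (union of transcript spans)
#' @param genes validated gene-model table.
#' @return `data.table` with one row per gene.
#' @export
gene_spans <- function(genes) {
  tx <- transcript_spans(genes)
  tx[, .(chrom = chrom[1], strand = strand[1], start = min(start),
         end = max(end)), by = gene_id]
}

#' Introns of every transcript
#' @param genes validated gene-model table.
#' @return `data.table` of intron intervals (`gene_id`, `transcript_id`,
#'   `chrom`, `strand`, `start`, `end`), empty when all transcripts are
#'   single-exon.
#' @export
introns_of <- function(genes) {
  genes <- data.table::as.data.table(genes)
  ex <- genes[feature == "exon"][order(transcript_id, start)]
  ex[, {
    if (.N < 2L) {
      data.table::data.table(chrom = character(), strand = character(),
                             start = integer(), end = integer(),
                             gene_id = character())[, .(gene_id, chrom,
                                                        strand, start, end)]
    } else {
      data.table::data.table(gene_id = gene_id[1], chrom = chrom[1],
                             strand = strand[1],
                             start = end[-.N], end = start[-1L])
    }
  }, by = transcript_id][, .(gene_id, transcript_id, chrom, strand,
                             start, end)]
}

#' Read gene models from GFF3
#'
#' Consumes `gene`, `mRNA`, `exon` and `CDS` features linked through
#' `ID`/`Parent` attributes, and converts them to the package's 0-based
#' half-open exon/CDS table.
#'
#' @param path GFF3 file.
#' @param genome optional `cyto_genome` for validation.
#' @return validated gene-model table.
#' @export
read_gff3 <- function(path, genome = NULL) {
  gr <- rtracklayer::import(path, format = "gff3")
  df <- as.data.frame(gr)
  type <- as.character(df$type)
  id <- as.character(df$ID)
  parent <- vapply(df$Parent, function(p)
    if (length(p)) as.character(p[1]) else NA_character_, character(1))
  mrna <- df[type == "mRNA", , drop = FALSE]
  mrna_id <- id[type == "mRNA"]
  mrna_gene <- parent[type == "mRNA"]
  tx2gene <- setNames(mrna_gene, mrna_id)
  keep <- type %in% c("exon", "CDS")
  if (!any(keep)) stopf("no exon/CDS features in '%s'", path)
  out <- data.table::data.table(
    transcript_id = parent[keep],
    chrom = as.character(df$seqnames)[keep],
    strand = as.character(df$strand)[keep],
    feature = ifelse(type[keep] == "exon", "exon", "CDS"),
    start = df$start[keep] - 1L,   # GFF3 is 1-based inclusive
    end = df$end[keep])
  out[, gene_id := tx2gene[transcript_id]]
  if (anyNA(out$gene_id))
    out[is.na(gene_id), gene_id := transcript_id]
  validate_gene_model(out[, .(gene_id, transcript_id, chrom, strand,
                              feature, start, end)], genome)
}

#' Write gene models to GFF3
#' @param genes validated gene-model table.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(genes, path) {
  genes <- validate_gene_model(genes)
  gs <- gene_spans(genes)
  tx <- transcript_spans(genes)
  mk <- function(chrom, start, end, strand, type, id, parent) {
    gr <- GenomicRanges::GRanges(chrom,
                                 IRanges::IRanges(start + 1L, end),
                                 strand = strand)
    S4Vectors::mcols(gr)$type <- type
    S4Vectors::mcols(gr)$ID <- id
    S4Vectors::mcols(gr)$Parent <- parent
    gr
  }
  g1 <- mk(gs$chrom, gs$start, gs$end, gs$strand, "gene", gs$gene_id,
           NA_character_)
  g2 <- mk(tx$chrom, tx$start, tx$end, tx$strand, "mRNA", tx$transcript_id,
           tx$gene_id)
  g3 <- mk(genes$chrom, genes$start, genes$end, genes$strand,
           ifelse(genes$feature == "exon", "exon", "CDS"),
           NA_character_, genes$transcript_id)
  all <- c(g1, g2, g3)
  S4Vectors::mcols(all)$phase <- c(
    rep(NA_integer_, length(g1) + length(g2)),
    ifelse(genes$feature == "CDS", 0L, NA_integer_))
  rtracklayer::export(all, path, format = "gff3")
  invisible(path)
}
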