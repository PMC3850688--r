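#' Region label vocabulary
#'
#' Labels are non-exclusive: one base may simultaneously be Exon, Cds, Gene
#' and Transcript. `SpliceSiteDonor` is the first `splice_site` bases of an
#' intron in transcription order and `SpliceSiteAcceptor` the last.
#' `Intragenic` marks bases inside a gene span that are in no exon and no
#' intron of any transcript (gaps between transcripts of one gene).
#' `Intergenic` is everything in no transcript span and no flank.
#'
#' @export
REGION_LABELS <- c("Exon", "Cds", "Intron", "SpliceSiteDonor",
                   "SpliceSiteAcceptor", "Gene", "Transcript", "Upstream",
                   "Downstream", "Intragenic", "Intergenic")

gr_make <- function(chrom, start, end, seqlens) {
  keep <- end > start
  gr <- GenomicRanges::GRanges(
    chrom[keep], IRanges::IRanges(start[keep] + 1L, end[keep]),
    seqinfo = GenomeInfoDb::Seqinfo(names(seqlens),
                                    seqlengths = unname(seqlens)))
  GenomicRanges::reduce(gr)
}

gr_empty <- function(seqlens) {
  GenomicRanges::GRanges(seqinfo = GenomeInfoDb::Seqinfo(
    names(seqlens), seqlengths = unname(seqlens)))
}

#' Build a genomic region index
#'
#' Maps every genomic position to the set of region labels it carries (see
#' [REGION_LABELS]). Flanks are assigned in transcription direction:
#' Upstream of a minus-strand gene lies to its right in genome coordinates.
#' Labels from overlapping genes union.
#'
#' @param genes gene-model table ([validate_gene_model]).
#' @param genome a `cyto_genome`.
#' @param flank flank size in bases (default 3000).
#' @param splice_site splice-site window in bases (default 2, the GT/AG
#'   motif length).
#' @return a `region_index` object: a named list of unstranded `GRanges`
#'   (one per label) plus the parameters.
#' @export
build_region_index <- function(genes, genome, flank = 3000L,
                               splice_site = 2L) {
  if (flank <= 0L) stopf("flank must be > 0")
  if (splice_site <= 0L) stopf("splice_site must be > 0")
  genes <- validate_gene_model(genes, genome)
  seqlens <- genome_lengths(genome)
  lab <- list()

  if (nrow(genes) == 0L) {
    for (l in setdiff(REGION_LABELS, "Intergenic")) lab[[l]] <- gr_empty(seqlens)
    lab[["Intergenic"]] <- gr_make(names(seqlens),
                                   rep(0L, length(seqlens)),
                                   unname(seqlens), seqlens)
    return(structure(list(labels = lab, flank = as.integer(flank),
                          splice_site = as.integer(splice_site),
                          seqlens = seqlens), class = "region_index"))
  }

  ex <- genes[feature == "exon"]
  cds <- genes[feature == "CDS"]
  tx <- transcript_spans(genes)
  gs <- gene_spans(genes)
  intr <- introns_of(genes)

  lab$Exon <- gr_make(ex$chrom, ex$start, ex$end, seqlens)
  lab$Cds <- if (nrow(cds)) gr_make(cds$chrom, cds$start, cds$end, seqlens)
             else gr_empty(seqlens)
  lab$Intron <- if (nrow(intr)) gr_make(intr$chrom, intr$start, intr$end,
                                        seqlens) else gr_empty(seqlens)
  lab$Transcript <- gr_make(tx$chrom, tx$start, tx$end, seqlens)
  lab$Gene <- gr_make(gs$chrom, gs$start, gs$end, seqlens)

  if (nrow(intr)) {
    ss <- pmin(as.integer(splice_site), intr$end - intr$start)
    don_start <- ifelse(intr$strand == "+", intr$start, intr$end - ss)
    don_end <- ifelse(intr$strand == "+", intr$start + ss, intr$end)
    acc_start <- ifelse(intr$strand == "+", intr$end - ss, intr$start)
    acc_end <- ifelse(intr$strand == "+", intr$end, intr$start + ss)
    lab$SpliceSiteDonor <- gr_make(intr$chrom, don_start, don_end, seqlens)
    lab$SpliceSiteAcceptor <- gr_make(intr$chrom, acc_start, acc_end, seqlens)
  } else {
    lab$SpliceSiteDonor <- gr_empty(seqlens)
    lab$SpliceSiteAcceptor <- gr_empty(seqlens)
  }

  up_start <- ifelse(gs$strand == "+", pmax(gs$start - flank, 0L), gs$end)
  up_end <- ifelse(gs$strand == "+", gs$start,
                   pmin(gs$end + flank, seqlens[gs$chrom]))
  dn_start <- ifelse(gs$strand == "+", gs$end, pmax(gs$start - flank, 0L))
  dn_end <- ifelse(gs$strand == "+", pmin(gs$end + flank, seqlens[gs$chrom]),
                   gs$start)
  lab$Upstream <- gr_make(gs$chrom, as.integer(up_start), as.integer(up_end),
                          seqlens)
  lab$Downstream <- gr_make(gs$chrom, as.integer(dn_start),
                            as.integer(dn_end), seqlens)

  ## Intragenic: inside a gene span but neither exonic nor intronic
  lab$Intragenic <- GenomicRanges::setdiff(
    lab$Gene, GenomicRanges::reduce(c(lab$Exon, lab$Intron)))

  ## Intergenic: in no transcript span and no flank
  covered <- GenomicRanges::reduce(c(lab$Transcript, lab$Upstream,
                                     lab$Downstream))
  lab$Intergenic <- GenomicRanges::gaps(covered)
  lab$Intergenic <- lab$Intergenic[
    BiocGenerics::strand(lab$Intergenic) == "*"]

  structure(list(labels = lab[REGION_LABELS], flank = as.integer(flank),
                 splice_site = as.integer(splice_site), seqlens = seqlens),
            class = "region_index")
}

#' @export
print.region_index <- function(x, ...) {
  n <- vapply(x$labels, function(g) sum(BiocGenerics::width(g)), numeric(1))
  cat("<region_index> bases per label:\n")
  print(n)
  invisible(x)
}

#' Region labels at genomic positions
#'
#' @param index a `region_index`.
#' @param chrom chromosome name (scalar).
#' @param pos 0-based position(s).
#' @return for a single position, a character vector of labels; for several,
#'   a list of character vectors.
#' @export
region_labels_at <- function(index, chrom, pos) {
  gp <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos + 1L, width = 1L))
  hits <- lapply(names(index$labels), function(l) {
    IRanges::overlapsAny(gp, index$labels[[l]])
  })
  names(hits) <- names(index$labels)
  out <- lapply(seq_along(pos), function(i) {
    names(hits)[vapply(hits, `[`, logical(1), i)]
  })
  if (length(pos) == 1L) out[[1]] else out
}

## logical membership of many sites in one label; sites as 0-based positions
label_member <- function(index, label, chrom, pos) {
  gr <- index$labels[[label]]
  if (is.null(gr)) stopf("unknown region label '%s'", label)
  gp <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos + 1L, width = 1L))
  IRanges::overlapsAny(gp, gr)
}

#' Export a region index as BED files
#'
#' Writes one BED file (0-based half-open) per label for inspection in a
#' genome browser.
#'
#' @param index a `region_index`.
#' @param dir output directory (created if needed).
#' @return named character vector of the written paths.
#' @export
export_region_bed <- function(index, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  out <- vapply(names(index$labels), function(l) {
    p <- file.path(dir, paste0(l, ".bed"))
    rtracklayer::export(index$labels[[l]], p, format = "BED")
    p
  }, character(1))
  out
}

#' Observed/expected CpG ratio per gene
#'
#' For each transcript, o/e = (number of CG dinucleotides in the genomic
#' transcript span) / (nC * nG / L), the count expected if C and G were
#' placed uniformly at random. Genes average their transcripts weighted by
#' span length. A transcript with no C or no G has no expected count and
#' contributes the `NA` sentinel.
#'
#' @param genes gene-model table.
#' @param genome a `cyto_genome`.
#' @return `data.table` with `gene_id` and `oe`.
#' @examples
#' g <- genome_from_seqs(c(chr1 = "CGCGAAAA"))
#' gm <- data.frame(gene_id = "g1", transcript_id = "t1", chrom = "chr1",
#'                  strand = "+", feature = "exon", start = 0, end = 4)
#' compute_oe(gm, g)  # observed 2, expected 1, o/e = 2
#' @export
compute_oe <- function(genes, genome) {
  genes <- validate_gene_model(genes, genome)
  tx <- transcript_spans(genes)
  if (nrow(tx) == 0L)
    return(data.table::data.table(gene_id = character(), oe = numeric()))
  tx[, oe := {
    vapply(seq_len(.N), function(i) {
      s <- Biostrings::DNAString(substr(genome_seq(genome, chrom[i]),
                                        start[i] + 1L, end[i]))
      obs <- Biostrings::countPattern("CG", s)
      f <- Biostrings::letterFrequency(s, c("C", "G"))
      expd <- f[["C"]] * f[["G"]] / length(s)
      if (expd == 0) NA_real_ else obs / expd
    }, numeric(1))
  }]
  tx[, width := end - start]
  tx[, .(oe = {
    ok <- !is.na(oe)
    if (!any(ok)) NA_real_
    else sum(oe[ok] * width[ok]) / sum(width[ok])
  }), by = gene_id]
}
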