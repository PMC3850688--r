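#' Region-by-context summary of methylation calls
#'
#' Counts analyzed (passing) and modified (level > 0) calls per
#' (region label, context) cell. Labels are non-exclusive: a site
#' contributes once to every label it carries, so per-label counts sum to
#' more than the genome-wide totals. `percent` is
#' `100 * modified / analyzed` rounded half-up to 2 decimals, `NA` when
#' nothing was analyzed.
#'
#' @param calls output of [call_methylation] (only `pass` rows are used).
#' @param index a `region_index` from [build_region_index].
#' @return `data.table` with `region`, `context`, `analyzed`, `modified`,
#'   `percent`, one row per label-context combination.
#' @export
summarize_by_region <- function(calls, index) {
  calls <- data.table::as.data.table(calls)[pass == TRUE]
  grid <- data.table::CJ(region = names(index$labels),
                         context = CONTEXT_LEVELS)
  if (nrow(calls) == 0L) {
    grid[, `:=`(analyzed = 0L, modified = 0L, percent = NA_real_)]
    return(grid[])
  }
  parts <- lapply(names(index$labels), function(l) {
    hit <- logical(nrow(calls))
    for (ch in unique(calls$chrom)) {
      ii <- which(calls$chrom == ch)
      hit[ii] <- label_member(index, l, ch, calls$pos[ii])
    }
    if (!any(hit)) return(NULL)
    calls[hit, .(region = l, analyzed = .N, modified = sum(level > 0)),
          by = context]
  })
  out <- data.table::rbindlist(parts)
  out <- out[grid, on = c("region", "context")]
  out[is.na(analyzed), `:=`(analyzed = 0L, modified = 0L)]
  out[, percent := pct_modified(modified, analyzed)]
  data.table::setcolorder(out, c("region", "context", "analyzed",
                                 "modified", "percent"))
  data.table::setorder(out, region, context)
  out[]
}

## Exclusive assignment priority for read/interval-level region tables
INTERVAL_REGION_PRIORITY <- c("SpliceSiteDonor", "SpliceSiteAcceptor",
                              "Exon", "Intron", "Intragenic", "Upstream",
                              "Downstream", "Intergenic")

#' Region table of genomic intervals (reads, fragments, cuts)
#'
#' Assigns each interval to one region by its midpoint using a fixed
#' priority (splice sites > exon > intron > intragenic > flanks >
#' intergenic), or with `mode = "any"` counts the interval once under every
#' label it overlaps. Reports counts and percent of total per region.
#'
#' @param intervals `data.table`/`data.frame` with `chrom`, `start`, `end`
#'   (0-based half-open); zero-width point records (cuts) may use
#'   `end = start + 1`.
#' @param index a `region_index`.
#' @param mode `"midpoint"` (default) or `"any"` (any-overlap, each label
#'   once).
#' @return `data.table` with `region`, `count`, `percent` (of total
#'   assignments).
#' @export
summarize_intervals_by_region <- function(intervals, index,
                                          mode = c("midpoint", "any")) {
  mode <- match.arg(mode)
  iv <- data.table::as.data.table(intervals)
  if (nrow(iv) == 0L)
    return(data.table::data.table(region = character(), count = integer(),
                                  percent = numeric()))
  if (!all(iv$chrom %in% names(index$seqlens)))
    stopf("intervals on chromosomes absent from the region index")
  if (mode == "midpoint") {
    mid <- iv$start + (iv$end - iv$start) %/% 2L
    assigned <- rep(NA_character_, nrow(iv))
    for (l in rev(INTERVAL_REGION_PRIORITY)) {
      hit <- logical(nrow(iv))
      for (ch in unique(iv$chrom)) {
        ii <- which(iv$chrom == ch)
        hit[ii] <- label_member(index, l, ch, mid[ii])
      }
      assigned[hit] <- l
    }
    tab <- data.table::data.table(region = assigned)[
      , .(count = .N), by = region]
  } else {
    gr <- GenomicRanges::GRanges(iv$chrom,
                                 IRanges::IRanges(iv$start + 1L, iv$end))
    parts <- lapply(INTERVAL_REGION_PRIORITY, function(l) {
      n <- sum(IRanges::overlapsAny(gr, index$labels[[l]]))
      data.table::data.table(region = l, count = n)
    })
    tab <- data.table::rbindlist(parts)[count > 0L]
  }
  tab[, percent := pct_modified(count, rep(sum(count), .N))]
  data.table::setorder(tab, region)
  tab[]
}

#' Metagene methylation profiles
#'
#' Scales the upstream flank, every exon, every intron and the downstream
#' flank of each gene to `nbins` equal spans and reports the per-bin ratio
#' of modified over analyzed cytosines, pooled across genes by feature
#' type. Bins run in transcription order (upstream of the gene first); for
#' minus-strand genes the bin order is reversed relative to genome
#' coordinates. Genes with fewer than `min_covered` covered cytosines in
#' gene body plus upstream flank are excluded.
#'
#' @param calls output of [call_methylation]; coverage is any call record,
#'   ratios use passing calls.
#' @param genes gene-model table.
#' @param nbins number of bins per feature (default 30).
#' @param flank flank size in bases (default 3000).
#' @param min_covered per-gene covered-cytosine floor (default 100).
#' @return `data.table` with `feature` (`upstream`, `exon`, `intron`,
#'   `downstream`), `bin` (1-based, transcription order), `analyzed`,
#'   `modified`, `ratio`; plus attribute `genes_used`.
#' @export
metagene_profile <- function(calls, genes, nbins = 30L, flank = 3000L,
                             min_covered = 100L) {
  if (nbins < 1L) stopf("nbins must be >= 1")
  calls <- data.table::as.data.table(calls)
  genes <- data.table::as.data.table(genes)
  gs <- gene_spans(genes)
  keep_genes <- character(0)
  feats <- list()
  for (i in seq_len(nrow(gs))) {
    g <- gs[i]
    ch_calls <- calls[chrom == g$chrom]
    up <- if (g$strand == "+") c(max(g$start - flank, 0L), g$start)
          else c(g$end, g$end + flank)
    covered <- ch_calls[(pos >= g$start & pos < g$end) |
                        (pos >= up[1] & pos < up[2]), .N]
    if (covered < min_covered) next
    keep_genes <- c(keep_genes, g$gene_id)
    ex <- genes[gene_id == g$gene_id & feature == "exon"][order(start)]
    intr <- introns_of(genes[gene_id == g$gene_id])
    dn <- if (g$strand == "+") c(g$end, g$end + flank)
          else c(max(g$start - flank, 0L), g$start)
    ivs <- data.table::rbindlist(list(
      data.table::data.table(feature = "upstream", start = up[1],
                             end = up[2]),
      data.table::data.table(feature = "exon", start = ex$start,
                             end = ex$end),
      if (nrow(intr)) data.table::data.table(feature = "intron",
                                             start = intr$start,
                                             end = intr$end),
      data.table::data.table(feature = "downstream", start = dn[1],
                             end = dn[2])))
    pc <- ch_calls[pass == TRUE]
    for (j in seq_len(nrow(ivs))) {
      s <- ivs$start[j]; e <- ivs$end[j]
      if (e <= s) next
      sub <- pc[pos >= s & pos < e]
      if (nrow(sub) == 0L) next
      rel <- (sub$pos - s) / (e - s)
      if (g$strand == "-") rel <- 1 - rel - 1e-12
      b <- pmin(pmax(floor(rel * nbins), 0), nbins - 1L) + 1L
      feats[[length(feats) + 1L]] <- data.table::data.table(
        feature = ivs$feature[j], bin = as.integer(b),
        modified = sub$level > 0)
    }
  }
  if (length(feats) == 0L) {
    out <- data.table::data.table(feature = character(), bin = integer(),
                                  analyzed = integer(), modified = integer(),
                                  ratio = numeric())
  } else {
    long <- data.table::rbindlist(feats)
    out <- long[, .(analyzed = .N, modified = sum(modified)),
                by = .(feature, bin)]
    out[, ratio := modified / analyzed]
    data.table::setorder(out, feature, bin)
  }
  data.table::setattr(out, "genes_used", keep_genes)
  out[]
}

#' Splice-junction template-strand methylation
#'
#' At each intron the spliceosome recognizes the sense-strand GT (donor)
#' and AG (acceptor) motifs; the guanosines pair with cytosines on the
#' template (antisense) strand, which can carry methylation. This scans
#' every intron for a passing modified call at the template cytosine
#' opposite the donor's first base and the acceptor's last base, and
#' reports each such junction with its actual motifs (non-canonical
#' junctions are reported, not dropped).
#'
#' @param calls output of [call_methylation].
#' @param genes gene-model table.
#' @param genome a `cyto_genome`.
#' @return list with `records` (one row per modified-template junction:
#'   `gene_id`, `transcript_id`, `kind`, intron interval, `template_pos`,
#'   `template_strand`, `motif_sense`, `motif_template`, `context`,
#'   `level`) and `summary` (per kind: modified junction count, canonical
#'   count, canonical percent).
#' @export
splice_junction_methylation <- function(calls, genes, genome) {
  calls <- data.table::as.data.table(calls)
  intr <- introns_of(data.table::as.data.table(genes))
  emp <- data.table::data.table(
    gene_id = character(), transcript_id = character(), kind = character(),
    chrom = character(), intron_start = integer(), intron_end = integer(),
    template_pos = integer(), template_strand = character(),
    motif_sense = character(), motif_template = character(),
    context = character(), level = numeric())
  if (nrow(intr) == 0L)
    return(list(records = emp,
                summary = data.table::data.table(
                  kind = c("donor", "acceptor"), modified = 0L,
                  canonical = 0L, percent = NA_real_)))
  plus <- intr$strand == "+"
  ## template cytosine opposite the sense G: donor = intron 5' end,
  ## acceptor = intron 3' end, both in transcription order
  don_pos <- ifelse(plus, intr$start, intr$end - 1L)
  acc_pos <- ifelse(plus, intr$end - 1L, intr$start)
  template_strand <- ifelse(plus, "-", "+")
  sense_dinuc <- function(p1, p2, chrom, minus) {
    s <- substring(vapply(chrom, function(ch) genome_seq(genome, ch),
                          character(1)),
                   pmin(p1, p2) + 1L, pmax(p1, p2) + 1L)
    ifelse(minus, revcomp(s), s)
  }
  jd <- data.table::data.table(
    gene_id = rep(intr$gene_id, 2L),
    transcript_id = rep(intr$transcript_id, 2L),
    kind = rep(c("donor", "acceptor"), each = nrow(intr)),
    chrom = rep(intr$chrom, 2L),
    intron_start = rep(intr$start, 2L), intron_end = rep(intr$end, 2L),
    template_pos = c(don_pos, acc_pos),
    template_strand = rep(template_strand, 2L),
    sense_first = c(ifelse(plus, intr$start, intr$end - 2L),
                    ifelse(plus, intr$end - 2L, intr$start)),
    minus = rep(!plus, 2L))
  jd[, motif_sense := sense_dinuc(sense_first, sense_first + 1L, chrom,
                                  minus)]
  jd[, motif_template := revcomp(motif_sense)]
  mod <- calls[pass == TRUE & level > 0,
               .(chrom, template_pos = pos, template_strand = strand,
                 context, level)]
  rec <- mod[jd, on = c("chrom", "template_pos", "template_strand"),
             nomatch = NULL]
  rec <- rec[, .(gene_id, transcript_id, kind, chrom, intron_start,
                 intron_end, template_pos, template_strand, motif_sense,
                 motif_template, context, level)]
  canon <- c(donor = "GT", acceptor = "AG")
  summary <- rec[, .(modified = .N,
                     canonical = sum(motif_sense == canon[kind[1]])),
                 by = kind]
  base <- data.table::data.table(kind = c("donor", "acceptor"))
  summary <- summary[base, on = "kind"]
  summary[is.na(modified), `:=`(modified = 0L, canonical = 0L)]
  summary[, percent := pct_modified(canonical, modified)]
  list(records = rec, summary = summary[])
}

#' Select gene panels by modification percent and o/e ratio
#'
#' Reproduces the bimodal-o/e gene-classification analysis: per gene, the
#' modification percent over passing sites of one context restricted to
#' exons or introns, selected by a comparison rule, with a minimum
#' motif-count eligibility floor for zero-percent panels (genes with few
#' sites trivially show 0%).
#'
#' @param calls output of [call_methylation].
#' @param genes gene-model table.
#' @param oe per-gene o/e table from [compute_oe].
#' @param context `"CG"`, `"CHG"` or `"CHH"`.
#' @param region `"exon"` or `"intron"`.
#' @param rule comparison: `">"`, `">="`, `"<"`, `"<="` or `"=="`.
#' @param threshold percent threshold the rule compares against.
#' @param min_sites minimum analyzed sites for eligibility (default 0; use
#'   e.g. 10 CpGs in exons, 400 CHHs or 100 CHGs in introns for
#'   zero-percent panels).
#' @return `data.table` of selected genes: `gene_id`, `analyzed`,
#'   `modified`, `percent`, `oe`.
#' @export
classify_genes_by_oe <- function(calls, genes, oe, context, region,
                                 rule = ">", threshold = 10,
                                 min_sites = 0L) {
  if (!context %in% CONTEXT_LEVELS) stopf("unknown context '%s'", context)
  if (!region %in% c("exon", "intron")) stopf("unknown region '%s'", region)
  cmp <- switch(rule, ">" = `>`, ">=" = `>=`, "<" = `<`, "<=" = `<=`,
                "==" = `==`, stopf("unknown rule '%s'", rule))
  calls <- data.table::as.data.table(calls)[pass == TRUE]
  genes <- data.table::as.data.table(genes)
  ivs <- if (region == "exon") genes[feature == "exon"] else
         introns_of(genes)
  ctx <- context
  per_gene <- lapply(split(ivs, ivs$gene_id), function(gi) {
    sub <- calls[chrom == gi$chrom[1] & context == ctx]
    if (nrow(sub) == 0L)
      return(data.table::data.table(gene_id = gi$gene_id[1], analyzed = 0L,
                                    modified = 0L))
    inside <- rep(FALSE, nrow(sub))
    for (j in seq_len(nrow(gi)))
      inside <- inside | (sub$pos >= gi$start[j] & sub$pos < gi$end[j])
    data.table::data.table(gene_id = gi$gene_id[1],
                           analyzed = sum(inside),
                           modified = sum(inside & sub$level > 0))
  })
  tab <- data.table::rbindlist(per_gene)
  tab[, percent := ifelse(analyzed > 0, 100 * modified / analyzed, NA_real_)]
  tab <- tab[analyzed >= min_sites & !is.na(percent)]
  tab <- tab[cmp(percent, threshold)]
  oe <- data.table::as.data.table(oe)
  tab <- oe[tab, on = "gene_id"]
  data.table::setcolorder(tab, c("gene_id", "analyzed", "modified",
                                 "percent", "oe"))
  tab[]
}

#' Write a region-context summary in the published-table dialect
#'
#' Columns `Type`, `Analyzed`, `Methylated`, `Methylated %`.
#'
#' @param summary output of [summarize_by_region] for one context.
#' @param path output TSV.
#' @return `path`, invisibly.
#' @export
write_region_summary <- function(summary, path) {
  s <- data.table::as.data.table(summary)
  out <- data.table::data.table(
    Type = s$region, Analyzed = s$analyzed, Methylated = s$modified,
    `Methylated %` = ifelse(is.na(s$percent), "NA",
                            sprintf("%.2f%%", s$percent)))
  data.table::fwrite(out, path, sep = "\t", quote = FALSE)
  invisible(path)
}
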