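#' Infer 5hmC candidate sites from restriction cut positions
#'
#' PvuRts1I cleaves at a fixed distance 3' of a hydroxymethylcytosine:
#' 11-13 bases on the top strand, 9-10 on the bottom strand. Inverting that
#' rule, a top-strand cut at p supports every position `p - d`
#' (d in `offsets_top`) whose plus-strand base is C, and a bottom-strand
#' cut at p supports every `p + d` (d in `offsets_bottom`) whose
#' minus-strand base is C (reference G). A cut supports all cytosines in
#' its offset window; candidates at non-C bases are silently skipped, and
#' out-of-bounds cuts are dropped with a message.
#'
#' @param cuts `data.table` of cut records (`chrom`, `pos` 0-based,
#'   `strand`), e.g. from [simulate_pvu_digestion] or [read_cuts_bed].
#' @param genome a `cyto_genome`.
#' @param offsets_top,offsets_bottom integer offset sets (defaults 11:13
#'   and 9:10).
#' @param min_support support threshold for a called site (default 2).
#' @return list with `evidence` (per candidate site: `chrom`, `pos`,
#'   `strand`, `support`) and `sites` (the subset with
#'   `support >= min_support`).
#' @export
infer_hmc_sites <- function(cuts, genome, offsets_top = 11:13,
                            offsets_bottom = 9:10, min_support = 2L) {
  if (length(offsets_top) == 0L || length(offsets_bottom) == 0L)
    stopf("offset sets must be non-empty")
  if (min_support < 1L) stopf("min_support must be >= 1")
  cuts <- data.table::as.data.table(cuts)
  lens <- genome_lengths(genome)
  emp <- data.table::data.table(chrom = character(), pos = integer(),
                                strand = character(), support = integer())
  if (nrow(cuts) == 0L)
    return(list(evidence = emp, sites = emp))
  if (!all(cuts$chrom %in% names(lens)))
    stopf("cuts on chromosomes absent from the genome")
  oob <- cuts$pos < 0L | cuts$pos >= lens[cuts$chrom]
  if (any(oob)) {
    message(sum(oob), " cut record(s) out of bounds; skipped")
    cuts <- cuts[!oob]
  }
  if (nrow(cuts) == 0L) return(list(evidence = emp, sites = emp))
  top <- cuts[strand == "+"]
  bot <- cuts[strand == "-"]
  cand <- data.table::rbindlist(list(
    if (nrow(top)) data.table::data.table(
      chrom = rep(top$chrom, each = length(offsets_top)),
      pos = rep(top$pos, each = length(offsets_top)) -
        rep(as.integer(offsets_top), nrow(top)),
      strand = "+"),
    if (nrow(bot)) data.table::data.table(
      chrom = rep(bot$chrom, each = length(offsets_bottom)),
      pos = rep(bot$pos, each = length(offsets_bottom)) +
        rep(as.integer(offsets_bottom), nrow(bot)),
      strand = "-")))
  cand <- cand[pos >= 0L & pos < lens[chrom]]
  if (nrow(cand) == 0L) return(list(evidence = emp, sites = emp))
  ## keep only candidates whose base is a cytosine on the implied strand
  cand[, base := substring(vapply(chrom, function(ch)
    genome_seq(genome, ch), character(1)), pos + 1L, pos + 1L)]
  cand <- cand[(strand == "+" & base == "C") |
               (strand == "-" & base == "G")]
  if (nrow(cand) == 0L) return(list(evidence = emp, sites = emp))
  evidence <- cand[, .(support = .N), by = .(chrom, pos, strand)]
  data.table::setorder(evidence, chrom, pos, strand)
  sites <- evidence[support >= min_support]
  list(evidence = evidence[], sites = sites[])
}

#' Naive windowed peak caller
#'
#' Computes base-level fragment coverage, smooths it with a sliding window
#' mean, and merges the positions whose windowed coverage exceeds
#' `min_fold` times the genome-wide mean into maximal peaks scored by their
#' maximum fold enrichment. A stand-in for model-based peak callers on
#' synthetic data.
#'
#' @param intervals fragment intervals (`chrom`, `start`, `end`, 0-based
#'   half-open).
#' @param seqlens named chromosome lengths (e.g. [genome_lengths]).
#' @param window sliding-window width in bases (default 200).
#' @param min_fold enrichment threshold over the genome-wide mean coverage
#'   (default 2).
#' @return `data.table` of peaks: `chrom`, `start`, `end` (0-based
#'   half-open), `score` (max fold enrichment).
#' @export
call_peaks_naive <- function(intervals, seqlens, window = 200L,
                             min_fold = 2) {
  if (window <= 0L) stopf("window must be > 0")
  iv <- data.table::as.data.table(intervals)
  emp <- data.table::data.table(chrom = character(), start = integer(),
                                end = integer(), score = numeric())
  if (nrow(iv) == 0L) return(emp)
  gmean <- sum(as.numeric(iv$end - iv$start)) / sum(as.numeric(seqlens))
  if (gmean == 0) return(emp)
  out <- lapply(names(seqlens), function(ch) {
    sub <- iv[chrom == ch]
    if (nrow(sub) == 0L) return(NULL)
    cov <- as.numeric(IRanges::coverage(
      IRanges::IRanges(sub$start + 1L, sub$end), width = seqlens[[ch]]))
    ## centered sliding mean via cumulative sums
    cs <- c(0, cumsum(cov))
    L <- length(cov)
    h <- window %/% 2L
    lo <- pmax(seq_len(L) - h, 1L)
    hi <- pmin(seq_len(L) + (window - h - 1L), L)
    wmean <- (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
    hot <- wmean > min_fold * gmean
    if (!any(hot)) return(NULL)
    r <- IRanges::reduce(IRanges::IRanges(which(hot), width = 1L))
    data.table::data.table(
      chrom = ch, start = IRanges::start(r) - 1L, end = IRanges::end(r),
      score = vapply(seq_along(r), function(i)
        max(wmean[IRanges::start(r)[i]:IRanges::end(r)[i]]) / gmean,
        numeric(1)))
  })
  res <- data.table::rbindlist(out)
  if (nrow(res) == 0L) return(emp)
  data.table::setorder(res, chrom, start)
  res[]
}

#' Fraction of peaks in A overlapping at least one peak in B
#'
#' @param peaksA,peaksB peak tables (`chrom`, `start`, `end`, 0-based
#'   half-open).
#' @return numeric fraction in `[0, 1]`; `NA` when A is empty.
#' @examples
#' a <- data.frame(chrom = "c", start = c(0, 20, 40), end = c(10, 30, 50))
#' b <- data.frame(chrom = "c", start = 5, end = 25)
#' peak_concordance(a, b)  # 2/3
#' @export
peak_concordance <- function(peaksA, peaksB) {
  a <- data.table::as.data.table(peaksA)
  b <- data.table::as.data.table(peaksB)
  if (nrow(a) == 0L) return(NA_real_)
  if (nrow(b) == 0L) return(0)
  ga <- GenomicRanges::GRanges(a$chrom, IRanges::IRanges(a$start + 1L,
                                                         a$end))
  gb <- GenomicRanges::GRanges(b$chrom, IRanges::IRanges(b$start + 1L,
                                                         b$end))
  mean(IRanges::overlapsAny(ga, gb))
}

#' Read restriction cut records from BED6
#'
#' The strand column carries the cut strand; the interval start is the cut
#' position.
#'
#' @param path BED file.
#' @return `data.table` with `chrom`, `pos` (0-based), `strand`.
#' @export
read_cuts_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  data.table::data.table(chrom = as.character(GenomeInfoDb::seqnames(gr)),
                         pos = BiocGenerics::start(gr) - 1L,
                         strand = as.character(BiocGenerics::strand(gr)))
}

#' Write cut records as BED6
#' @param cuts `data.table` with `chrom`, `pos`, `strand`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_cuts_bed <- function(cuts, path) {
  gr <- GenomicRanges::GRanges(cuts$chrom,
                               IRanges::IRanges(cuts$pos + 1L, width = 1L),
                               strand = cuts$strand)
  S4Vectors::mcols(gr)$score <- 0L
  S4Vectors::mcols(gr)$name <- sprintf("cut%06d", seq_along(gr))
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}
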