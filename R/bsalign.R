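#' Map bisulfite reads with a reduced-alphabet seed-and-extend mapper
#'
#' Bisulfite conversion makes C and T indistinguishable on the interrogated
#' strand, so reads are compared to the genome in two reduced alphabets:
#' C->T (forward orientation, plus-strand interrogation) and G->A (read
#' reverse-complemented, minus-strand interrogation). Seeding is exact on
#' the first `k` reduced bases; extension is ungapped and counts
#' reduced-alphabet mismatches. A read is reported only when exactly one
#' location attains the best mismatch count and that count is at most
#' `max_mismatch`; ties leave the read unmapped.
#'
#' @param genome a `cyto_genome`.
#' @param reads `data.table`/`data.frame` with `read_id`, `seq`, `qual`
#'   (e.g. from [simulate_bs_reads] or [read_fastq]).
#' @param k seed length (default 20; values below 8 trigger a warning for
#'   high ambiguity).
#' @param max_mismatch maximum reduced-alphabet mismatches (default 2).
#' @return `data.table` of aligned reads: `read_id`, `chrom`, `start`
#'   (0-based), `bs_strand` (the genomic strand the read interrogates),
#'   `seq` (reference-oriented), `qual` (reference-oriented), `mismatches`,
#'   `unique` (always `TRUE` in mapper output).
#' @export
map_bs_reads <- function(genome, reads, k = 20L, max_mismatch = 2L) {
  reads <- data.table::as.data.table(reads)
  if (nrow(reads) == 0L)
    return(data.table::data.table(read_id = character(), chrom = character(),
                                  start = integer(), bs_strand = character(),
                                  seq = character(), qual = character(),
                                  mismatches = integer(), unique = logical()))
  if (k < 8L) warning("seed length k < 8: expect high seeding ambiguity")
  if (any(nchar(reads$seq) < k))
    stopf("seed length k exceeds the shortest read")
  lens <- genome_lengths(genome)
  sep <- strrep("N", 32L)
  ref <- paste(unclass(genome), collapse = sep)
  offs <- c(0L, cumsum(lens + 32L))[seq_along(lens)]
  names(offs) <- names(lens)
  hit <- map_reads_cpp(ref, reads$seq, unname(offs),
                       unname(offs + lens), as.integer(k),
                       as.integer(max_mismatch))
  ok <- which(hit$mapped)
  if (length(ok) == 0L)
    return(data.table::data.table(read_id = character(), chrom = character(),
                                  start = integer(), bs_strand = character(),
                                  seq = character(), qual = character(),
                                  mismatches = integer(), unique = logical()))
  ci <- findInterval(hit$pos[ok], unname(offs))
  minus <- hit$strand[ok] == 1L
  seqs <- reads$seq[ok]
  quals <- reads$qual
  if (is.null(quals)) quals <- strrep("I", nchar(reads$seq))
  quals <- quals[ok]
  if (any(minus)) {
    seqs[minus] <- revcomp(seqs[minus])
    quals[minus] <- vapply(strsplit(quals[minus], ""),
                           function(x) paste(rev(x), collapse = ""),
                           character(1))
  }
  data.table::data.table(
    read_id = reads$read_id[ok],
    chrom = names(lens)[ci],
    start = hit$pos[ok] - unname(offs)[ci],
    bs_strand = ifelse(minus, "-", "+"),
    seq = seqs, qual = quals,
    mismatches = hit$mm[ok],
    unique = TRUE)
}

#' Read aligned reads from a SAM file
#'
#' Ingests externally aligned bisulfite reads. The interrogated strand is
#' taken from an explicit bisulfite-strand tag when present (default `XG`,
#' values `CT` -> `+`, `GA` -> `-`), otherwise from SAM flag bit 16
#' (reverse-complemented alignment implies `-`). Unmapped, secondary and
#' supplementary records, and records below the mapping-quality floor, are
#' dropped.
#'
#' @param path SAM file.
#' @param genome a `cyto_genome`; records on unknown chromosomes are an
#'   error.
#' @param min_mapq mapping-quality floor (default 0).
#' @param strand_tag name of the bisulfite-strand tag (default `"XG"`).
#' @return `data.table` in the same shape as [map_bs_reads] output.
#' @export
read_sam <- function(path, genome, min_mapq = 0L, strand_tag = "XG") {
  lines <- readLines(path)
  body <- which(!startsWith(lines, "@"))
  lens <- genome_lengths(genome)
  tagpat <- paste0("^", strand_tag, ":Z:")
  out <- lapply(body, function(i) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 11L)
      stopf("malformed SAM record at line %d: %d field(s)", i, length(f))
    flag <- suppressWarnings(as.integer(f[2]))
    if (is.na(flag)) stopf("malformed SAM record at line %d: bad flag", i)
    if (bitwAnd(flag, 4L) > 0L || bitwAnd(flag, 256L) > 0L ||
        bitwAnd(flag, 2048L) > 0L) return(NULL)
    mapq <- suppressWarnings(as.integer(f[5]))
    if (is.na(mapq) || mapq < min_mapq) return(NULL)
    if (!f[3] %in% names(lens))
      stopf("SAM line %d: chromosome '%s' not in genome", i, f[3])
    pos <- suppressWarnings(as.integer(f[4]))
    if (is.na(pos) || pos < 1L)
      stopf("malformed SAM record at line %d: bad position", i)
    tags <- if (length(f) > 11L) f[12:length(f)] else character(0)
    xg <- grep(tagpat, tags, value = TRUE)
    bs <- if (length(xg)) {
      v <- sub(tagpat, "", xg[1])
      if (v == "CT") "+" else if (v == "GA") "-"
      else stopf("SAM line %d: unknown %s value '%s'", i, strand_tag, v)
    } else if (bitwAnd(flag, 16L) > 0L) "-" else "+"
    nm <- grep("^NM:i:", tags, value = TRUE)
    data.table::data.table(
      read_id = f[1], chrom = f[3], start = pos - 1L, bs_strand = bs,
      seq = toupper(f[10]), qual = f[11],
      mismatches = if (length(nm)) as.integer(sub("^NM:i:", "", nm[1]))
                   else NA_integer_,
      unique = TRUE)
  })
  res <- data.table::rbindlist(out)
  if (nrow(res) == 0L)
    return(data.table::data.table(read_id = character(), chrom = character(),
                                  start = integer(), bs_strand = character(),
                                  seq = character(), qual = character(),
                                  mismatches = integer(), unique = logical()))
  if (any(res$start + nchar(res$seq) > lens[res$chrom]))
    stopf("SAM record extends beyond chromosome bounds")
  res[]
}

#' Write aligned reads as a minimal SAM file
#'
#' Emits `@HD`/`@SQ` headers, flags 0/16, MAPQ 37, full-length match CIGAR
#' and an `XG` tag recording the interrogated strand.
#'
#' @param alignments output of [map_bs_reads] or [read_sam].
#' @param genome a `cyto_genome` (for `@SQ` headers).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_sam <- function(alignments, genome, path) {
  lens <- genome_lengths(genome)
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           sprintf("@SQ\tSN:%s\tLN:%d", names(lens), lens))
  a <- data.table::as.data.table(alignments)
  body <- sprintf("%s\t%d\t%s\t%d\t37\t%dM\t*\t0\t0\t%s\t%s\tXG:Z:%s",
                  a$read_id, ifelse(a$bs_strand == "-", 16L, 0L), a$chrom,
                  a$start + 1L, nchar(a$seq), a$seq, a$qual,
                  ifelse(a$bs_strand == "-", "GA", "CT"))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read reads from FASTQ
#' @param path FASTQ file.
#' @return `data.table` with `read_id`, `seq`, `qual`.
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq",
                                    with.qualities = TRUE)
  data.table::data.table(read_id = names(x), seq = as.character(x),
                         qual = as.character(S4Vectors::mcols(x)$qualities))
}

#' Write reads to FASTQ
#' @param reads `data.table` with `read_id`, `seq`, `qual`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  x <- Biostrings::DNAStringSet(reads$seq)
  names(x) <- reads$read_id
  Biostrings::writeXStringSet(x, path, format = "fastq",
                              qualities = Biostrings::BStringSet(reads$qual))
  invisible(path)
}
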