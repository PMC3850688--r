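## Shared fixtures and independent oracles, all built in code.

library(data.table)

## random genome of given length, fixed seed handled by caller
random_genome <- function(len, chrom = "chr1") {
  genome_from_seqs(setNames(
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = ""),
    chrom))
}

## a single-transcript gene model from an exon coordinate list
toy_gene <- function(gene_id, chrom, strand, exons, cds = exons) {
  rbindlist(list(
    data.table(gene_id = gene_id, transcript_id = paste0(gene_id, ".t1"),
               chrom = chrom, strand = strand, feature = "exon",
               start = vapply(exons, `[`, numeric(1), 1),
               end = vapply(exons, `[`, numeric(1), 2)),
    data.table(gene_id = gene_id, transcript_id = paste0(gene_id, ".t1"),
               chrom = chrom, strand = strand, feature = "CDS",
               start = vapply(cds, `[`, numeric(1), 1),
               end = vapply(cds, `[`, numeric(1), 2))))
}

## Independent context oracle: classify by literal string inspection of the
## plus strand, and of the reverse-complemented chromosome for minus sites.
oracle_context <- function(seq, pos, strand) {
  L <- nchar(seq)
  if (strand == "-") {
    rc <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(seq)))
    return(oracle_context(rc, L - 1L - pos, "+"))
  }
  tri <- substr(seq, pos + 1L, pos + 3L)
  if (substr(seq, pos + 1L, pos + 1L) != "C") return("not-C")
  if (nchar(tri) < 3L || grepl("N", tri)) return(NA_character_)
  if (substr(tri, 2L, 2L) == "G") "CG"
  else if (substr(tri, 3L, 3L) == "G") "CHG"
  else "CHH"
}

## Independent brute-force bisulfite mapper: scan every placement on both
## interrogation strands in the reduced alphabets.
oracle_map <- function(seq, read, max_mm = 2L) {
  reduce_ct <- function(x) chartr("C", "T", x)
  reduce_ga <- function(x) chartr("G", "A", x)
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(read)))
  L <- nchar(seq); l <- nchar(read)
  best <- list(mm = max_mm + 1L, pos = -1L, strand = NA, n = 0L)
  mm_at <- function(a, b) {
    va <- utf8ToInt(a); vb <- utf8ToInt(b)
    sum(va != vb)
  }
  for (probe in 1:2) {
    q <- if (probe == 1) reduce_ct(read) else reduce_ga(rc)
    ref <- if (probe == 1) reduce_ct(seq) else reduce_ga(seq)
    for (p in 0:(L - l)) {
      m <- mm_at(substr(ref, p + 1L, p + l), q)
      if (m < best$mm) best <- list(mm = m, pos = p,
                                    strand = c("+", "-")[probe], n = 1L)
      else if (m == best$mm) best$n <- best$n + 1L
    }
  }
  if (best$mm <= max_mm && best$n == 1L) best else NULL
}

## Independent three-level caller oracle: plain-space likelihood
## enumeration per observation (no aggregation, no log space).
oracle_call <- function(evidence, quals, conv_fail = 0.005,
                        error_floor = 1e-4) {
  levels <- c(0, 0.5, 1)
  lik <- vapply(levels, function(m) {
    prod(vapply(seq_along(evidence), function(i) {
      e <- max(10^(-quals[i] / 10), error_floor)
      pC <- m * (1 - e) + (1 - m) * (conv_fail * (1 - e) + (1 - conv_fail) * e)
      if (evidence[i] == "C") pC else 1 - pC
    }, numeric(1)))
  }, numeric(1))
  post <- lik / sum(lik)
  pick <- which.max(post)  # which.max takes the first (lower) level on ties
  list(level = levels[pick], posterior = post,
       Q = min(-10 * log10(max(1 - post[pick], 1e-300)), 255))
}

## small deterministic pileup row builder
pileup_row <- function(pos, strand, qual, c_count, t_count,
                       chrom = "chr1") {
  data.table(chrom = chrom, pos = as.integer(pos), strand = strand,
             qual = as.integer(qual), c_count = as.integer(c_count),
             t_count = as.integer(t_count))
}

## calls table builder for summarize-level tests (already-called sites)
calls_table <- function(pos, context, level, chrom = "chr1", strand = "+",
                        pass = TRUE) {
  n <- max(length(pos), length(context), length(level))
  data.table(chrom = chrom, pos = as.integer(rep_len(pos, n)),
             strand = rep_len(strand, n),
             context = rep_len(context, n),
             trinuc = NA_character_,
             level = rep_len(level, n), Q = 99, depth = 10L,
             c_count = 5L, t_count = 5L, pass = rep_len(pass, n))
}
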