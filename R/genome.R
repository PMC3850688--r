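#' Construct a genome object
#'
#' A genome is a named character vector of uppercase chromosome sequences
#' over the alphabet A, C, G, T, N. All positions in the package are
#' 0-based half-open internally; text reports use 1-based coordinates.
#'
#' @param seqs named character vector (or named list) of sequences.
#' @return an object of class `cyto_genome` (a validated named character
#'   vector).
#' @examples
#' g <- genome_from_seqs(c(chr1 = "ACGTACGT"))
#' genome_lengths(g)
#' @export
genome_from_seqs <- function(seqs) {
  seqs <- unlist(seqs)
  if (length(seqs) == 0L) stopf("genome must contain at least one sequence")
  if (is.null(names(seqs)) || anyNA(names(seqs)) || any(names(seqs) == ""))
    stopf("every chromosome must be named")
  if (anyDuplicated(names(seqs)))
    stopf("chromosome names must be unique")
  seqs <- toupper(seqs)
  if (any(nchar(seqs) == 0L)) stopf("every sequence must be non-empty")
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad))
    stopf("sequence '%s' contains characters outside A,C,G,T,N",
          names(seqs)[which(bad)[1]])
  structure(seqs, class = "cyto_genome")
}

#' @export
print.cyto_genome <- function(x, ...) {
  cat(sprintf("<cyto_genome> %d sequence(s), %s bases total\n",
              length(x), format(sum(nchar(x)), big.mark = ",")))
  invisible(x)
}

#' Chromosome lengths of a genome
#' @param genome a `cyto_genome`.
#' @return named integer vector of sequence lengths.
#' @export
genome_lengths <- function(genome) {
  setNames(nchar(unclass(genome)), names(genome))
}

genome_seq <- function(genome, chrom) {
  if (!chrom %in% names(genome))
    stopf("chromosome '%s' not in genome", chrom)
  unclass(genome)[[chrom]]
}

#' Read a genome from FASTA
#' @param path FASTA file path.
#' @return a `cyto_genome`.
#' @export
read_genome_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  nm <- sub("\\s.*$", "", names(x))
  genome_from_seqs(setNames(as.character(x), nm))
}

#' Write a genome to FASTA
#' @param genome a `cyto_genome`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(genome, path) {
  x <- Biostrings::DNAStringSet(unclass(genome))
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

## cache of context-code scans, keyed by chromosome content hash
context_codes <- function(genome, chrom) {
  seq <- genome_seq(genome, chrom)
  context_codes_cpp(seq)
}

CONTEXT_LEVELS <- c("CG", "CHG", "CHH")

code_to_klass <- function(code) {
  out <- rep(NA_character_, length(code))
  out[code == 1L] <- "CG"
  out[code == 2L] <- "CHG"
  out[code == 3L] <- "CHH"
  out
}

#' Classify the context of a cytosine
#'
#' Determines the CG / CHG / CHH class (H = A, T or C) of a strand-specific
#' cytosine and its trinucleotide, read 5'->3' on the cytosine's own strand.
#' The context is the `NA` sentinel (not an error) when the trinucleotide
#' window runs off the chromosome or contains an N.
#'
#' @param genome a `cyto_genome`.
#' @param chrom chromosome name.
#' @param pos 0-based position(s) of the cytosine.
#' @param strand `"+"` or `"-"` (recycled). On the minus strand the
#'   reference base must be G.
#' @return a `data.table` with columns `chrom`, `pos`, `strand`, `klass`,
#'   `trinuc` (`klass`/`trinuc` are `NA` for undefined contexts).
#' @examples
#' g <- genome_from_seqs(c(chr1 = "ACGT"))
#' classify_context(g, "chr1", 1, "+")  # CG, trinucleotide CGT
#' @export
classify_context <- function(genome, chrom, pos, strand = "+") {
  seq <- genome_seq(genome, chrom)
  L <- nchar(seq)
  pos <- as.integer(pos)
  n <- max(length(pos), length(strand))
  pos <- rep_len(pos, n)
  strand <- rep_len(strand, n)
  if (any(pos < 0L | pos >= L))
    stopf("position out of range for chromosome '%s'", chrom)
  if (!all(strand %in% c("+", "-"))) stopf("strand must be '+' or '-'")
  base <- substring(seq, pos + 1L, pos + 1L)
  need <- ifelse(strand == "+", "C", "G")
  if (any(base != need))
    stopf("base at position %d is not a cytosine on strand %s",
          pos[which(base != need)[1]] + 1L, strand[which(base != need)[1]])
  codes <- context_codes(genome, chrom)
  code <- ifelse(strand == "+", codes$plus[pos + 1L], codes$minus[pos + 1L])
  klass <- code_to_klass(code)
  trinuc <- rep(NA_character_, n)
  okp <- strand == "+" & !is.na(klass)
  if (any(okp))
    trinuc[okp] <- substring(seq, pos[okp] + 1L, pos[okp] + 3L)
  okm <- strand == "-" & !is.na(klass)
  if (any(okm))
    trinuc[okm] <- revcomp(substring(seq, pos[okm] - 1L, pos[okm] + 1L))
  data.table::data.table(chrom = chrom, pos = pos, strand = strand,
                         klass = klass, trinuc = trinuc)
}

#' Symmetric-partner position of a CG or CHG cytosine
#'
#' CG and CHG contexts are palindromic: the opposite strand carries a
#' cytosine whose methylation state can mirror this one. CHH contexts have
#' no partner.
#'
#' @param klass `"CG"`, `"CHG"` or `"CHH"`.
#' @param pos 0-based position of the cytosine.
#' @param strand `"+"` or `"-"`.
#' @return a list with `pos` and `strand` of the partner, or `NULL` for CHH.
#'   Bounds are not checked (caller's responsibility).
#' @examples
#' partner_position("CG", 10, "+")   # pos 11, minus strand
#' partner_position("CHH", 10, "+")  # NULL
#' @export
partner_position <- function(klass, pos, strand) {
  if (!klass %in% CONTEXT_LEVELS) stopf("unknown context class '%s'", klass)
  if (klass == "CHH") return(NULL)
  off <- if (klass == "CG") 1L else 2L
  if (strand == "+") list(pos = pos + off, strand = "-")
  else list(pos = pos - off, strand = "+")
}

## vectorized partner positions for internal use; NA for CHH
partner_pos_vec <- function(klass, pos, strand) {
  off <- ifelse(klass == "CG", 1L, ifelse(klass == "CHG", 2L, NA_integer_))
  list(pos = ifelse(strand == "+", pos + off, pos - off),
       strand = ifelse(strand == "+", "-", "+"))
}

#' Enumerate all cytosine sites of a genome
#'
#' Lists every strand-specific cytosine with a defined context. Cytosines
#' whose trinucleotide window contains an N or runs off the chromosome are
#' excluded (they enter no denominator anywhere in the package).
#'
#' @param genome a `cyto_genome`.
#' @return `data.table` with `chrom`, `pos` (0-based), `strand`, `context`.
#' @export
cytosine_sites <- function(genome) {
  res <- lapply(names(genome), function(chrom) {
    codes <- context_codes(genome, chrom)
    pp <- which(codes$plus > 0L) - 1L
    pm <- which(codes$minus > 0L) - 1L
    data.table::data.table(
      chrom = chrom,
      pos = c(pp, pm),
      strand = rep(c("+", "-"), c(length(pp), length(pm))),
      context = c(code_to_klass(codes$plus[pp + 1L]),
                  code_to_klass(codes$minus[pm + 1L])))
  })
  data.table::rbindlist(res)
}
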