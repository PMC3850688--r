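#' Default region-by-context modification rates
#'
#' Per-site probabilities that a cytosine in a given (region, context) cell
#' carries 5mC or 5hmC. The defaults emulate the European-honey-bee-like
#' pattern: CG methylation concentrated in exons (6.26%), CHH/CHG
#' modification concentrated in introns (3.99% / 1.08%), with a substantial
#' 5hmC share of the intronic and intergenic non-CG modification. Regions
#' here are the simulator's exclusive site classes (priority Exon > Intron >
#' Upstream > Downstream > Intergenic), not the non-exclusive summary
#' labels.
#'
#' @return `data.table` with columns `region`, `context`, `p_5mC`, `p_5hmC`.
#' @export
default_modification_rates <- function() {
  data.table::rbindlist(list(
    data.table::data.table(
      region = "Exon", context = c("CG", "CHG", "CHH"),
      p_5mC = c(0.0626, 0.0112, 0.0233), p_5hmC = c(0, 0, 0)),
    data.table::data.table(
      region = "Intron", context = c("CG", "CHG", "CHH"),
      p_5mC = c(0.0109, 0.0054, 0.0200), p_5hmC = c(0, 0.0054, 0.0199)),
    data.table::data.table(
      region = "Upstream", context = c("CG", "CHG", "CHH"),
      p_5mC = c(0.0356, 0.0126, 0.0346), p_5hmC = c(0, 0, 0)),
    data.table::data.table(
      region = "Downstream", context = c("CG", "CHG", "CHH"),
      p_5mC = c(0.0397, 0.0135, 0.0364), p_5hmC = c(0, 0, 0)),
    data.table::data.table(
      region = "Intergenic", context = c("CG", "CHG", "CHH"),
      p_5mC = c(0.0107, 0.0110, 0.0200), p_5hmC = c(0, 0, 0.0207))
  ))
}

#' Simulation configuration
#'
#' Bundles every tunable of the synthetic-data generator. Randomness is
#' reproducible: each generator seeds R's RNG with `seed` plus a fixed
#' per-stage offset (genome +0, methylome +1, bisulfite reads +2,
#' restriction digestion +3, immunoprecipitation fragments +4), so each
#' stage is individually deterministic given (seed, config).
#'
#' @param seed integer seed.
#' @param genome_length total genome length in bases.
#' @param n_genes number of non-overlapping genes to place.
#' @param coverage target fold-coverage of bisulfite reads.
#' @param read_length read length in bases (default 76).
#' @param conv_fail bisulfite non-conversion probability c (default 0.005).
#' @param seq_error per-base sequencing miscall probability e
#'   (default 0.001).
#' @param base_quality constant phred base quality of simulated reads.
#' @param rates region-by-context modification rate table
#'   ([default_modification_rates]).
#' @param sym_comod probability that the opposite-strand partner of a
#'   modified CG site is co-modified (default 0.21).
#' @param hemi_fraction fraction of modified strand-sites planted at level
#'   0.5 (hemi-modified on this strand's site in half of molecules).
#' @param flank,splice_site region-index parameters used when planting.
#' @param pvu_offsets_top,pvu_offsets_bottom PvuRts1I cut offsets 3' of a
#'   5hmC: 11-13 bases on the top strand, 9-10 on the bottom strand.
#' @param pvu_mean_fragments Poisson mean number of fragment ends emitted
#'   per 5hmC site.
#' @param pvu_background_rate per-base probability of a spurious cut.
#' @param dip_fragment_range sheared-fragment length range in bases
#'   (default 300-600).
#' @param dip_mean_fragments Poisson mean fragments per targeted site.
#' @param dip_background_rate per-base probability of a background fragment
#'   start.
#' @param oe_low,oe_high target o/e CpG ratios of the two gene classes.
#' @param frac_low_oe fraction of genes in the low-o/e class.
#' @return a `sim_config` list.
#' @export
sim_config <- function(seed = 1L, genome_length = 1e5, n_genes = 10L,
                       coverage = 20, read_length = 76L, conv_fail = 0.005,
                       seq_error = 0.001, base_quality = 30L,
                       rates = default_modification_rates(),
                       sym_comod = 0.21, hemi_fraction = 0.1,
                       flank = 3000L, splice_site = 2L,
                       pvu_offsets_top = 11:13, pvu_offsets_bottom = 9:10,
                       pvu_mean_fragments = 10, pvu_background_rate = 0,
                       dip_fragment_range = c(300L, 600L),
                       dip_mean_fragments = 10, dip_background_rate = 0,
                       oe_low = 0.6, oe_high = 1.2, frac_low_oe = 0.5) {
  probs <- c(conv_fail, seq_error, sym_comod, hemi_fraction,
             pvu_background_rate, dip_background_rate,
             rates$p_5mC, rates$p_5hmC)
  if (any(probs < 0 | probs > 1)) stopf("probabilities must lie in [0, 1]")
  if (any(rates$p_5mC + rates$p_5hmC > 1))
    stopf("p_5mC + p_5hmC must not exceed 1")
  if (length(pvu_offsets_top) == 0L || length(pvu_offsets_bottom) == 0L)
    stopf("cut offset sets must be non-empty")
  if (dip_fragment_range[1] >= dip_fragment_range[2])
    stopf("fragment range low must be < high")
  structure(list(
    seed = as.integer(seed), genome_length = as.integer(genome_length),
    n_genes = as.integer(n_genes), coverage = coverage,
    read_length = as.integer(read_length), conv_fail = conv_fail,
    seq_error = seq_error, base_quality = as.integer(base_quality),
    rates = data.table::as.data.table(rates), sym_comod = sym_comod,
    hemi_fraction = hemi_fraction, flank = as.integer(flank),
    splice_site = as.integer(splice_site),
    pvu_offsets_top = as.integer(pvu_offsets_top),
    pvu_offsets_bottom = as.integer(pvu_offsets_bottom),
    pvu_mean_fragments = pvu_mean_fragments,
    pvu_background_rate = pvu_background_rate,
    dip_fragment_range = as.integer(dip_fragment_range),
    dip_mean_fragments = dip_mean_fragments,
    dip_background_rate = dip_background_rate,
    oe_low = oe_low, oe_high = oe_high, frac_low_oe = frac_low_oe),
    class = "sim_config")
}

## Rewrite a gene-span sequence so its CpG o/e moves toward a target.
## Thinning (target < 1): each CG keeps its G with probability 4t/(?) solved
## from oe' = 4f/(3+f); boosting (target > 1): each C followed by a non-G
## gains a G with probability q solved from oe' = (1+3q)/(1+3q/4).
adjust_cg_density <- function(bases, target) {
  n <- length(bases)
  if (n < 2L) return(bases)
  if (target < 1) {
    f <- 3 * target / (4 - target)      # keep probability
    cg <- which(bases[-n] == "C" & bases[-1L] == "G")
    drop <- cg[runif(length(cg)) >= f]
    if (length(drop))
      bases[drop + 1L] <- sample(c("A", "T", "C"), length(drop),
                                 replace = TRUE)
  } else if (target > 1) {
    q <- 4 * (target - 1) / (3 * (4 - target))  # conversion probability
    q <- min(max(q, 0), 1)
    cx <- which(bases[-n] == "C" & bases[-1L] != "G")
    conv <- cx[runif(length(cx)) < q]
    if (length(conv)) bases[conv + 1L] <- "G"
  }
  bases
}

#' Simulate a gene-bearing genome
#'
#' Generates a uniform-random background sequence and places
#' non-overlapping multi-exon genes separated by at least one flank length.
#' Genes fall into two classes whose spans are rewritten to low (~0.6) or
#' high (~1.2) CpG o/e, so [compute_oe] on the result is bimodal. Intron
#' boundaries carry canonical GT...AG splice motifs in transcription order.
#'
#' @param config a [sim_config].
#' @return list with elements `genome` (a `cyto_genome`) and `genes` (a
#'   gene-model table; empty when `n_genes = 0`). The gene table gains an
#'   `oe_class` attribute naming each gene's class.
#' @export
simulate_genome <- function(config) {
  set.seed(config$seed)
  L <- config$genome_length
  bases <- sample(c("A", "C", "G", "T"), L, replace = TRUE)

  genes <- data.table::data.table(
    gene_id = character(), transcript_id = character(), chrom = character(),
    strand = character(), feature = character(), start = integer(),
    end = integer())
  oe_class <- character(0)

  if (config$n_genes > 0L) {
    n <- config$n_genes
    ## draw structures first so the packing check is exact
    structs <- lapply(seq_len(n), function(i) {
      ne <- sample(2:4, 1)
      ex_len <- sample(150:400, ne, replace = TRUE)
      in_len <- sample(200:1200, ne - 1L, replace = TRUE)
      list(ex = ex_len, intr = in_len, span = sum(ex_len) + sum(in_len))
    })
    spans <- vapply(structs, `[[`, numeric(1), "span")
    gap <- config$flank + 100L
    need <- sum(spans) + gap * (n + 1L)
    if (need > L)
      stopf("infeasible packing: %d genes need %d bases, genome has %d",
            n, need, L)
    extra <- L - need
    cuts <- sort(sample.int(extra + 1L, n + 1L, replace = TRUE) - 1L)
    gaps <- gap + diff(c(0L, cuts))

    n_low <- round(n * config$frac_low_oe)
    cls <- sample(rep(c("low", "high"), c(n_low, n - n_low)))
    cursor <- gaps[1]
    rows <- vector("list", n)
    for (i in seq_len(n)) {
      st <- structs[[i]]
      strand <- sample(c("+", "-"), 1)
      s0 <- cursor
      ex_start <- integer(length(st$ex))
      ex_end <- integer(length(st$ex))
      p <- s0
      for (j in seq_along(st$ex)) {
        ex_start[j] <- p
        ex_end[j] <- p + st$ex[j]
        p <- ex_end[j] + if (j < length(st$ex)) st$intr[j] else 0L
      }
      gid <- sprintf("g%04d", i)
      rows[[i]] <- data.table::data.table(
        gene_id = gid, transcript_id = paste0(gid, ".t1"), chrom = "chr1",
        strand = strand,
        feature = rep(c("exon", "CDS"), each = length(st$ex)),
        start = rep(ex_start, 2L), end = rep(ex_end, 2L))
      span_end <- ex_end[length(ex_end)]
      target <- if (cls[i] == "low") config$oe_low else config$oe_high
      bases[(s0 + 1L):span_end] <-
        adjust_cg_density(bases[(s0 + 1L):span_end], target)
      ## canonical splice motifs, transcription order
      for (j in seq_len(length(st$ex) - 1L)) {
        is <- ex_end[j]; ie <- ex_start[j + 1L]
        if (strand == "+") {
          bases[(is + 1L):(is + 2L)] <- c("G", "T")
          bases[(ie - 1L):ie] <- c("A", "G")
        } else {
          bases[(ie - 1L):ie] <- c("A", "C")   # revcomp(GT)
          bases[(is + 1L):(is + 2L)] <- c("C", "T")  # revcomp(AG)
        }
      }
      cursor <- span_end + gaps[i + 1L]
      oe_class <- c(oe_class, cls[i])
    }
    genes <- data.table::rbindlist(rows)
  }

  genome <- genome_from_seqs(c(chr1 = paste(bases, collapse = "")))
  genes <- validate_gene_model(genes, genome)
  data.table::setattr(genes, "oe_class",
                      setNames(oe_class, unique(genes$gene_id)))
  list(genome = genome, genes = genes)
}

## exclusive region class per site for rate lookup
site_region_class <- function(index, chrom, pos) {
  out <- rep("Intergenic", length(pos))
  for (l in c("Downstream", "Upstream", "Intron", "Exon")) {
    out[label_member(index, l, chrom, pos)] <- l
  }
  out
}

#' Plant a ground-truth methylome
#'
#' Assigns each cytosine site a state (unmodified / 5mC / 5hmC) from its
#' (region, context) rate. CHG/CHH sites (and CG sites without a complete
#' opposite-strand partner) draw independently. Complete CG pairs draw
#' jointly so that each strand-site keeps the marginal rate p of its rate
#' cell while a fraction `sym_comod` of modified CG sites sit in
#' both-modified pairs (both modified with probability `sym_comod * p`,
#' each single strand with probability `(1 - sym_comod) * p`, mirroring the
#' published symmetric-methylation share without inflating the marginal).
#' Modified sites get level 1, or 0.5 (hemi) with probability
#' `hemi_fraction`; a co-modified pair shares one state and level.
#'
#' @param genome a `cyto_genome`.
#' @param genes gene-model table.
#' @param config a [sim_config].
#' @return `data.table` of modified sites only: `chrom`, `pos` (0-based),
#'   `strand`, `context`, `region`, `state` (`"5mC"`/`"5hmC"`), `level`
#'   (0.5 or 1). Unlisted cytosines are unmodified (level 0).
#' @export
plant_methylome <- function(genome, genes, config) {
  set.seed(config$seed + 1L)
  index <- build_region_index(genes, genome, config$flank,
                              config$splice_site)
  sites <- cytosine_sites(genome)
  sites[, region := site_region_class(index, chrom[1], pos), by = chrom]

  rates <- config$rates
  key <- paste(sites$region, sites$context)
  rkey <- paste(rates$region, rates$context)
  missing <- setdiff(unique(key), rkey)
  if (length(missing))
    stopf("rate table missing (region, context) key(s): %s",
          paste(missing, collapse = "; "))
  m <- match(key, rkey)
  sites[, `:=`(p_m = rates$p_5mC[m], p_h = rates$p_5hmC[m])]

  ## locate complete CG pairs: plus-strand CG at i with minus-strand CG at
  ## i + 1 (the partner is absent only near N bases or chromosome edges)
  sites[, sid := .I]
  plus_cg <- sites[context == "CG" & strand == "+"]
  minus_cg <- sites[context == "CG" & strand == "-",
                    .(chrom, pos, minus_sid = sid)]
  pairs <- minus_cg[plus_cg[, .(chrom, pos = pos + 1L, plus_sid = sid)],
                    on = c("chrom", "pos"), nomatch = NULL]
  paired <- c(pairs$plus_sid, pairs$minus_sid)

  draw_state <- function(pm, ph) {
    p <- pm + ph
    ifelse(p <= 0, "5mC",
           ifelse(runif(length(pm)) < pm / pmax(p, 1e-300), "5mC", "5hmC"))
  }
  draw_level <- function(n) ifelse(runif(n) < config$hemi_fraction, 0.5, 1)

  sites[, `:=`(state = "none", level = 0)]

  ## independent draws for everything outside complete CG pairs
  solo <- sites[!sid %in% paired]
  u <- runif(nrow(solo))
  solo_state <- ifelse(u < solo$p_m, "5mC",
                       ifelse(u < solo$p_m + solo$p_h, "5hmC", "none"))
  solo_mod <- which(solo_state != "none")
  sites[solo$sid, state := solo_state]
  sites[solo$sid[solo_mod], level := draw_level(length(solo_mod))]

  ## joint pair draws preserving the marginal rate p per strand-site while
  ## a share sym_comod of modified sites fall in both-modified pairs
  if (nrow(pairs)) {
    s <- config$sym_comod
    pp <- sites[pairs$plus_sid, p_m + p_h]
    ## both-modified probability: s*p targets the symmetric share, but the
    ## marginals force at least 2p - 1 (at p = 1 every pair is symmetric)
    b <- pmax(s * pp, 2 * pp - 1)
    u <- runif(nrow(pairs))
    kind <- ifelse(u < b, "both",
                   ifelse(u < pp, "plus",
                          ifelse(u < 2 * pp - b, "minus", "none")))
    modp <- kind %in% c("both", "plus")
    modm <- kind %in% c("both", "minus")
    st <- draw_state(sites[pairs$plus_sid, p_m], sites[pairs$plus_sid, p_h])
    lv <- draw_level(nrow(pairs))
    sites[pairs$plus_sid[modp], `:=`(state = st[modp], level = lv[modp])]
    sites[pairs$minus_sid[modm], `:=`(state = st[modm], level = lv[modm])]
  }
  out <- sites[state != "none",
               .(chrom, pos, strand, context, region, state, level)]
  data.table::setkey(out, chrom, pos, strand)
  out[]
}

## per-chromosome planted level vectors (length L, by position)
truth_level_vectors <- function(truth, genome) {
  lens <- genome_lengths(genome)
  lapply(setNames(names(lens), names(lens)), function(ch) {
    lp <- numeric(lens[[ch]])
    lm <- numeric(lens[[ch]])
    tt <- truth[chrom == ch]
    tp <- tt[strand == "+"]
    tm <- tt[strand == "-"]
    lp[tp$pos + 1L] <- tp$level
    lm[tm$pos + 1L] <- tm$level
    list(plus = lp, minus = lm)
  })
}

#' Simulate whole-genome bisulfite reads
#'
#' Reads are drawn uniformly from both strands. For each cytosine on the
#' read's origin strand: the molecule is modified with probability equal to
#' the planted level; an unmodified cytosine converts to T with probability
#' `1 - conv_fail`; finally every base suffers a symmetric miscall with
#' probability `seq_error`. Read names carry origin metadata after `|`
#' separators (`id|chrom|start0|strand`).
#'
#' @param genome a `cyto_genome`.
#' @param truth planted methylome from [plant_methylome] (may be empty).
#' @param config a [sim_config].
#' @param n_reads optional read count override (default from coverage).
#' @return `data.table` with `read_id`, `seq`, `qual`, and origin columns
#'   `chrom`, `start` (0-based), `strand`.
#' @export
simulate_bs_reads <- function(genome, truth, config, n_reads = NULL) {
  set.seed(config$seed + 2L)
  if (config$coverage <= 0 && is.null(n_reads))
    stopf("coverage must be > 0")
  lens <- genome_lengths(genome)
  if (config$read_length > max(lens))
    stopf("read length exceeds genome length")
  if (is.null(n_reads))
    n_reads <- ceiling(config$coverage * sum(lens) / config$read_length)
  lv <- truth_level_vectors(truth, genome)
  w <- pmax(lens - config$read_length + 1L, 0L)
  chrom_of <- sample(names(lens), n_reads, replace = TRUE, prob = w)
  res <- lapply(names(lens), function(ch) {
    nr <- sum(chrom_of == ch)
    if (nr == 0L) return(NULL)
    sim <- simulate_reads_cpp(genome_seq(genome, ch), lv[[ch]]$plus,
                              lv[[ch]]$minus, nr, config$read_length,
                              config$conv_fail, config$seq_error)
    data.table::data.table(chrom = ch, start = sim$start,
                           strand = ifelse(sim$strand == 0L, "+", "-"),
                           seq = sim$seq)
  })
  out <- data.table::rbindlist(res)
  out[, read_id := sprintf("r%07d|%s|%d|%s", .I, chrom, start, strand)]
  out[, qual := strrep(rawToChar(as.raw(config$base_quality + 33L)),
                       config$read_length)]
  out[, .(read_id, seq, qual, chrom, start, strand)]
}

#' Simulate PvuRts1I digestion fragment ends
#'
#' Each planted 5hmC site emits a Poisson number of cuts at a fixed offset
#' 3' of the modified cytosine on its own strand: a 5hmC at plus-strand
#' position q cuts the top strand at q + d (d drawn uniformly from
#' `pvu_offsets_top`), a minus-strand 5hmC cuts the bottom strand at q - d
#' (d from `pvu_offsets_bottom`). Background cuts occur at
#' `pvu_background_rate` per base per strand.
#'
#' @param genome a `cyto_genome`.
#' @param truth planted methylome.
#' @param config a [sim_config].
#' @return `data.table` of cut records: `chrom`, `pos` (0-based cut
#'   position), `strand` (`+` = top).
#' @export
simulate_pvu_digestion <- function(genome, truth, config) {
  set.seed(config$seed + 3L)
  lens <- genome_lengths(genome)
  hmc <- truth[state == "5hmC"]
  res <- list()
  if (nrow(hmc)) {
    nfrag <- rpois(nrow(hmc), config$pvu_mean_fragments)
    idx <- rep(seq_len(nrow(hmc)), nfrag)
    if (length(idx)) {
      site <- hmc[idx]
      top <- site$strand == "+"
      d <- integer(length(idx))
      ot <- config$pvu_offsets_top
      ob <- config$pvu_offsets_bottom
      d[top] <- ot[sample.int(length(ot), sum(top), replace = TRUE)]
      d[!top] <- ob[sample.int(length(ob), sum(!top), replace = TRUE)]
      res$sites <- data.table::data.table(
        chrom = site$chrom,
        pos = ifelse(top, site$pos + d, site$pos - d),
        strand = site$strand)
    }
  }
  if (config$pvu_background_rate > 0) {
    bg <- lapply(names(lens), function(ch) {
      nb <- rpois(1, 2 * lens[[ch]] * config$pvu_background_rate)
      if (nb == 0L) return(NULL)
      data.table::data.table(chrom = ch,
                             pos = sample.int(lens[[ch]], nb, TRUE) - 1L,
                             strand = sample(c("+", "-"), nb, TRUE))
    })
    res$bg <- data.table::rbindlist(bg)
  }
  out <- data.table::rbindlist(res)
  if (nrow(out) == 0L)
    return(data.table::data.table(chrom = character(), pos = integer(),
                                  strand = character()))
  out <- out[pos >= 0L & pos < lens[chrom]]
  data.table::setorder(out, chrom, pos, strand)
  out[]
}

#' Simulate immunoprecipitation fragments
#'
#' For each modified site of the targeted state, emits a Poisson number of
#' sheared fragments with length uniform in `dip_fragment_range` that
#' contain the site at a uniform internal offset, mimicking
#' antibody pulldown of modified DNA; optional uniform background
#' fragments.
#'
#' @param genome a `cyto_genome` (for chromosome bounds).
#' @param truth planted methylome.
#' @param config a [sim_config].
#' @param target `"5hmC"` (hydroxymethyl pulldown) or `"5mC"`.
#' @return `data.table` of intervals: `chrom`, `start`, `end` (0-based
#'   half-open).
#' @export
simulate_dip_fragments <- function(genome, truth, config,
                                   target = c("5hmC", "5mC")) {
  target <- match.arg(target)
  set.seed(config$seed + 4L)
  lens <- genome_lengths(genome)
  lo <- config$dip_fragment_range[1]
  hi <- config$dip_fragment_range[2]
  sites <- truth[state == target]
  res <- list()
  if (nrow(sites)) {
    nfrag <- rpois(nrow(sites), config$dip_mean_fragments)
    idx <- rep(seq_len(nrow(sites)), nfrag)
    if (length(idx)) {
      site <- sites[idx]
      len <- sample(lo:hi, length(idx), replace = TRUE)
      off <- floor(runif(length(idx)) * len)  # site offset inside fragment
      start <- site$pos - off
      res$sites <- data.table::data.table(chrom = site$chrom, start = start,
                                          end = start + len)
    }
  }
  if (config$dip_background_rate > 0) {
    bg <- lapply(names(lens), function(ch) {
      nb <- rpois(1, lens[[ch]] * config$dip_background_rate)
      if (nb == 0L) return(NULL)
      len <- sample(lo:hi, nb, replace = TRUE)
      start <- sample.int(lens[[ch]], nb, TRUE) - 1L
      data.table::data.table(chrom = ch, start = start, end = start + len)
    })
    res$bg <- data.table::rbindlist(bg)
  }
  out <- data.table::rbindlist(res)
  if (nrow(out) == 0L)
    return(data.table::data.table(chrom = character(), start = integer(),
                                  end = integer()))
  ## clip to chromosome bounds, preserving length where possible
  out[, start := pmax(start, 0L)]
  out[, end := pmin(end, lens[chrom])]
  out <- out[end > start]
  data.table::setorder(out, chrom, start)
  out[]
}

#' Write the planted methylome as a TSV truth table
#' @param truth planted methylome.
#' @param path output file.
#' @return `path`, invisibly. Positions are written 1-based.
#' @export
write_truth_tsv <- function(truth, path) {
  out <- data.table::copy(truth)[, pos := pos + 1L]
  data.table::fwrite(out, path, sep = "\t")
  invisible(path)
}

#' Read a truth table written by [write_truth_tsv]
#' @param path TSV file.
#' @return `data.table` with 0-based positions.
#' @export
read_truth_tsv <- function(path) {
  x <- data.table::fread(path, sep = "\t")
  x[, pos := pos - 1L]
  x[]
}
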