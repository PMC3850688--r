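#' Build a per-site bisulfite pileup
#'
#' Collects, for every strand-specific cytosine with a defined context, the
#' C-retained vs converted evidence from uniquely aligned reads whose
#' interrogated strand matches the site strand. Two read-level filters from
#' whole-genome bisulfite practice are applied: an observation is discarded
#' when the read has a reduced-alphabet mismatch within `context_window`
#' bases of the cytosine, and (optionally) a whole read is discarded when it
#' contains three or more consecutive C-retained CHH cytosines
#' ([chh_read_filter]).
#'
#' @param alignments unique alignments from [map_bs_reads] or [read_sam].
#' @param genome a `cyto_genome`.
#' @param chh_filter apply the consecutive-CHH read filter (default
#'   `FALSE`; the unbiased caller keeps such reads, the conservative mode
#'   drops them).
#' @param context_window half-width of the mismatch-discard window in bases
#'   (default 2).
#' @return `data.table` aggregated per (site, base quality): `chrom`, `pos`
#'   (0-based), `strand`, `qual`, `c_count`, `t_count`.
#' @export
build_pileup <- function(alignments, genome, chh_filter = FALSE,
                         context_window = 2L) {
  a <- data.table::as.data.table(alignments)
  lens <- genome_lengths(genome)
  if (nrow(a) && any(a$start < 0L | a$start + nchar(a$seq) > lens[a$chrom]))
    stopf("alignment beyond chromosome bounds")
  res <- lapply(names(lens), function(ch) {
    sub <- a[chrom == ch]
    if (nrow(sub) == 0L) return(NULL)
    codes <- context_codes(genome, ch)
    pu <- pileup_cpp(genome_seq(genome, ch), codes$plus, codes$minus,
                     sub$start, ifelse(sub$bs_strand == "+", 0L, 1L),
                     sub$seq, sub$qual, chh_filter,
                     as.integer(context_window), 33L)
    pu <- data.table::as.data.table(pu)
    pu[, chrom := ch]
    pu
  })
  out <- data.table::rbindlist(res)
  if (nrow(out) == 0L)
    return(data.table::data.table(chrom = character(), pos = integer(),
                                  strand = character(), qual = integer(),
                                  c_count = integer(), t_count = integer()))
  out[, strand := ifelse(strand == 0L, "+", "-")]
  data.table::setcolorder(out, c("chrom", "pos", "strand", "qual",
                                 "c_count", "t_count"))
  data.table::setorder(out, chrom, pos, strand, qual)
  out[]
}

#' Consecutive-CHH read filter
#'
#' Discards a read when three or more consecutive CHH cytosines on it (no
#' intervening CHH) are all C-retained; cytosines in other contexts do not
#' interrupt a run but do not extend it either.
#'
#' @param states per-read cytosine states in position order: `"C"`
#'   (retained) or `"T"` (converted).
#' @param contexts matching context classes (`"CG"`, `"CHG"`, `"CHH"`).
#' @return `"keep"` or `"discard"`.
#' @examples
#' chh_read_filter(c("C", "C", "C"), c("CHH", "CHH", "CHH"))  # discard
#' chh_read_filter(c("C", "C", "T", "C"), rep("CHH", 4))      # keep
#' @export
chh_read_filter <- function(states, contexts) {
  stopifnot(length(states) == length(contexts))
  run <- 0L
  for (i in seq_along(states)) {
    if (contexts[i] != "CHH") next
    if (states[i] == "C") {
      run <- run + 1L
      if (run >= 3L) return("discard")
    } else {
      run <- 0L
    }
  }
  "keep"
}

#' Calling-model parameters
#'
#' The caller models each observation as a Bernoulli draw: the probability
#' of seeing a retained C given true level m is
#' `P(C | m) = m (1 - e) + (1 - m) (c (1 - e) + (1 - c) e)`, where c is the
#' bisulfite non-conversion probability and e the per-base miscall
#' probability derived from the read base quality (floored at
#' `error_floor`). The prior over the three levels {0, 0.5, 1} is uniform.
#'
#' @param conversion_fail non-conversion probability c (default 0.005).
#' @param error_floor lower bound on the per-base error probability
#'   (default 1e-4).
#' @param min_depth minimum depth for a call to pass (default 1).
#' @param q_cap phred cap on call quality (default 255).
#' @return a `call_params` list.
#' @export
call_params <- function(conversion_fail = 0.005, error_floor = 1e-4,
                        min_depth = 1L, q_cap = 255) {
  if (conversion_fail < 0 || conversion_fail >= 0.5)
    stopf("conversion_fail must lie in [0, 0.5)")
  list(conversion_fail = conversion_fail, error_floor = error_floor,
       min_depth = as.integer(min_depth), q_cap = q_cap)
}

CALL_LEVELS <- c(0, 0.5, 1)

## log-likelihood contribution of an aggregated (qual, c, t) row at level m
ll_row <- function(m, e, cc, tt, c_fail) {
  pC <- m * (1 - e) + (1 - m) * (c_fail * (1 - e) + (1 - c_fail) * e)
  cc * log(pC) + tt * log1p(-pC)
}

#' Call three-level methylation per site
#'
#' Computes the posterior over levels {0, 0.5, 1} in log space from the
#' aggregated pileup, calls the maximum-posterior level (ties broken toward
#' the lower level), and attaches a phred-scaled call quality
#' `Q = -10 log10(1 - posterior)`, capped. A call passes when `Q >= 20` and
#' depth reaches `min_depth`.
#'
#' @param pileup output of [build_pileup].
#' @param genome a `cyto_genome` (context annotation).
#' @param params a [call_params].
#' @param keep_posterior attach the three posterior columns (`p0`, `p05`,
#'   `p1`).
#' @return `data.table` of calls: `chrom`, `pos` (0-based), `strand`,
#'   `context`, `trinuc`, `level`, `Q`, `depth`, `c_count`, `t_count`,
#'   `pass`.
#' @export
call_methylation <- function(pileup, genome = NULL, params = call_params(),
                             keep_posterior = FALSE) {
  pu <- data.table::as.data.table(pileup)
  if (nrow(pu) == 0L)
    return(data.table::data.table(chrom = character(), pos = integer(),
                                  strand = character(), context = character(),
                                  trinuc = character(), level = numeric(),
                                  Q = numeric(), depth = integer(),
                                  c_count = integer(), t_count = integer(),
                                  pass = logical()))
  e <- pmax(10^(-pu$qual / 10), params$error_floor)
  cf <- params$conversion_fail
  pu[, `:=`(ll0 = ll_row(0, e, c_count, t_count, cf),
            llh = ll_row(0.5, e, c_count, t_count, cf),
            ll1 = ll_row(1, e, c_count, t_count, cf))]
  calls <- pu[, .(ll0 = sum(ll0), llh = sum(llh), ll1 = sum(ll1),
                  c_count = sum(c_count), t_count = sum(t_count)),
              by = .(chrom, pos, strand)]
  pu[, c("ll0", "llh", "ll1") := NULL]
  llm <- as.matrix(calls[, .(ll0, llh, ll1)])
  mx <- apply(llm, 1L, max)
  post <- exp(llm - mx)
  post <- post / rowSums(post)
  pick <- max.col(post, ties.method = "first")  # first max = lower level
  best <- post[cbind(seq_len(nrow(post)), pick)]
  Q <- ifelse(best >= 1, params$q_cap,
              pmin(-10 * log10(pmax(1 - best, 1e-300)), params$q_cap))
  calls[, `:=`(level = CALL_LEVELS[pick], Q = Q,
               depth = c_count + t_count)]
  calls[, pass := Q >= 20 & depth >= params$min_depth]
  if (keep_posterior)
    calls[, `:=`(p0 = post[, 1], p05 = post[, 2], p1 = post[, 3])]
  calls[, c("ll0", "llh", "ll1") := NULL]
  if (!is.null(genome)) {
    calls[, c("context", "trinuc") := {
      ctx <- classify_context(genome, chrom[1], pos, strand)
      list(ctx$klass, ctx$trinuc)
    }, by = chrom]
  } else {
    calls[, `:=`(context = NA_character_, trinuc = NA_character_)]
  }
  data.table::setcolorder(calls, c("chrom", "pos", "strand", "context",
                                   "trinuc", "level", "Q", "depth",
                                   "c_count", "t_count", "pass"))
  data.table::setorder(calls, chrom, pos, strand)
  calls[]
}

#' Symmetric-methylation pairing
#'
#' For every passing CG/CHG call with level > 0, looks up the
#' opposite-strand partner cytosine ([partner_position]) and reports whether
#' both sides are modified. The per-context percentage uses all modified
#' sites as the denominator, whether or not the partner is covered.
#'
#' @param calls output of [call_methylation].
#' @return list with `pairs` (one row per modified CG/CHG site: partner
#'   coordinates and `both_modified`) and `summary` (per context: modified
#'   sites, symmetric sites, percent).
#' @export
symmetric_calls <- function(calls) {
  calls <- data.table::as.data.table(calls)
  mods <- calls[pass == TRUE & level > 0 & context %in% c("CG", "CHG")]
  if (nrow(mods)) {
    pp <- partner_pos_vec(mods$context, mods$pos, mods$strand)
    mods[, `:=`(partner_pos = pp$pos, partner_strand = pp$strand)]
    partner <- calls[pass == TRUE & level > 0,
                     .(chrom, partner_pos = pos, partner_strand = strand,
                       hit = TRUE)]
    mods[, both_modified := FALSE]
    mods[partner, on = c("chrom", "partner_pos", "partner_strand"),
         both_modified := TRUE]
    pairs <- mods[, .(chrom, pos, strand, context, level, partner_pos,
                      partner_strand, both_modified)]
  } else {
    pairs <- data.table::data.table(
      chrom = character(), pos = integer(), strand = character(),
      context = character(), level = numeric(), partner_pos = integer(),
      partner_strand = character(), both_modified = logical())
  }
  chh_mod <- calls[pass == TRUE & level > 0 & context == "CHH", .N]
  summary <- data.table::rbindlist(list(
    pairs[, .(modified = .N, symmetric = sum(both_modified)), by = context],
    data.table::data.table(context = "CHH", modified = chh_mod,
                           symmetric = 0L)))
  full <- data.table::data.table(context = CONTEXT_LEVELS)
  summary <- summary[full, on = "context"]
  summary[is.na(modified), `:=`(modified = 0L, symmetric = 0L)]
  summary[, percent := pct_modified(symmetric, modified)]
  list(pairs = pairs, summary = summary[])
}

#' Write a per-cytosine TSV report
#'
#' One standard dialect with a documented header line: columns `chrom`,
#' `pos` (1-based), `strand`, `context`, `trinuc`, `level`, `Q`, `depth`,
#' `c_count`, `t_count`, `pass`.
#'
#' @param calls output of [call_methylation].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_methyl_report <- function(calls, path) {
  out <- data.table::as.data.table(calls)[
    , .(chrom, pos = pos + 1L, strand, context, trinuc, level, Q, depth,
        c_count, t_count, pass)]
  data.table::fwrite(out, path, sep = "\t")
  invisible(path)
}

#' Read a per-cytosine TSV report written by [write_methyl_report]
#' @param path TSV file.
#' @return `data.table` of calls with 0-based positions.
#' @export
read_methyl_report <- function(path) {
  x <- data.table::fread(path, sep = "\t")
  x[, pos := pos - 1L]
  x[]
}
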