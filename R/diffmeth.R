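#' Fisher's exact test for a 2x2 table
#'
#' Two-sided exact hypergeometric test: the p-value sums the probabilities
#' of all tables with the same margins whose probability does not exceed
#' the observed one. The reported odds ratio is the sample odds ratio
#' `a*d / (b*c)` (NA sentinel for degenerate tables).
#'
#' @param a,b,c,d non-negative cell counts, rows = condition, columns =
#'   outcome.
#' @return list with `odds_ratio` and `p_value` (`NA` for the all-zero
#'   table).
#' @examples
#' fisher_test_2x2(5, 5, 5, 5)  # p = 1
#' @export
fisher_test_2x2 <- function(a, b, c, d) {
  if (any(c(a, b, c, d) < 0)) stopf("counts must be non-negative")
  if (a + b + c + d == 0)
    return(list(odds_ratio = NA_real_, p_value = NA_real_))
  p <- stats::fisher.test(matrix(c(a, b, c, d), 2, byrow = TRUE))$p.value
  or <- if (b * c == 0) {
    if (a * d == 0) NA_real_ else Inf
  } else a * d / (b * c)
  list(odds_ratio = or, p_value = p)
}

## standardized hypergeometric enrichment of a member set in the top-k
## prefix, for all k; z[k] = (x_k - E x_k) / sd(x_k). The rank-sum test of
## members vs non-members on the dichotomized score 1{rank <= k} reduces to
## exactly this statistic (binary values make the tie-corrected rank-sum a
## function of x_k alone).
greedy_prefix_z <- function(member_ord) {
  n <- length(member_ord)
  m <- sum(member_ord)
  k <- seq_len(n - 1L)
  x <- cumsum(member_ord)[k]
  mu <- k * m / n
  v <- k * (m / n) * (1 - m / n) * (n - k) / (n - 1)
  (x - mu) / sqrt(v)
}

#' Wilcoxon rank-sum gene-set enrichment
#'
#' `mode = "fixed"` is the standard two-sample Wilcoxon rank-sum test of
#' member vs non-member scores (exact when both groups have at most 10
#' untied observations, normal approximation with tie correction
#' otherwise). `mode = "greedy"` scans every prefix cutoff of the ranked
#' list for the cutoff where set members are most concentrated
#' (a one-sided rank-sum statistic on the dichotomized top-k indicator,
#' equivalently a standardized hypergeometric count), and corrects the
#' cutoff search by label permutation.
#'
#' @param scores named numeric vector, gene id -> score (higher = more of
#'   the phenotype; the ranked list is sorted decreasing).
#' @param gene_set character vector of member gene ids; members missing
#'   from `scores` are dropped with a message.
#' @param mode `"fixed"` or `"greedy"`.
#' @param n_perm permutations for the greedy correction (default 10000).
#' @param correct permutation-correct the greedy p-value (default `TRUE`;
#'   `FALSE` reports the naive best-cutoff normal p, which is
#'   anti-conservative and exists to demonstrate why the correction is
#'   needed).
#' @return one-row `data.table`: `unit_id`, `statistic`, `p_value`,
#'   `q_value` (`NA`, filled by multi-set callers), `direction`,
#'   `best_cutoff` (`NA` for fixed mode), `n_members`.
#' @export
ranksum_enrichment <- function(scores, gene_set, mode = c("fixed", "greedy"),
                               n_perm = 10000L, correct = TRUE) {
  mode <- match.arg(mode)
  if (is.null(names(scores))) stopf("scores must be named by gene id")
  set_id <- attr(gene_set, "set_id") %||% "set"
  miss <- setdiff(gene_set, names(scores))
  if (length(miss))
    message(length(miss), " set member(s) absent from scores; dropped")
  gene_set <- intersect(gene_set, names(scores))
  if (length(gene_set) == 0L) stopf("empty gene set")
  if (length(gene_set) == length(scores))
    stopf("gene set covers every scored gene")
  member <- names(scores) %in% gene_set

  if (mode == "fixed") {
    w <- stats::wilcox.test(scores[member], scores[!member],
                            exact = (sum(member) <= 10 &&
                                     sum(!member) <= 10 &&
                                     !anyDuplicated(scores)))
    dir <- if (mean(rank(scores)[member]) >= mean(rank(scores)[!member]))
      "up" else "down"
    return(data.table::data.table(
      unit_id = set_id, statistic = unname(w$statistic),
      p_value = w$p.value, q_value = NA_real_, direction = dir,
      best_cutoff = NA_integer_, n_members = sum(member)))
  }

  ord <- order(scores, decreasing = TRUE)
  mo <- member[ord]
  z <- greedy_prefix_z(mo)
  best_k <- which.max(z)
  z_obs <- z[best_k]
  if (correct) {
    perm_max <- vapply(seq_len(n_perm), function(i)
      max(greedy_prefix_z(sample(mo))), numeric(1))
    p <- (1 + sum(perm_max >= z_obs)) / (n_perm + 1)
  } else {
    p <- stats::pnorm(z_obs, lower.tail = FALSE)
  }
  data.table::data.table(
    unit_id = set_id, statistic = z_obs, p_value = p, q_value = NA_real_,
    direction = "up", best_cutoff = as.integer(best_k),
    n_members = sum(member))
}

#' Quantile normalization of a count/score matrix
#'
#' Classic quantile normalization: each column is replaced by the rank-wise
#' mean of the sorted columns, mapped back through the column's original
#' ranks; tied values receive the mean of the reference values their tied
#' ranks span.
#'
#' @param x numeric matrix (units x samples), at least 2 columns.
#' @return normalized matrix of the same shape; all columns share the same
#'   sorted values.
#' @examples
#' quantile_normalize(cbind(a = c(1, 2, 3), b = c(4, 5, 6)))
#' @export
quantile_normalize <- function(x) {
  x <- as.matrix(x)
  if (ncol(x) < 2L) stopf("need at least 2 samples (columns)")
  if (anyNA(x)) stopf("matrix must not contain NA")
  ref <- rowMeans(apply(x, 2L, sort))
  out <- apply(x, 2L, function(col) {
    v <- numeric(length(col))
    v[order(col)] <- ref
    ## tied values share the mean of the reference values their ranks span
    stats::ave(v, col, FUN = mean)
  })
  dimnames(out) <- dimnames(x)
  out
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up q-values: `q(i) = min over j >= i of p(j) * m / j` in sorted
#' order, clipped to 1 and mapped back to the input order.
#'
#' @param pvalues numeric vector of p-values in `[0, 1]`.
#' @return q-values in the input order.
#' @examples
#' bh_fdr(c(0.01, 0.02, 0.03))  # all 0.03
#' @export
bh_fdr <- function(pvalues) {
  if (any(pvalues < 0 | pvalues > 1, na.rm = TRUE))
    stopf("p-values must lie in [0, 1]")
  stats::p.adjust(pvalues, method = "BH")
}

#' Per-gene differential modification between two samples
#'
#' For each gene, tests the 2x2 table (modified, unmodified) x (sample A,
#' sample B) with Fisher's exact test and adjusts across genes with
#' Benjamini-Hochberg FDR.
#'
#' @param profileA,profileB per-gene count tables with `gene_id`,
#'   `modified`, `analyzed` (e.g. from aggregating [call_methylation]
#'   output over gene intervals).
#' @return `data.table` with `gene_id`, counts for both samples,
#'   `odds_ratio`, `p_value`, `q_value`, `direction` (`"up"` = more
#'   modified in A).
#' @export
diff_modification_genes <- function(profileA, profileB) {
  a <- data.table::as.data.table(profileA)
  b <- data.table::as.data.table(profileB)
  if (any(a$modified > a$analyzed) || any(b$modified > b$analyzed))
    stopf("modified count exceeds analyzed count")
  merged <- merge(a, b, by = "gene_id", suffixes = c("_A", "_B"))
  if (nrow(merged) == 0L)
    return(data.table::data.table(
      gene_id = character(), modified_A = integer(), analyzed_A = integer(),
      modified_B = integer(), analyzed_B = integer(), odds_ratio = numeric(),
      p_value = numeric(), q_value = numeric(), direction = character()))
  res <- merged[, {
    ft <- fisher_test_2x2(modified_A, analyzed_A - modified_A,
                          modified_B, analyzed_B - modified_B)
    rA <- if (analyzed_A > 0) modified_A / analyzed_A else NA_real_
    rB <- if (analyzed_B > 0) modified_B / analyzed_B else NA_real_
    .(odds_ratio = ft$odds_ratio, p_value = ft$p_value,
      direction = if (is.na(rA) || is.na(rB) || rA == rB) "none"
                  else if (rA > rB) "up" else "down")
  }, by = .(gene_id, modified_A, analyzed_A, modified_B, analyzed_B)]
  res[, q_value := bh_fdr(p_value)]
  data.table::setcolorder(res, c("gene_id", "modified_A", "analyzed_A",
                                 "modified_B", "analyzed_B", "odds_ratio",
                                 "p_value", "q_value", "direction"))
  res[]
}

#' Aggregate methylation calls into a per-gene count profile
#'
#' @param calls output of [call_methylation].
#' @param genes gene-model table.
#' @param region `"exon"`, `"intron"` or `"gene"` (whole span).
#' @param context optional context restriction (`"CG"`, `"CHG"`, `"CHH"`).
#' @return `data.table` with `gene_id`, `modified`, `analyzed` (passing
#'   sites only; genes with no sites report zeros).
#' @export
gene_count_profile <- function(calls, genes, region = "gene",
                               context = NULL) {
  calls <- data.table::as.data.table(calls)[pass == TRUE]
  if (!is.null(context)) {
    ctx <- context
    calls <- calls[context == ctx]
  }
  genes <- data.table::as.data.table(genes)
  ivs <- switch(region,
                exon = genes[feature == "exon"],
                intron = introns_of(genes),
                gene = gene_spans(genes),
                stopf("unknown region '%s'", region))
  gids <- unique(genes$gene_id)
  per <- lapply(split(ivs, ivs$gene_id), function(gi) {
    sub <- calls[chrom == gi$chrom[1]]
    inside <- rep(FALSE, nrow(sub))
    for (j in seq_len(nrow(gi)))
      inside <- inside | (sub$pos >= gi$start[j] & sub$pos < gi$end[j])
    data.table::data.table(gene_id = gi$gene_id[1],
                           modified = sum(inside & sub$level > 0),
                           analyzed = sum(inside))
  })
  tab <- data.table::rbindlist(per)
  base <- data.table::data.table(gene_id = gids)
  tab <- tab[base, on = "gene_id"]
  tab[is.na(analyzed), `:=`(modified = 0L, analyzed = 0L)]
  tab[]
}

#' Read gene sets from a two-column TSV (set id, gene id)
#' @param path TSV file without header.
#' @return named list of character vectors, one per set.
#' @export
read_gene_sets <- function(path) {
  x <- data.table::fread(path, sep = "\t", header = FALSE,
                         col.names = c("set_id", "gene_id"))
  lapply(split(x$gene_id, x$set_id), unique)
}
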