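test_that("pileup classifies retained and converted observations by
           strand", {
  g <- genome_from_seqs(c(chr1 = "AACGTTAACGTTAACGTTAACC"))
  ## perfect plus read over the C at position 2: retained
  aln <- data.table(read_id = "r1", chrom = "chr1", start = 0L,
                    bs_strand = "+", seq = "AACGTTAACG",
                    qual = strrep("I", 10), mismatches = 0L, unique = TRUE)
  pu <- build_pileup(aln, g)
  expect_equal(pu[pos == 2 & strand == "+", c_count], 1)
  expect_equal(pu[pos == 2 & strand == "+", t_count], 0)

  ## same read with the C converted: one converted observation
  aln2 <- copy(aln)[, seq := "AATGTTAACG"]
  pu2 <- build_pileup(aln2, g)
  expect_equal(pu2[pos == 2 & strand == "+", t_count], 1)

  ## minus-interrogation read showing A over the reference G at position 3:
  ## converted observation at the minus-strand cytosine
  aln3 <- data.table(read_id = "r3", chrom = "chr1", start = 0L,
                     bs_strand = "-", seq = "AACATTAACG",
                     qual = strrep("I", 10), mismatches = 0L, unique = TRUE)
  pu3 <- build_pileup(aln3, g)
  expect_equal(pu3[pos == 3 & strand == "-", t_count], 1)
  expect_equal(pu3[pos == 9 & strand == "-", c_count], 1)
})

test_that("a mismatch within the 2-bp surrounding context discards the
           observation", {
  g <- genome_from_seqs(c(chr1 = "AAAACGAAAA"))
  ## read with a reduced-alphabet mismatch one base left of the C at pos 4
  aln <- data.table(read_id = "r", chrom = "chr1", start = 0L,
                    bs_strand = "+", seq = "AAAGCGAAAA",
                    qual = strrep("I", 10), mismatches = 1L, unique = TRUE)
  pu <- build_pileup(aln, g)
  expect_equal(nrow(pu[pos == 4]), 0)
  ## three bases away the observation survives
  aln2 <- data.table(read_id = "r", chrom = "chr1", start = 0L,
                     bs_strand = "+", seq = "AGAACGAAAA",
                     qual = strrep("I", 10), mismatches = 1L, unique = TRUE)
  pu2 <- build_pileup(aln2, g)
  expect_equal(pu2[pos == 4 & strand == "+", c_count], 1)
})

test_that("the consecutive-CHH read filter applies exactly the three-run
           rule", {
  expect_equal(chh_read_filter(c("C", "C", "C"), rep("CHH", 3)), "discard")
  expect_equal(chh_read_filter(c("C", "C", "T", "C"), rep("CHH", 4)), "keep")
  ## only CHH cytosines count in the run; other contexts are transparent
  ## (they neither extend nor break it)
  expect_equal(chh_read_filter(c("C", "C", "C", "C"),
                               c("CG", "CHH", "CHH", "CHH")), "discard")
  expect_equal(chh_read_filter(c("C", "C", "T", "C"),
                               c("CHH", "CHH", "CG", "CHH")), "discard")
  expect_equal(chh_read_filter(c("C", "C", "C"),
                               c("CHH", "CG", "CHH")), "keep")

  ## end-to-end: a read carrying three consecutive retained CHHs is dropped
  ## from the pileup when the filter is on, kept when off
  g <- genome_from_seqs(c(chr1 = "AACACACAAAAA"))
  ## CHH sites at 2, 4, 6 (CAC, CAC, CAA); read retains all three
  aln <- data.table(read_id = "r", chrom = "chr1", start = 0L,
                    bs_strand = "+", seq = "AACACACAAAAA",
                    qual = strrep("I", 12), mismatches = 0L, unique = TRUE)
  expect_equal(nrow(build_pileup(aln, g, chh_filter = TRUE)), 0)
  expect_equal(nrow(build_pileup(aln, g, chh_filter = FALSE)), 3)
  ## converting the middle one breaks the run
  aln2 <- copy(aln)[, seq := "AACATACAAAAA"]
  expect_equal(nrow(build_pileup(aln2, g, chh_filter = TRUE)), 3)
})

test_that("the three-level caller matches exhaustive likelihood enumeration
           for all pileups with depth <= 12", {
  params <- call_params(conversion_fail = 0.005)
  rows <- list()
  expected <- list()
  id <- 0L
  for (depth in 1:12) {
    for (cc in 0:depth) {
      for (q in c(20L, 30L, 40L)) {
        id <- id + 1L
        rows[[id]] <- pileup_row(id, "+", q, cc, depth - cc)
        expected[[id]] <- oracle_call(rep(c("C", "T"), c(cc, depth - cc)),
                                      rep(q, depth))
      }
    }
  }
  pu <- rbindlist(rows)
  calls <- call_methylation(pu, genome = NULL, params = params,
                            keep_posterior = TRUE)
  setkey(calls, pos)
  for (i in seq_len(nrow(calls))) {
    exp_i <- expected[[calls$pos[i]]]
    expect_equal(calls$level[i], exp_i$level,
                 info = sprintf("case %d", calls$pos[i]))
    ## Q is -10 log10(1 - posterior): at posteriors within 1e-10 of 1 the
    ## two float paths (log-space sum vs plain product) differ in the last
    ## ulp, so compare Q to 1e-4 relative; posteriors match to 1e-12.
    expect_equal(calls$Q[i], exp_i$Q, tolerance = 1e-4,
                 info = sprintf("case %d", calls$pos[i]))
    expect_equal(c(calls$p0[i], calls$p05[i], calls$p1[i]),
                 exp_i$posterior, tolerance = 1e-12)
  }
})

test_that("posteriors sum to one and retained counts move calls
           monotonically upward", {
  params <- call_params()
  pu <- rbindlist(lapply(0:20, function(cc)
    pileup_row(cc, "+", 30L, cc, 20L - cc)))
  calls <- call_methylation(pu, params = params, keep_posterior = TRUE)
  expect_true(all(abs(calls$p0 + calls$p05 + calls$p1 - 1) < 1e-12))
  setkey(calls, pos)  # pos = retained count
  expect_true(all(diff(calls$level) >= 0))
})

test_that("the caller honors the worked likelihood examples", {
  params <- call_params(conversion_fail = 0.005)
  ## 10 retained, 0 converted at Q30 -> full methylation, passing
  c1 <- call_methylation(pileup_row(0, "+", 30L, 10, 0), params = params)
  expect_equal(c1$level, 1)
  expect_true(c1$pass)
  o1 <- oracle_call(rep("C", 10), rep(30, 10))
  expect_equal(c1$Q, o1$Q, tolerance = 1e-9)

  ## 5 retained / 5 converted -> hemi
  c2 <- call_methylation(pileup_row(0, "+", 30L, 5, 5), params = params)
  expect_equal(c2$level, 0.5)

  ## 0 retained / 10 converted with c = 0: level 1 is impossible
  ## (P(T | m=1) = e ~ 0) but level 0.5 still converts half its molecules,
  ## so the posterior is 1 / (1 + 0.5^10), not exactly 1 -- enumeration
  ## fixes the exact value
  p0 <- call_params(conversion_fail = 0, error_floor = 1e-12)
  pu <- pileup_row(0, "+", 120L, 0, 10)
  c3 <- call_methylation(pu, params = p0, keep_posterior = TRUE)
  o3 <- oracle_call(rep("T", 10), rep(120, 10), conv_fail = 0,
                    error_floor = 1e-12)
  expect_equal(c3$level, 0)
  expect_equal(c3$p0, o3$posterior[1], tolerance = 1e-12)
  expect_equal(c3$p1, 0, tolerance = 1e-100)
  expect_equal(c3$Q, o3$Q, tolerance = 1e-4)
})

test_that("depth-zero sites are absent and Q<20 or shallow calls fail the
           pass filter", {
  params <- call_params(min_depth = 5L)
  calls <- call_methylation(rbind(pileup_row(0, "+", 30L, 1, 0),
                                  pileup_row(1, "+", 30L, 10, 0)),
                            params = params)
  expect_equal(nrow(calls), 2)
  expect_false(calls[pos == 0, pass])   # depth 1 < 5
  expect_true(calls[pos == 1, pass])
})

test_that("symmetric pairing counts partners by context and uses all
           modified sites as the denominator", {
  g <- genome_from_seqs(c(chr1 = "AACGTTACATGGTAACAGTA"))
  ## CG pair at (2,+)/(3,-); CHG-like positions are irrelevant here; build
  ## calls directly
  calls <- rbind(
    calls_table(2, "CG", 1, strand = "+"),
    calls_table(3, "CG", 1, strand = "-"),
    calls_table(8, "CG", 1, strand = "+"),    # partner uncovered
    calls_table(12, "CHH", 1, strand = "+"))
  sym <- symmetric_calls(calls)
  expect_equal(sym$pairs[pos == 2, both_modified], TRUE)
  expect_equal(sym$pairs[pos == 3, both_modified], TRUE)
  expect_equal(sym$pairs[pos == 8, both_modified], FALSE)
  s <- sym$summary
  expect_equal(s[context == "CG", modified], 3)
  expect_equal(s[context == "CG", symmetric], 2)
  expect_equal(s[context == "CG", percent], 66.67)
  expect_equal(s[context == "CHH", percent], 0)

  ## partner covered but unmodified is not symmetric
  calls2 <- rbind(calls_table(2, "CG", 1, strand = "+"),
                  calls_table(3, "CG", 0, strand = "-"))
  s2 <- symmetric_calls(calls2)$summary
  expect_equal(s2[context == "CG", symmetric], 0)

  ## CHG partner offset is 2
  calls3 <- rbind(calls_table(5, "CHG", 1, strand = "+"),
                  calls_table(7, "CHG", 0.5, strand = "-"))
  s3 <- symmetric_calls(calls3)
  expect_equal(s3$pairs[pos == 5, partner_pos], 7)
  expect_true(s3$pairs[pos == 5, both_modified])
})

test_that("methylation reports round-trip through TSV", {
  calls <- rbind(calls_table(c(2, 5, 9), c("CG", "CHH", "CHG"),
                             c(1, 0.5, 0)))
  calls[, trinuc := c("CGT", "CAT", "CAG")]
  f <- tempfile(fileext = ".tsv")
  write_methyl_report(calls, f)
  head1 <- readLines(f, n = 1)
  expect_equal(head1, paste(c("chrom", "pos", "strand", "context", "trinuc",
                              "level", "Q", "depth", "c_count", "t_count",
                              "pass"), collapse = "\t"))
  back <- read_methyl_report(f)
  expect_equal(back$pos, calls$pos)
  expect_equal(back$level, calls$level)
  unlink(f)
})

test_that("parameter recovery: planted levels come back from a simulated
           genome at depth", {
  cfg <- sim_config(seed = 51, genome_length = 120000, n_genes = 8,
                    coverage = 24)
  sim <- simulate_genome(cfg)
  truth <- plant_methylome(sim$genome, sim$genes, cfg)
  reads <- simulate_bs_reads(sim$genome, truth, cfg)
  aln <- map_bs_reads(sim$genome, reads)
  pu <- build_pileup(aln, sim$genome)
  calls <- call_methylation(pu, sim$genome,
                            call_params(conversion_fail = cfg$conv_fail))
  m <- merge(calls, truth[, .(chrom, pos, strand, level_true = level)],
             by = c("chrom", "pos", "strand"), all.x = TRUE)
  m[is.na(level_true), level_true := 0]
  deep <- m[depth >= 10]
  expect_gt(nrow(deep), 10000)
  expect_gte(deep[, mean(level == level_true)], 0.99)
  ## false-modification rate at planted-zero sites below 0.5%
  expect_lt(deep[level_true == 0, mean(level > 0)], 0.005)
})
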