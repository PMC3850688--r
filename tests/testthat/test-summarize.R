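test_that("region-context summary counts, percents and sentinels follow the
           table arithmetic", {
  set.seed(61)
  g <- random_genome(5000)
  gm <- toy_gene("g1", "chr1", "+", list(c(1000, 2000), c(2500, 3500)))
  idx <- build_region_index(gm, g, flank = 500)

  ## 10 exon CG sites, 3 modified -> 30.00
  calls <- calls_table(seq(1000, 1090, by = 10), "CG",
                       c(rep(1, 2), 0.5, rep(0, 7)))
  s <- summarize_by_region(calls, idx)
  expect_equal(s[region == "Exon" & context == "CG", analyzed], 10)
  expect_equal(s[region == "Exon" & context == "CG", modified], 3)
  expect_equal(s[region == "Exon" & context == "CG", percent], 30.00)

  ## labels are a set: the same sites also count under Gene and Transcript
  expect_equal(s[region == "Gene" & context == "CG", analyzed], 10)
  expect_equal(s[region == "Cds" & context == "CG", analyzed], 10)

  ## nothing analyzed -> NA sentinel
  expect_true(is.na(s[region == "Intron" & context == "CG", percent]))
  expect_equal(s[region == "Intron" & context == "CG", analyzed], 0)

  ## non-passing calls are excluded
  calls2 <- rbind(calls, calls_table(2600, "CG", 1, pass = FALSE))
  s2 <- summarize_by_region(calls2, idx)
  expect_equal(s2[region == "Intron" & context == "CG", analyzed], 0)

  ## every percent equals the independent recomputation
  s3 <- s[analyzed > 0]
  expect_equal(s3$percent, round(100 * s3$modified / s3$analyzed + 1e-9, 2))
})

test_that("summary percentages reproduce printed worked examples from count
           fixtures", {
  ## single giant exon covering all fixture sites
  g <- genome_from_seqs(c(chr1 = strrep("A", 2100000)))
  gm <- toy_gene("g1", "chr1", "+", list(c(0, 2000000)))
  idx <- build_region_index(gm, g)
  fixture <- function(analyzed, modified, context) {
    calls_table(seq_len(analyzed) - 1L, context,
                c(rep(1, modified), rep(0, analyzed - modified)))
  }
  cell <- function(analyzed, modified, ctx) {
    s <- summarize_by_region(fixture(analyzed, modified, ctx), idx)
    s[region == "Exon" & context == ctx][[1, "percent"]]
  }
  expect_equal(cell(2257, 81, "CG"), 3.59)       # splice-donor-scale cell
  expect_equal(cell(14, 1, "CG"), 7.14)
  expect_equal(cell(2504, 215, "CG"), 8.59)
  expect_equal(cell(17187, 538, "CHH"), 3.13)
  expect_equal(cell(18474, 257, "CHG"), 1.39)
})

test_that("interval region tables assign by midpoint with exclusive
           priority", {
  set.seed(62)
  g <- random_genome(20000)
  gm <- toy_gene("g1", "chr1", "+", list(c(5000, 6000), c(8000, 9000)))
  idx <- build_region_index(gm, g, flank = 2000)

  ## all intervals midpoint-inside the intron -> Intron 100%
  iv <- data.table(chrom = "chr1", start = c(6500, 7000, 7400),
                   end = c(6700, 7200, 7600))
  t1 <- summarize_intervals_by_region(iv, idx)
  expect_equal(t1$region, "Intron")
  expect_equal(t1$percent, 100.00)

  ## empty input -> empty table
  expect_equal(nrow(summarize_intervals_by_region(iv[0], idx)), 0)

  ## mixed toy set against a manual tally: midpoints at 5500 (exon),
  ## 6000 (splice donor: first 2 intron bases are 6000-6001), 10000
  ## (downstream flank [9000, 11000)), 15000 (intergenic)
  iv2 <- data.table(chrom = "chr1",
                    start = c(5400, 5900, 9900, 14900),
                    end = c(5600, 6101, 10100, 15100))
  t2 <- summarize_intervals_by_region(iv2, idx)
  expect_equal(t2[region == "Exon", count], 1)
  expect_equal(t2[region == "SpliceSiteDonor", count], 1)
  expect_equal(t2[region == "Downstream", count], 1)
  expect_equal(t2[region == "Intergenic", count], 1)
  expect_equal(sum(t2$count), 4)
  expect_equal(sum(t2$percent), 100)

  ## any-overlap mode counts each overlapped label once
  t3 <- summarize_intervals_by_region(iv2, idx, mode = "any")
  expect_gte(t3[region == "Intron", count], 1)  # 5900-6101 spans into intron
})

test_that("metagene profiles honor binning, the coverage floor and strand
           reflection", {
  set.seed(63)
  g <- random_genome(30000)
  gm <- toy_gene("g1", "chr1", "+", list(c(10000, 13000)))
  ## uniform 50% modification at 300 evenly spread sites -> every bin 0.5
  pos <- seq(10000, 12999, by = 10)
  calls <- calls_table(pos, "CG", rep(c(1, 0), length.out = length(pos)))
  prof <- metagene_profile(calls, gm, nbins = 30, flank = 3000,
                           min_covered = 100)
  ex <- prof[feature == "exon"]
  expect_equal(nrow(ex), 30)
  expect_true(all(abs(ex$ratio - 0.5) < 1e-9))
  ## per-bin analyzed counts sum to the feature's site count
  expect_equal(sum(ex$analyzed), length(pos))

  ## gene with 99 covered cytosines is excluded
  calls99 <- calls_table(seq(10000, by = 10, length.out = 99), "CG", 1)
  prof99 <- metagene_profile(calls99, gm, min_covered = 100)
  expect_equal(length(attr(prof99, "genes_used")), 0)
  expect_equal(metagene_profile(calls99, gm, min_covered = 99)[
    , length(attr(metagene_profile(calls99, gm, min_covered = 99),
                  "genes_used"))], 1)

  ## minus-strand gene: a gradient along the genome reverses in bin order
  gmm <- toy_gene("g2", "chr1", "-", list(c(10000, 13000)))
  grad <- calls_table(pos, "CG", as.numeric(pos >= 11500))
  pp <- metagene_profile(grad, gm, nbins = 10, min_covered = 50)
  pm <- metagene_profile(grad, gmm, nbins = 10, min_covered = 50)
  expect_equal(pm[feature == "exon"]$ratio,
               rev(pp[feature == "exon"]$ratio))
})

test_that("splice-junction template cytosines and motifs are located by
           complementary logic", {
  ## plus-strand gene, canonical GT...AG intron
  ##            0123456789012345678901234567890
  seq <- paste0("AAACCCGGGT", "GT", "AAATTTAAA", "AG", "CCCGGGTTTAAAA")
  g <- genome_from_seqs(c(chr1 = seq))
  ## exon1 [0,10), intron [10,23), exon2 [23,36)
  gm <- toy_gene("g1", "chr1", "+", list(c(0, 10), c(23, 36)))

  ## donor template C sits on the minus strand opposite the G at 10;
  ## acceptor opposite the G at 22
  calls <- rbind(calls_table(10, "CHH", 1, strand = "-"),
                 calls_table(22, "CHH", 0.5, strand = "-"))
  sj <- splice_junction_methylation(calls, gm, g)
  expect_equal(nrow(sj$records), 2)
  don <- sj$records[kind == "donor"]
  expect_equal(don$template_pos, 10)
  expect_equal(don$template_strand, "-")
  expect_equal(don$motif_sense, "GT")
  expect_equal(don$motif_template, "AC")
  acc <- sj$records[kind == "acceptor"]
  expect_equal(acc$motif_sense, "AG")
  expect_equal(acc$motif_template, "CT")
  expect_equal(sj$summary[kind == "donor", percent], 100)

  ## no modified template Cs -> empty
  sj0 <- splice_junction_methylation(calls_table(5, "CHH", 1), gm, g)
  expect_equal(nrow(sj0$records), 0)

  ## non-canonical junction is reported with its actual motif
  seq2 <- paste0("AAACCCGGGT", "CA", "AATTTAAAA", "AG", "CCCGGGTTTAAAA")
  g2 <- genome_from_seqs(c(chr1 = seq2))
  calls2 <- calls_table(10, "CHH", 1, strand = "-")
  sj2 <- splice_junction_methylation(calls2, gm, g2)
  expect_equal(sj2$records$motif_sense, "CA")
  expect_equal(sj2$summary[kind == "donor", canonical], 0)
})

test_that("minus-strand splice junctions mirror the plus-strand geometry", {
  set.seed(64)
  ## build a minus-strand gene; donor is at the intron's right end
  cfg <- sim_config(seed = 65, genome_length = 30000, n_genes = 2)
  sim <- simulate_genome(cfg)
  gmin <- sim$genes[strand == "-"]
  if (nrow(gmin) == 0) {
    gmin <- sim$genes  # fall back; generator seeds guarantee both strands
  }
  intr <- introns_of(gmin)[1]
  ## template strand of a minus gene is plus; donor C at intron end - 1
  calls <- calls_table(intr$end - 1L, "CHH", 1, strand = "+")
  sj <- splice_junction_methylation(calls, gmin, sim$genome)
  don <- sj$records[kind == "donor"]
  expect_equal(nrow(don), 1)
  expect_equal(don$template_strand, "+")
  expect_equal(don$motif_sense, "GT")  # generator plants canonical motifs
})

test_that("o/e gene panels select by percent rule and motif-count floor", {
  set.seed(66)
  g <- random_genome(40000)
  gm <- rbind(toy_gene("g1", "chr1", "+", list(c(1000, 3000), c(4000, 6000))),
              toy_gene("g2", "chr1", "+", list(c(10000, 12000),
                                               c(13000, 15000))),
              toy_gene("g3", "chr1", "+", list(c(20000, 22000),
                                               c(23000, 25000))))
  oe <- compute_oe(gm, g)

  ## g1: 12 exon CpGs none modified; g2: 9 exon CpGs none modified;
  ## g3: 20 intron CHHs, 3 modified (15%)
  calls <- rbind(
    calls_table(seq(1000, 1110, by = 10), "CG", 0),            # 12 sites g1
    calls_table(seq(10000, 10080, by = 10), "CG", 0),          # 9 sites g2
    calls_table(seq(22000, 22190, by = 10), "CHH",
                c(rep(1, 3), rep(0, 17))))                     # g3 introns
  zero <- classify_genes_by_oe(calls, gm, oe, context = "CG",
                               region = "exon", rule = "==", threshold = 0,
                               min_sites = 10)
  expect_equal(zero$gene_id, "g1")
  expect_equal(zero$analyzed, 12)

  over10 <- classify_genes_by_oe(calls, gm, oe, context = "CHH",
                                 region = "intron", rule = ">",
                                 threshold = 10)
  expect_equal(over10$gene_id, "g3")
  expect_equal(over10$percent, 15)
  expect_false(is.na(over10$oe))

  expect_error(classify_genes_by_oe(calls, gm, oe, "XX", "exon"),
               "context")
  expect_error(classify_genes_by_oe(calls, gm, oe, "CG", "flank"),
               "region")
})

test_that("region summaries export in the published-table dialect", {
  set.seed(67)
  g <- random_genome(3000)
  gm <- toy_gene("g1", "chr1", "+", list(c(500, 1000), c(1500, 2000)))
  idx <- build_region_index(gm, g, flank = 300)
  s <- summarize_by_region(calls_table(seq(500, 590, 10), "CG",
                                       c(rep(1, 3), rep(0, 7))), idx)
  f <- tempfile(fileext = ".tsv")
  write_region_summary(s[context == "CG"], f)
  lines <- readLines(f)
  expect_equal(lines[1], "Type\tAnalyzed\tMethylated\tMethylated %")
  expect_true(any(grepl("^Exon\t10\t3\t30.00%$", lines)))
  unlink(f)
})
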