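test_that("window grid arithmetic follows the 50-kb/25-kb convention", {
  w <- make_windows(c(chr1 = 100000))
  expect_equal(nrow(w), 4L)
  expect_equal(w$start, c(1L, 25001L, 50001L, 75001L))
  expect_equal(w$end, w$start + 49999L)

  expect_equal(make_windows(c(chr1 = 50000))$start, c(1L, 25001L))
  w3 <- make_windows(c(chr1 = 10))
  expect_equal(nrow(w3), 1L)
  expect_equal(c(w3$start, w3$end), c(1L, 50000L))
})

test_that("each SNP contributes to every window containing it", {
  comp <- data.frame(chrom = "chr1", pos = 30000L, a = 0.2, b = 0.1,
                     c = 0.1, theta = 0.5, defined = TRUE)
  w <- window_fst(comp, make_windows(c(chr1 = 100000)))
  expect_equal(w$n_snps, c(1L, 1L, 0L, 0L))
  expect_equal(w$fst_weighted[1], 0.5)
  expect_true(all(is.na(w$fst_weighted[3:4])))
  expect_false(any(w$eligible[3:4]))

  # interior SNPs fall in exactly two 50/25-kb windows; the first 25 kb in one
  set.seed(1)
  pos <- sort(sample(25001:975000, 400))
  comp2 <- data.frame(chrom = "chr1", pos = pos, a = 1, b = 1, c = 0,
                      theta = 0.5, defined = TRUE)
  w2 <- window_fst(comp2, make_windows(c(chr1 = 1e6)))
  expect_equal(sum(w2$n_snps), 2L * length(pos))
  head_pos <- c(10L, 24999L)
  comp3 <- data.frame(chrom = "chr1", pos = head_pos, a = 1, b = 1, c = 0,
                      theta = 0.5, defined = TRUE)
  expect_equal(sum(window_fst(comp3,
                              make_windows(c(chr1 = 1e6)))$n_snps), 2L)
})

test_that("window Fst is the ratio of summed components", {
  comp <- data.frame(chrom = "chr1", pos = seq(30001, 30010),
                     a = 0.1, b = 0.05, c = 0.05, theta = 0.5,
                     defined = TRUE)
  w <- window_fst(comp, make_windows(c(chr1 = 50000)))
  expect_equal(w$fst_weighted[w$n_snps > 0], c(0.5, 0.5))
  # a window with a single SNP equals the per-SNP ratio
  one <- comp[1, ]; one$a <- 0.3; one$b <- 0.2; one$c <- 0.1
  w1 <- window_fst(one, make_windows(c(chr1 = 25000)))
  expect_equal(w1$fst_weighted[1], 0.3 / 0.6)
})

test_that("top-window selection uses ceiling and includes cutoff ties", {
  mkstats <- function(fst) {
    n <- length(fst)
    data.frame(chrom = rep("chr1", n), start = seq_len(n), end = seq_len(n),
               n_snps = rep(1L, n), sum_a = fst, sum_abc = rep(1, n),
               fst_weighted = fst, fst_mean = fst,
               eligible = rep(TRUE, n))
  }
  expect_equal(nrow(top_windows(mkstats(seq_len(400) / 400))), 4L)
  expect_equal(nrow(top_windows(mkstats(seq_len(399) / 399))), 4L)
  expect_equal(nrow(top_windows(mkstats(rep(0.3, 100)))), 100L)
  # deterministic order: fst desc, then position
  tw <- top_windows(mkstats(c(0.9, 0.9, 0.1, 0.5)),
                    scan_params(top_fraction = 0.75))
  expect_equal(tw$fst_weighted, c(0.9, 0.9, 0.5))
  # ceiling(0.5 * 4) = 2, cutoff 0.9 has no further ties
  tw2 <- top_windows(mkstats(c(0.9, 0.9, 0.1, 0.5)),
                     scan_params(top_fraction = 0.5))
  expect_equal(tw2$fst_weighted, c(0.9, 0.9))
  expect_error(top_windows(mkstats(numeric(0))), "eligible")
})

test_that("candidate regions extend, clip and merge correctly", {
  top <- data.frame(chrom = "chr16", start = 300001L, end = 350000L,
                    fst_weighted = 0.22)
  cr <- candidate_regions(top, scan_params(), c(chr16 = 1e6))
  expect_equal(cr$regions$start, 250001L)
  expect_equal(cr$regions$end, 400000L)

  top1 <- data.frame(chrom = "chr1", start = 1L, end = 50000L,
                     fst_weighted = 0.5)
  cr1 <- candidate_regions(top1, scan_params(), c(chr1 = 60000))
  expect_equal(cr1$regions$start, 1L)     # clipped at chromosome start
  expect_equal(cr1$regions$end, 60000L)   # and at chromosome end

  # windows 25 kb apart merge after +/-50 kb extension
  top2 <- data.frame(chrom = "chr1", start = c(100001L, 125001L),
                     end = c(150000L, 175000L), fst_weighted = c(0.4, 0.3))
  cr2 <- candidate_regions(top2, scan_params(), c(chr1 = 1e6))
  expect_equal(nrow(cr2$regions), 1L)
  expect_equal(cr2$regions$n_windows, 2L)
  expect_equal(cr2$regions$max_fst, 0.4)

  # distant windows stay separate
  top3 <- data.frame(chrom = "chr1", start = c(1L, 500001L),
                     end = c(50000L, 550000L), fst_weighted = c(0.4, 0.3))
  expect_equal(nrow(candidate_regions(top3, scan_params(),
                                      c(chr1 = 1e6))$regions), 2L)
})

test_that("gene annotation uses >= 1 bp overlap on 1-based inclusive spans", {
  top <- data.frame(chrom = "chr16", start = 300001L, end = 350000L,
                    fst_weighted = 0.22)
  cr <- candidate_regions(top, scan_params(), c(chr16 = 1e6))
  genes <- data.frame(
    gene_id = c("gIn", "gEdge", "gOut"),
    chrom = "chr16",
    start = c(300500L, 399950L, 400001L),
    end = c(301000L, 401000L, 401000L),
    strand = "+")
  ann <- annotate_candidates(cr, genes)
  expect_setequal(ann$genes$gene_id, c("gIn", "gEdge"))
  expect_equal(ann$genes$best_fst, c(0.22, 0.22))

  empty <- annotate_candidates(cr, genes[0, ])
  expect_equal(nrow(empty$genes), 0L)
})

test_that("scan recovers a planted sweep and writes deterministic outputs", {
  sr <- data.frame(chrom = "chr1", start = 2.4e6, end = 2.5e6,
                   F_sweep = 0.25)
  sim <- simulate_genotypes(sweep_sim_config(
    n_wild = 20, n_dom = 20, chrom_length = 5e6, snp_density = 1 / 500,
    F_background = 0.05, sweep_regions = sr, seed = 77))
  genes <- simulate_gene_annotation(50, c(chr1 = 5e6), seed = 78)
  scan <- fst_scan(sim$table, sim$groups, genes,
                   chrom_lengths = c(chr1 = 5e6))
  r <- scan$candidates$regions
  hit <- any(r$chrom == "chr1" & r$start <= 2.5e6 & r$end >= 2.4e6)
  expect_true(hit)

  d1 <- tempfile(); d2 <- tempfile()
  write_scan(scan, d1)
  scan2 <- fst_scan(sim$table, sim$groups, genes,
                    chrom_lengths = c(chr1 = 5e6))
  write_scan(scan2, d2)
  for (suf in c(".windows.tsv", ".regions.bed", ".candidate_genes.tsv",
                ".summary.json")) {
    expect_identical(readLines(paste0(d1, suf)),
                     readLines(paste0(d2, suf)))
  }

  # top_fraction = 1 turns every eligible window into a region
  all_top <- top_windows(scan$windows, scan_params(top_fraction = 1))
  expect_equal(nrow(all_top), sum(scan$windows$eligible))
})
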