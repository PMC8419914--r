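test_that("genotype simulator is deterministic given config + seed", {
  cfg <- sweep_sim_config(n_wild = 5, n_dom = 5, chrom_length = 1e5,
                          snp_density = 1 / 200, missing_rate = 0.05,
                          seed = 99)
  a <- simulate_genotypes(cfg)
  b <- simulate_genotypes(cfg)
  expect_identical(a$table, b$table)
  expect_identical(a$truth, b$truth)
  p1 <- tempfile(fileext = ".vcf"); p2 <- tempfile(fileext = ".vcf")
  write_vcf(a$table, p1); write_vcf(b$table, p2)
  expect_identical(readLines(p1), readLines(p2))
})

test_that("near-zero divergence gives near-zero mean per-SNP Fst", {
  cfg <- sweep_sim_config(n_wild = 20, n_dom = 20, chrom_length = 1e6,
                          snp_density = 1 / 150, F_background = 1e-6,
                          seed = 3)
  sim <- simulate_genotypes(cfg)
  expect_gt(n_variants(sim$table), 5000)
  s <- snp_fst(sim$table, sim$groups)
  expect_lt(abs(mean(s$theta[s$defined])), 0.01)
})

test_that("sweep regions are planted where configured and flagged in truth", {
  sr <- data.frame(chrom = "chr1", start = 2e5, end = 3e5, F_sweep = 0.3)
  cfg <- sweep_sim_config(n_wild = 8, n_dom = 8, chrom_length = 1e6,
                          snp_density = 1 / 500, F_background = 0.05,
                          sweep_regions = sr, seed = 12)
  sim <- simulate_genotypes(cfg)
  tr <- sim$truth
  expect_true(all(tr$F_used[tr$in_sweep] == 0.3))
  expect_true(all(tr$pos[tr$in_sweep] >= 2e5 & tr$pos[tr$in_sweep] <= 3e5))
  expect_true(all(tr$F_used[!tr$in_sweep] == 0.05))
})

test_that("simulator configs validate their bounds", {
  expect_error(sweep_sim_config(F_background = 0), "F_background")
  sr <- data.frame(chrom = "chr1", start = 1, end = 10, F_sweep = 0.04)
  expect_error(sweep_sim_config(F_background = 0.05, sweep_regions = sr),
               "F_sweep")
  sr2 <- data.frame(chrom = "chr1", start = 1, end = 2e9, F_sweep = 0.5)
  expect_error(sweep_sim_config(sweep_regions = sr2), "bounds")
})

test_that("info-annotation planting produces exactly the designated failures", {
  sim <- simulate_genotypes(sweep_sim_config(n_wild = 3, n_dom = 3,
                                             chrom_length = 1e5,
                                             snp_density = 1 / 500,
                                             seed = 8))
  n <- n_variants(sim$table)

  ann0 <- simulate_info_annotations(sim$table, fail_spec = NULL, seed = 1)
  h0 <- hard_filter(ann0$table)
  expect_equal(n_variants(h0$table), n)

  ann <- simulate_info_annotations(sim$table, fail_spec = c(QD = 0.1),
                                   seed = 2)
  h <- hard_filter(ann$table)
  expect_equal(n_variants(h$table), n - sum(ann$truth[, "QD"]))
  expect_equal(h$report$removed_by$QD, sum(ann$truth[, "QD"]))
})

test_that("disjoint per-criterion failures remove exactly their sum", {
  geno <- matrix(0L, 200, 4)
  geno[, 2] <- 1L  # keep sites polymorphic-looking
  vt <- make_vt(geno, pos = seq_len(200) * 50L)
  spec <- c(QUAL = 0.05, QD = 0.05, FS = 0.05, MQ = 0.05,
            MQRankSum = 0.05, ReadPosRankSum = 0.05)
  ann <- simulate_info_annotations(vt, fail_spec = spec, seed = 4,
                                   disjoint = TRUE)
  expect_equal(sum(ann$truth), 60L)   # 6 criteria x 10 records
  h <- hard_filter(ann$table)
  expect_equal(n_variants(h$table), 140L)
  expect_equal(unlist(h$report$removed_by, use.names = FALSE),
               rep(10L, 6))
})

test_that("gene annotation simulator places sorted non-overlapping genes", {
  lens <- c(chr1 = 5e5, chr2 = 3e5)
  g <- simulate_gene_annotation(80, lens, gene_length_range = c(500, 5000),
                                seed = 6)
  expect_equal(nrow(g), 80L)
  expect_false(anyDuplicated(g$gene_id) > 0)
  for (ch in names(lens)) {
    gc <- g[g$chrom == ch, ]
    expect_true(all(diff(gc$start) > 0))
    expect_true(all(gc$start[-1] > gc$end[-nrow(gc)]))  # no overlap
    expect_true(all(gc$end <= lens[[ch]]))
  }
  expect_identical(g, simulate_gene_annotation(
    80, lens, gene_length_range = c(500, 5000), seed = 6))
  expect_equal(nrow(simulate_gene_annotation(0, lens)), 0L)
})

test_that("count simulator honours its truth construction", {
  cfg <- count_sim_config(n_genes = 2000, frac_de = 0.1, lfc = 2, seed = 21)
  sim <- simulate_counts(cfg)
  expect_equal(sum(sim$truth$is_de), 200L)
  expect_true(all(abs(sim$truth$true_lfc[sim$truth$is_de]) == 2))
  expect_true(all(sim$truth$true_lfc[!sim$truth$is_de] == 0))

  sim0 <- simulate_counts(count_sim_config(n_genes = 500, frac_de = 0,
                                           seed = 1))
  expect_equal(sum(sim0$truth$is_de), 0L)
  expect_identical(sim$counts$counts,
                   simulate_counts(cfg)$counts$counts)
})

test_that("zero dispersion reduces to Poisson (variance tracks the mean)", {
  # many replicate columns of one condition: with alpha = 0 and size
  # factors absent from the variance check, var/mean of counts for a gene
  # should concentrate near 1 + spread from the Uniform(0.7, 1.3) size
  # factors; compare against alpha = 0.5 which must be far overdispersed
  simP <- simulate_counts(count_sim_config(n_genes = 400, n_per_group = 50,
                                           frac_de = 0, dispersion = 0,
                                           mean_log_mu = 5, sd_log_mu = 0,
                                           seed = 2))
  simN <- simulate_counts(count_sim_config(n_genes = 400, n_per_group = 50,
                                           frac_de = 0, dispersion = 0.5,
                                           mean_log_mu = 5, sd_log_mu = 0,
                                           seed = 2))
  vmrP <- median(apply(simP$counts$counts, 1, var) /
                   rowMeans(simP$counts$counts))
  vmrN <- median(apply(simN$counts$counts, 1, var) /
                   rowMeans(simN$counts$counts))
  expect_lt(vmrP, 8)      # Poisson + size-factor spread stays small
  expect_gt(vmrN, 20)     # NB with alpha = 0.5 at mu ~ 148 is >> Poisson
})
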