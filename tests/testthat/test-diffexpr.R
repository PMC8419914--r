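make_cm <- function(counts, lengths = NULL, cond = NULL) {
  if (is.null(rownames(counts))) {
    rownames(counts) <- sprintf("g%03d", seq_len(nrow(counts)))
  }
  if (is.null(colnames(counts))) {
    colnames(counts) <- sprintf("s%02d", seq_len(ncol(counts)))
  }
  if (is.null(lengths)) lengths <- rep(1000, nrow(counts))
  if (is.null(cond)) {
    cond <- rep(c("A", "B"), each = ncol(counts) / 2)
  }
  count_matrix(counts, lengths,
               group_assignment(colnames(counts), cond))
}

test_that("FPKM follows its closed form and scale invariances", {
  counts <- matrix(0L, 2, 2)
  counts[1, 1] <- 10L
  counts[2, 1] <- 999990L
  counts[, 2] <- c(5L, 15L)
  cm <- make_cm(counts, lengths = c(2000, 500))
  f <- fpkm(cm)
  # count 10, length 2000 bp, library 1e6 -> FPKM 5
  expect_equal(f[1, 1], 5)
  expect_equal(fpkm(make_cm(matrix(c(0L, 10L), 2, 2),
                            lengths = c(100, 100)))[1, ], c(s01 = 0, s02 = 0))
  # doubling every count in a sample leaves that sample's FPKM unchanged
  counts2 <- counts; counts2[, 1] <- counts2[, 1] * 2L
  expect_equal(fpkm(make_cm(counts2, lengths = c(2000, 500)))[, 1], f[, 1])
  # zero library size is a contract error naming the sample
  countsz <- counts; countsz[, 2] <- 0L
  expect_error(fpkm(make_cm(countsz, lengths = c(2000, 500))), "s02")
})

test_that("median-of-ratios size factors behave as documented", {
  set.seed(3)
  base <- matrix(rpois(100 * 4, 50) + 1L, 100, 4)
  expect_equal(unname(size_factors(make_cm(base[, c(1, 1, 1, 1)]))),
               rep(1, 4))
  doubled <- base; doubled[, 4] <- doubled[, 4] * 2L
  sf <- size_factors(make_cm(doubled))
  expect_equal(unname(sf[4] / sf[1]), 2, tolerance = 0.1)
  expect_equal(exp(mean(log(sf))), 1, tolerance = 1e-12)
  # fallback when no gene is nonzero everywhere
  sparse <- base; sparse[, 1] <- 0L; sparse[1, 1] <- 5L
  sparse[1, 2:4] <- 0L
  expect_message(size_factors(make_cm(sparse)), "library-size")
})

test_that("BH adjustment matches the brute-force step-up definition", {
  expect_equal(stats::p.adjust(c(0.01, 0.02, 0.03, 0.04), method = "BH"),
               rep(0.04, 4))
  set.seed(11)
  for (rep in 1:50) {
    p <- runif(sample(1:40, 1))^sample(1:3, 1)
    expect_lt(max(abs(stats::p.adjust(p, "BH") - oracle_bh(p))), 1e-12)
  }
})

test_that("genes with no signal give log2FC 0 and no DEG call", {
  counts <- matrix(rep(c(20L, 40L), each = 8), 2, 8, byrow = TRUE)
  fit <- nb_de(make_cm(counts))
  expect_equal(fit$results$log2fc, c(0, 0))
  expect_false(any(fit$results$deg))
  expect_true(all(fit$results$padj >= fit$results$pvalue))
})

test_that("all-zero genes are excluded from testing and the BH denominator", {
  set.seed(5)
  counts <- matrix(rpois(50 * 8, 30), 50, 8)
  counts[c(3, 7), ] <- 0L
  fit <- nb_de(make_cm(counts))
  expect_equal(fit$n_zero, 2L)
  expect_equal(nrow(fit$results), 48L)
  expect_false(any(fit$results$gene_id %in% c("g003", "g007")))
  expect_equal(fit$results$padj,
               stats::p.adjust(fit$results$pvalue, "BH"))
})

test_that("the DEG rule is strict on both thresholds", {
  res <- data.frame(
    gene_id = c("a", "b", "c", "d"),
    base_mean = 10, fpkm_mean_1 = 1, fpkm_mean_2 = 1,
    log2fc = c(log2(1.5), log2(1.5) + 1e-9, -1, 1),
    pvalue = c(0.001, 0.001, 0.001, 0.001),
    padj = c(0.01, 0.01, 0.05, 0.049),
    deg = FALSE)
  fit <- structure(list(results = res, conditions = c("A", "B"),
                        params = de_params()), class = "nb_de")
  out <- call_degs(fit, de_params())
  # |log2FC| = log2(1.5) exactly fails; padj = 0.05 exactly fails
  expect_setequal(out$gene_id, c("b", "d"))
})

test_that("null simulation holds the nominal type-I level", {
  sim <- simulate_counts(count_sim_config(n_genes = 5000, n_per_group = 7,
                                          frac_de = 0, dispersion = 0.1,
                                          seed = 301))
  fit <- nb_de(sim$counts)
  frac <- mean(fit$results$pvalue < 0.05)
  expect_gt(frac, 0.04)
  expect_lt(frac, 0.06)
  # and almost nothing survives BH + the fold-change rule
  expect_lt(sum(fit$results$deg), 5)
})

test_that("planted fold changes are recovered with controlled FDR", {
  stats <- sapply(1:5, function(sd) {
    sim <- simulate_counts(count_sim_config(n_genes = 2000, n_per_group = 7,
                                            frac_de = 0.1, lfc = 2,
                                            dispersion = 0.05,
                                            seed = 400 + sd))
    d <- call_degs(nb_de(sim$counts))
    truth <- sim$truth
    sens <- mean(truth$gene_id[truth$is_de] %in% d$gene_id)
    fdr <- if (nrow(d)) mean(!truth$is_de[match(d$gene_id,
                                                truth$gene_id)]) else 0
    c(sens, fdr)
  })
  expect_gte(mean(stats[1, ]), 0.8)
  expect_lte(mean(stats[2, ]), 0.10)
  # directions carry the right sign
  sim <- simulate_counts(count_sim_config(n_genes = 1000, n_per_group = 7,
                                          frac_de = 0.2, lfc = 2,
                                          dispersion = 0.05, seed = 500))
  d <- call_degs(nb_de(sim$counts))
  tr <- sim$truth[match(d$gene_id, sim$truth$gene_id), ]
  agree <- sign(d$log2fc) == sign(tr$true_lfc)
  expect_gt(mean(agree[tr$is_de]), 0.95)
})

test_that("nb_de enforces its design contracts", {
  counts <- matrix(rpois(20 * 4, 30), 20, 4)
  expect_error(nb_de(make_cm(counts, cond = c("A", "A", "A", "B"))),
               ">= 2 samples")
  expect_error(nb_de(make_cm(counts, cond = c("A", "B", "C", "C"))),
               "two conditions")
})
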