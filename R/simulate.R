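#' Configuration for the Balding-Nichols genotype simulator
#'
#' Describes a two-population divergence scenario: an ancestral allele
#' frequency per SNP, daughter-population frequencies drawn from a Beta
#' distribution with divergence parameter F (so that the expected
#' Weir-Cockerham Fst is approximately F), and optional planted sweep regions
#' where a larger F applies.
#'
#' @param n_wild,n_dom diploid sample counts in the two populations.
#' @param n_chrom number of chromosomes.
#' @param chrom_length chromosome length in bp (all chromosomes equal).
#' @param snp_density expected SNPs per bp (positions uniform, without
#'   replacement).
#' @param F_background genome-wide divergence parameter in (0, 1).  The
#'   default 0.06 is typical of a recently domesticated lineage versus its
#'   wild progenitor.
#' @param sweep_regions data frame with columns `chrom`, `start`, `end`,
#'   `F_sweep` (each `F_sweep > F_background`); may be `NULL`.
#' @param maf_min minimum ancestral allele frequency (ascertainment knob).
#' @param missing_rate per-genotype missing probability.
#' @param seed integer RNG seed; every output is reproducible from it.
#' @return A list of class `sweep_sim_config`.
#' @export
sweep_sim_config <- function(n_wild = 20, n_dom = 20, n_chrom = 1,
                             chrom_length = 5e6, snp_density = 1 / 500,
                             F_background = 0.06, sweep_regions = NULL,
                             maf_min = 0.05, missing_rate = 0,
                             seed = 1L) {
  stopifnot(n_wild >= 1, n_dom >= 1, n_chrom >= 1, chrom_length >= 1,
            snp_density > 0, F_background > 0, F_background < 1,
            maf_min >= 0, maf_min < 0.5, missing_rate >= 0, missing_rate < 1)
  if (!is.null(sweep_regions)) {
    stopifnot(is.data.frame(sweep_regions),
              all(c("chrom", "start", "end", "F_sweep") %in%
                    colnames(sweep_regions)))
    if (any(sweep_regions$F_sweep <= F_background) ||
        any(sweep_regions$F_sweep >= 1)) {
      stop("config error: need F_background < F_sweep < 1")
    }
    if (any(sweep_regions$start < 1) ||
        any(sweep_regions$end > chrom_length) ||
        any(sweep_regions$start > sweep_regions$end)) {
      stop("config error: sweep region outside chromosome bounds")
    }
    chroms <- paste0("chr", seq_len(n_chrom))
    if (!all(sweep_regions$chrom %in% chroms)) {
      stop("config error: sweep region on unknown chromosome")
    }
  }
  structure(list(n_wild = n_wild, n_dom = n_dom, n_chrom = n_chrom,
                 chrom_length = chrom_length, snp_density = snp_density,
                 F_background = F_background, sweep_regions = sweep_regions,
                 maf_min = maf_min, missing_rate = missing_rate,
                 seed = as.integer(seed)),
            class = "sweep_sim_config")
}

#' Simulate two-population diploid genotypes under the Balding-Nichols model
#'
#' For each SNP an ancestral frequency `p ~ Uniform(maf_min, 1 - maf_min)` is
#' drawn; each population's frequency is
#' `p_k ~ Beta(p (1 - F) / F, (1 - p)(1 - F) / F)` with `F` equal to
#' `F_sweep` inside a planted sweep region and `F_background` elsewhere;
#' dosages are `Binomial(2, p_k)` per diploid sample, then masked at the
#' missing rate.
#'
#' @param config a [sweep_sim_config()].
#' @return A list with elements `table` (a [variant_table()]; INFO columns
#'   are empty), `groups` (a [group_assignment()] with labels `wild` /
#'   `domestic`), and `truth` (data frame: `chrom`, `pos`, `F_used`,
#'   `in_sweep`).
#' @export
simulate_genotypes <- function(config) {
  stopifnot(inherits(config, "sweep_sim_config"))
  set.seed(config$seed)
  chroms <- paste0("chr", seq_len(config$n_chrom))
  pos_list <- lapply(chroms, function(ch) {
    n <- stats::rpois(1, config$snp_density * config$chrom_length)
    n <- min(n, config$chrom_length)
    sort(sample.int(config$chrom_length, n))
  })
  chrom <- rep(chroms, lengths(pos_list))
  pos <- unlist(pos_list)
  m <- length(pos)

  Fv <- rep(config$F_background, m)
  in_sweep <- rep(FALSE, m)
  sr <- config$sweep_regions
  if (!is.null(sr)) {
    for (i in seq_len(nrow(sr))) {
      hit <- chrom == sr$chrom[i] & pos >= sr$start[i] & pos <= sr$end[i]
      Fv[hit] <- sr$F_sweep[i]
      in_sweep <- in_sweep | hit
    }
  }

  p <- stats::runif(m, config$maf_min, 1 - config$maf_min)
  shape_scale <- (1 - Fv) / Fv
  p1 <- stats::rbeta(m, p * shape_scale, (1 - p) * shape_scale)
  p2 <- stats::rbeta(m, p * shape_scale, (1 - p) * shape_scale)

  n1 <- config$n_wild; n2 <- config$n_dom
  g1 <- matrix(stats::rbinom(m * n1, 2, rep(p1, n1)), nrow = m)
  g2 <- matrix(stats::rbinom(m * n2, 2, rep(p2, n2)), nrow = m)
  geno <- cbind(g1, g2)
  colnames(geno) <- c(sprintf("wild%02d", seq_len(n1)),
                      sprintf("dom%02d", seq_len(n2)))
  if (config$missing_rate > 0) {
    geno[stats::runif(length(geno)) < config$missing_rate] <- NA_integer_
  }

  ref_alt <- pick_alleles(m)
  info <- as.data.frame(stats::setNames(
    rep(list(rep(NA_real_, m)), 5),
    c("QD", "FS", "MQ", "MQRankSum", "ReadPosRankSum")))
  table <- variant_table(chrom, pos, ref_alt$ref, ref_alt$alt,
                         rep(NA_real_, m), info, geno)
  groups <- group_assignment(colnames(geno),
                             rep(c("wild", "domestic"), c(n1, n2)))
  truth <- data.frame(chrom = chrom, pos = pos, F_used = Fv,
                      in_sweep = in_sweep)
  list(table = table, groups = groups, truth = truth)
}

# Random distinct REF/ALT base pairs.
pick_alleles <- function(m) {
  nt <- c("A", "C", "G", "T")
  ref <- sample(nt, m, replace = TRUE)
  shift <- sample.int(3, m, replace = TRUE)
  alt <- nt[(match(ref, nt) - 1L + shift) %% 4L + 1L]
  list(ref = ref, alt = alt)
}

#' Plant known QC-filter failures into a variant table
#'
#' Assigns QUAL and INFO annotations so that a known, recorded subset of
#' records fails exactly the designated hard-filter criteria.  Passing values
#' are drawn from strictly passing ranges and failing values from strictly
#' failing ranges; no boundary values are emitted.
#'
#' @param table a [variant_table()].
#' @param fail_spec named numeric vector of failure fractions in `[0, 1]` for
#'   any of `QUAL`, `QD`, `FS`, `MQ`, `MQRankSum`, `ReadPosRankSum`.
#'   Failure sets for different criteria are drawn independently unless
#'   `disjoint = TRUE`.
#' @param seed integer seed.
#' @param disjoint if `TRUE`, failure sets of the criteria are disjoint
#'   (requires the fractions to sum to at most 1).
#' @param thresholds a [hard_filter_thresholds()] defining the pass/fail
#'   boundaries.
#' @return A list with `table` (annotated copy) and `truth` (logical matrix,
#'   records x criteria, `TRUE` = designated failure; plus attribute-free
#'   column `pass_all` available via `rowSums`).
#' @export
simulate_info_annotations <- function(table, fail_spec = NULL, seed = 1L,
                                      disjoint = FALSE,
                                      thresholds = hard_filter_thresholds()) {
  stopifnot(inherits(table, "variant_table"))
  crit <- c("QUAL", "QD", "FS", "MQ", "MQRankSum", "ReadPosRankSum")
  frac <- stats::setNames(rep(0, length(crit)), crit)
  if (!is.null(fail_spec)) {
    if (any(!names(fail_spec) %in% crit)) {
      stop("unknown criteria in fail_spec: ",
           paste(setdiff(names(fail_spec), crit), collapse = ", "))
    }
    if (any(fail_spec < 0 | fail_spec > 1)) {
      stop("fail fractions must lie in [0, 1]")
    }
    frac[names(fail_spec)] <- fail_spec
  }
  n <- n_variants(table)
  set.seed(seed)
  fail <- matrix(FALSE, n, length(crit), dimnames = list(NULL, crit))
  if (disjoint) {
    k <- round(frac * n)
    if (sum(k) > n) stop("disjoint failure fractions exceed the record count")
    pool <- sample.int(n)
    off <- 0L
    for (j in seq_along(crit)) {
      if (k[j] > 0) fail[pool[off + seq_len(k[j])], j] <- TRUE
      off <- off + k[j]
    }
  } else {
    for (j in seq_along(crit)) {
      fail[, j] <- stats::runif(n) < frac[j]
    }
  }
  th <- thresholds
  # strictly passing / strictly failing draws, margin keeps values off the
  # boundary
  draw <- function(nn, lo, hi) stats::runif(nn, lo, hi)
  val <- function(fails, pass_lo, pass_hi, fail_lo, fail_hi) {
    out <- numeric(n)
    out[!fails] <- draw(sum(!fails), pass_lo, pass_hi)
    out[fails] <- draw(sum(fails), fail_lo, fail_hi)
    out
  }
  table$qual <- val(fail[, "QUAL"], th$qual_min + 1, th$qual_min + 100,
                    0, th$qual_min - 1)
  table$info$QD <- val(fail[, "QD"], th$qd_min + 1, th$qd_min + 30,
                       0, th$qd_min - 1)
  table$info$FS <- val(fail[, "FS"], 0, th$fs_max - 1,
                       th$fs_max + 1, th$fs_max + 100)
  table$info$MQ <- val(fail[, "MQ"], th$mq_min + 1, th$mq_min + 20,
                       0, th$mq_min - 1)
  table$info$MQRankSum <- val(fail[, "MQRankSum"],
                              th$mqranksum_min + 1, th$mqranksum_min + 15,
                              th$mqranksum_min - 10, th$mqranksum_min - 1)
  table$info$ReadPosRankSum <- val(fail[, "ReadPosRankSum"],
                                   th$readposranksum_min + 1,
                                   th$readposranksum_min + 10,
                                   th$readposranksum_min - 10,
                                   th$readposranksum_min - 1)
  list(table = table, truth = fail)
}

#' Simulate a non-overlapping gene annotation
#'
#' Places `n_genes` gene bodies uniformly without overlap across the given
#' chromosome layout.
#'
#' @param n_genes gene count.
#' @param chrom_lengths named numeric vector, chromosome name to length (bp).
#' @param gene_length_range length-2 vector: min and max gene length (bp).
#' @param seed integer seed.
#' @return Gene data frame as from [read_genes()], sorted, non-overlapping.
#' @export
simulate_gene_annotation <- function(n_genes, chrom_lengths,
                                     gene_length_range = c(1000, 20000),
                                     seed = 1L) {
  stopifnot(n_genes >= 0, all(chrom_lengths >= 1),
            !is.null(names(chrom_lengths)),
            length(gene_length_range) == 2,
            gene_length_range[1] <= gene_length_range[2])
  set.seed(seed)
  if (n_genes == 0) {
    return(data.frame(gene_id = character(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0)))
  }
  n_chr <- length(chrom_lengths)
  per_chr <- tabulate(sample.int(n_chr, n_genes, replace = TRUE,
                                 prob = chrom_lengths / sum(chrom_lengths)),
                      nbins = n_chr)
  res <- vector("list", n_chr)
  for (ci in seq_len(n_chr)) {
    k <- per_chr[ci]
    if (k == 0) next
    L <- chrom_lengths[ci]
    len <- round(stats::runif(k, gene_length_range[1], gene_length_range[2]))
    slack <- L - sum(len) - k  # >=1 bp gap between genes
    if (slack < 0) stop("config error: genes do not fit without overlap")
    gaps <- stats::runif(k + 1)
    gaps <- floor(gaps / sum(gaps) * slack)
    start <- cumsum(c(1, len + 1)[seq_len(k)]) + cumsum(gaps[seq_len(k)])
    res[[ci]] <- data.frame(chrom = names(chrom_lengths)[ci],
                            start = as.integer(start),
                            end = as.integer(start + len - 1),
                            stringsAsFactors = FALSE)
  }
  d <- do.call(rbind, res)
  d <- d[order(d$chrom, d$start), , drop = FALSE]
  data.frame(gene_id = sprintf("gene%04d", seq_len(nrow(d))),
             chrom = d$chrom, start = d$start, end = d$end,
             strand = sample(c("+", "-"), nrow(d), replace = TRUE))
}

#' Configuration for the negative-binomial count simulator
#'
#' @param n_genes gene count.
#' @param n_per_group samples per condition (default 7, a typical tissue
#'   cohort size in livestock RNA-seq designs).
#' @param frac_de fraction of genes that are truly differentially expressed.
#' @param lfc absolute true log2 fold change for DE genes (sign random).
#' @param mean_log_mu,sd_log_mu natural-log mean and sd of baseline gene
#'   means.
#' @param dispersion NB dispersion alpha, so that `Var = mu + alpha * mu^2`;
#'   0 gives Poisson counts.
#' @param gene_length_range length-2 range of simulated gene lengths (bp).
#' @param seed integer seed.
#' @return A list of class `count_sim_config`.
#' @export
count_sim_config <- function(n_genes = 5000, n_per_group = 7, frac_de = 0,
                             lfc = 2, mean_log_mu = 4, sd_log_mu = 1.5,
                             dispersion = 0.05,
                             gene_length_range = c(500, 10000), seed = 1L) {
  stopifnot(n_genes >= 1, n_per_group >= 2, frac_de >= 0, frac_de <= 1,
            lfc >= 0, dispersion >= 0)
  structure(list(n_genes = n_genes, n_per_group = n_per_group,
                 frac_de = frac_de, lfc = lfc, mean_log_mu = mean_log_mu,
                 sd_log_mu = sd_log_mu, dispersion = dispersion,
                 gene_length_range = gene_length_range,
                 seed = as.integer(seed)),
            class = "count_sim_config")
}

#' Simulate an RNA-seq count matrix with planted fold changes
#'
#' Counts are negative binomial with mean
#' `mu_g * s_j * 2^(sign_g * lfc)` for DE genes in condition 2 (otherwise
#' `mu_g * s_j`), with per-sample size factors `s_j ~ Uniform(0.7, 1.3)` and
#' dispersion `alpha` (`Var = mu + alpha mu^2`; `alpha = 0` gives Poisson).
#'
#' @param config a [count_sim_config()].
#' @return A list with `counts` (a [count_matrix()], conditions `ctrl` /
#'   `case`) and `truth` (data frame: `gene_id`, `is_de`, `true_lfc`).
#' @export
simulate_counts <- function(config) {
  stopifnot(inherits(config, "count_sim_config"))
  set.seed(config$seed)
  G <- config$n_genes; n <- config$n_per_group
  gene_id <- sprintf("gene%05d", seq_len(G))
  mu <- exp(stats::rnorm(G, config$mean_log_mu, config$sd_log_mu))
  n_de <- round(config$frac_de * G)
  is_de <- rep(FALSE, G)
  is_de[sample.int(G, n_de)] <- TRUE
  sign_g <- ifelse(is_de, sample(c(-1, 1), G, replace = TRUE), 0)
  true_lfc <- sign_g * config$lfc

  s <- stats::runif(2 * n, 0.7, 1.3)
  cond <- rep(c("ctrl", "case"), each = n)
  mu_mat <- outer(mu, s) * 2^(true_lfc %o% as.numeric(cond == "case"))
  counts <- if (config$dispersion == 0) {
    matrix(stats::rpois(G * 2 * n, mu_mat), nrow = G)
  } else {
    matrix(stats::rnbinom(G * 2 * n, mu = mu_mat,
                          size = 1 / config$dispersion), nrow = G)
  }
  storage.mode(counts) <- "integer"
  rownames(counts) <- gene_id
  colnames(counts) <- sprintf("%s%02d", cond, c(seq_len(n), seq_len(n)))
  gl <- round(stats::runif(G, config$gene_length_range[1],
                           config$gene_length_range[2]))
  cm <- count_matrix(counts, gl,
                     group_assignment(colnames(counts), cond))
  list(counts = cm,
       truth = data.frame(gene_id = gene_id, is_de = is_de,
                          true_lfc = true_lfc))
}
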