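#' Hard-filter thresholds for SNP retention
#'
#' The six GATK-style site-level thresholds.  A record is retained only if it
#' strictly satisfies every rule: `QUAL > qual_min`, `QD > qd_min`,
#' `FS < fs_max`, `MQ > mq_min`, `MQRankSum > mqranksum_min`,
#' `ReadPosRankSum > readposranksum_min`.
#'
#' @param qual_min,qd_min,fs_max,mq_min,mqranksum_min,readposranksum_min
#'   numeric thresholds; defaults are the conventional resequencing values.
#' @return A list of class `hard_filter_thresholds`.
#' @export
hard_filter_thresholds <- function(qual_min = 30.0, qd_min = 5.0,
                                   fs_max = 60.0, mq_min = 40.0,
                                   mqranksum_min = -12.5,
                                   readposranksum_min = -8.0) {
  th <- list(qual_min = qual_min, qd_min = qd_min, fs_max = fs_max,
             mq_min = mq_min, mqranksum_min = mqranksum_min,
             readposranksum_min = readposranksum_min)
  stopifnot(all(vapply(th, is.finite, logical(1))))
  structure(th, class = "hard_filter_thresholds")
}

new_qc_report <- function(stage, n_in, n_out, removed_by) {
  structure(list(stage = stage, n_in = n_in, n_out = n_out,
                 removed_by = removed_by),
            class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("QC stage '%s': %d -> %d records (%d removed)\n",
              x$stage, x$n_in, x$n_out, x$n_in - x$n_out))
  for (nm in names(x$removed_by)) {
    cat(sprintf("  %-16s %d\n", nm, x$removed_by[[nm]]))
  }
  invisible(x)
}

#' Apply the six site-level hard filters
#'
#' A record missing an INFO annotation is, by default, exempt from that
#' single rule (rank-sum annotations are undefined at sites without
#' heterozygotes); set `missing_info = "fail"` to reject on absence instead.
#' Each removed record is attributed to the first failing rule in the order
#' QUAL, QD, FS, MQ, MQRankSum, ReadPosRankSum.
#'
#' @param table a [variant_table()].
#' @param thresholds a [hard_filter_thresholds()].
#' @param missing_info `"pass"` (default) or `"fail"`.
#' @return A list with `table` (retained records) and `report`
#'   (a `qc_report` with per-rule removal counts).
#' @export
hard_filter <- function(table, thresholds = hard_filter_thresholds(),
                        missing_info = c("pass", "fail")) {
  stopifnot(inherits(table, "variant_table"))
  missing_info <- match.arg(missing_info)
  th <- thresholds
  tests <- list(
    QUAL = table$qual > th$qual_min,
    QD = table$info$QD > th$qd_min,
    FS = table$info$FS < th$fs_max,
    MQ = table$info$MQ > th$mq_min,
    MQRankSum = table$info$MQRankSum > th$mqranksum_min,
    ReadPosRankSum = table$info$ReadPosRankSum > th$readposranksum_min
  )
  fill <- missing_info == "pass"
  tests <- lapply(tests, function(t) {
    if (is.null(t)) t <- rep(NA, n_variants(table))
    t[is.na(t)] <- fill
    t
  })
  keep <- Reduce(`&`, tests)
  first_fail <- rep(NA_character_, n_variants(table))
  for (nm in rev(names(tests))) first_fail[!tests[[nm]]] <- nm
  removed <- table(factor(first_fail[!keep], levels = names(tests)))
  report <- new_qc_report("hard_filter", n_variants(table), sum(keep),
                          as.list(removed))
  list(table = vt_subset(table, keep), report = report)
}

#' Cluster-filter parameters
#'
#' @param window_bp span of consecutive bases considered a cluster window.
#' @param max_snps maximum SNPs tolerated in any such span; any span holding
#'   more marks all its SNPs for removal.
#' @return A list of class `cluster_filter_params`.
#' @export
cluster_filter_params <- function(window_bp = 10, max_snps = 3) {
  stopifnot(window_bp >= 1, max_snps >= 1)
  structure(list(window_bp = as.integer(window_bp),
                 max_snps = as.integer(max_snps)),
            class = "cluster_filter_params")
}

#' Remove clustered SNPs (likely alignment artifacts)
#'
#' If more than `max_snps` SNPs fall within any placement of a `window_bp`
#' consecutive-base span, all SNPs of every such span are removed.  With
#' defaults: more than three SNPs in any 10-bp window.
#'
#' @param table a [variant_table()], sorted by (chrom, pos).
#' @param params a [cluster_filter_params()].
#' @return A list with `table` and `report` as in [hard_filter()].
#' @export
cluster_filter <- function(table, params = cluster_filter_params()) {
  stopifnot(inherits(table, "variant_table"))
  n <- n_variants(table)
  drop <- rep(FALSE, n)
  if (n > 0) {
    idx <- split(seq_len(n), table$chrom)
    for (ii in idx) {
      p <- table$pos[ii]
      if (is.unsorted(p)) stop("contract error: unsorted positions")
      # right end of each candidate span starting at SNP i
      j <- findInterval(p + params$window_bp - 1L, p)
      viol <- (j - seq_along(p) + 1L) > params$max_snps
      for (i in which(viol)) drop[ii[i:j[i]]] <- TRUE
    }
  }
  report <- new_qc_report("cluster_filter", n, sum(!drop),
                          list(snp_cluster = sum(drop)))
  list(table = vt_subset(table, !drop), report = report)
}

#' Remove SNPs with a high genotype missing rate
#'
#' Drops records whose fraction of missing genotypes strictly exceeds
#' `max_missing` (a rate exactly equal to the threshold is retained).
#'
#' @param table a [variant_table()].
#' @param max_missing maximum tolerated missing fraction.
#' @return A list with `table` and `report`.
#' @export
missing_rate_filter <- function(table, max_missing = 0.1) {
  stopifnot(inherits(table, "variant_table"), max_missing >= 0)
  rate <- rowMeans(is.na(table$geno))
  keep <- rate <= max_missing
  report <- new_qc_report("missing_rate_filter", n_variants(table),
                          sum(keep), list(missing_rate = sum(!keep)))
  list(table = vt_subset(table, keep), report = report)
}

#' Drop records on excluded chromosomes
#'
#' Typically used to restrict a divergence scan to autosomes by excluding the
#' sex chromosomes by name.
#'
#' @param table a [variant_table()].
#' @param excluded_chroms character vector of chromosome names to drop
#'   (default none).
#' @return A [variant_table()].
#' @export
autosome_filter <- function(table, excluded_chroms = character(0)) {
  stopifnot(inherits(table, "variant_table"))
  vt_subset(table, !(table$chrom %in% excluded_chroms))
}

#' Run the full SNP retention pipeline
#'
#' Applies, in order: the six hard filters, the SNP-cluster filter, the
#' missing-rate filter, and the chromosome exclusion.
#'
#' @param table a [variant_table()].
#' @param thresholds a [hard_filter_thresholds()].
#' @param cluster a [cluster_filter_params()].
#' @param max_missing maximum missing-genotype fraction.
#' @param excluded_chroms chromosomes to drop (e.g. sex chromosomes).
#' @param missing_info hard-filter policy for absent INFO keys.
#' @return A list with `table` (surviving records) and `reports` (list of the
#'   per-stage `qc_report`s).
#' @export
variant_qc <- function(table, thresholds = hard_filter_thresholds(),
                       cluster = cluster_filter_params(), max_missing = 0.1,
                       excluded_chroms = character(0),
                       missing_info = "pass") {
  h <- hard_filter(table, thresholds, missing_info)
  k <- cluster_filter(h$table, cluster)
  m <- missing_rate_filter(k$table, max_missing)
  out <- autosome_filter(m$table, excluded_chroms)
  list(table = out,
       reports = list(hard = h$report, cluster = k$report,
                      missing = m$report))
}

#' Write QC reports as a TSV
#' @param reports list of `qc_report` objects.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_qc_report <- function(reports, path) {
  rows <- do.call(rbind, lapply(reports, function(r) {
    data.frame(stage = r$stage, rule = names(r$removed_by),
               removed = unlist(r$removed_by), n_in = r$n_in, n_out = r$n_out)
  }))
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
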