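#' Run the full divergence-scan pipeline
#'
#' Composes the stages in the canonical order: variant QC (hard filters,
#' cluster filter, missing-rate filter, chromosome exclusion), windowed Fst
#' scan with candidate-region extraction and gene annotation, genotype PCA,
#' per-tissue differential expression, and the candidate x DEG intersection.
#' Every intermediate is written under `out_dir` and a JSON run manifest
#' records the configuration and per-stage record counts.
#'
#' @param config a list naming the inputs and parameters:
#'   \describe{
#'     \item{vcf}{path to the input VCF (required)}
#'     \item{groups}{path to the sample-to-group TSV (required)}
#'     \item{genes}{path to the gene annotation (BED6/GFF3; required)}
#'     \item{counts}{named list or vector, tissue -> counts TSV (optional)}
#'     \item{conditions}{tissue -> condition TSV, same names as `counts`}
#'     \item{thresholds, cluster, max_missing, excluded_chroms,
#'           missing_info}{QC settings, see [variant_qc()]}
#'     \item{scan}{a [scan_params()]}
#'     \item{de}{a [de_params()]}
#'     \item{pca_k}{components for [genotype_pca()] (default 20)}
#'     \item{chrom_lengths}{named vector of chromosome lengths (optional)}
#'   }
#' @param out_dir output directory (created if needed).
#' @return A list with `qc`, `scan`, `pca`, `de` (named by tissue),
#'   `integration` and `manifest`, invisibly writing all artifacts.
#' @export
run_pipeline <- function(config, out_dir) {
  for (req in c("vcf", "groups", "genes")) {
    if (is.null(config[[req]])) stop("missing input in config: ", req)
    if (!file.exists(config[[req]])) {
      stop("stage 'input': missing file for '", req, "': ", config[[req]])
    }
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(config = config[!vapply(config, is.object, logical(1))],
                   stages = list())
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("stage '", name, "': ", conditionMessage(e), call. = FALSE)
    })
  }

  table <- stage("read_vcf", read_vcf(config$vcf))
  groups <- stage("read_groups", read_groups(config$groups))
  genes <- stage("read_genes", read_genes(config$genes))
  manifest$stages$input <- list(n_snps = n_variants(table),
                                n_samples = length(vt_samples(table)),
                                n_genes = nrow(genes))

  qc <- stage("variant_qc", variant_qc(
    table,
    thresholds = config$thresholds %||% hard_filter_thresholds(),
    cluster = config$cluster %||% cluster_filter_params(),
    max_missing = config$max_missing %||% 0.1,
    excluded_chroms = config$excluded_chroms %||% character(0),
    missing_info = config$missing_info %||% "pass"))
  write_vcf(qc$table, file.path(out_dir, "filtered.vcf"))
  write_qc_report(qc$reports, file.path(out_dir, "qc_report.tsv"))
  manifest$stages$variant_qc <- list(n_in = n_variants(table),
                                     n_out = n_variants(qc$table))

  scan <- stage("fst_scan", fst_scan(
    qc$table, groups, genes,
    params = config$scan %||% scan_params(),
    chrom_lengths = config$chrom_lengths))
  write_scan(scan, file.path(out_dir, "scan"))
  manifest$stages$fst_scan <- list(
    n_windows = sum(scan$windows$eligible),
    mean_fst_weighted = scan$mean_fst_weighted,
    n_top_windows = nrow(scan$top),
    n_candidate_regions = nrow(scan$candidates$regions),
    n_candidate_genes = nrow(scan$candidates$genes))

  pca <- stage("genotype_pca",
               genotype_pca(qc$table, k = config$pca_k %||% 20))
  write_pca(pca, file.path(out_dir, "pca"))
  manifest$stages$pca <- list(k = pca$k,
                              varfrac_top3 = sum(pca$varfrac[
                                seq_len(min(3, pca$k))]))

  de_fits <- list()
  if (!is.null(config$counts)) {
    tissues <- names(config$counts)
    if (is.null(tissues)) stop("config$counts must be a named list")
    for (ts in tissues) {
      fit <- stage(paste0("nb_de:", ts), nb_de(
        read_counts(config$counts[[ts]], config$conditions[[ts]]),
        params = config$de %||% de_params()))
      write_de(fit, file.path(out_dir, paste0("de_", ts, ".tsv")))
      de_fits[[ts]] <- fit
      manifest$stages[[paste0("de_", ts)]] <-
        summary(fit)[c("n_tested", "n_deg", "n_up", "n_down")]
    }
  }

  integration <- NULL
  if (length(de_fits)) {
    integration <- stage("integrate",
                         intersect_candidates(scan$candidates, de_fits))
    utils::write.table(format_tsv_num(integration),
                       file.path(out_dir, "integration.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    manifest$stages$integrate <- list(n_rows = nrow(integration))
  }

  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, na = "null",
                       force = TRUE)
  invisible(list(qc = qc, scan = scan, pca = pca, de = de_fits,
                 integration = integration, manifest = manifest))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
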