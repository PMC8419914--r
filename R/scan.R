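#' Windowed Fst selective-sweep scan
#'
#' The end-to-end divergence scan: per-SNP Weir-Cockerham variance
#' components between two populations, sliding-window aggregation
#' (ratio-of-averages), top-percentile outlier windows, flank extension and
#' merge into candidate regions, and (optionally) candidate-gene annotation.
#'
#' @param table a filtered [variant_table()].
#' @param groups a [group_assignment()] with exactly two groups.
#' @param genes optional gene data frame from [read_genes()]; when supplied,
#'   candidate genes are annotated.
#' @param params a [scan_params()].
#' @param chrom_lengths named vector of chromosome lengths (bp); defaults to
#'   the last SNP position per chromosome.
#' @param estimator `"wc"` (Weir-Cockerham, default) or `"hudson"`
#'   (cross-check estimator; window statistic is the corresponding ratio of
#'   sums).
#' @return An object of class `fst_scan` with components `snps` (per-SNP
#'   statistics), `windows` (per-window statistics), `top` (outlier
#'   windows), `candidates` (a `candidate_regions` object), `params`,
#'   `groups` and summary fields `mean_fst_weighted` (genome-wide
#'   `sum(a)/sum(a+b+c)`), `mean_fst_windows` (mean of window values) and
#'   `max_window`.
#' @examples
#' sim <- simulate_genotypes(sweep_sim_config(
#'   n_wild = 10, n_dom = 10, chrom_length = 5e5, snp_density = 1 / 500,
#'   F_background = 0.05, seed = 42))
#' scan <- fst_scan(sim$table, sim$groups,
#'                  params = scan_params(top_fraction = 0.05))
#' scan
#' @export
fst_scan <- function(table, groups, genes = NULL, params = scan_params(),
                     chrom_lengths = NULL, estimator = c("wc", "hudson")) {
  estimator <- match.arg(estimator)
  stopifnot(inherits(table, "variant_table"))
  if (n_variants(table) == 0) stop("empty variant table")
  if (is.null(chrom_lengths)) {
    chrom_lengths <- tapply(table$pos, table$chrom, max)
    chrom_lengths <- stats::setNames(as.numeric(chrom_lengths),
                                     names(chrom_lengths))
  }
  if (estimator == "wc") {
    snps <- snp_fst(table, groups)
    num <- snps$a; den <- snps$a + snps$b + snps$c
  } else {
    hud <- snp_fst_hudson(table, groups)
    snps <- data.frame(chrom = hud$chrom, pos = hud$pos, a = hud$num,
                       b = hud$den - hud$num, c = 0, theta = hud$fst,
                       defined = hud$defined)
    num <- hud$num; den <- hud$den
  }
  grid <- make_windows(chrom_lengths, params)
  win <- window_fst(snps, grid, params)
  top <- top_windows(win, params)
  cand <- candidate_regions(top, params, chrom_lengths)
  if (!is.null(genes)) cand <- annotate_candidates(cand, genes)

  def <- snps$defined
  mean_w <- sum(num[def]) / sum(den[def])
  maxrow <- win[win$eligible, , drop = FALSE]
  maxrow <- maxrow[which.max(maxrow$fst_weighted), , drop = FALSE]
  structure(list(
    snps = snps, windows = win, top = top, candidates = cand,
    params = params, groups = groups, estimator = estimator,
    chrom_lengths = chrom_lengths,
    mean_fst_weighted = mean_w,
    mean_fst_windows = mean(win$fst_weighted[win$eligible]),
    max_window = maxrow
  ), class = "fst_scan")
}

#' @export
print.fst_scan <- function(x, ...) {
  cat("Windowed Fst scan (", toupper(x$estimator), " estimator)\n", sep = "")
  cat(sprintf("  SNPs: %d (%d with defined components)\n",
              nrow(x$snps), sum(x$snps$defined)))
  cat(sprintf("  windows: %d eligible of %d\n",
              sum(x$windows$eligible), nrow(x$windows)))
  cat(sprintf("  genome-wide weighted Fst: %.4f (window mean %.4f)\n",
              x$mean_fst_weighted, x$mean_fst_windows))
  cat(sprintf("  max window: %s:%d-%d  Fst = %.4f\n",
              x$max_window$chrom, x$max_window$start, x$max_window$end,
              x$max_window$fst_weighted))
  cat(sprintf("  top windows: %d; candidate regions: %d\n",
              nrow(x$top), nrow(x$candidates$regions)))
  if (!is.null(x$candidates$genes)) {
    cat(sprintf("  candidate genes: %d\n", nrow(x$candidates$genes)))
  }
  invisible(x)
}

#' @export
summary.fst_scan <- function(object, ...) {
  out <- list(
    n_snps = nrow(object$snps),
    n_snps_defined = sum(object$snps$defined),
    n_windows = nrow(object$windows),
    n_windows_eligible = sum(object$windows$eligible),
    mean_fst_weighted = object$mean_fst_weighted,
    mean_fst_windows = object$mean_fst_windows,
    max_window = object$max_window,
    n_top_windows = nrow(object$top),
    n_candidate_regions = nrow(object$candidates$regions),
    n_candidate_genes = if (is.null(object$candidates$genes)) NA_integer_
                        else nrow(object$candidates$genes)
  )
  class(out) <- "summary.fst_scan"
  out
}

#' @export
print.summary.fst_scan <- function(x, ...) {
  cat("Fst scan summary\n")
  for (nm in setdiff(names(x), "max_window")) {
    cat(sprintf("  %-22s %s\n", nm,
                if (is.numeric(x[[nm]]) && !is.integer(x[[nm]]))
                  sprintf("%.4f", x[[nm]]) else format(x[[nm]])))
  }
  cat(sprintf("  max window: %s:%d-%d (Fst %.4f, %d SNPs)\n",
              x$max_window$chrom, x$max_window$start, x$max_window$end,
              x$max_window$fst_weighted, x$max_window$n_snps))
  invisible(x)
}

#' Manhattan-style plot of window Fst
#'
#' @param x an `fst_scan` object.
#' @param ... passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.fst_scan <- function(x, ...) {
  w <- x$windows[x$windows$eligible, , drop = FALSE]
  chroms <- names(x$chrom_lengths)
  offs <- cumsum(c(0, as.numeric(x$chrom_lengths)))[seq_along(chroms)]
  names(offs) <- chroms
  xs <- offs[w$chrom] + (w$start + w$end) / 2
  cols <- (match(w$chrom, chroms) %% 2) + 1
  graphics::plot(xs, w$fst_weighted, pch = 16, cex = 0.5,
                 col = c("grey30", "steelblue")[cols],
                 xlab = "genome position (bp)", ylab = "window Fst", ...)
  cut <- min(x$top$fst_weighted)
  graphics::abline(h = cut, lty = 2, col = "red")
  invisible(x)
}

#' Write the scan outputs as TSV/JSON files
#'
#' Emits `<prefix>.windows.tsv` (per-window statistics),
#' `<prefix>.regions.bed` (candidate regions; BED, 0-based half-open),
#' `<prefix>.candidate_genes.tsv` (when gene annotation was supplied) and
#' `<prefix>.summary.json`.
#'
#' @param scan an `fst_scan` object.
#' @param prefix output path prefix.
#' @return The vector of written paths, invisibly.
#' @export
write_scan <- function(scan, prefix) {
  stopifnot(inherits(scan, "fst_scan"))
  paths <- character(0)
  wp <- paste0(prefix, ".windows.tsv")
  w <- scan$windows[, c("chrom", "start", "end", "n_snps",
                        "fst_weighted", "fst_mean")]
  utils::write.table(format_tsv_num(w), wp, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  paths <- c(paths, wp)
  rp <- paste0(prefix, ".regions.bed")
  r <- scan$candidates$regions
  utils::write.table(
    data.frame(r$chrom, r$start - 1L, r$end,
               sprintf("region%03d", seq_len(nrow(r))),
               format_tsv_num(data.frame(x = r$max_fst))$x, "."),
    rp, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  paths <- c(paths, rp)
  if (!is.null(scan$candidates$genes)) {
    gp <- paste0(prefix, ".candidate_genes.tsv")
    utils::write.table(format_tsv_num(scan$candidates$genes), gp, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    paths <- c(paths, gp)
  }
  sp <- paste0(prefix, ".summary.json")
  s <- summary(scan)
  jsonlite::write_json(
    list(mean_fst_weighted = s$mean_fst_weighted,
         mean_fst_windows = s$mean_fst_windows,
         n_windows_eligible = s$n_windows_eligible,
         n_top_windows = s$n_top_windows,
         n_candidate_regions = s$n_candidate_regions,
         n_candidate_genes = s$n_candidate_genes,
         max_window = as.list(s$max_window[1, c("chrom", "start", "end",
                                                "fst_weighted", "n_snps")])),
    sp, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(c(paths, sp))
}

# Round-trip-stable numeric formatting for deterministic TSV output.
format_tsv_num <- function(d) {
  for (j in seq_along(d)) {
    if (is.double(d[[j]])) d[[j]] <- sprintf("%.10g", d[[j]])
  }
  d
}
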