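#' Sliding-window scan parameters
#'
#' @param window_bp window size (bp).
#' @param step_bp step between window starts (bp); must not exceed
#'   `window_bp`.
#' @param top_fraction fraction of eligible windows ranked as outliers
#'   (default the top 1 percent).
#' @param flank_bp extension added on each side of a top window to form a
#'   candidate region.
#' @param min_snps_per_window minimum SNPs with defined components for a
#'   window to be eligible for ranking.
#' @return A list of class `scan_params`.
#' @export
scan_params <- function(window_bp = 50000, step_bp = 25000,
                        top_fraction = 0.01, flank_bp = 50000,
                        min_snps_per_window = 1) {
  stopifnot(window_bp >= 1, step_bp >= 1, step_bp <= window_bp,
            top_fraction > 0, top_fraction <= 1, flank_bp >= 0,
            min_snps_per_window >= 1)
  structure(list(window_bp = as.integer(window_bp),
                 step_bp = as.integer(step_bp),
                 top_fraction = top_fraction,
                 flank_bp = as.integer(flank_bp),
                 min_snps_per_window = as.integer(min_snps_per_window)),
            class = "scan_params")
}

#' Lay out the sliding-window grid
#'
#' Per chromosome, windows start at `1 + k * step_bp` for `k = 0, 1, ...`
#' while the start does not exceed the chromosome length; each window spans
#' `[start, start + window_bp - 1]`.  Trailing windows may extend past the
#' chromosome end (nominal bounds are not truncated; no SNPs exist there).
#'
#' @param chrom_lengths named numeric vector, chromosome name to length (bp).
#' @param params a [scan_params()].
#' @return Data frame with `chrom`, `start`, `end`.
#' @export
make_windows <- function(chrom_lengths, params = scan_params()) {
  stopifnot(all(chrom_lengths >= 1), !is.null(names(chrom_lengths)))
  res <- lapply(names(chrom_lengths), function(ch) {
    starts <- seq.int(1L, chrom_lengths[[ch]], by = params$step_bp)
    data.frame(chrom = ch, start = starts,
               end = starts + params$window_bp - 1L,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Aggregate per-SNP components over windows
#'
#' Each SNP with defined components contributes its `(a, b, c)` to every
#' window containing its position (overlapping windows double-count by
#' design).  The window statistic is the ratio of averages
#' `fst_weighted = sum(a) / sum(a + b + c)`; the mean of per-SNP theta is
#' kept as a diagnostic.
#'
#' @param components per-SNP components from [snp_fst()].
#' @param windows window grid from [make_windows()].
#' @param params a [scan_params()] (supplies `min_snps_per_window`).
#' @return The `windows` data frame with added columns `n_snps`,
#'   `fst_weighted`, `fst_mean`, `eligible`.
#' @export
window_fst <- function(components, windows, params = scan_params()) {
  comp <- components[components$defined, , drop = FALSE]
  w <- windows
  w$n_snps <- 0L
  w$sum_a <- 0; w$sum_abc <- 0; w$sum_theta <- 0
  if (nrow(comp) > 0) {
    wg <- GenomicRanges::GRanges(w$chrom,
                                 IRanges::IRanges(w$start, w$end))
    sg <- GenomicRanges::GRanges(comp$chrom,
                                 IRanges::IRanges(comp$pos, comp$pos))
    hits <- GenomicRanges::findOverlaps(sg, wg)
    qi <- S4Vectors::queryHits(hits); si <- S4Vectors::subjectHits(hits)
    agg <- rowsum(cbind(1, comp$a[qi], (comp$a + comp$b + comp$c)[qi],
                        comp$theta[qi]), si)
    rows <- as.integer(rownames(agg))
    w$n_snps[rows] <- as.integer(agg[, 1])
    w$sum_a[rows] <- agg[, 2]
    w$sum_abc[rows] <- agg[, 3]
    w$sum_theta[rows] <- agg[, 4]
  }
  w$fst_weighted <- ifelse(w$sum_abc != 0, w$sum_a / w$sum_abc, NA_real_)
  w$fst_mean <- ifelse(w$n_snps > 0, w$sum_theta / w$n_snps, NA_real_)
  w$eligible <- w$n_snps >= params$min_snps_per_window &
    !is.na(w$fst_weighted)
  w$sum_theta <- NULL
  w
}

#' Select the top outlier windows
#'
#' Ranks eligible windows by weighted Fst (descending) and selects the top
#' `ceil(top_fraction * n_eligible)`; any window tied with the cutoff value
#' is also included, so the output may exceed the ceiling.  Order is
#' deterministic: Fst descending, then chromosome, then start.
#'
#' @param stats window statistics from [window_fst()].
#' @param params a [scan_params()].
#' @return The selected rows of `stats`.
#' @export
top_windows <- function(stats, params = scan_params()) {
  el <- stats[stats$eligible, , drop = FALSE]
  if (nrow(el) == 0) stop("contract error: no eligible windows")
  el <- el[order(-el$fst_weighted, el$chrom, el$start), , drop = FALSE]
  k <- ceiling(params$top_fraction * nrow(el))
  cutoff <- el$fst_weighted[k]
  sel <- el[el$fst_weighted >= cutoff, , drop = FALSE]
  rownames(sel) <- NULL
  sel
}

#' Extend and merge top windows into candidate regions
#'
#' Each top window `[s, e]` is extended by `flank_bp` on both sides (clipped
#' to `[1, chrom_length]`); overlapping or book-ended extended intervals on a
#' chromosome are merged.  Per region, the contributing windows and their
#' maximum weighted Fst are retained as provenance.
#'
#' @param top selected windows from [top_windows()].
#' @param params a [scan_params()].
#' @param chrom_lengths named vector of chromosome lengths (bp); used to clip
#'   extensions.
#' @return A list of class `candidate_regions` with element `regions`
#'   (data frame: `chrom`, `start`, `end`, `n_windows`, `max_fst`) and, after
#'   [annotate_candidates()], `genes`.
#' @export
candidate_regions <- function(top, params = scan_params(), chrom_lengths) {
  stopifnot(nrow(top) > 0, !is.null(names(chrom_lengths)))
  ext_start <- pmax(1L, top$start - params$flank_bp)
  clen <- unlist(chrom_lengths)[top$chrom]
  ext_end <- pmin(as.numeric(clen), top$end + params$flank_bp)
  gr <- GenomicRanges::GRanges(top$chrom,
                               IRanges::IRanges(ext_start, ext_end))
  merged <- GenomicRanges::reduce(gr, min.gapwidth = 1L)
  hits <- GenomicRanges::findOverlaps(gr, merged)
  region_of <- S4Vectors::subjectHits(hits)
  max_fst <- as.numeric(tapply(top$fst_weighted, region_of, max))
  n_win <- as.integer(tapply(top$fst_weighted, region_of, length))
  regions <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(merged)),
    start = GenomicRanges::start(merged),
    end = GenomicRanges::end(merged),
    n_windows = n_win, max_fst = max_fst, stringsAsFactors = FALSE)
  regions <- regions[order(regions$chrom, regions$start), , drop = FALSE]
  rownames(regions) <- NULL
  structure(list(regions = regions, windows = top, genes = NULL),
            class = "candidate_regions")
}

#' @export
print.candidate_regions <- function(x, ...) {
  cat("Candidate regions: ", nrow(x$regions), " merged interval(s) from ",
      nrow(x$windows), " top window(s)\n", sep = "")
  if (!is.null(x$genes)) {
    cat("  candidate genes: ", nrow(x$genes), "\n", sep = "")
  }
  invisible(x)
}

#' Annotate candidate regions with overlapping genes
#'
#' A gene is a candidate if its body overlaps any candidate region by at
#' least 1 bp (1-based inclusive coordinates).  Each candidate gene records
#' the best (maximum) `max_fst` among the regions it overlaps; output is
#' sorted by that value, descending.
#'
#' @param regions a `candidate_regions` object.
#' @param genes gene data frame from [read_genes()].
#' @return The `candidate_regions` object with a `genes` data frame added
#'   (`gene_id`, `chrom`, `start`, `end`, `region_chrom`, `region_start`,
#'   `region_end`, `best_fst`).
#' @export
annotate_candidates <- function(regions, genes) {
  stopifnot(inherits(regions, "candidate_regions"))
  if (nrow(genes) == 0) {
    regions$genes <- data.frame(gene_id = character(0), chrom = character(0),
                                start = integer(0), end = integer(0),
                                region_chrom = character(0),
                                region_start = integer(0),
                                region_end = integer(0),
                                best_fst = numeric(0))
    return(regions)
  }
  gg <- GenomicRanges::GRanges(genes$chrom,
                               IRanges::IRanges(genes$start, genes$end))
  rg <- GenomicRanges::GRanges(regions$regions$chrom,
                               IRanges::IRanges(regions$regions$start,
                                                regions$regions$end))
  hits <- GenomicRanges::findOverlaps(gg, rg)
  qi <- S4Vectors::queryHits(hits); si <- S4Vectors::subjectHits(hits)
  if (length(qi) == 0) {
    regions$genes <- data.frame(gene_id = character(0), chrom = character(0),
                                start = integer(0), end = integer(0),
                                region_chrom = character(0),
                                region_start = integer(0),
                                region_end = integer(0),
                                best_fst = numeric(0))
    return(regions)
  }
  # keep, per gene, the overlapping region with the largest window Fst
  fst <- regions$regions$max_fst[si]
  ord <- order(qi, -fst)
  first <- !duplicated(qi[ord])
  qi1 <- qi[ord][first]; si1 <- si[ord][first]
  out <- data.frame(
    gene_id = genes$gene_id[qi1], chrom = genes$chrom[qi1],
    start = genes$start[qi1], end = genes$end[qi1],
    region_chrom = regions$regions$chrom[si1],
    region_start = regions$regions$start[si1],
    region_end = regions$regions$end[si1],
    best_fst = regions$regions$max_fst[si1], stringsAsFactors = FALSE)
  out <- out[order(-out$best_fst, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  regions$genes <- out
  regions
}
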