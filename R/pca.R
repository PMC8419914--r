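#' Genotype principal component analysis
#'
#' PCA of the samples x SNPs dosage matrix with allele-frequency scaling:
#' missing dosages are imputed with the SNP mean; each SNP column is centered
#' by its mean `2 p_hat` and scaled by `sqrt(2 p_hat (1 - p_hat))` where
#' `p_hat` is half the column mean; zero-variance columns are dropped.  The
#' sample covariance of the scaled matrix is decomposed exactly (full SVD).
#' The sign of each component is fixed so that its largest-magnitude score is
#' positive.
#'
#' @param table a [variant_table()] with at least two samples and one
#'   polymorphic SNP.
#' @param k number of components to return (default 20, the usual depth kept
#'   for population-relationship inspection); truncated with a warning when
#'   it exceeds what the data support.
#' @return An object of class `genotype_pca` with `scores` (samples x k),
#'   `varfrac` (explained-variance fraction per returned component over the
#'   total variance of all components), `loadings` (SNPs x k), `k`, and
#'   `n_snps_used`.
#' @export
genotype_pca <- function(table, k = 20) {
  stopifnot(inherits(table, "variant_table"))
  g <- t(table$geno)  # samples x SNPs
  n <- nrow(g)
  if (n < 2) stop("need at least two samples")
  cm <- colMeans(g, na.rm = TRUE)
  nacol <- is.na(cm)  # SNPs with no calls at all
  if (any(is.na(g))) {
    idx <- which(is.na(g), arr.ind = TRUE)
    g[idx] <- cm[idx[, 2]]
  }
  p <- cm / 2
  sdv <- sqrt(2 * p * (1 - p))
  keep <- !nacol & sdv > 0
  if (!any(keep)) stop("contract error: no polymorphic SNPs")
  x <- sweep(g[, keep, drop = FALSE], 2, cm[keep], "-")
  x <- sweep(x, 2, sdv[keep], "/")
  kmax <- min(n - 1, sum(keep))
  if (k > kmax) {
    warning("k truncated from ", k, " to ", kmax)
    k <- kmax
  }
  sv <- svd(x)
  ev <- sv$d^2 / ncol(x)  # eigenvalues of the sample covariance x x^T / m
  total <- sum(ev)
  if (total <= 0) stop("contract error: zero total variance")
  scores <- sv$u %*% diag(sv$d, nrow = length(sv$d))
  loadings <- sv$v
  for (j in seq_len(k)) {
    s <- sign(scores[which.max(abs(scores[, j])), j])
    if (s < 0) { scores[, j] <- -scores[, j]; loadings[, j] <- -loadings[, j] }
  }
  scores <- scores[, seq_len(k), drop = FALSE]
  loadings <- loadings[, seq_len(k), drop = FALSE]
  rownames(scores) <- vt_samples(table)
  colnames(scores) <- paste0("PC", seq_len(k))
  colnames(loadings) <- paste0("PC", seq_len(k))
  structure(list(scores = scores, varfrac = ev[seq_len(k)] / total,
                 eigenvalues = ev, loadings = loadings, k = k,
                 n_snps_used = sum(keep),
                 scaling = "mean-imputed, allele-frequency scaled"),
            class = "genotype_pca")
}

#' @export
print.genotype_pca <- function(x, ...) {
  cat("Genotype PCA: ", nrow(x$scores), " samples, ", x$n_snps_used,
      " SNPs, top ", x$k, " components\n", sep = "")
  vf <- x$varfrac[seq_len(min(3, x$k))]
  cat(sprintf("  variance explained: %s (top %d: %.2f%%)\n",
              paste(sprintf("%.2f%%", 100 * vf), collapse = ", "),
              length(vf), 100 * sum(vf)))
  invisible(x)
}

#' Plot the first two principal components
#'
#' @param x a `genotype_pca` object.
#' @param groups optional [group_assignment()] used to colour samples.
#' @param ... passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.genotype_pca <- function(x, groups = NULL, ...) {
  col <- "grey30"
  if (!is.null(groups)) {
    lab <- unclass(groups)[rownames(x$scores)]
    col <- as.integer(factor(lab)) + 1L
  }
  graphics::plot(x$scores[, 1], x$scores[, 2], col = col, pch = 16,
                 xlab = sprintf("PC1 (%.1f%%)", 100 * x$varfrac[1]),
                 ylab = sprintf("PC2 (%.1f%%)", 100 * x$varfrac[2]), ...)
  graphics::abline(v = 0, lty = 3)
  invisible(x)
}

#' Write PCA scores and variance fractions as TSVs
#'
#' @param pca a `genotype_pca` object.
#' @param prefix output path prefix; writes `<prefix>.scores.tsv` and
#'   `<prefix>.variance.tsv`.
#' @return The written paths, invisibly.
#' @export
write_pca <- function(pca, prefix) {
  sp <- paste0(prefix, ".scores.tsv")
  d <- data.frame(sample = rownames(pca$scores),
                  format_tsv_num(as.data.frame(pca$scores)))
  utils::write.table(d, sp, sep = "\t", quote = FALSE, row.names = FALSE)
  vp <- paste0(prefix, ".variance.tsv")
  utils::write.table(
    data.frame(component = paste0("PC", seq_len(pca$k)),
               varfrac = sprintf("%.10g", pca$varfrac)),
    vp, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(sp, vp))
}
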