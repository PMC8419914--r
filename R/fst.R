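#' Per-SNP Weir-Cockerham variance components
#'
#' Computes, for each SNP and two populations, the Weir & Cockerham (1984)
#' variance components: `a` (between populations), `b` (between individuals
#' within populations) and `c` (within individuals), from the non-missing
#' diploid genotypes.  The per-SNP estimator is `theta = a / (a + b + c)`,
#' undefined when `a + b + c = 0` (monomorphic sites) or when a population
#' has no non-missing call.
#'
#' With group sizes `n_i`, alternate-allele frequencies `p_i` and observed
#' heterozygote proportions `h_i` (r = 2 populations):
#' \deqn{\bar n = \sum n_i / r, \quad
#'       n_c = (r\bar n - \sum n_i^2/(r\bar n))/(r-1)}
#' \deqn{\bar p = \sum n_i p_i/(r\bar n), \quad
#'       s^2 = \sum n_i (p_i-\bar p)^2/((r-1)\bar n), \quad
#'       \bar h = \sum n_i h_i/(r\bar n)}
#' \deqn{a = \frac{\bar n}{n_c}\left[s^2 - \frac{1}{\bar n - 1}
#'       \left(\bar p(1-\bar p) - \frac{r-1}{r}s^2 -
#'       \frac{\bar h}{4}\right)\right]}
#' \deqn{b = \frac{\bar n}{\bar n - 1}\left[\bar p(1-\bar p) -
#'       \frac{r-1}{r}s^2 - \frac{2\bar n - 1}{4\bar n}\bar h\right],
#'       \qquad c = \bar h / 2}
#'
#' @param table a [variant_table()].
#' @param groups a [group_assignment()] with exactly two groups covering all
#'   samples of the table.
#' @return A data frame with columns `chrom`, `pos`, `a`, `b`, `c`, `theta`
#'   and logical `defined`.  Undefined components are `NA` with
#'   `defined = FALSE` (never an error).
#' @references Weir, B.S. & Cockerham, C.C. (1984) Estimating F-statistics
#'   for the analysis of population structure. Evolution 38:1358-1370.
#' @export
snp_fst <- function(table, groups) {
  stopifnot(inherits(table, "variant_table"))
  lab <- align_groups(table, groups, require_two = TRUE)
  gl <- sort(unique(lab))
  g <- table$geno
  comp <- wc_components(g[, lab == gl[1], drop = FALSE],
                        g[, lab == gl[2], drop = FALSE])
  data.frame(chrom = table$chrom, pos = table$pos,
             a = comp$a, b = comp$b, c = comp$c, theta = comp$theta,
             defined = comp$defined, stringsAsFactors = FALSE)
}

# Vectorized two-population Weir-Cockerham components from dosage matrices
# (rows = SNPs).  r = 2 throughout.
wc_components <- function(g1, g2) {
  n1 <- rowSums(!is.na(g1)); n2 <- rowSums(!is.na(g2))
  ok <- n1 >= 1 & n2 >= 1
  p1 <- rowSums(g1, na.rm = TRUE) / (2 * n1)
  p2 <- rowSums(g2, na.rm = TRUE) / (2 * n2)
  h1 <- rowSums(g1 == 1L, na.rm = TRUE) / n1
  h2 <- rowSums(g2 == 1L, na.rm = TRUE) / n2

  r <- 2
  nbar <- (n1 + n2) / r
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)

  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2

  a[!ok] <- NA_real_; b[!ok] <- NA_real_; cc[!ok] <- NA_real_
  denom <- a + b + cc
  theta <- ifelse(ok & denom != 0, a / denom, NA_real_)
  defined <- ok & !is.na(denom) & denom != 0
  list(a = a, b = b, c = cc, theta = theta, defined = defined)
}

#' Per-SNP Hudson Fst (cross-check estimator)
#'
#' Hudson's two-population estimator
#' `1 - Hw / Hb` with within-population heterozygosity
#' `Hw = (H1 + H2)/2`, `H_i = 2 n_i p_i (1 - p_i) / (n_i - 1)` on allele
#' counts, and between-population heterozygosity
#' `Hb = p1 (1 - p2) + p2 (1 - p1)`.  Provided as an independent cross-check
#' of the Weir-Cockerham scan, not as its default.
#'
#' @inheritParams snp_fst
#' @return A data frame with `chrom`, `pos`, `num`, `den`, `fst`, `defined`;
#'   window-level aggregation uses the ratio of summed numerators and
#'   denominators.
#' @export
snp_fst_hudson <- function(table, groups) {
  stopifnot(inherits(table, "variant_table"))
  lab <- align_groups(table, groups, require_two = TRUE)
  gl <- sort(unique(lab))
  g1 <- table$geno[, lab == gl[1], drop = FALSE]
  g2 <- table$geno[, lab == gl[2], drop = FALSE]
  m1 <- 2 * rowSums(!is.na(g1)); m2 <- 2 * rowSums(!is.na(g2))  # allele counts
  ok <- m1 >= 2 & m2 >= 2
  p1 <- rowSums(g1, na.rm = TRUE) / m1
  p2 <- rowSums(g2, na.rm = TRUE) / m2
  Hw <- (m1 * p1 * (1 - p1) / (m1 - 1) + m2 * p2 * (1 - p2) / (m2 - 1))
  Hb <- p1 * (1 - p2) + p2 * (1 - p1)
  num <- Hb - Hw
  defined <- ok & Hb > 0
  data.frame(chrom = table$chrom, pos = table$pos,
             num = ifelse(ok, num, NA_real_),
             den = ifelse(ok, Hb, NA_real_),
             fst = ifelse(defined, num / Hb, NA_real_),
             defined = defined, stringsAsFactors = FALSE)
}
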