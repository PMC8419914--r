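#' Construct a variant table
#'
#' The central substrate of the pipeline: biallelic SNP records with QUAL,
#' numeric INFO annotations and per-sample alternate-allele dosages.
#' Coordinates are 1-based throughout the package.
#'
#' @param chrom character vector of chromosome names.
#' @param pos integer vector of 1-based positions.
#' @param ref,alt single-nucleotide alleles (A/C/G/T), `ref != alt` per record.
#' @param qual numeric phred-scaled variant quality (VCF QUAL); may be `NA`.
#' @param info data frame of numeric INFO annotations, one row per record.
#'   Recognised keys: `QD`, `FS`, `MQ`, `MQRankSum`, `ReadPosRankSum`; any may
#'   be absent or `NA`.
#' @param geno integer matrix of alternate-allele dosages in `{0, 1, 2, NA}`,
#'   one row per record, one column per sample (column names are sample ids).
#'
#' @return An object of class `variant_table`.
#' @export
variant_table <- function(chrom, pos, ref, alt, qual, info, geno) {
  n <- length(chrom)
  pos <- as.integer(pos)
  stopifnot(
    length(pos) == n, length(ref) == n, length(alt) == n, length(qual) == n,
    is.matrix(geno), nrow(geno) == n, is.data.frame(info), nrow(info) == n
  )
  if (n > 0) {
    if (any(pos < 1L)) stop("positions must be >= 1")
    bad <- !(ref %in% c("A", "C", "G", "T")) | !(alt %in% c("A", "C", "G", "T")) |
      ref == alt
    if (any(bad)) {
      stop("records must be biallelic SNPs (single-base REF != ALT): record ",
           which(bad)[1])
    }
    o <- order(chrom, pos)
    if (!identical(o, seq_len(n))) {
      chrom <- chrom[o]; pos <- pos[o]; ref <- ref[o]; alt <- alt[o]
      qual <- qual[o]; info <- info[o, , drop = FALSE]
      geno <- geno[o, , drop = FALSE]
      rownames(info) <- NULL
    }
    if (anyDuplicated(paste(chrom, pos))) {
      stop("duplicate (chrom, pos) records are not allowed")
    }
    gv <- geno[!is.na(geno)]
    if (length(gv) && !all(gv %in% 0:2)) stop("dosages must be 0, 1, 2 or NA")
  }
  if (is.null(colnames(geno))) {
    colnames(geno) <- paste0("S", seq_len(ncol(geno)))
  }
  structure(
    list(chrom = as.character(chrom), pos = pos, ref = as.character(ref),
         alt = as.character(alt), qual = as.numeric(qual), info = info,
         geno = geno),
    class = "variant_table"
  )
}

#' @export
print.variant_table <- function(x, ...) {
  cat("Variant table: ", n_variants(x), " biallelic SNPs, ",
      ncol(x$geno), " samples\n", sep = "")
  if (n_variants(x) > 0) {
    tab <- table(x$chrom)
    cat("  chromosomes: ",
        paste(names(tab), " (", as.integer(tab), ")", sep = "", collapse = ", "),
        "\n", sep = "")
    miss <- mean(is.na(x$geno))
    cat(sprintf("  missing genotype fraction: %.4f\n", miss))
  }
  invisible(x)
}

#' Number of variant records
#' @param x a `variant_table`.
#' @return Integer record count.
#' @export
n_variants <- function(x) length(x$pos)

#' Sample identifiers of a variant table
#' @param x a `variant_table`.
#' @return Character vector of sample ids.
#' @export
vt_samples <- function(x) colnames(x$geno)

#' Subset a variant table by record index
#' @param x a `variant_table`.
#' @param i logical or integer index over records.
#' @return A `variant_table` with the selected records.
#' @export
vt_subset <- function(x, i) {
  variant_table(x$chrom[i], x$pos[i], x$ref[i], x$alt[i], x$qual[i],
                x$info[i, , drop = FALSE], x$geno[i, , drop = FALSE])
}

#' Construct a sample-to-group assignment
#'
#' @param sample character vector of sample ids.
#' @param group character vector of group labels (two groups expected for Fst,
#'   e.g. wild / domestic).
#' @return A named character vector (names = samples, values = group labels)
#'   of class `group_assignment`.
#' @export
group_assignment <- function(sample, group) {
  stopifnot(length(sample) == length(group), !anyDuplicated(sample))
  g <- as.character(group)
  names(g) <- as.character(sample)
  if (any(!nzchar(g)) || any(is.na(g))) stop("empty group labels")
  class(g) <- "group_assignment"
  g
}

#' @export
print.group_assignment <- function(x, ...) {
  tab <- table(unclass(x))
  cat("Group assignment: ", length(x), " samples in ", length(tab),
      " groups (", paste(names(tab), as.integer(tab), sep = ": ",
                         collapse = ", "), ")\n", sep = "")
  invisible(x)
}

# Check that a group assignment covers the table's samples and (optionally)
# has exactly two groups; returns the per-sample label vector aligned to the
# table's column order.
align_groups <- function(table, groups, require_two = TRUE) {
  s <- vt_samples(table)
  missing <- setdiff(s, names(groups))
  if (length(missing)) {
    stop("samples absent from group assignment: ",
         paste(utils::head(missing, 5), collapse = ", "))
  }
  lab <- unclass(groups)[s]
  if (require_two && length(unique(lab)) != 2L) {
    stop("exactly two groups are required, got ", length(unique(lab)))
  }
  lab
}

#' Construct a gene-level count matrix
#'
#' @param counts integer matrix, genes x samples, with gene ids as row names.
#' @param gene_length numeric vector of gene lengths in bp (>= 1), one per gene.
#' @param condition named character vector mapping sample id to condition
#'   label (two conditions for the differential-expression stage).
#' @return An object of class `count_matrix`.
#' @export
count_matrix <- function(counts, gene_length, condition) {
  stopifnot(is.matrix(counts), length(gene_length) == nrow(counts))
  if (is.null(rownames(counts))) stop("counts must carry gene ids as row names")
  if (anyDuplicated(rownames(counts))) stop("duplicate gene ids")
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be non-negative integers")
  }
  if (any(gene_length < 1)) stop("gene lengths must be >= 1 bp")
  missing <- setdiff(colnames(counts), names(condition))
  if (length(missing)) {
    stop("samples present in counts but absent from condition map: ",
         paste(missing, collapse = ", "))
  }
  cond <- as.character(unclass(condition)[colnames(counts)])
  structure(
    list(counts = counts, gene_length = as.numeric(gene_length),
         condition = stats::setNames(cond, colnames(counts))),
    class = "count_matrix"
  )
}

#' @export
print.count_matrix <- function(x, ...) {
  tab <- table(x$condition)
  cat("Count matrix: ", nrow(x$counts), " genes x ", ncol(x$counts),
      " samples (", paste(names(tab), as.integer(tab), sep = ": ",
                          collapse = ", "), ")\n", sep = "")
  invisible(x)
}
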