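#' Read a VCF into a variant table
#'
#' Reads a (optionally gzipped) VCF v4.2-like file, keeping only biallelic SNP
#' records.  Multiallelic and indel records are skipped and tallied with a
#' message.  Diploid genotypes are parsed to alternate-allele dosage; `/` and
#' `|` separators are equivalent and `./.` or `.` become missing.
#'
#' @param path path to a VCF file (plain text or `.gz`).
#' @param info_keys INFO annotations to extract as numeric columns.
#' @return A [variant_table()]; the number of skipped non-SNP records is
#'   attached as attribute `skipped`.
#' @export
read_vcf <- function(path,
                     info_keys = c("QD", "FS", "MQ", "MQRankSum",
                                   "ReadPosRankSum")) {
  if (!file.exists(path)) stop("no such file: ", path)
  header_ok <- local({
    con <- if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
    on.exit(close(con))
    ok <- FALSE
    repeat {
      ln <- readLines(con, n = 1L)
      if (!length(ln)) break
      if (startsWith(ln, "#CHROM")) { ok <- TRUE; break }
      if (!startsWith(ln, "##")) break
    }
    ok
  })
  if (!header_ok) stop("format error: no #CHROM header line in ", path)

  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- v@fix
  if (nrow(fix) == 0) {
    geno <- matrix(integer(0), 0, max(0L, ncol(v@gt) - 1L))
    if (ncol(v@gt) > 1) colnames(geno) <- colnames(v@gt)[-1]
    info <- as.data.frame(stats::setNames(
      rep(list(numeric(0)), length(info_keys)), info_keys))
    out <- variant_table(character(0), integer(0), character(0), character(0),
                         numeric(0), info, geno)
    attr(out, "skipped") <- 0L
    return(out)
  }
  nt <- c("A", "C", "G", "T")
  is_snp <- fix[, "REF"] %in% nt & fix[, "ALT"] %in% nt &
    fix[, "REF"] != fix[, "ALT"]
  is_snp[is.na(is_snp)] <- FALSE
  skipped <- sum(!is_snp)
  if (skipped > 0) {
    message("read_vcf: skipped ", skipped, " non-biallelic-SNP record(s)")
  }
  fix <- fix[is_snp, , drop = FALSE]
  gt <- v@gt[is_snp, , drop = FALSE]

  fmt <- gt[, 1]
  if (nrow(gt) > 0 && !all(startsWith(fmt, "GT"))) {
    bad <- which(!startsWith(fmt, "GT"))[1]
    stop("format error: GT is not the first FORMAT key at record ",
         fix[bad, "CHROM"], ":", fix[bad, "POS"])
  }
  gmat <- gt[, -1, drop = FALSE]
  gall <- sub(":.*$", "", gmat)
  dose <- matrix(NA_integer_, nrow(gall), ncol(gall))
  dose[gall %in% c("0/0", "0|0")] <- 0L
  dose[gall %in% c("0/1", "0|1", "1/0", "1|0")] <- 1L
  dose[gall %in% c("1/1", "1|1")] <- 2L
  colnames(dose) <- colnames(gmat)

  info <- parse_info(fix[, "INFO"], info_keys)
  qual <- suppressWarnings(as.numeric(fix[, "QUAL"]))
  out <- variant_table(fix[, "CHROM"], as.integer(fix[, "POS"]),
                       fix[, "REF"], fix[, "ALT"], qual, info, dose)
  attr(out, "skipped") <- as.integer(skipped)
  out
}

# Parse selected key=value INFO annotations into a numeric data frame.
parse_info <- function(info_str, keys) {
  info_str[is.na(info_str)] <- ""
  out <- lapply(keys, function(k) {
    mm <- regexpr(paste0("(?:^|;)", k, "=([^;]*)"), info_str, perl = TRUE)
    val <- rep(NA_real_, length(info_str))
    hit <- mm > 0
    txt <- regmatches(info_str, mm)
    val[hit] <- suppressWarnings(as.numeric(
      sub(paste0("^;?", k, "="), "", txt)))
    val
  })
  as.data.frame(stats::setNames(out, keys))
}

#' Write a variant table as VCF
#'
#' Emits a minimal VCF v4.2: declared INFO keys, GT-only FORMAT, no contig
#' lines.  Missing dosages become `./.`; output is deterministic, so identical
#' tables give byte-identical files.
#'
#' @param table a [variant_table()].
#' @param path output path; a `.gz` suffix gzips the output.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(table, path) {
  stopifnot(inherits(table, "variant_table"))
  keys <- colnames(table$info)
  hdr <- c(
    "##fileformat=VCFv4.2",
    sprintf('##INFO=<ID=%s,Number=1,Type=Float,Description="%s">', keys, keys),
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", vt_samples(table)), collapse = "\t")
  )
  n <- n_variants(table)
  lines <- hdr
  if (n > 0) {
    info_txt <- apply(table$info, 1, function(r) {
      keep <- !is.na(r)
      if (!any(keep)) return(".")
      paste(paste0(keys[keep], "=", format_num(r[keep])), collapse = ";")
    })
    gt_txt <- matrix(c("0/0", "0/1", "1/1")[table$geno + 1L],
                     nrow = n, ncol = ncol(table$geno))
    gt_txt[is.na(gt_txt)] <- "./."
    body <- paste(table$chrom, table$pos, ".", table$ref, table$alt,
                  ifelse(is.na(table$qual), ".", format_num(table$qual)),
                  "PASS", info_txt, "GT",
                  apply(gt_txt, 1, paste, collapse = "\t"),
                  sep = "\t")
    lines <- c(hdr, body)
  }
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

# Numeric formatting for VCF fields: plain decimal, no trailing noise.
format_num <- function(x) {
  out <- formatC(x, format = "fg", digits = 15)
  sub("\\.?0+$", "", trimws(out))
}

#' Read gene models from BED6 or GFF3
#'
#' Auto-detects the format by extension: `.bed` is 0-based half-open, `.gff`,
#' `.gff3` or `.gtf` is 1-based inclusive (only `gene`-type features with an
#' `ID` attribute are kept).  All coordinates are normalized to 1-based
#' inclusive.
#'
#' @param path input file.
#' @return A data frame with columns `gene_id`, `chrom`, `start`, `end`,
#'   `strand`, sorted by (chrom, start).
#' @export
read_genes <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  ext <- tolower(tools::file_ext(sub("\\.gz$", "", path)))
  if (ext == "bed") {
    d <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE)
    if (ncol(d) < 4) stop("format error: BED needs >= 4 columns")
    strand <- if (ncol(d) >= 6) d[[6]] else "."
    genes <- data.frame(gene_id = as.character(d[[4]]), chrom = d[[1]],
                        start = as.integer(d[[2]]) + 1L,
                        end = as.integer(d[[3]]), strand = strand,
                        stringsAsFactors = FALSE)
  } else if (ext %in% c("gff", "gff3", "gtf")) {
    d <- utils::read.table(path, sep = "\t", header = FALSE, comment.char = "#",
                           quote = "", stringsAsFactors = FALSE)
    d <- d[d[[3]] == "gene", , drop = FALSE]
    ids <- sub("^.*ID=([^;]+).*$", "\\1", d[[9]])
    genes <- data.frame(gene_id = ids, chrom = d[[1]],
                        start = as.integer(d[[4]]), end = as.integer(d[[5]]),
                        strand = d[[7]], stringsAsFactors = FALSE)
  } else {
    stop("unrecognized gene annotation extension: .", ext)
  }
  bad <- which(genes$start > genes$end)
  if (length(bad)) {
    stop("format error: start > end after normalization at line ", bad[1])
  }
  if (anyDuplicated(genes$gene_id)) {
    stop("duplicate gene_id: ",
         genes$gene_id[duplicated(genes$gene_id)][1])
  }
  genes <- genes[order(genes$chrom, genes$start), , drop = FALSE]
  rownames(genes) <- NULL
  genes
}

#' Write gene models as BED6
#'
#' The inverse of [read_genes()]: 1-based inclusive spans become 0-based
#' half-open BED lines.
#'
#' @param genes data frame as returned by [read_genes()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_genes_bed <- function(genes, path) {
  d <- data.frame(genes$chrom, genes$start - 1L, genes$end, genes$gene_id,
                  ".", genes$strand)
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Read a gene-level count matrix
#'
#' Expects a TSV with header `gene_id`, `length`, then one column per sample.
#'
#' @param counts_path counts TSV.
#' @param conditions_path two-column TSV (sample, condition) with header.
#' @return A [count_matrix()].
#' @export
read_counts <- function(counts_path, conditions_path) {
  d <- utils::read.table(counts_path, sep = "\t", header = TRUE,
                         stringsAsFactors = FALSE, check.names = FALSE)
  if (!all(c("gene_id", "length") %in% colnames(d))) {
    stop("format error: counts TSV needs gene_id and length columns")
  }
  samp_cols <- setdiff(colnames(d), c("gene_id", "length"))
  m <- as.matrix(d[, samp_cols, drop = FALSE])
  if (any(is.na(m)) || any(m != round(m)) || any(m < 0)) {
    stop("format error: counts must be non-negative integers")
  }
  storage.mode(m) <- "integer"
  rownames(m) <- d$gene_id
  cond <- read_groups(conditions_path)
  count_matrix(m, d$length, cond)
}

#' Read a sample-to-group (or sample-to-condition) assignment
#'
#' @param path two-column TSV `sample<TAB>group`, with or without a header row.
#' @return A [group_assignment()].
#' @export
read_groups <- function(path) {
  d <- utils::read.table(path, sep = "\t", header = FALSE,
                         stringsAsFactors = FALSE)
  if (ncol(d) < 2) stop("format error: expected two tab-separated columns")
  if (identical(tolower(d[1, 1]), "sample")) d <- d[-1, , drop = FALSE]
  group_assignment(d[[1]], d[[2]])
}

#' Write a group assignment as a two-column TSV
#' @param groups a [group_assignment()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_groups <- function(groups, path) {
  utils::write.table(data.frame(sample = names(groups),
                                group = unclass(groups)),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read gene sets in GMT format
#'
#' @param path GMT file: per line, set name, description, then member ids,
#'   tab-separated.
#' @return Named list of character vectors of gene ids.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(lines, function(ln) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(f) < 3) stop("format error: GMT line with < 3 fields")
    unique(f[-(1:2)])
  })
  names(sets) <- vapply(lines, function(ln)
    strsplit(ln, "\t", fixed = TRUE)[[1]][1], character(1))
  if (anyDuplicated(names(sets))) stop("duplicate gene-set names in GMT")
  sets
}
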