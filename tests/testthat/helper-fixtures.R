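# Small in-code fixtures shared across test files.

# Build a variant table from a dosage matrix (SNPs x samples).
make_vt <- function(geno, chrom = NULL, pos = NULL, qual = NULL,
                    info = NULL) {
  n <- nrow(geno)
  if (is.null(chrom)) chrom <- rep("chr1", n)
  if (is.null(pos)) pos <- seq_len(n) * 100L
  if (is.null(qual)) qual <- rep(100, n)
  if (is.null(info)) {
    keys <- c("QD", "FS", "MQ", "MQRankSum", "ReadPosRankSum")
    info <- as.data.frame(stats::setNames(
      rep(list(rep(NA_real_, n)), length(keys)), keys))
  }
  if (is.null(colnames(geno))) {
    colnames(geno) <- sprintf("s%02d", seq_len(ncol(geno)))
  }
  variant_table(chrom, pos, rep("A", n), rep("G", n), qual, info, geno)
}

# Two-group assignment over the columns of a dosage matrix.
make_groups <- function(geno, n1) {
  group_assignment(colnames(geno),
                   rep(c("wild", "domestic"),
                       c(n1, ncol(geno) - n1)))
}

# Expand genotype-class counts (n_homref, n_het, n_homalt) to a dosage vector.
dosages_from_counts <- function(counts3) {
  rep(c(0L, 1L, 2L), counts3)
}

# Write a small hand-rolled VCF text file; returns the path.
write_toy_vcf <- function(lines, path = tempfile(fileext = ".vcf")) {
  hdr <- c(
    "##fileformat=VCFv4.2",
    '##INFO=<ID=QD,Number=1,Type=Float,Description="QD">',
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\ts1\ts2")
  writeLines(c(hdr, lines), path)
  path
}

# Build a complete small synthetic study on disk: genotypes with one planted
# sweep, genes (one inside the sweep), and counts where that gene carries a
# planted fold change.  Used by the pipeline and end-to-end tests.
build_study <- function(dir, seed = 1) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sr <- data.frame(chrom = "chr1", start = 1.2e6, end = 1.3e6,
                   F_sweep = 0.3)
  sim <- simulate_genotypes(sweep_sim_config(
    n_wild = 12, n_dom = 12, chrom_length = 3e6, snp_density = 1 / 600,
    F_background = 0.05, sweep_regions = sr, seed = seed))
  ann <- simulate_info_annotations(sim$table,
                                   fail_spec = c(QD = 0.05, FS = 0.05),
                                   seed = seed + 1)
  vcf <- file.path(dir, "in.vcf")
  write_vcf(ann$table, vcf)
  gpath <- file.path(dir, "groups.tsv")
  write_groups(sim$groups, gpath)

  genes <- simulate_gene_annotation(40, c(chr1 = 3e6), seed = seed + 2)
  # force one gene body inside the sweep
  genes$start[1] <- 1240001L; genes$end[1] <- 1250000L
  genes <- genes[order(genes$chrom, genes$start), ]
  sweep_gene <- "gene0001"
  bed <- file.path(dir, "genes.bed")
  write_genes_bed(genes, bed)

  cs <- simulate_counts(count_sim_config(n_genes = 40, n_per_group = 7,
                                         frac_de = 0, dispersion = 0.05,
                                         seed = seed + 3))
  cm <- cs$counts
  rownames(cm$counts) <- genes$gene_id
  # plant a strong fold change on the sweep gene
  case <- cm$condition == "case"
  cm$counts[sweep_gene, case] <-
    as.integer(round(cm$counts[sweep_gene, case] * 6 + 30))
  ct <- file.path(dir, "counts.tsv")
  utils::write.table(
    data.frame(gene_id = rownames(cm$counts),
               length = cm$gene_length, cm$counts, check.names = FALSE),
    ct, sep = "\t", quote = FALSE, row.names = FALSE)
  cd <- file.path(dir, "cond.tsv")
  utils::write.table(data.frame(sample = names(cm$condition),
                                condition = unname(cm$condition)),
                     cd, sep = "\t", quote = FALSE, row.names = FALSE)
  list(vcf = vcf, groups = gpath, genes = bed, counts = ct, cond = cd,
       sweep_gene = sweep_gene, sweep = sr)
}
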