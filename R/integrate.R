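#' Intersect sweep candidate genes with per-tissue DEG lists
#'
#' For each tissue, keeps the genes that are both sweep candidates and DEGs,
#' carrying the expression direction and the best window Fst of the
#' overlapping candidate region.
#'
#' @param candidates a `candidate_regions` object with gene annotation (see
#'   [annotate_candidates()]), or a data frame with at least `gene_id` and
#'   `best_fst`.
#' @param deg_tables named list (tissue -> `nb_de` fit or DEG data frame with
#'   `gene_id`, `log2fc`, `padj`, `deg`).
#' @return Data frame with one row per (gene, tissue): `gene_id`, `tissue`,
#'   `direction`, `log2fc`, `padj`, `best_fst`, `region_chrom`,
#'   `region_start`, `region_end`; sorted by tissue then `best_fst`
#'   descending.
#' @export
intersect_candidates <- function(candidates, deg_tables) {
  cg <- if (inherits(candidates, "candidate_regions")) {
    if (is.null(candidates$genes)) {
      stop("candidate regions carry no gene annotation; ",
           "run annotate_candidates() first")
    }
    candidates$genes
  } else candidates
  stopifnot(is.data.frame(cg), "gene_id" %in% colnames(cg))
  if (!all(c("region_chrom", "region_start", "region_end") %in% colnames(cg))) {
    cg$region_chrom <- NA_character_
    cg$region_start <- NA_integer_
    cg$region_end <- NA_integer_
  }
  stopifnot(is.list(deg_tables), length(names(deg_tables)) ==
              length(deg_tables))
  rows <- lapply(names(deg_tables), function(tissue) {
    d <- deg_tables[[tissue]]
    if (inherits(d, "nb_de")) d <- d$results
    full_ids <- d$gene_id
    if ("deg" %in% colnames(d)) d <- d[d$deg, , drop = FALSE]
    # namespace check against the tissue's full tested gene list, not just
    # its called DEGs: disjoint DEG sets are fine, disjoint namespaces are
    # suspicious
    if (nrow(cg) > 0 && length(full_ids) > 0 &&
        !any(full_ids %in% cg$gene_id)) {
      warning("no shared gene ids between candidates and the ", tissue,
              " expression table; e.g. candidates: ",
              paste(utils::head(cg$gene_id, 3), collapse = ", "),
              " vs tested: ",
              paste(utils::head(full_ids, 3), collapse = ", "))
    }
    shared <- intersect(cg$gene_id, d$gene_id)
    if (length(shared) == 0) return(NULL)
    ci <- match(shared, cg$gene_id)
    di <- match(shared, d$gene_id)
    data.frame(gene_id = shared, tissue = tissue,
               direction = ifelse(d$log2fc[di] > 0, "up", "down"),
               log2fc = d$log2fc[di], padj = d$padj[di],
               best_fst = cg$best_fst[ci],
               region_chrom = cg$region_chrom[ci],
               region_start = cg$region_start[ci],
               region_end = cg$region_end[ci],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(gene_id = character(0), tissue = character(0),
                      direction = character(0), log2fc = numeric(0),
                      padj = numeric(0), best_fst = numeric(0),
                      region_chrom = character(0),
                      region_start = integer(0), region_end = integer(0))
  } else {
    out <- out[order(out$tissue, -out$best_fst, out$gene_id), , drop = FALSE]
    rownames(out) <- NULL
  }
  out
}

#' Hypergeometric over-representation test
#'
#' Database-free gene-set over-representation: for each set, the one-sided
#' tail `P(X >= k)` with `X ~ Hypergeometric(N, K, n)` (`N` universe size,
#' `K` set size within the universe, `n` query size, `k` overlap), followed
#' by BH adjustment across sets.  Sets with no member in the universe are
#' skipped.
#'
#' @param query character vector of gene ids (must lie in `universe`).
#' @param sets named list of gene-id vectors (e.g. from [read_gmt()]).
#' @param universe character vector of gene ids defining the background
#'   (default: the union of all set members and the query is NOT assumed —
#'   supply the annotation's full gene list).
#' @return Data frame: `set`, `k`, `K`, `n`, `N`, `pvalue`, `padj`,
#'   `overlap` (comma-joined ids), sorted by p-value.
#' @export
hypergeom_enrich <- function(query, sets, universe) {
  query <- unique(query); universe <- unique(universe)
  bad <- setdiff(query, universe)
  if (length(bad)) {
    stop("contract error: query genes outside universe: ",
         paste(utils::head(bad, 5), collapse = ", "))
  }
  N <- length(universe); n <- length(query)
  rows <- lapply(names(sets), function(nm) {
    s <- intersect(unique(sets[[nm]]), universe)
    K <- length(s)
    if (K == 0) return(NULL)
    ov <- intersect(query, s)
    k <- length(ov)
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(set = nm, k = k, K = K, n = n, N = N, pvalue = p,
               overlap = paste(sort(ov), collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    return(data.frame(set = character(0), k = integer(0), K = integer(0),
                      n = integer(0), N = integer(0), pvalue = numeric(0),
                      padj = numeric(0), overlap = character(0)))
  }
  out$padj <- stats::p.adjust(out$pvalue, method = "BH")
  out <- out[order(out$pvalue, out$set),
             c("set", "k", "K", "n", "N", "pvalue", "padj", "overlap")]
  rownames(out) <- NULL
  out
}
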