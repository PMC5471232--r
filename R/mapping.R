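# SNP-to-gene mapping and pathway assembly: merge isoform rows into one
# interval per gene, extend by a flank on both sides, assign SNPs falling in
# the flanked window, filter pathways by mappable-gene count, and collect
# each pathway's SNP set.

#' Merge isoform rows into single gene models
#'
#' Overlapping isoforms of a gene (intervals sharing at least one base pair)
#' are unioned into a single full-length span. When a gene's isoforms form
#' several disjoint clusters, the cluster whose flanked window contains the
#' most significant SNP (lowest P-value) is kept; if no cluster window holds
#' any SNP, the longest cluster is kept (ties broken leftmost). A symbol
#' annotated on two chromosomes is treated as disjoint clusters of one gene,
#' so the same rule picks a single model.
#'
#' Strand is ignored when extending: the 5' and 3' extensions are equal, so
#' the window is symmetric around the merged span regardless of orientation.
#'
#' @param isoforms Tibble of isoform rows (`gene_symbol`, `chrom`, `strand`,
#'   `tx_start`, `tx_end`), as from [read_gene_table()].
#' @param snps Summary-statistics tibble, used only to arbitrate between
#'   disjoint isoform clusters; may be `NULL`, in which case the longest
#'   cluster always wins.
#' @param flank Flanking distance in base pairs added upstream of the start
#'   and downstream of the end (default 15000, the distance within which the
#'   large majority of eQTL variants fall). The window start is floored at 1.
#' @return A tibble with one row per gene: `gene_symbol`, `chrom`, `start`,
#'   `end`, `window_start`, `window_end`.
#' @export
merge_isoforms <- function(isoforms, snps = NULL, flank = 15000L) {
  stopifnot(flank >= 0)
  by_gene <- split(seq_len(nrow(isoforms)), isoforms$gene_symbol)
  rows <- lapply(names(by_gene), function(sym) {
    iso <- isoforms[by_gene[[sym]], ]
    clusters <- merge_intervals(iso$chrom, iso$tx_start, iso$tx_end)
    pick <- pick_cluster(clusters, snps, flank)
    tibble::tibble(gene_symbol = sym, chrom = pick$chrom,
                   start = pick$start, end = pick$end)
  })
  out <- do.call(rbind, rows)
  out$window_start <- pmax(out$start - as.integer(flank), 1L)
  out$window_end <- out$end + as.integer(flank)
  out[order(out$gene_symbol), ]
}

# Union intervals sharing >= 1 bp on the same chromosome. Abutting intervals
# (end + 1 == next start) stay separate. Returns a data.frame of clusters.
merge_intervals <- function(chrom, start, end) {
  out <- list()
  for (ch in unique(chrom)) {
    i <- chrom == ch
    s <- start[i]; e <- end[i]
    o <- order(s, e)
    s <- s[o]; e <- e[o]
    cs <- s[1]; ce <- e[1]
    for (k in seq_along(s)[-1]) {
      if (s[k] <= ce) {  # overlap by >= 1 bp
        ce <- max(ce, e[k])
      } else {
        out[[length(out) + 1L]] <- list(chrom = ch, start = cs, end = ce)
        cs <- s[k]; ce <- e[k]
      }
    }
    out[[length(out) + 1L]] <- list(chrom = ch, start = cs, end = ce)
  }
  data.frame(chrom = vapply(out, `[[`, "", "chrom"),
             start = vapply(out, function(x) as.integer(x$start), 0L),
             end = vapply(out, function(x) as.integer(x$end), 0L),
             stringsAsFactors = FALSE)
}

# Among disjoint clusters of one gene, keep the one whose flanked window
# contains the lowest-P SNP; fall back to the longest (then leftmost).
pick_cluster <- function(clusters, snps, flank) {
  if (nrow(clusters) == 1L) return(clusters[1, ])
  best_p <- rep(Inf, nrow(clusters))
  if (!is.null(snps) && nrow(snps)) {
    for (k in seq_len(nrow(clusters))) {
      ws <- max(clusters$start[k] - flank, 1)
      we <- clusters$end[k] + flank
      inwin <- snps$chrom == clusters$chrom[k] &
        snps$pos >= ws & snps$pos <= we
      if (any(inwin)) best_p[k] <- min(snps$pvalue[inwin])
    }
  }
  if (any(is.finite(best_p))) {
    cand <- which(best_p == min(best_p))
  } else {
    cand <- seq_len(nrow(clusters))
  }
  # tie-break: longer cluster, then leftmost
  len <- clusters$end[cand] - clusters$start[cand]
  cand <- cand[len == max(len)]
  cand <- cand[order(clusters$chrom[cand], clusters$start[cand])][1]
  clusters[cand, ]
}

#' Assign SNPs to flanked gene windows
#'
#' A SNP belongs to a gene when it lies on the same chromosome and its
#' position falls inside the closed interval
#' `[window_start, window_end]`. A SNP inside several overlapping gene
#' windows is assigned to each of them.
#'
#' @param genes Gene models from [merge_isoforms()].
#' @param snps Summary-statistics tibble.
#' @return Named list: gene symbol -> character vector of SNP ids (possibly
#'   empty).
#' @export
assign_snps <- function(genes, snps) {
  out <- vector("list", nrow(genes))
  names(out) <- genes$gene_symbol
  snp_dt <- data.table::data.table(snp_id = snps$snp_id, chrom = snps$chrom,
                                   pos = snps$pos)
  by_chrom <- split(snp_dt, snp_dt$chrom)
  for (i in seq_len(nrow(genes))) {
    ch <- by_chrom[[genes$chrom[i]]]
    if (is.null(ch)) {
      out[[i]] <- character(0)
    } else {
      hit <- ch$pos >= genes$window_start[i] & ch$pos <= genes$window_end[i]
      out[[i]] <- ch$snp_id[hit]
    }
  }
  out
}

#' Filter pathways by mappable gene count
#'
#' Gene lists are first intersected with the available gene models (symbols
#' that cannot contribute SNPs are irrelevant to the test), then pathways
#' retaining fewer than `min_genes` or more than `max_genes` genes are
#' removed. Idempotent.
#'
#' @param pathways Named list of gene-symbol vectors, as from [read_gmt()].
#' @param gene_symbols Character vector of available gene-model symbols.
#' @param min_genes,max_genes Inclusive retention bounds on the mappable
#'   gene count (defaults 5 and 300).
#' @return Named list of the retained pathways with gene lists intersected.
#' @export
filter_pathways <- function(pathways, gene_symbols, min_genes = 5L,
                            max_genes = 300L) {
  out <- lapply(pathways, function(g) {
    kept <- intersect(g, gene_symbols)
    desc <- attr(g, "description")
    if (!is.null(desc)) attr(kept, "description") <- desc
    kept
  })
  sizes <- lengths(out)
  out[sizes >= min_genes & sizes <= max_genes]
}

#' Bin pathways by gene-count quartiles
#'
#' Splits a size-filtered collection into four size ranges at the 25th, 50th
#' and 75th percentiles of the collection's own gene counts (type-1
#' quantiles, so cutpoints are observed sizes). Bins are left-closed:
#' `size < q25` is bin 1, `q25 <= size < q50` bin 2, and so on. Explicit
#' cutpoints (for example the reference cutpoints 10/17/37 giving ranges
#' \[5,9\], \[10,16\], \[17,36\], \[37,300\]) can be supplied instead.
#'
#' @param pathways Named list of (filtered) pathways.
#' @param cutpoints `NULL` for empirical quartile cutpoints, or a numeric
#'   vector of three increasing cutpoints.
#' @return Named integer vector: pathway id -> bin in 1..4.
#' @export
size_bins <- function(pathways, cutpoints = NULL) {
  sizes <- lengths(pathways)
  if (is.null(cutpoints)) {
    if (length(unique(sizes)) < 4) {
      warning("fewer than 4 distinct pathway sizes; all pathways in bin 1")
      return(stats::setNames(rep(1L, length(sizes)), names(pathways)))
    }
    cutpoints <- stats::quantile(sizes, c(0.25, 0.5, 0.75), type = 1)
  }
  if (length(cutpoints) != 3 || is.unsorted(cutpoints, strictly = TRUE))
    stop("cutpoints must be three strictly increasing values")
  bins <- findInterval(sizes, cutpoints, left.open = FALSE) + 1L
  stats::setNames(bins, names(pathways))
}

#' Collect a pathway's SNP set
#'
#' Union of the SNPs assigned to the pathway's member genes; a SNP reached
#' through several member genes appears once. A pathway whose genes carry no
#' SNPs is flagged non-testable.
#'
#' @param genes Character vector of the pathway's gene symbols.
#' @param gene_snps Assignment list from [assign_snps()].
#' @return List with `snp_ids` (character) and `testable` (logical).
#' @export
collect_pathway_snps <- function(genes, gene_snps) {
  ids <- unique(unlist(gene_snps[intersect(genes, names(gene_snps))],
                       use.names = FALSE))
  if (is.null(ids)) ids <- character(0)
  list(snp_ids = ids, testable = length(ids) > 0)
}
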