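# LD-block partitioning. SNPs whose pairwise r2 exceeds a threshold are
# grouped together by single-linkage: blocks are the connected components of
# the graph with an edge wherever r2 > threshold, so grouping is transitive.
# At pathway scope the whole pathway SNP set is partitioned at once; at gene
# scope each member gene's SNPs are partitioned separately, ignoring LD
# between genes.

#' Partition a SNP set into LD blocks
#'
#' Blocks are the connected components of the graph on `snp_ids` with an
#' edge whenever r2 is strictly greater than `r2_threshold` (a pair at
#' exactly the threshold is not linked). SNPs with no qualifying partner —
#' including SNPs absent from the LD source — form singleton blocks. When
#' chromosome assignments are supplied, edges between chromosomes are
#' discarded before clustering: LD is an intra-chromosomal phenomenon and
#' trans correlations in a reference panel are treated as noise.
#'
#' @param snp_ids Character vector of SNP ids (duplicates ignored).
#' @param ld An `ld_source`.
#' @param r2_threshold Pairs with r2 strictly above this are linked
#'   (default 0.1).
#' @param chrom Optional named character vector mapping snp_id -> chromosome.
#' @return A tibble with `block_id` and a `snp_ids` list-column; rows sorted
#'   by each block's smallest member id, and block ids numbered in that
#'   order. Empty input gives zero rows.
#' @export
block_snps <- function(snp_ids, ld, r2_threshold = 0.1, chrom = NULL) {
  stopifnot(r2_threshold >= 0, r2_threshold < 1)
  snp_ids <- unique(as.character(snp_ids))
  if (!length(snp_ids))
    return(tibble::tibble(block_id = character(0), snp_ids = list()))
  edges <- ld_edges(ld, snp_ids, r2_threshold)
  if (!is.null(chrom) && nrow(edges)) {
    same <- chrom[edges$snp_a] == chrom[edges$snp_b]
    same[is.na(same)] <- FALSE
    edges <- edges[same, ]
  }
  g <- igraph::graph_from_data_frame(
    edges[, c("snp_a", "snp_b")], directed = FALSE,
    vertices = data.frame(name = snp_ids))
  comp <- igraph::components(g)$membership
  members <- split(names(comp), comp)
  members <- lapply(members, sort)
  members <- members[order(vapply(members, `[`, "", 1))]
  tibble::tibble(
    block_id = sprintf("B%04d", seq_along(members)),
    snp_ids = unname(members)
  )
}

#' Block a pathway's SNPs at pathway or gene scope
#'
#' Pathway scope runs [block_snps()] once over the pathway's full SNP union,
#' so LD between SNPs of different member genes merges blocks across genes.
#' Gene scope runs the clustering per member gene and concatenates the
#' blocks: cross-gene LD is ignored, and a SNP assigned to two overlapping
#' member genes contributes to both genes' blocks.
#'
#' @param pathway_snps Character vector: the pathway's SNP union.
#' @param member_gene_snps Named list mapping the pathway's member genes to
#'   their assigned SNP ids (required for gene scope).
#' @param ld An `ld_source`.
#' @param scope `"pathway"` (default) or `"gene"`.
#' @param r2_threshold Clustering threshold, see [block_snps()].
#' @param chrom Optional named chromosome map, see [block_snps()].
#' @return A tibble of blocks (`block_id`, `snp_ids`, `scope`, `gene`);
#'   `gene` is `NA` at pathway scope.
#' @export
block_pathway <- function(pathway_snps, member_gene_snps = NULL, ld,
                          scope = c("pathway", "gene"), r2_threshold = 0.1,
                          chrom = NULL) {
  scope <- match.arg(scope)
  if (scope == "pathway") {
    blocks <- block_snps(pathway_snps, ld, r2_threshold, chrom)
    blocks$scope <- rep("pathway", nrow(blocks))
    blocks$gene <- rep(NA_character_, nrow(blocks))
    return(blocks)
  }
  if (is.null(member_gene_snps))
    stop("gene scope requires the per-gene SNP assignments")
  pieces <- lapply(names(member_gene_snps), function(g) {
    ids <- intersect(member_gene_snps[[g]], pathway_snps)
    b <- block_snps(ids, ld, r2_threshold, chrom)
    if (nrow(b)) {
      b$gene <- g
    } else {
      b$gene <- character(0)
    }
    b
  })
  out <- do.call(rbind, pieces)
  if (is.null(out) || !nrow(out))
    return(tibble::tibble(block_id = character(0), snp_ids = list(),
                          scope = character(0), gene = character(0)))
  out$scope <- "gene"
  out$block_id <- sprintf("%s:%s", out$gene, out$block_id)
  out[, c("block_id", "snp_ids", "scope", "gene")]
}
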