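# Post-hoc utilities: family-wise significance thresholds and the
# ranked-pathway associated-gene overlap curve.

#' Bonferroni pathway-significance threshold
#'
#' Plain Bonferroni: the family-wise level divided by the number of tested
#' pathways. For a collection of 5,764 pathways at family alpha 0.05 this
#' gives 8.7e-06.
#'
#' @param n_pathways Number of pathways tested (>= 1).
#' @param family_alpha Family-wise significance level (default 0.05).
#' @return The per-pathway significance threshold.
#' @export
significance_threshold <- function(n_pathways, family_alpha = 0.05) {
  if (length(n_pathways) != 1 || !is.finite(n_pathways) || n_pathways < 1)
    stop("n_pathways must be a positive count")
  family_alpha / n_pathways
}

#' Ranked-pathway gene-overlap curve
#'
#' Walks pathways in rank order (ascending association P, ties by pathway
#' id), accumulates the union of their mapped genes, and reports the
#' percentage of the cumulative union found in a user-supplied list of
#' associated genes. Pathways are included until adding one would push the
#' union past `cap` genes; a pathway contributing no new genes emits no
#' point.
#'
#' @param results Result tibble from [run_pathway_test()] (or any tibble
#'   with `pathway_id` and `p_assoc`).
#' @param pathway_genes Named list: pathway id -> mapped gene symbols.
#' @param catalog_genes Character vector of associated genes (non-empty).
#' @param cap Maximum cumulative number of genes (default 1000).
#' @return A tibble (`pathway_id`, `cum_genes`, `pct_overlap`), with
#'   `cum_genes` strictly increasing and `pct_overlap` in \[0, 100\].
#' @export
overlap_curve <- function(results, pathway_genes, catalog_genes,
                          cap = 1000L) {
  if (!length(catalog_genes)) stop("the associated-gene list is empty")
  catalog_genes <- unique(as.character(catalog_genes))
  ord <- order(results$p_assoc, results$pathway_id)
  ids <- results$pathway_id[ord]
  cum <- character(0)
  pts <- list()
  for (pid in ids) {
    genes <- pathway_genes[[pid]]
    if (is.null(genes)) next
    new_union <- union(cum, genes)
    if (length(new_union) > cap) break
    if (length(new_union) == length(cum)) next
    cum <- new_union
    pts[[length(pts) + 1L]] <- tibble::tibble(
      pathway_id = pid, cum_genes = length(cum),
      pct_overlap = 100 * length(intersect(cum, catalog_genes)) /
        length(cum))
  }
  if (!length(pts))
    return(tibble::tibble(pathway_id = character(0), cum_genes = integer(0),
                          pct_overlap = numeric(0)))
  do.call(rbind, pts)
}
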