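# End-to-end orchestration: mapping -> blocking -> scoring -> pool ->
# adaptive permutation, for every testable pathway of a collection.

#' Run the LD-block pathway association test
#'
#' Full pipeline over loaded inputs: isoforms are merged into gene models,
#' SNPs are assigned to flanked gene windows, pathways are size-filtered,
#' each pathway's SNP set is partitioned into LD blocks and scored, the
#' block statistics of all testable pathways form the permutation pool, and
#' every pathway's association P-value is estimated by adaptive permutation
#' against that pool. Per-pathway RNG substreams are derived from the master
#' seed by hashing the pathway id, so results do not depend on iteration
#' order.
#'
#' @param snps Summary-statistics tibble ([read_summary_stats()]).
#' @param isoforms Isoform-row tibble ([read_gene_table()]); a pre-merged
#'   gene-model tibble (with `window_start`/`window_end` columns) is also
#'   accepted.
#' @param pathways Named list of gene-symbol vectors ([read_gmt()]).
#' @param ld An `ld_source`.
#' @param flank Gene-window flank in bp (default 15000).
#' @param r2_threshold LD-block clustering threshold (default 0.1).
#' @param scope `"pathway"` (block across the whole pathway, the default) or
#'   `"gene"` (block within genes only, ignoring cross-gene LD).
#' @param min_genes,max_genes Pathway-size filter bounds (defaults 5, 300).
#' @param schedule,alpha_stop,replace Permutation controls, see
#'   [perm_pvalue()].
#' @param seed Master seed (integer). Required for reproducible output.
#' @return A tibble with one row per testable pathway — `pathway_id`,
#'   `n_genes_mapped`, `n_snps`, `n_blocks`, `s_obs`, `n_perm_used`,
#'   `n_exceed`, `p_assoc` — sorted by `p_assoc` (ties by `pathway_id`).
#'   Attributes: `non_testable` (ids of filtered-in pathways without SNPs)
#'   and `config` (the parameter fingerprint).
#' @export
run_pathway_test <- function(snps, isoforms, pathways, ld,
                             flank = 15000L, r2_threshold = 0.1,
                             scope = c("pathway", "gene"),
                             min_genes = 5L, max_genes = 300L,
                             schedule = c(1e3, 1e4, 1e5, 1e6),
                             alpha_stop = 0.05, replace = FALSE,
                             seed = 1L) {
  scope <- match.arg(scope)
  if (all(c("window_start", "window_end") %in% names(isoforms))) {
    genes <- isoforms
  } else {
    genes <- merge_isoforms(isoforms, snps, flank)
  }
  gene_snps <- assign_snps(genes, snps)
  pathways <- filter_pathways(pathways, genes$gene_symbol, min_genes,
                              max_genes)
  if (!length(pathways))
    stop("no pathway passes the ", min_genes, "-", max_genes, " gene filter")

  pvals <- stats::setNames(snps$pvalue, snps$snp_id)
  chrom <- stats::setNames(snps$chrom, snps$snp_id)

  scored <- list()
  meta <- list()
  non_testable <- character(0)
  for (pid in names(pathways)) {
    members <- pathways[[pid]]
    pset <- collect_pathway_snps(members, gene_snps)
    if (!pset$testable) {
      non_testable <- c(non_testable, pid)
      next
    }
    blocks <- block_pathway(pset$snp_ids, gene_snps[members], ld,
                            scope = scope, r2_threshold = r2_threshold,
                            chrom = chrom)
    sb <- score_blocks(blocks, pvals)
    scored[[pid]] <- sb
    meta[[pid]] <- list(n_genes_mapped = length(members),
                        n_snps = length(pset$snp_ids))
  }
  if (!length(scored))
    stop("zero testable pathways: no pathway gene carries a SNP")

  pool <- build_pool(scored)
  rows <- lapply(names(scored), function(pid) {
    ps <- pathway_score(scored[[pid]])
    res <- perm_pvalue(ps$s_obs, ps$n_blocks, pool,
                       schedule = schedule, alpha_stop = alpha_stop,
                       seed = derive_seed(seed, pid), replace = replace)
    tibble::tibble(pathway_id = pid,
                   n_genes_mapped = meta[[pid]]$n_genes_mapped,
                   n_snps = meta[[pid]]$n_snps,
                   n_blocks = res$n_blocks, s_obs = res$s_obs,
                   n_perm_used = res$n_perm_used, n_exceed = res$n_exceed,
                   p_assoc = res$p_assoc)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$p_assoc, out$pathway_id), ]
  attr(out, "non_testable") <- non_testable
  attr(out, "config") <- list(flank = flank, r2_threshold = r2_threshold,
                              scope = scope, min_genes = min_genes,
                              max_genes = max_genes, schedule = schedule,
                              alpha_stop = alpha_stop, replace = replace,
                              seed = seed)
  out
}

#' Write a pathway results table
#'
#' Tab-separated output with a leading comment line carrying the
#' configuration fingerprint (r2 threshold, flank, scope, seed, schedule) so
#' any results file identifies the run that produced it.
#'
#' @param results Result tibble from [run_pathway_test()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_results <- function(results, path) {
  cfg <- attr(results, "config")
  header <- if (!is.null(cfg)) {
    sprintf(
      "# r2_threshold=%s flank=%s scope=%s seed=%s schedule=%s alpha_stop=%s",
      cfg$r2_threshold, cfg$flank, cfg$scope, cfg$seed,
      paste(cfg$schedule, collapse = ","), cfg$alpha_stop)
  } else {
    character(0)
  }
  dt <- data.table::as.data.table(results)
  dt$s_obs <- formatC(dt$s_obs, digits = 17, format = "g")
  dt$p_assoc <- formatC(dt$p_assoc, digits = 17, format = "g")
  body <- c(paste(names(dt), collapse = "\t"),
            do.call(paste, c(as.list(dt), sep = "\t")))
  writeLines(c(header, body), path)
  invisible(path)
}
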