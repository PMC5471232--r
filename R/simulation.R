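# Evaluation designs for set-based tests on summary statistics.
#
# Type I error: pathways are assembled by randomly assigning genes, which
# breaks biological relationships between genes while keeping the LD
# structure between SNPs intact; the fraction of such null pathways called
# significant at a nominal level is the empirical type I error, tabulated
# overall and within pathway-size bins.
#
# Power: each tested pathway's SNP P-values are multiplied by one factor so
# that a fixed percentage of its SNPs becomes significant (P < 0.05), the
# pathway is re-scored on the scaled values, and its association P-value is
# computed against the unscaled genome-wide pool; power is the fraction of
# pathways significant at 0.05.

#' Generate random pathways from a gene pool
#'
#' Each pathway is a uniform sample of distinct gene symbols; SNP contents
#' and LD are untouched, so the pathways are null by construction.
#'
#' @param gene_pool Character vector of available gene symbols.
#' @param sizes Integer vector of requested pathway sizes.
#' @param seed Integer seed.
#' @return Named list of gene-symbol vectors (`rand00001`, ...).
#' @export
random_pathways <- function(gene_pool, sizes, seed = 1L) {
  if (any(sizes > length(gene_pool)))
    stop("requested pathway size exceeds the gene pool (",
         length(gene_pool), ")")
  with_seed(seed, {
    out <- lapply(sizes, function(k) sample(gene_pool, k))
    names(out) <- sprintf("rand%05d", seq_along(out))
    out
  })
}

# Default null-pathway size distribution: log-uniform over [lo, hi], which
# spreads pathways across all four reference size bins.
draw_pathway_sizes <- function(n, lo, hi, seed) {
  with_seed(seed, {
    as.integer(round(exp(runif(n, log(lo), log(hi)))))
  })
}

#' Empirical type I error of the pathway test
#'
#' Builds `n_pathways` random pathways from the dataset's mappable genes,
#' runs the full pipeline on them, and tabulates the fraction with
#' association P-value below each nominal level, overall and per size bin,
#' with exact binomial 95% confidence intervals.
#'
#' @param snps,isoforms,ld Loaded inputs as for [run_pathway_test()].
#' @param n_pathways Number of random pathways (default 1000).
#' @param sizes Optional explicit pathway sizes; by default sizes are drawn
#'   log-uniformly between `min_genes` and the smaller of `max_genes` and
#'   the gene-pool size, spanning all four size bins.
#' @param alphas Nominal significance levels (default includes 0.05).
#' @param bin_cutpoints Size-bin cutpoints (default 10/17/37, the reference
#'   quartile bounds giving ranges \[5,9\], \[10,16\], \[17,36\],
#'   \[37,300\]).
#' @param scope,flank,r2_threshold,min_genes,max_genes,schedule,alpha_stop
#'   Pipeline parameters, see [run_pathway_test()].
#' @param seed Master seed.
#' @return A tibble (`alpha`, `bin`, `n`, `n_sig`, `rate`, `ci_low`,
#'   `ci_high`); `bin` is `"1"`..`"4"` or `"overall"`. The pathway-level
#'   results table is attached as attribute `results`.
#' @export
type1_error <- function(snps, isoforms, ld, n_pathways = 1000L,
                        sizes = NULL,
                        alphas = c(0.01, 0.02, 0.05, 0.08, 0.1),
                        bin_cutpoints = c(10, 17, 37),
                        scope = c("pathway", "gene"), flank = 15000L,
                        r2_threshold = 0.1, min_genes = 5L, max_genes = 300L,
                        schedule = c(1e3, 1e4), alpha_stop = 0.05,
                        seed = 1L) {
  scope <- match.arg(scope)
  if (all(c("window_start", "window_end") %in% names(isoforms))) {
    genes <- isoforms
  } else {
    genes <- merge_isoforms(isoforms, snps, flank)
  }
  pool_hi <- min(max_genes, length(genes$gene_symbol))
  if (is.null(sizes))
    sizes <- draw_pathway_sizes(n_pathways, min_genes, pool_hi,
                                derive_seed(seed, "sizes"))
  rp <- random_pathways(genes$gene_symbol, sizes,
                        seed = derive_seed(seed, "random_pathways"))
  res <- run_pathway_test(snps, genes, rp, ld, flank = flank,
                          r2_threshold = r2_threshold, scope = scope,
                          min_genes = min_genes, max_genes = max_genes,
                          schedule = schedule, alpha_stop = alpha_stop,
                          seed = seed)
  kept <- filter_pathways(rp, genes$gene_symbol, min_genes, max_genes)
  bins <- size_bins(kept, cutpoints = bin_cutpoints)
  res_bin <- as.character(bins[res$pathway_id])
  out <- rate_table(res$p_assoc, res_bin, alphas)
  attr(out, "results") <- res
  out
}

# Tabulate significance rates per nominal level and bin (+ overall).
rate_table <- function(pvals, bins, alphas) {
  cells <- list()
  for (alpha in alphas) {
    for (b in c(sort(unique(bins)), "overall")) {
      sel <- if (b == "overall") rep(TRUE, length(pvals)) else bins == b
      n <- sum(sel)
      if (n == 0) next
      k <- sum(pvals[sel] < alpha)
      ci <- stats::binom.test(k, n)$conf.int
      cells[[length(cells) + 1L]] <- tibble::tibble(
        alpha = alpha, bin = b, n = n, n_sig = k, rate = k / n,
        ci_low = ci[1], ci_high = ci[2])
    }
  }
  do.call(rbind, cells)
}

#' Scaling factor achieving a target fraction of significant SNPs
#'
#' Returns the factor f such that multiplying the pathway's SNP P-values by
#' f makes the smallest attainable fraction of them significant
#' (P < `snp_alpha`) that is at least `target_fraction`: with
#' k = ceiling(target * n), f is `snp_alpha / p_(k)` shrunk by a fixed
#' relative nudge so the k-th order statistic falls strictly below the
#' cutoff. f exceeds 1 when the pathway must be de-enriched to reach the
#' target from above.
#'
#' @param pvals Numeric vector of the pathway's SNP P-values (length >= 1).
#' @param target_fraction Target fraction of significant SNPs, in (0, 1).
#' @param snp_alpha Per-SNP significance cutoff (default 0.05).
#' @param eps Relative strictness nudge (default 1e-9).
#' @return The scaling factor (positive scalar).
#' @export
enrichment_factor <- function(pvals, target_fraction, snp_alpha = 0.05,
                              eps = 1e-9) {
  n <- length(pvals)
  if (n < 1) stop("pathway has no SNPs")
  if (target_fraction <= 0 || target_fraction >= 1)
    stop("target_fraction must lie strictly between 0 and 1")
  k <- ceiling(target_fraction * n)
  pk <- sort(pvals)[k]
  snp_alpha / pk * (1 - eps)
}

#' Power of the pathway test at fixed significant-SNP fractions
#'
#' For every tested pathway and every target fraction, the pathway's SNP
#' P-values are scaled by its [enrichment_factor()] (capped at 1), its
#' blocks are re-scored on the scaled values (the LD blocks themselves do
#' not depend on P-values), and the association P-value is computed against
#' the pool of unscaled block statistics — so the null reference is the
#' same genome-wide pool the observed analysis would use. Power is the
#' fraction of pathways with association P below `alpha`, per size bin and
#' overall.
#'
#' @param snps,isoforms,pathways,ld Loaded inputs as for
#'   [run_pathway_test()].
#' @param fractions Target significant-SNP fractions
#'   (default 0.30/0.50/0.70/0.80).
#' @param snp_alpha Per-SNP significance cutoff used by the scaling
#'   (default 0.05).
#' @param alpha Pathway-level significance cutoff for declaring detection
#'   (default 0.05).
#' @param bin_cutpoints Size-bin cutpoints (default 10/17/37).
#' @param scope,flank,r2_threshold,min_genes,max_genes,schedule,alpha_stop
#'   Pipeline parameters, see [run_pathway_test()].
#' @param seed Master seed.
#' @return A tibble (`fraction`, `bin`, `n`, `n_sig`, `power`); pathways
#'   for which the target is unattainable are excluded and counted in the
#'   `n_excluded` attribute.
#' @export
power_estimate <- function(snps, isoforms, pathways, ld,
                           fractions = c(0.3, 0.5, 0.7, 0.8),
                           snp_alpha = 0.05, alpha = 0.05,
                           bin_cutpoints = c(10, 17, 37),
                           scope = c("pathway", "gene"), flank = 15000L,
                           r2_threshold = 0.1, min_genes = 5L,
                           max_genes = 300L, schedule = c(1e3, 1e4),
                           alpha_stop = 0.05, seed = 1L) {
  scope <- match.arg(scope)
  if (all(c("window_start", "window_end") %in% names(isoforms))) {
    genes <- isoforms
  } else {
    genes <- merge_isoforms(isoforms, snps, flank)
  }
  gene_snps <- assign_snps(genes, snps)
  pathways <- filter_pathways(pathways, genes$gene_symbol, min_genes,
                              max_genes)
  if (!length(pathways)) stop("no pathway passes the gene-count filter")
  bins <- size_bins(pathways, cutpoints = bin_cutpoints)
  pvals <- stats::setNames(snps$pvalue, snps$snp_id)
  chrom <- stats::setNames(snps$chrom, snps$snp_id)

  # observed (unscaled) blocks and the null pool
  blocks <- list()
  for (pid in names(pathways)) {
    pset <- collect_pathway_snps(pathways[[pid]], gene_snps)
    if (!pset$testable) next
    b <- block_pathway(pset$snp_ids, gene_snps[pathways[[pid]]], ld,
                       scope = scope, r2_threshold = r2_threshold,
                       chrom = chrom)
    blocks[[pid]] <- score_blocks(b, pvals)
  }
  if (!length(blocks)) stop("zero testable pathways")
  pool <- build_pool(blocks)

  cells <- list()
  n_excluded <- 0L
  for (fr in fractions) {
    sig <- character(0)
    tested <- character(0)
    for (pid in names(blocks)) {
      snp_ids <- unique(unlist(blocks[[pid]]$snp_ids, use.names = FALSE))
      f <- tryCatch(enrichment_factor(pvals[snp_ids], fr, snp_alpha),
                    error = function(e) NA_real_)
      if (is.na(f)) {
        n_excluded <- n_excluded + 1L
        next
      }
      scaled <- pvals
      scaled[snp_ids] <- pmin(pvals[snp_ids] * f, 1)
      sb <- score_blocks(blocks[[pid]][, c("block_id", "snp_ids")], scaled)
      ps <- pathway_score(sb)
      res <- perm_pvalue(ps$s_obs, ps$n_blocks, pool, schedule = schedule,
                         alpha_stop = alpha_stop,
                         seed = derive_seed(seed, paste0(pid, "@", fr)))
      tested <- c(tested, pid)
      if (res$p_assoc < alpha) sig <- c(sig, pid)
    }
    for (b in c(sort(unique(as.character(bins[tested]))), "overall")) {
      in_bin <- if (b == "overall") tested else
        tested[as.character(bins[tested]) == b]
      if (!length(in_bin)) next
      cells[[length(cells) + 1L]] <- tibble::tibble(
        fraction = fr, bin = b, n = length(in_bin),
        n_sig = sum(in_bin %in% sig),
        power = sum(in_bin %in% sig) / length(in_bin))
    }
  }
  out <- do.call(rbind, cells)
  attr(out, "n_excluded") <- n_excluded
  out
}
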