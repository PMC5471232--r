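# Block scoring: each LD block is represented by its most significant SNP,
# whose P-value is converted to the upper-tail chi-square(1 df) quantile;
# the pathway's observed score S_obs is the sum over blocks. The block
# minimum is deliberately not adjusted for the number of SNPs in the block:
# the permutation pool is built by the identical procedure, so the same
# min-P bias enters both sides of the comparison.

#' Upper-tail chi-square(1) statistic from a P-value
#'
#' Returns the value x whose upper-tail probability under a chi-square
#' distribution with one degree of freedom equals p, i.e. the statistic a
#' two-sided z-test would have needed to produce that P-value. Vectorized.
#' P-values below `p_floor` are clamped, and the quantile is evaluated
#' through the log-scale tail so extremely small P cannot overflow to
#' infinity.
#'
#' @param p Numeric vector of P-values in (0, 1].
#' @param p_floor Clamp for underflowing P-values (default 1e-300).
#' @return Numeric vector of chi-square statistics (>= 0); `p = 1` maps
#'   to 0.
#' @export
chi2_from_p <- function(p, p_floor = 1e-300) {
  if (any(!is.finite(p) | p <= 0 | p > 1))
    stop("P-values must lie in (0, 1]")
  p <- pmax(p, p_floor)
  qchisq(log(p), df = 1, lower.tail = FALSE, log.p = TRUE)
}

#' Score LD blocks by their minimum P-value
#'
#' For each block, the representative SNP is the member with the lowest
#' P-value (ties broken by lexicographically smallest SNP id for
#' determinism), and the block statistic is [chi2_from_p()] of that P-value.
#'
#' @param blocks Block tibble from [block_snps()] or [block_pathway()].
#' @param pvals Named numeric vector: snp_id -> P-value; every block member
#'   must be present.
#' @return `blocks` with added columns `rep_snp`, `rep_p`, `chi2`.
#' @export
score_blocks <- function(blocks, pvals) {
  n <- nrow(blocks)
  rep_snp <- character(n)
  rep_p <- numeric(n)
  for (i in seq_len(n)) {
    ids <- sort(blocks$snp_ids[[i]])
    p <- pvals[ids]
    if (anyNA(p))
      stop("no P-value for SNP(s): ",
           paste(head(ids[is.na(p)], 5), collapse = ", "))
    j <- which.min(p)  # first minimum; ids sorted, so ties break lexically
    rep_snp[i] <- ids[j]
    rep_p[i] <- p[[j]]
  }
  blocks$rep_snp <- rep_snp
  blocks$rep_p <- rep_p
  blocks$chi2 <- chi2_from_p(rep_p)
  blocks
}

#' Observed pathway score
#'
#' Sums the block chi-square statistics into the observed score S_obs.
#'
#' @param scored Scored block tibble from [score_blocks()]; must be
#'   non-empty.
#' @return List with `n_blocks` and `s_obs`.
#' @export
pathway_score <- function(scored) {
  if (!nrow(scored))
    stop("cannot score a pathway with zero blocks (non-testable)")
  list(n_blocks = nrow(scored), s_obs = sum(scored$chi2))
}
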