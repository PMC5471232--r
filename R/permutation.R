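# Permutation null: pool together the block statistics of all analyzed
# pathways (built by the identical blocking + scoring procedure as the
# observed scores), then estimate each pathway's association P-value as the
# chance that a random same-sized set of pool blocks sums to at least the
# observed score. Sampling is adaptive: permutations run in increasing
# stages and stop early once the interim estimate is clearly non-significant.

#' Build the genome-wide block-statistic pool
#'
#' Concatenates the block chi-square values of every analyzed pathway into
#' one multiset. A genomic block reached through several pathways
#' contributes once per pathway, so the pool is frequency-weighted by
#' pathway usage.
#'
#' @param scored_blocks List of scored-block tibbles (one per pathway), or a
#'   single numeric vector of block statistics.
#' @return A numeric vector of class `block_pool`.
#' @export
build_pool <- function(scored_blocks) {
  if (is.numeric(scored_blocks)) {
    stats <- as.numeric(scored_blocks)
  } else {
    if (!length(scored_blocks)) stop("cannot build a pool from no pathways")
    stats <- unlist(lapply(scored_blocks, function(b) b$chi2),
                    use.names = FALSE)
  }
  if (!length(stats)) stop("cannot build an empty block pool")
  structure(stats, class = "block_pool")
}

#' @export
print.block_pool <- function(x, ...) {
  cat("<block_pool> ", length(x), " block statistics, mean ",
      format(mean(unclass(x)), digits = 4), "\n", sep = "")
  invisible(x)
}

# Sums of `n`-block draws from the pool, one sum per permutation.
# Without replacement within a draw; independent permutations redraw freely.
perm_sums <- function(pool, n, n_perm, replace = FALSE) {
  pool <- as.numeric(pool)
  m <- length(pool)
  if (n == 1L)
    return(sample(pool, n_perm, replace = TRUE))
  if (replace) {
    idx <- sample.int(m, n * n_perm, replace = TRUE)
    return(colSums(matrix(pool[idx], nrow = n)))
  }
  vapply(seq_len(n_perm),
         function(i) sum(pool[sample.int(m, n)]),
         numeric(1))
}

#' Adaptive permutation P-value for one pathway
#'
#' Each permutation draws `n_blocks` statistics from the pool (without
#' replacement within the draw, mirroring a random pathway of that many
#' distinct blocks) and sums them. The association P-value is the add-one
#' estimate `(n_exceed + 1) / (n_perm + 1)` of the probability that a
#' permuted score reaches the observed score, where exceedance means
#' `S_perm >= s_obs`. Permutations run in increasing stages; after each
#' completed stage the interim estimate is checked and sampling stops once
#' it exceeds `alpha_stop`, so clearly non-significant pathways are settled
#' cheaply while small P-values get the full schedule.
#'
#' @param s_obs Observed pathway score.
#' @param n_blocks Number of blocks in the pathway.
#' @param pool A `block_pool` (or numeric vector).
#' @param schedule Increasing cumulative permutation counts
#'   (default 10^3 .. 10^6).
#' @param alpha_stop Early-stopping threshold on the interim P-value
#'   (default 0.05).
#' @param seed Optional integer; when given, results are deterministic and
#'   the caller's RNG state is left untouched.
#' @param replace Sample pool blocks with replacement within a permutation
#'   (needed when `n_blocks` exceeds the pool size).
#' @return List: `n_blocks`, `s_obs`, `n_perm_used`, `n_exceed`, `p_assoc`.
#' @export
perm_pvalue <- function(s_obs, n_blocks, pool,
                        schedule = c(1e3, 1e4, 1e5, 1e6),
                        alpha_stop = 0.05, seed = NULL, replace = FALSE) {
  pool <- as.numeric(pool)
  schedule <- as.numeric(schedule)
  if (is.unsorted(schedule, strictly = TRUE))
    stop("schedule must be strictly increasing")
  if (!replace && n_blocks > length(pool))
    stop("pathway has more blocks (", n_blocks, ") than the pool (",
         length(pool), "); use replace = TRUE to sample with replacement")
  run <- function() {
    n_done <- 0
    n_exceed <- 0
    for (stage in schedule) {
      batch <- stage - n_done
      sums <- perm_sums(pool, n_blocks, batch, replace)
      n_exceed <- n_exceed + sum(sums >= s_obs)
      n_done <- stage
      if ((n_exceed + 1) / (n_done + 1) > alpha_stop) break
    }
    list(n_blocks = as.integer(n_blocks), s_obs = s_obs,
         n_perm_used = as.integer(n_done), n_exceed = as.integer(n_exceed),
         p_assoc = (n_exceed + 1) / (n_done + 1))
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}
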