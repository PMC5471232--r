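# Shared fixture builders. Everything is generated in code; files are
# written to tempdir() only to exercise the real parsers.

# Build an ld_source by writing a pair table through the PLINK-style writer
# and reading it back, so tests go through the actual parser.
ld_from_pairs <- function(snp_a, snp_b, r2) {
  path <- tempfile(fileext = ".ld")
  writeLines(c("SNP_A\tSNP_B\tR2",
               sprintf("%s\t%s\t%s", snp_a, snp_b, r2)), path)
  read_ld_pairs(path)
}

# Minimal summary-stats tibble.
make_snps <- function(snp_id, chrom, pos, pvalue) {
  tibble::tibble(snp_id = snp_id, chrom = chrom, pos = as.integer(pos),
                 pvalue = pvalue)
}

make_isoforms <- function(gene_symbol, chrom, tx_start, tx_end,
                          strand = "+") {
  tibble::tibble(gene_symbol = gene_symbol, chrom = chrom,
                 strand = rep_len(strand, length(gene_symbol)),
                 tx_start = as.integer(tx_start),
                 tx_end = as.integer(tx_end))
}

# Independent blocking oracle: brute-force transitive closure (Warshall) on
# the r2 > threshold adjacency matrix; returns a canonical partition
# (sorted list of sorted member vectors).
oracle_components <- function(ids, r2m, threshold) {
  n <- length(ids)
  adj <- r2m > threshold
  diag(adj) <- TRUE
  for (k in seq_len(n)) for (i in seq_len(n)) {
    if (adj[i, k]) adj[i, ] <- adj[i, ] | adj[k, ]
  }
  comp <- integer(n)
  next_id <- 0L
  for (i in seq_len(n)) {
    if (comp[i] == 0L) {
      next_id <- next_id + 1L
      comp[adj[i, ]] <- next_id
    }
  }
  parts <- lapply(split(ids, comp), sort)
  unname(parts[order(vapply(parts, `[`, "", 1))])
}

canonical_blocks <- function(blocks) {
  parts <- lapply(blocks$snp_ids, sort)
  unname(parts[order(vapply(parts, `[`, "", 1))])
}

# Independent chi-square(1) upper-tail quantile via bisection on the
# survival function (does not touch qchisq).
oracle_chi2_from_p <- function(p, tol = 1e-12) {
  vapply(p, function(pp) {
    if (pp >= 1) return(0)
    lo <- 0; hi <- 1
    while (pchisq(hi, 1, lower.tail = FALSE) > pp) hi <- hi * 2
    while (hi - lo > tol * max(1, hi)) {
      mid <- (lo + hi) / 2
      if (pchisq(mid, 1, lower.tail = FALSE) > pp) lo <- mid else hi <- mid
    }
    (lo + hi) / 2
  }, numeric(1))
}

# The standard end-to-end fixture: 100 genes on 2 chromosomes, one strongly
# enriched pathway among 50 nulls.
standard_fixture_spec <- function(seed) {
  fixture_spec(n_chroms = 2L, genes_per_chrom = 50L,
               enriched_targets = c(enrich_01 = 0.8),
               n_null_pathways = 50L, pathway_size_range = c(5L, 30L),
               seed = seed)
}

# Memoized medium fixture shared by several test files.
.fixture_cache <- new.env(parent = emptyenv())
cached_fixture <- function(key, spec_fn) {
  if (is.null(.fixture_cache[[key]]))
    .fixture_cache[[key]] <- generate_fixture(spec_fn())
  .fixture_cache[[key]]
}
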