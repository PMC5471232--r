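# The fixture generator: LD structure, null/enriched statistics, round
# trips through the real file formats.

test_that("genotype blocks realize the declared LD structure", {
  spec <- fixture_spec(n_chroms = 1, genes_per_chrom = 6,
                       within_r2 = 0.5, cross_gene_ld_fraction = 0,
                       n_samples = 500, seed = 2)
  g <- generate_genotypes(spec)
  ld <- ld_from_genotypes(g$dosages, min_r2 = 0)
  lb <- g$snps$latent_block
  ids <- g$snps$snp_id
  within <- c(); between <- c()
  set.seed(4)
  for (k in 1:1000) {
    ij <- sample(length(ids), 2)
    r2 <- ld_r2(ld, ids[ij[1]], ids[ij[2]])
    if (lb[ij[1]] == lb[ij[2]]) within <- c(within, r2)
    else between <- c(between, r2)
  }
  expect_lt(abs(mean(within) - 0.5), 0.1)  # declared within-block r2
  expect_lt(mean(between), 0.05)           # blocks nearly independent

  # perfect-LD degenerate case: all block SNP columns identical
  spec1 <- fixture_spec(n_chroms = 1, genes_per_chrom = 2, within_r2 = 1,
                        n_samples = 50, seed = 3)
  g1 <- generate_genotypes(spec1)
  b1 <- g1$snps$snp_id[g1$snps$latent_block == g1$snps$latent_block[1]]
  expect_true(all(g1$dosages[, b1] == g1$dosages[, b1[1]]))

  # determinism: same spec, same matrix
  expect_identical(generate_genotypes(spec1)$dosages, g1$dosages)

  expect_error(fixture_spec(within_r2 = 0), "within_r2")
  expect_error(fixture_spec(gene_spacing = 40000, gene_length = 20000),
               "30 kb")
})

test_that("null statistics are uniform, coupled within blocks on request", {
  spec <- fixture_spec(n_chroms = 2, genes_per_chrom = 25, seed = 6)
  g <- generate_genotypes(spec)

  p_iid <- generate_null_stats(g$snps, mode = "iid", seed = 1)
  expect_gt(stats::ks.test(p_iid, "punif")$p.value, 0.01)
  expect_lt(abs(mean(p_iid < 0.05) - 0.05),
            3 * sqrt(0.05 * 0.95 / length(p_iid)) + 0.01)

  p_ld <- generate_null_stats(g$snps, mode = "ld_coupled", rho = 0.5,
                              seed = 1)
  expect_gt(stats::ks.test(p_ld, "punif")$p.value, 0.01)
  # within-block P-values are more similar than between-block ones
  z <- qnorm(p_ld / 2)  # monotone transform, finite
  by_block <- split(z, g$snps$latent_block)
  within_var <- mean(vapply(by_block, stats::var, 0), na.rm = TRUE)
  expect_lt(within_var, stats::var(z) * 0.95)
})

test_that("enriched overlays hit their significant-SNP targets", {
  spec <- fixture_spec(n_chroms = 2, genes_per_chrom = 25, seed = 12)
  g <- generate_genotypes(spec)
  null_p <- generate_null_stats(g$snps, seed = 2)
  sets <- split(g$snps$snp_id, g$snps$gene)
  enriched_snps <- unique(unlist(sets[1:20], use.names = FALSE))  # 240 SNPs
  p <- generate_enriched_stats(null_p, list(E1 = enriched_snps),
                               c(E1 = 0.8), seed = 3)
  expect_lt(abs(mean(p[enriched_snps] < 0.05) - 0.8), 0.05)

  # non-pathway SNPs keep their null values exactly
  others <- setdiff(names(null_p), enriched_snps)
  expect_identical(p[others], null_p[others])

  # target at the null rate is statistically indistinguishable from null
  p_null_target <- generate_enriched_stats(null_p,
                                           list(E1 = enriched_snps),
                                           c(E1 = 0.05), seed = 3)
  expect_lt(abs(mean(p_null_target[enriched_snps] < 0.05) - 0.05), 0.06)

  # conflicting targets on overlapping enriched pathways are rejected
  expect_error(generate_enriched_stats(
    null_p, list(E1 = enriched_snps, E2 = enriched_snps[1:10]),
    c(E1 = 0.8, E2 = 0.3), seed = 1), "overlap")
})

test_that("fixtures round-trip through the writers and readers", {
  fx <- cached_fixture("small", function() fixture_spec(seed = 5))
  dir <- tempfile("fix")
  paths <- write_fixture(fx, dir)

  snps <- read_summary_stats(paths[["summary"]])
  expect_identical(snps$snp_id, fx$snps$snp_id)
  expect_identical(snps$pvalue, fx$snps$pvalue)

  iso <- read_gene_table(paths[["genes"]])
  expect_identical(iso$gene_symbol, fx$isoforms$gene_symbol)
  expect_identical(iso$tx_start, fx$isoforms$tx_start)

  pw <- read_gmt(paths[["gmt"]])
  expect_identical(names(pw), names(fx$pathways))
  expect_identical(lapply(pw, as.character),
                   lapply(fx$pathways, as.character))

  ld <- read_ld_pairs(paths[["ld"]])
  expect_equal(nrow(ld$pairs), nrow(fx$ld$pairs))
  idx <- sample.int(nrow(ld$pairs), 100)
  expect_identical(ld_r2(ld, fx$ld$pairs$snp_a[idx], fx$ld$pairs$snp_b[idx]),
                   fx$ld$pairs$r2[idx])

  truth <- jsonlite::read_json(paths[["truth"]])
  expect_equal(truth$spec_seed, 5)
  expect_equal(length(truth$latent_blocks), nrow(fx$snps))
})
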