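# Gene-model merging, SNP assignment, pathway filtering and binning.

test_that("overlapping isoforms union into a single span", {
  iso <- make_isoforms(c("G", "G"), "1", c(100, 150), c(200, 300))
  g <- merge_isoforms(iso, snps = NULL, flank = 0L)
  expect_equal(nrow(g), 1)
  expect_equal(c(g$start, g$end), c(100L, 300L))

  # abutting intervals (end + 1 == start) are NOT merged: strict overlap
  iso <- make_isoforms(c("G", "G"), "1", c(100, 201), c(200, 300))
  snps <- make_snps("rs1", "1", 250, 0.01)
  g <- merge_isoforms(iso, snps, flank = 0L)
  expect_equal(c(g$start, g$end), c(201L, 300L))
})

test_that("disjoint isoform clusters keep the one with the lowest-P SNP", {
  iso <- make_isoforms(c("G", "G"), "1", c(1000, 90000), c(2000, 95000))
  snps <- make_snps(c("rs1", "rs2"), "1", c(1500, 91000), c(0.5, 0.001))
  g <- merge_isoforms(iso, snps, flank = 15000L)
  expect_equal(c(g$start, g$end), c(90000L, 95000L))

  # no SNP in any window: longest cluster wins, leftmost on ties
  far <- make_snps("rs9", "9", 1, 0.5)
  g <- merge_isoforms(iso, far, flank = 15000L)
  expect_equal(g$start, 90000L)  # longer cluster
  iso_tie <- make_isoforms(c("G", "G"), "1", c(50000, 1000), c(51000, 2000))
  g <- merge_isoforms(iso_tie, far, flank = 0L)
  expect_equal(g$start, 1000L)   # equal lengths -> leftmost

  # a symbol on two chromosomes behaves as disjoint clusters of one gene
  iso2 <- make_isoforms(c("G", "G"), c("1", "2"), c(100, 100), c(200, 300))
  snps2 <- make_snps("rs1", "2", 150, 0.01)
  g <- merge_isoforms(iso2, snps2, flank = 0L)
  expect_equal(nrow(g), 1)
  expect_equal(g$chrom, "2")
})

test_that("SNPs map to flanked windows with inclusive 1-based bounds", {
  iso <- make_isoforms("G", "1", 20000, 30000)
  genes <- merge_isoforms(iso, snps = NULL, flank = 15000L)
  expect_equal(genes$window_start, 5000L)
  expect_equal(genes$window_end, 45000L)

  snps <- make_snps(c("in_lo", "out_lo", "in_hi", "out_hi", "wrong_chr"),
                    c("1", "1", "1", "1", "2"),
                    c(5000, 4999, 45000, 45001, 25000),
                    rep(0.5, 5))
  asn <- assign_snps(genes, snps)
  expect_setequal(asn$G, c("in_lo", "in_hi"))

  # window start floors at 1 near the chromosome start
  g2 <- merge_isoforms(make_isoforms("H", "1", 100, 300), NULL, 15000L)
  expect_equal(g2$window_start, 1L)

  # a SNP inside two overlapping windows maps to both genes
  iso3 <- make_isoforms(c("A", "B"), "1", c(100, 150), c(200, 400))
  g3 <- merge_isoforms(iso3, NULL, flank = 0L)
  asn3 <- assign_snps(g3, make_snps("rs1", "1", 180, 0.5))
  expect_equal(asn3$A, "rs1")
  expect_equal(asn3$B, "rs1")
})

test_that("pathway filter counts mappable genes and is idempotent", {
  available <- sprintf("G%03d", 1:400)
  pw <- list(tiny = sprintf("G%03d", 1:4),
             atmin = sprintf("G%03d", 1:5),
             big = sprintf("G%03d", 1:301),
             atmax = sprintf("G%03d", 1:300),
             ghostly = c(sprintf("G%03d", 1:5), "NOT1", "NOT2"))
  kept <- filter_pathways(pw, available)
  expect_setequal(names(kept), c("atmin", "atmax", "ghostly"))
  # unmappable symbols are dropped before counting
  expect_length(kept$ghostly, 5)
  expect_identical(filter_pathways(kept, available), kept)
})

test_that("size bins follow the reference cutpoints and partition the set", {
  pw <- lapply(c(a = 5, b = 9, c = 10, d = 16, e = 17, f = 36, g = 37,
                 h = 300), function(k) sprintf("G%d", seq_len(k)))
  bins <- size_bins(pw, cutpoints = c(10, 17, 37))
  expect_equal(unname(bins), c(1L, 1L, 2L, 2L, 3L, 3L, 4L, 4L))
  expect_true(all(bins %in% 1:4))  # every pathway in exactly one bin

  # degenerate: fewer than 4 distinct sizes -> all bin 1 with warning
  same <- lapply(1:3, function(i) sprintf("G%d", 1:7))
  names(same) <- c("x", "y", "z")
  expect_warning(b <- size_bins(same), "distinct")
  expect_equal(unname(b), c(1L, 1L, 1L))

  # empirical percentile cutpoints partition a spread collection
  sizes <- c(5:9, 12, 15, 20, 30, 40, 80, 200)
  pw2 <- lapply(sizes, function(k) sprintf("G%d", seq_len(k)))
  names(pw2) <- sprintf("p%02d", seq_along(pw2))
  b2 <- size_bins(pw2)
  expect_setequal(unique(b2), 1:4)
})

test_that("pathway SNP sets union member genes and flag non-testable", {
  gene_snps <- list(A = c("s1", "s2"), B = c("s2", "s3"), C = character(0))
  ps <- collect_pathway_snps(c("A", "B"), gene_snps)
  expect_setequal(ps$snp_ids, c("s1", "s2", "s3"))
  expect_true(ps$testable)
  expect_setequal(collect_pathway_snps(c("A", "C"), gene_snps)$snp_ids,
                  c("s1", "s2"))
  empty <- collect_pathway_snps("C", gene_snps)
  expect_false(empty$testable)
})

test_that("assigned pathway SNPs always satisfy the window predicate", {
  fx <- cached_fixture("small", function() fixture_spec(seed = 5))
  genes <- merge_isoforms(fx$isoforms, fx$snps, flank = 15000L)
  asn <- assign_snps(genes, fx$snps)
  pos <- setNames(fx$snps$pos, fx$snps$snp_id)
  chr <- setNames(fx$snps$chrom, fx$snps$snp_id)
  for (i in seq_len(nrow(genes))) {
    ids <- asn[[genes$gene_symbol[i]]]
    if (!length(ids)) next
    expect_true(all(chr[ids] == genes$chrom[i]))
    expect_true(all(pos[ids] >= genes$window_start[i] &
                      pos[ids] <= genes$window_end[i]))
  }
})
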