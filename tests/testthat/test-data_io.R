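# Readers, writers and the LD source.

test_that("summary statistics parse, normalize and validate", {
  path <- tempfile(fileext = ".tsv")
  writeLines(c("CHR SNP BP P",
               "1 rs1 1000 0.05",
               "chr2 rs2 500 1",
               "x rs3 42 0.9"), path)
  snps <- read_summary_stats(path)
  expect_equal(snps$snp_id, c("rs1", "rs2", "rs3"))
  expect_equal(snps$chrom, c("1", "2", "X"))
  expect_equal(snps$pos, c(1000L, 500L, 42L))
  expect_equal(snps$pvalue, c(0.05, 1, 0.9))

  # out-of-range P rejected with the line number
  writeLines(c("CHR SNP BP P", "1 rs1 1000 0.05", "1 rs2 2000 1.5"), path)
  expect_error(read_summary_stats(path), "line 3")

  # zero P: rejected by default, clamped on request
  writeLines(c("CHR SNP BP P", "1 rs1 1000 0"), path)
  expect_error(read_summary_stats(path), "P-value of 0")
  expect_equal(read_summary_stats(path, p_zero = "clamp")$pvalue, 1e-300)

  # duplicate ids and missing columns
  writeLines(c("CHR SNP BP P", "1 rs1 1000 0.1", "1 rs1 2000 0.2"), path)
  expect_error(read_summary_stats(path), "duplicate")
  writeLines(c("CHR SNP BP", "1 rs1 1000"), path)
  expect_error(read_summary_stats(path), "P")

  # custom column names
  writeLines(c("chrom marker position pval", "7 rs9 123 0.5"), path)
  snps <- read_summary_stats(path, column_map = c(
    chrom = "chrom", snp = "marker", pos = "position", p = "pval"))
  expect_equal(snps$snp_id, "rs9")
})

test_that("summary statistics round-trip exactly through write/read", {
  snps <- make_snps(sprintf("rs%02d", 1:30), rep(c("1", "2", "X"), 10),
                    sample.int(1e6, 30),
                    c(1e-300, 10^runif(28, -12, 0), 1))
  path <- tempfile(fileext = ".tsv")
  write_summary_stats(snps, path)
  back <- read_summary_stats(path)
  expect_identical(back$snp_id, snps$snp_id)
  expect_identical(back$chrom, snps$chrom)
  expect_identical(back$pos, snps$pos)
  expect_identical(back$pvalue, snps$pvalue)
})

test_that("GMT parsing deduplicates, skips empties and enforces unique ids", {
  path <- tempfile(fileext = ".gmt")
  writeLines("P1\tdesc\tA\tB\tA", path)
  p <- read_gmt(path)
  expect_equal(sort(p$P1), c("A", "B"))

  writeLines(character(0), path)
  expect_length(read_gmt(path), 0)

  writeLines(c("P1\tdesc\tA", "P1\tdesc\tB"), path)
  expect_error(read_gmt(path), "duplicate pathway id")

  writeLines("P1\tdesc", path)
  expect_error(read_gmt(path), "fewer than 3")

  writeLines(c("P1\tdesc\tA", "P2\tdesc\t\t"), path)
  expect_warning(p <- read_gmt(path), "empty gene list")
  expect_equal(names(p), "P1")
})

test_that("LD pair lists are symmetric, default absent pairs to 0, keep max", {
  ld <- ld_from_pairs(c("a", "b"), c("b", "c"), c(0.5, 0.3))
  expect_equal(ld_r2(ld, "a", "b"), 0.5)
  expect_equal(ld_r2(ld, "b", "a"), 0.5)   # symmetry
  expect_equal(ld_r2(ld, "a", "c"), 0)     # absent pair
  expect_equal(ld_r2(ld, "a", "a"), 1)     # self
  expect_equal(ld_r2(ld, "nope", "b"), 0)  # unknown SNP

  expect_warning(
    ld2 <- ld_from_pairs(c("a", "a"), c("b", "b"), c(0.2, 0.4)),
    "maximum")
  expect_equal(ld_r2(ld2, "a", "b"), 0.4)

  path <- tempfile(fileext = ".ld")
  writeLines(c("SNP_A\tSNP_B\tR2", "a\tb\t1.2"), path)
  expect_error(read_ld_pairs(path), "R2 outside")
})

test_that("every stored LD pair queries symmetrically", {
  fx <- cached_fixture("small", function() fixture_spec(seed = 5))
  pairs <- fx$ld$pairs[sample.int(nrow(fx$ld$pairs), 200), ]
  expect_equal(ld_r2(fx$ld, pairs$snp_a, pairs$snp_b),
               ld_r2(fx$ld, pairs$snp_b, pairs$snp_a))
})

test_that("dosage r2 equals squared Pearson correlation (textbook oracle)", {
  # closed-form check on a hand-sized pair
  a <- c(0, 1, 2, 0); b <- c(0, 1, 0, 2)
  num <- sum((a - mean(a)) * (b - mean(b)))
  den <- sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  ld <- ld_from_genotypes(cbind(a, b), c("a", "b"))
  expect_equal(ld_r2(ld, "a", "b"), (num / den)^2, tolerance = 1e-12)

  # identical and complementary columns are perfect LD
  ld <- ld_from_genotypes(cbind(a = a, b = a, c = 2 - a))
  expect_equal(ld_r2(ld, "a", "b"), 1)
  expect_equal(ld_r2(ld, "a", "c"), 1)

  # random 50-SNP matrix against a naive two-pass Pearson implementation
  set.seed(42)
  dos <- matrix(rbinom(50 * 60, 2, 0.4), nrow = 60)
  colnames(dos) <- sprintf("s%02d", 1:50)
  ld <- ld_from_genotypes(dos, min_r2 = 0)
  naive_r2 <- function(x, y) {
    mx <- sum(x) / length(x); my <- sum(y) / length(y)
    sxy <- sum((x - mx) * (y - my))
    sxx <- sum((x - mx)^2); syy <- sum((y - my)^2)
    (sxy / sqrt(sxx * syy))^2
  }
  for (idx in list(c(1, 2), c(3, 40), c(17, 50), c(25, 26))) {
    expect_equal(ld_r2(ld, colnames(dos)[idx[1]], colnames(dos)[idx[2]]),
                 naive_r2(dos[, idx[1]], dos[, idx[2]]), tolerance = 1e-12)
  }

  # constant column: r2 defined as 0 with a warning
  dos2 <- cbind(a = a, k = rep(1, 4))
  expect_warning(ldc <- ld_from_genotypes(dos2), "constant")
  expect_equal(ld_r2(ldc, "a", "k"), 0)
})

test_that("gene tables read from refflat and BED dialects agree", {
  path <- tempfile()
  writeLines(c("geneSymbol\tchrom\tstrand\ttxStart\ttxEnd",
               "GENE1\tchr1\t+\t100\t200"), path)
  flat <- read_gene_table(path)
  expect_equal(flat$chrom, "1")
  expect_equal(flat$tx_start, 100L)

  # BED is 0-based half-open: [99, 200) is the same closed interval
  writeLines("chr1\t99\t200\tGENE1\t0\t+", path)
  bed <- read_gene_table(path, format = "bed")
  expect_equal(bed$tx_start, 100L)
  expect_equal(bed$tx_end, 200L)
  expect_equal(bed$gene_symbol, "GENE1")
})
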