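# Self-contained synthetic fixtures with known ground truth: LD-structured
# genotype dosages laid out in blocks along genes, gene annotations with
# multi-isoform rows, pathway collections with optional enriched pathways,
# and null or enriched summary statistics. The LD model is stylized block
# LD — each block has one latent biallelic signal and every block SNP is a
# noisy copy — which reproduces the statistical structure the method relies
# on (transitive within-block correlation, near-independence between
# blocks) without coalescent realism.

#' Describe a synthetic fixture
#'
#' Bundles and validates the generator parameters. Genes are laid out along
#' chromosomes far enough apart that their flanked windows never overlap;
#' each gene carries `blocks_per_gene` LD blocks of `snps_per_block` SNPs.
#' A `cross_gene_ld_fraction` of adjacent same-chromosome gene pairs share
#' one latent block (the downstream gene's first block copies the upstream
#' gene's last), producing the cross-gene LD that distinguishes
#' pathway-scope from gene-scope blocking.
#'
#' @param n_chroms Number of chromosomes.
#' @param genes_per_chrom Genes per chromosome.
#' @param blocks_per_gene LD blocks per gene.
#' @param snps_per_block SNPs per block.
#' @param within_r2 Target within-block dosage r2, in (0, 1\].
#' @param cross_gene_ld_fraction Fraction of adjacent gene pairs sharing a
#'   latent block, in \[0, 1\].
#' @param n_samples Reference-panel sample count used to realize dosages.
#' @param gene_length,gene_spacing Gene span and start-to-start spacing in
#'   bp; spacing must exceed the span by more than twice the 15 kb flank.
#' @param isoform_split_fraction Fraction of genes emitted as two
#'   overlapping isoform rows instead of one.
#' @param n_null_pathways Number of null pathways.
#' @param pathway_size_range Inclusive size range from which null pathway
#'   sizes are drawn log-uniformly (capped at the gene-pool size).
#' @param enriched_targets Named numeric vector: enriched pathway id ->
#'   target fraction of significant SNPs (may be empty).
#' @param enriched_size Gene count of each enriched pathway.
#' @param ld_min_r2 Smallest r2 stored in the fixture's `ld_source`.
#' @param seed Master seed; all randomness flows from it through named
#'   substreams, so components are independently reproducible.
#' @return A `fixture_spec` list.
#' @export
fixture_spec <- function(n_chroms = 2L, genes_per_chrom = 20L,
                         blocks_per_gene = 3L, snps_per_block = 4L,
                         within_r2 = 0.5, cross_gene_ld_fraction = 0.2,
                         n_samples = 200L, gene_length = 20000L,
                         gene_spacing = 80000L,
                         isoform_split_fraction = 0.3,
                         n_null_pathways = 50L,
                         pathway_size_range = c(5L, 300L),
                         enriched_targets = numeric(0),
                         enriched_size = 12L, ld_min_r2 = 0.01,
                         seed = 1L) {
  if (within_r2 <= 0 || within_r2 > 1)
    stop("within_r2 must lie in (0, 1]")
  if (cross_gene_ld_fraction < 0 || cross_gene_ld_fraction > 1)
    stop("cross_gene_ld_fraction must lie in [0, 1]")
  if (gene_spacing - gene_length <= 2 * 15000)
    stop("gene_spacing must leave more than 30 kb between gene spans so ",
         "flanked windows do not overlap")
  if (length(enriched_targets) &&
      (is.null(names(enriched_targets)) || any(!nzchar(names(enriched_targets)))))
    stop("enriched_targets must be a named vector")
  structure(list(
    n_chroms = as.integer(n_chroms),
    genes_per_chrom = as.integer(genes_per_chrom),
    blocks_per_gene = as.integer(blocks_per_gene),
    snps_per_block = as.integer(snps_per_block),
    within_r2 = within_r2,
    cross_gene_ld_fraction = cross_gene_ld_fraction,
    n_samples = as.integer(n_samples),
    gene_length = as.integer(gene_length),
    gene_spacing = as.integer(gene_spacing),
    isoform_split_fraction = isoform_split_fraction,
    n_null_pathways = as.integer(n_null_pathways),
    pathway_size_range = as.integer(pathway_size_range),
    enriched_targets = enriched_targets,
    enriched_size = as.integer(enriched_size),
    ld_min_r2 = ld_min_r2,
    seed = as.integer(seed)), class = "fixture_spec")
}

# Layout of genes and SNPs implied by a spec, plus the latent-block labels
# (after applying cross-gene sharing) that drive both genotypes and
# ld-coupled statistics.
fixture_layout <- function(spec) {
  genes <- list()
  snps <- list()
  latent_counter <- 0L
  for (c_i in seq_len(spec$n_chroms)) {
    chrom <- as.character(c_i)
    share <- with_seed(derive_seed(spec$seed, paste0("share", chrom)), {
      runif(spec$genes_per_chrom - 1L) < spec$cross_gene_ld_fraction
    })
    prev_last_latent <- NA_integer_
    for (g_i in seq_len(spec$genes_per_chrom)) {
      sym <- sprintf("G%s_%03d", chrom, g_i)
      start <- 1000000L + (g_i - 1L) * spec$gene_spacing
      end <- start + spec$gene_length - 1L
      genes[[length(genes) + 1L]] <- tibble::tibble(
        gene_symbol = sym, chrom = chrom, start = start, end = end)
      n_snps_gene <- spec$blocks_per_gene * spec$snps_per_block
      pos <- as.integer(round(seq(start, end, length.out = n_snps_gene)))
      for (b_i in seq_len(spec$blocks_per_gene)) {
        shared <- b_i == 1L && g_i > 1L && isTRUE(share[g_i - 1L]) &&
          !is.na(prev_last_latent)
        if (shared) {
          latent <- prev_last_latent
        } else {
          latent_counter <- latent_counter + 1L
          latent <- latent_counter
        }
        for (s_i in seq_len(spec$snps_per_block)) {
          k <- (b_i - 1L) * spec$snps_per_block + s_i
          snps[[length(snps) + 1L]] <- tibble::tibble(
            snp_id = sprintf("rs%s_%03d_%d_%d", chrom, g_i, b_i, s_i),
            chrom = chrom, pos = pos[k], gene = sym,
            latent_block = latent)
        }
        if (b_i == spec$blocks_per_gene) prev_last_latent <- latent
      }
    }
  }
  list(genes = do.call(rbind, genes), snps = do.call(rbind, snps),
       n_latent = latent_counter)
}

#' Generate LD-structured genotype dosages
#'
#' Realizes a dosage matrix from a [fixture_spec()]: every latent block has
#' two latent binary haplotypes per sample (allele frequency 0.5), and each
#' block SNP copies them with a per-haplotype flip probability calibrated
#' so the expected pairwise dosage r2 within a block equals `within_r2`
#' (for flip probability e, the dosage correlation of two SNPs copying the
#' same latent haplotypes is (1-2e)^4). Between-block dosages are
#' independent. Deterministic per seed.
#'
#' @param spec A [fixture_spec()].
#' @return List: `dosages` (samples x SNPs matrix, SNP ids as column
#'   names), `snps` (tibble: snp_id, chrom, pos, gene, latent_block), and
#'   `genes` (tibble of true gene spans).
#' @export
generate_genotypes <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  lay <- fixture_layout(spec)
  flip <- (1 - spec$within_r2^(1 / 4)) / 2
  n <- spec$n_samples
  with_seed(derive_seed(spec$seed, "genotypes"), {
    hap1 <- matrix(rbinom(n * lay$n_latent, 1L, 0.5), nrow = n)
    hap2 <- matrix(rbinom(n * lay$n_latent, 1L, 0.5), nrow = n)
    dos <- matrix(0L, nrow = n, ncol = nrow(lay$snps),
                  dimnames = list(NULL, lay$snps$snp_id))
    for (j in seq_len(nrow(lay$snps))) {
      lb <- lay$snps$latent_block[j]
      f1 <- rbinom(n, 1L, flip)
      f2 <- rbinom(n, 1L, flip)
      dos[, j] <- xor(hap1[, lb], f1) + xor(hap2[, lb], f2)
    }
    list(dosages = dos, snps = lay$snps, genes = lay$genes)
  })
}

#' Generate null summary statistics
#'
#' In `"ld_coupled"` mode (the default) each latent block receives one
#' standard-normal signal and each SNP's z-value mixes the block signal
#' (weight `sqrt(rho)`) with independent noise, so P-values are marginally
#' uniform but correlated within blocks — the block minimum then behaves
#' like a real LD-shared association signal. `"iid"` mode draws plain
#' uniforms.
#'
#' @param snps SNP tibble from [generate_genotypes()] (needs `snp_id`, and
#'   `latent_block` for the coupled mode).
#' @param mode `"ld_coupled"` or `"iid"`.
#' @param rho Within-block z-correlation weight (default 0.5, matching the
#'   default within-block r2).
#' @param seed Integer seed.
#' @return Named numeric vector of P-values in (0, 1).
#' @export
generate_null_stats <- function(snps, mode = c("ld_coupled", "iid"),
                                rho = 0.5, seed = 1L) {
  mode <- match.arg(mode)
  with_seed(seed, {
    if (mode == "iid") {
      p <- runif(nrow(snps))
    } else {
      blocks <- unique(snps$latent_block)
      zb <- stats::setNames(rnorm(length(blocks)), blocks)
      z <- sqrt(rho) * zb[as.character(snps$latent_block)] +
        sqrt(1 - rho) * rnorm(nrow(snps))
      p <- pchisq(z^2, df = 1, lower.tail = FALSE)
    }
    p <- pmin(pmax(p, 1e-300), 1)
    stats::setNames(as.numeric(p), snps$snp_id)
  })
}

#' Overlay enriched signals on null statistics
#'
#' SNPs belonging to enriched pathways are redrawn from a mixture: with
#' probability equal to the pathway's target fraction the P-value comes
#' from a component concentrated below `snp_alpha` (`snp_alpha * u^2`,
#' denser near zero), otherwise from Uniform(`snp_alpha`, 1). All other
#' SNPs keep their null values.
#'
#' @param null_p Named P-value vector from [generate_null_stats()].
#' @param pathway_snp_sets Named list: enriched pathway id -> SNP ids.
#' @param targets Named numeric vector: pathway id -> target significant
#'   fraction in (0, 1).
#' @param snp_alpha Per-SNP significance cutoff (default 0.05).
#' @param seed Integer seed.
#' @return Named P-value vector of the same length as `null_p`.
#' @export
generate_enriched_stats <- function(null_p, pathway_snp_sets, targets,
                                    snp_alpha = 0.05, seed = 1L) {
  stopifnot(all(names(targets) %in% names(pathway_snp_sets)))
  # conflicting targets on overlapping pathways are ambiguous
  if (length(targets) > 1) {
    ids <- names(targets)
    for (i in seq_along(ids)[-1]) for (j in seq_len(i - 1)) {
      shared <- intersect(pathway_snp_sets[[ids[i]]],
                          pathway_snp_sets[[ids[j]]])
      if (length(shared) && targets[ids[i]] != targets[ids[j]])
        stop("enriched pathways ", ids[j], " and ", ids[i],
             " overlap but request different targets")
    }
  }
  out <- null_p
  with_seed(seed, {
    for (pid in names(targets)) {
      ids <- intersect(pathway_snp_sets[[pid]], names(out))
      hit <- runif(length(ids)) < targets[[pid]]
      p <- numeric(length(ids))
      p[hit] <- snp_alpha * runif(sum(hit))^2
      p[!hit] <- runif(sum(!hit), snp_alpha, 1)
      out[ids] <- pmax(p, 1e-300)
    }
  })
  out
}

#' Generate a complete in-memory fixture
#'
#' Runs the whole generator: genotypes and positions, isoform rows (a
#' fraction of genes split into two overlapping isoforms), a pathway
#' collection (null pathways with log-uniform sizes plus any enriched
#' pathways), an `ld_source` computed from the dosages, and summary
#' statistics (ld-coupled null, with enriched overlays where requested).
#'
#' @param spec A [fixture_spec()].
#' @return List: `snps` (summary-statistics tibble), `isoforms`,
#'   `pathways` (named list; enriched ids carry their targets in the
#'   `truth`), `ld`, `dosages`, `snp_table` (with latent-block truth), and
#'   `truth` (latent blocks, enriched ids and targets).
#' @export
generate_fixture <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  geno <- generate_genotypes(spec)
  gene_pool <- geno$genes$gene_symbol

  # isoform rows: some genes split into two overlapping isoforms
  iso <- with_seed(derive_seed(spec$seed, "isoforms"), {
    rows <- list()
    for (i in seq_len(nrow(geno$genes))) {
      g <- geno$genes[i, ]
      strand <- if (i %% 2L) "+" else "-"
      if (runif(1) < spec$isoform_split_fraction) {
        cut1 <- g$start + as.integer(0.6 * (g$end - g$start))
        cut2 <- g$start + as.integer(0.4 * (g$end - g$start))
        rows[[length(rows) + 1L]] <- tibble::tibble(
          gene_symbol = g$gene_symbol, chrom = g$chrom, strand = strand,
          tx_start = c(g$start, cut2), tx_end = c(cut1, g$end))
      } else {
        rows[[length(rows) + 1L]] <- tibble::tibble(
          gene_symbol = g$gene_symbol, chrom = g$chrom, strand = strand,
          tx_start = g$start, tx_end = g$end)
      }
    }
    do.call(rbind, rows)
  })

  # pathway collection
  hi <- min(max(spec$pathway_size_range), length(gene_pool))
  lo <- min(spec$pathway_size_range)
  sizes <- draw_pathway_sizes(spec$n_null_pathways, lo, hi,
                              derive_seed(spec$seed, "pathway_sizes"))
  pathways <- random_pathways(gene_pool, sizes,
                              seed = derive_seed(spec$seed, "pathways"))
  names(pathways) <- sprintf("null_%04d", seq_along(pathways))
  enriched_ids <- names(spec$enriched_targets)
  if (length(enriched_ids)) {
    enr <- with_seed(derive_seed(spec$seed, "enriched_pathways"), {
      lapply(enriched_ids, function(id)
        sample(gene_pool, min(spec$enriched_size, length(gene_pool))))
    })
    names(enr) <- enriched_ids
    pathways <- c(enr, pathways)
  }

  ld <- ld_from_genotypes(geno$dosages, colnames(geno$dosages),
                          min_r2 = spec$ld_min_r2)

  pvals <- generate_null_stats(geno$snps, mode = "ld_coupled",
                               rho = spec$within_r2,
                               seed = derive_seed(spec$seed, "stats"))
  if (length(enriched_ids)) {
    gene_snp_sets <- split(geno$snps$snp_id, geno$snps$gene)
    psets <- lapply(pathways[enriched_ids], function(g)
      unique(unlist(gene_snp_sets[intersect(g, names(gene_snp_sets))],
                    use.names = FALSE)))
    pvals <- generate_enriched_stats(pvals, psets, spec$enriched_targets,
                                     seed = derive_seed(spec$seed,
                                                        "enrichment"))
  }

  snps <- tibble::tibble(snp_id = geno$snps$snp_id,
                         chrom = geno$snps$chrom, pos = geno$snps$pos,
                         pvalue = unname(pvals[geno$snps$snp_id]))
  list(snps = snps, isoforms = iso, pathways = pathways, ld = ld,
       dosages = geno$dosages, snp_table = geno$snps,
       truth = list(latent_blocks = stats::setNames(geno$snps$latent_block,
                                                    geno$snps$snp_id),
                    enriched = spec$enriched_targets,
                    spec_seed = spec$seed))
}

#' Write a fixture to disk in the package's external formats
#'
#' Emits the summary-statistics TSV, gene annotation table, GMT pathway
#' file, PLINK-style `.ld` pair list, dosage matrix (TSV, SNP-id header)
#' and a ground-truth JSON (latent block per SNP, enriched pathway
#' targets), all in the exact dialects the readers in this package parse —
#' so integration tests exercise the real parsers.
#'
#' @param fixture A fixture from [generate_fixture()].
#' @param dir Output directory (created if missing).
#' @return Named character vector of the written paths, invisibly.
#' @export
write_fixture <- function(fixture, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(
    summary = file.path(dir, "summary_stats.tsv"),
    genes = file.path(dir, "genes.tsv"),
    gmt = file.path(dir, "pathways.gmt"),
    ld = file.path(dir, "pairs.ld"),
    dosages = file.path(dir, "dosages.tsv"),
    truth = file.path(dir, "truth.json"))
  write_summary_stats(fixture$snps, paths[["summary"]])
  write_gene_table(fixture$isoforms, paths[["genes"]])
  write_gmt(fixture$pathways, paths[["gmt"]])
  write_ld_pairs(fixture$ld, paths[["ld"]])
  data.table::fwrite(data.table::as.data.table(fixture$dosages),
                     paths[["dosages"]], sep = "\t", quote = FALSE)
  jsonlite::write_json(
    list(latent_blocks = as.list(fixture$truth$latent_blocks),
         enriched = as.list(fixture$truth$enriched),
         spec_seed = fixture$truth$spec_seed),
    paths[["truth"]], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
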