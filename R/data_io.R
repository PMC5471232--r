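# Readers/writers for the external formats, normalising everything into the
# in-memory types the rest of the package works with:
#   - summary stats  -> tibble (snp_id, chrom, pos, pvalue)
#   - gene models    -> tibble of isoform rows (gene_symbol, chrom, strand,
#                       tx_start, tx_end); 1-based closed intervals
#   - pathways       -> named list of character vectors (GMT)
#   - pairwise LD    -> "ld_source" object (symmetric r2 lookup)

#' Read GWAS summary statistics
#'
#' Reads a delimited (tab or whitespace) text file with a header row holding
#' at least chromosome, SNP identifier, base-pair position and P-value
#' columns. Column names are resolved through `column_map`, so any dialect
#' with those four fields can be loaded.
#'
#' @param path Path to the summary-statistics file.
#' @param column_map Named character vector mapping the internal field names
#'   `chrom`, `snp`, `pos`, `p` to the column names used in the file.
#' @param p_zero How to treat P-values of exactly zero: `"error"` rejects the
#'   record (default), `"clamp"` replaces it with `p_floor`. The chi-square
#'   conversion diverges at zero, so a zero must not pass through unchanged.
#' @param p_floor Replacement value used when `p_zero = "clamp"`.
#'
#' @return A tibble with columns `snp_id`, `chrom` (normalized: no "chr"
#'   prefix, uppercase X/Y), `pos` (1-based integer) and `pvalue` in (0, 1].
#' @export
read_summary_stats <- function(path,
                               column_map = c(chrom = "CHR", snp = "SNP",
                                              pos = "BP", p = "P"),
                               p_zero = c("error", "clamp"),
                               p_floor = 1e-300) {
  p_zero <- match.arg(p_zero)
  need <- c("chrom", "snp", "pos", "p")
  if (!all(need %in% names(column_map)))
    stop("column_map must name columns for: ", paste(need, collapse = ", "))
  dt <- data.table::fread(path, header = TRUE, colClasses = list(
    character = column_map[["snp"]]))
  missing_cols <- setdiff(unname(column_map[need]), names(dt))
  if (length(missing_cols))
    stop("summary-statistics file lacks required column(s): ",
         paste(missing_cols, collapse = ", "))
  out <- tibble::tibble(
    snp_id = as.character(dt[[column_map[["snp"]]]]),
    chrom  = normalize_chrom(dt[[column_map[["chrom"]]]]),
    pos    = dt[[column_map[["pos"]]]],
    pvalue = dt[[column_map[["p"]]]]
  )
  line_no <- seq_len(nrow(out)) + 1L  # header is line 1

  pos_num <- suppressWarnings(as.numeric(out$pos))
  bad <- which(!is.finite(pos_num) | pos_num < 1 | pos_num != round(pos_num))
  if (length(bad))
    stop("invalid base-pair position at line ", bad[1] + 1L)
  out$pos <- as.integer(pos_num)

  p_num <- suppressWarnings(as.numeric(out$pvalue))
  bad <- which(!is.finite(p_num) | p_num < 0 | p_num > 1)
  if (length(bad))
    stop("non-numeric or out-of-range P-value at line ", line_no[bad[1]],
         " (", out$pvalue[bad[1]], ")")
  zero <- which(p_num == 0)
  if (length(zero)) {
    if (p_zero == "error")
      stop("P-value of 0 at line ", line_no[zero[1]],
           "; use p_zero = \"clamp\" to replace with p_floor")
    p_num[zero] <- p_floor
  }
  out$pvalue <- p_num

  dup <- out$snp_id[duplicated(out$snp_id)]
  if (length(dup))
    stop("duplicate SNP id(s) in summary statistics: ",
         paste(unique(head(dup, 5)), collapse = ", "))
  out
}

#' Write GWAS summary statistics
#'
#' Writes the package's summary-statistics tibble back to a tab-delimited
#' file with the default CHR/SNP/BP/P header. P-values are written at full
#' double precision so that a write/read round trip is exact.
#'
#' @param snps Tibble as returned by [read_summary_stats()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_summary_stats <- function(snps, path) {
  dt <- data.table::data.table(CHR = snps$chrom, SNP = snps$snp_id,
                               BP = snps$pos,
                               P = formatC(snps$pvalue, digits = 17,
                                           format = "g"))
  data.table::fwrite(dt, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' Read a GMT gene-set file
#'
#' One set per line: `id<TAB>description<TAB>gene1<TAB>gene2...`. Duplicate
#' gene symbols within a line are dropped; lines with an empty gene list are
#' skipped with a warning.
#'
#' @param path Path to the GMT file.
#' @return A named list of character vectors of gene symbols; the
#'   `"description"` attribute on each element carries the second field.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  out <- list()
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3) {
      stop("GMT line ", i, " has fewer than 3 tab-separated fields")
    }
    id <- fields[1]
    genes <- unique(fields[-(1:2)])
    genes <- genes[nzchar(genes)]
    if (!length(genes)) {
      warning("GMT line ", i, " (", id, ") has an empty gene list; skipped")
      next
    }
    if (id %in% names(out))
      stop("duplicate pathway id in GMT: ", id)
    attr(genes, "description") <- fields[2]
    out[[id]] <- genes
  }
  out
}

#' Write a GMT gene-set file
#'
#' @param pathways Named list of character vectors of gene symbols.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(pathways, path) {
  lines <- vapply(names(pathways), function(id) {
    desc <- attr(pathways[[id]], "description") %||% id
    paste(c(id, desc, pathways[[id]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Read a gene annotation table
#'
#' Reads isoform rows from either a RefSeq-flat-like delimited table with a
#' header (`geneSymbol`, `chrom`, `strand`, `txStart`, `txEnd`; extra columns
#' ignored) or BED6 (no header; gene symbol in the name field). BED's 0-based
#' half-open coordinates are converted to the 1-based closed convention used
#' throughout the package. A gene may contribute several isoform rows.
#'
#' @param path Path to the annotation file.
#' @param format `"refflat"` (default) or `"bed"`.
#' @return A tibble with columns `gene_symbol`, `chrom`, `strand`,
#'   `tx_start`, `tx_end`.
#' @export
read_gene_table <- function(path, format = c("refflat", "bed")) {
  format <- match.arg(format)
  if (format == "refflat") {
    dt <- data.table::fread(path, header = TRUE)
    need <- c("geneSymbol", "chrom", "strand", "txStart", "txEnd")
    missing_cols <- setdiff(need, names(dt))
    if (length(missing_cols))
      stop("gene table lacks required column(s): ",
           paste(missing_cols, collapse = ", "))
    out <- tibble::tibble(
      gene_symbol = as.character(dt$geneSymbol),
      chrom = normalize_chrom(dt$chrom),
      strand = as.character(dt$strand),
      tx_start = as.integer(dt$txStart),
      tx_end = as.integer(dt$txEnd)
    )
  } else {
    dt <- data.table::fread(path, header = FALSE)
    if (ncol(dt) < 6)
      stop("BED gene input requires 6 columns (chrom, start, end, name, ",
           "score, strand)")
    out <- tibble::tibble(
      gene_symbol = as.character(dt[[4]]),
      chrom = normalize_chrom(dt[[1]]),
      strand = as.character(dt[[6]]),
      tx_start = as.integer(dt[[2]]) + 1L,  # 0-based half-open -> 1-based closed
      tx_end = as.integer(dt[[3]])
    )
  }
  if (!all(out$strand %in% c("+", "-")))
    stop("strand must be '+' or '-'")
  bad <- which(out$tx_start > out$tx_end)
  if (length(bad))
    stop("tx_start > tx_end for gene ", out$gene_symbol[bad[1]])
  out
}

#' Write a gene annotation table (RefSeq-flat-like)
#'
#' @param genes Tibble of isoform rows as returned by [read_gene_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_table <- function(genes, path) {
  dt <- data.table::data.table(geneSymbol = genes$gene_symbol,
                               chrom = genes$chrom, strand = genes$strand,
                               txStart = genes$tx_start, txEnd = genes$tx_end)
  data.table::fwrite(dt, path, sep = "\t", quote = FALSE)
  invisible(path)
}

# ---------------------------------------------------------------------------
# LD source: symmetric pairwise r2 lookup

# Construct an ld_source from a canonical pair table. Pairs are stored once
# with snp_a < snp_b (lexicographic); absent pairs query as r2 = 0.
new_ld_source <- function(pairs) {
  stopifnot(all(c("snp_a", "snp_b", "r2") %in% names(pairs)))
  dt <- data.table::as.data.table(pairs)[, c("snp_a", "snp_b", "r2")]
  swap <- dt$snp_a > dt$snp_b
  if (any(swap)) {
    tmp <- dt$snp_a[swap]
    dt$snp_a[swap] <- dt$snp_b[swap]
    dt$snp_b[swap] <- tmp
  }
  dt <- dt[dt$snp_a != dt$snp_b, ]
  if (anyDuplicated(dt, by = c("snp_a", "snp_b"))) {
    dt <- dt[, list(r2 = max(r2)), by = c("snp_a", "snp_b")]
  }
  data.table::setkeyv(dt, c("snp_a", "snp_b"))
  structure(list(pairs = dt), class = "ld_source")
}

#' @export
print.ld_source <- function(x, ...) {
  cat("<ld_source> ", nrow(x$pairs), " stored SNP pairs, ",
      length(unique(c(x$pairs$snp_a, x$pairs$snp_b))), " SNPs\n", sep = "")
  invisible(x)
}

#' Read a PLINK-style pairwise LD file
#'
#' Expects a whitespace/tab-delimited file whose header contains at least
#' `SNP_A`, `SNP_B` and `R2` (extra columns such as CHR_A/BP_A are ignored).
#' Pairs absent from the file query as r2 = 0, matching the convention that
#' below-threshold pairs are omitted from such lists. Conflicting duplicate
#' pairs keep the maximum r2 with a warning.
#'
#' @param path Path to the `.ld`-style pair list.
#' @return An `ld_source` object; query it with [ld_r2()].
#' @export
read_ld_pairs <- function(path) {
  dt <- data.table::fread(path, header = TRUE)
  need <- c("SNP_A", "SNP_B", "R2")
  missing_cols <- setdiff(need, names(dt))
  if (length(missing_cols))
    stop("LD pair file lacks required column(s): ",
         paste(missing_cols, collapse = ", "))
  r2 <- as.numeric(dt$R2)
  bad <- which(!is.finite(r2) | r2 < 0 | r2 > 1)
  if (length(bad))
    stop("R2 outside [0,1] at data line ", bad[1], " (", dt$R2[bad[1]], ")")
  pairs <- data.table::data.table(snp_a = as.character(dt$SNP_A),
                                  snp_b = as.character(dt$SNP_B), r2 = r2)
  swap <- pairs$snp_a > pairs$snp_b
  if (any(swap)) {
    tmp <- pairs$snp_a[swap]
    pairs$snp_a[swap] <- pairs$snp_b[swap]
    pairs$snp_b[swap] <- tmp
  }
  if (anyDuplicated(pairs, by = c("snp_a", "snp_b")))
    warning("duplicate SNP pairs with conflicting r2; keeping the maximum")
  new_ld_source(pairs)
}

#' Write a PLINK-style pairwise LD file
#'
#' @param ld An `ld_source`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ld_pairs <- function(ld, path) {
  dt <- data.table::data.table(SNP_A = ld$pairs$snp_a,
                               SNP_B = ld$pairs$snp_b,
                               R2 = formatC(ld$pairs$r2, digits = 17,
                                            format = "g"))
  data.table::fwrite(dt, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' Pairwise r-squared from a genotype dosage matrix
#'
#' Computes r2 as the squared Pearson correlation of dosage columns — the
#' standard deterministic approximation when phased haplotypes are not
#' available — and stores all non-zero pairs in an `ld_source`. A constant
#' dosage column has no defined correlation; its pairs are set to r2 = 0
#' with a warning.
#'
#' @param dosages Numeric matrix, samples in rows, SNPs in columns; values
#'   in \[0, 2\].
#' @param snp_ids Character vector of SNP ids, one per column.
#' @param min_r2 Pairs with r2 below this are not stored (they query as 0
#'   anyway); default `1e-8` drops numerically-zero correlations.
#' @return An `ld_source` object.
#' @export
ld_from_genotypes <- function(dosages, snp_ids = colnames(dosages),
                              min_r2 = 1e-8) {
  dosages <- as.matrix(dosages)
  if (is.null(snp_ids) || length(snp_ids) != ncol(dosages))
    stop("snp_ids must name every dosage column")
  if (nrow(dosages) < 2) stop("need at least 2 samples to estimate r2")
  sds <- apply(dosages, 2, stats::sd)
  if (any(sds == 0))
    warning("constant dosage column(s): ",
            paste(head(snp_ids[sds == 0], 5), collapse = ", "),
            "; their r2 is defined as 0")
  keep <- sds > 0
  r2m <- matrix(0, ncol(dosages), ncol(dosages))
  if (sum(keep) >= 2) {
    cc <- suppressWarnings(cor(dosages[, keep, drop = FALSE]))
    r2m[keep, keep] <- pmin(pmax(cc^2, 0), 1)
  }
  idx <- which(upper.tri(r2m) & r2m > min_r2, arr.ind = TRUE)
  pairs <- data.table::data.table(snp_a = snp_ids[idx[, 1]],
                                  snp_b = snp_ids[idx[, 2]],
                                  r2 = r2m[idx])
  new_ld_source(pairs)
}

#' Query pairwise r-squared
#'
#' Vectorized symmetric lookup; any pair not stored in the source (including
#' unknown SNPs) returns 0, and `ld_r2(ld, a, a)` returns 1.
#'
#' @param ld An `ld_source`.
#' @param a,b Character vectors of SNP ids (recycled to common length).
#' @return Numeric vector of r2 values in \[0, 1\].
#' @export
ld_r2 <- function(ld, a, b) {
  stopifnot(inherits(ld, "ld_source"))
  n <- max(length(a), length(b))
  a <- rep_len(as.character(a), n)
  b <- rep_len(as.character(b), n)
  lo <- pmin(a, b)
  hi <- pmax(a, b)
  q <- data.table::data.table(snp_a = lo, snp_b = hi)
  hit <- ld$pairs[q, on = c("snp_a", "snp_b")]$r2
  out <- ifelse(is.na(hit), 0, hit)
  out[a == b] <- 1
  out
}

# All stored pairs among `snp_ids` with r2 strictly above `threshold`.
# Internal: used by the blocking module.
ld_edges <- function(ld, snp_ids, threshold) {
  dt <- ld$pairs
  sel <- dt$snp_a %in% snp_ids & dt$snp_b %in% snp_ids & dt$r2 > threshold
  dt[sel, ]
}
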