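# Internal helpers shared across modules.

#' @importFrom stats cor pchisq qchisq runif rnorm pnorm rbinom qnorm
#' @importFrom utils head
#' @importFrom data.table data.table as.data.table setkeyv fread fwrite :=
NULL

# Stable 32-bit polynomial hash of a string, for deriving per-pathway RNG
# substreams that do not depend on iteration order.
str_hash31 <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  m <- 2147483647  # 2^31 - 1
  h <- 0
  for (code in utf8ToInt(x)) {
    h <- (h * 31 + code) %% m
  }
  as.integer(h)
}

# Derive a deterministic substream seed from a master seed and a label.
derive_seed <- function(master_seed, label) {
  m <- 2147483647
  as.integer((as.numeric(master_seed) %% m + str_hash31(label)) %% m)
}

# Evaluate `expr` under a local RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards so package functions do not perturb the
# session's random stream.
with_seed <- function(seed, expr) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  expr
}

# Normalize chromosome labels: strip a leading "chr", uppercase X/Y.
# Unplaced contigs and mitochondrial labels pass through verbatim.
normalize_chrom <- function(chrom) {
  chrom <- sub("^[Cc][Hh][Rr]", "", as.character(chrom))
  ifelse(toupper(chrom) %in% c("X", "Y"), toupper(chrom), chrom)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
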