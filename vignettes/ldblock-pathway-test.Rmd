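---
title: "LD-block pathway association testing: model, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{LD-block pathway association testing: model, choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pathblocks)
```

## The problem

Pathway tests on GWAS summary statistics ask whether the SNPs mapping to
a set of functionally related genes are collectively more associated with
a trait than chance allows. The obstacle is linkage disequilibrium: a
single causal signal is echoed by every SNP correlated with it, so
pathways (and especially large pathways) containing LD clumps of small
P-values look spuriously strong if SNPs are treated as independent.

`pathblocks` neutralizes this redundancy by making the *LD block*, not
the SNP, the unit of evidence, and by calibrating significance against a
permutation null built with exactly the same redundancy.

## The procedure and its assumptions

**Mapping.** Isoform rows are merged per gene: intervals sharing at least
one base pair are unioned. Strictly disjoint isoform clusters of one gene
are resolved by keeping the cluster whose flanked window contains the
lowest-P SNP — the cluster that actually carries the association signal —
falling back to the longest (then leftmost) cluster when no window holds
a SNP. SNPs are assigned within a symmetric flank around the merged span.
Strand is ignored: the upstream and downstream extensions are equal, so
orientation cannot change the window. Coordinates are 1-based closed
intervals everywhere; BED input is converted on read.

**Blocking.** Within a pathway's SNP set, any pair with r² strictly above
the threshold is linked, and blocks are the connected components of that
graph (single-linkage, hence transitive). Pairwise r² with a grouping
criterion most naturally yields transitive closure; the rule is isolated
behind `block_snps()` so an alternative clustering could be swapped in.
Three supporting conventions: pairs absent from the LD source count as
r² = 0 (PLINK-style pair lists omit below-threshold pairs); SNPs missing
from the LD reference become singleton blocks rather than being dropped
(absence is lack of evidence, not evidence of redundancy); and edges
between chromosomes are zeroed before clustering, because LD is
intra-chromosomal and trans correlations in a finite reference panel are
noise. No physical-distance window is imposed — locality is whatever the
LD input encodes.

**Scoring.** Each block contributes the upper-tail χ²(1 df) quantile of
its minimum P-value, and the pathway score S_obs is the block sum. Taking
the block minimum without a within-block multiplicity adjustment biases
every block statistic upward; this is deliberate. The permutation pool is
built by the identical procedure, so the bias is present in the null
exactly as in the observed score, and only the *excess* of S_obs over
same-sized pool samples is interpreted as association. For the same
reason no analytic χ²(n) P-value is offered: the pool's min-P statistics
are stochastically larger than χ²(1), and an analytic null would be
anti-conservative.

**Permutation.** The pool concatenates the block statistics of all
analyzed pathways, duplicates kept — a block reached by several pathways
appears once per pathway, so the pool is frequency-weighted the way a
random pathway draw would be. Each permutation draws `n_blocks` values
*without replacement* (a pathway cannot contain the same block twice);
independent permutations redraw freely. A `replace = TRUE` switch covers
the corner case of a pathway with more blocks than the pool. The
association P-value uses the add-one estimator (x+1)/(N+1): it can never
return zero, and it is the standard conservative choice for Monte-Carlo
tests. Exceedance is `S_perm >= S_obs`.

**Adaptive schedule.** Permutations run in cumulative stages (default
10³, 10⁴, 10⁵, 10⁶) and stop once the interim estimate exceeds 0.05.
Checking only at stage boundaries, not per draw, keeps the estimator
unbiased — sequential per-draw stopping would condition on the running
count. At these stage sizes, a pathway whose true P-value is below half
the stopping threshold has a vanishing chance of an interim estimate
above it, so early stopping effectively never truncates a significant
pathway.

**Determinism.** One master seed; each pathway's permutation stream is
derived by a stable string hash of its id. Results are therefore
identical across runs, iteration orders and (hypothetically) parallel
execution, and package functions restore the caller's RNG state.

## Tunable parameters

| parameter | default | units | why |
|---|---|---|---|
| `flank` | 15,000 | bp | window within which the large majority of eQTL variants fall |
| `r2_threshold` | 0.1 | r² | conventional low-LD boundary; strict (`>`) comparison |
| `scope` | `"pathway"` | — | `"gene"` blocks within genes only, to expose the cost of ignoring cross-gene LD |
| `min_genes`, `max_genes` | 5, 300 | genes | below 5 a set test adds nothing; above 300 annotation sets are too generic |
| `schedule` | 10³…10⁶ | permutations | floor P of 1/(10⁶+1) with cheap early exits |
| `alpha_stop` | 0.05 | P | interim threshold above which further sampling cannot change conclusions |
| `bin_cutpoints` | 10/17/37 | genes | reference quartile bounds giving bins [5,9], [10,16], [17,36], [37,300]; empirical quartiles available |

Pathway size is counted *after* intersecting with mappable genes:
symbols absent from the annotation cannot contribute SNPs, and counting
them would distort the 5–300 filter.

## Numerical choices and degenerate inputs

- P = 0 diverges under the χ² transform; loaders reject it by default or
  clamp to 1e-300 on request, and `chi2_from_p()` evaluates through the
  log-scale tail so clamped values stay finite.
- Representative-SNP ties (equal minimum P) break by lexicographic SNP
  id; ranked outputs break P-value ties by pathway id. Both make results
  platform-independent.
- Duplicate LD pairs keep the maximum r² with a warning; r² outside
  [0, 1] is a hard error; a constant dosage column has undefined
  correlation and is defined to r² = 0 with a warning.
- Pathways whose genes carry no SNPs are reported as non-testable rather
  than silently dropped; an empty blocking input returns an empty block
  table.
- The enrichment factor uses k = ceiling(target·n) and shrinks
  `snp_alpha / p_(k)` by a relative 1e-9 so the k-th order statistic
  lands strictly below the cutoff; scaled P-values are capped at 1. The
  factor may exceed 1 when a pathway must be de-enriched down to the
  target.

## The simulation designs

**Type I error.** Pathways are assembled by randomly assigning genes:
gene–SNP contents and LD are untouched, only the biological grouping is
broken, so every such pathway is null while retaining realistic internal
correlation. The rate of association P < α, overall and within size
bins, is the empirical type I error, with exact binomial intervals.
Because sampling without replacement from a finite block pool is
slightly conservative for pathways covering much of that pool — and
because a real pathway's blocks are more internally correlated than
independent pool draws — rates at α = 0.05 typically land somewhat
*below* α, in the low single-digit percent range, flat across size bins;
that stability across sizes is the property the design is meant to
check. `type1_error()` takes either an explicit size vector (e.g. the
empirical sizes of a real collection) or draws sizes log-uniformly so
all four bins are populated.

**Power.** Each pathway's SNP P-values are multiplied by one factor so a
fixed percentage becomes significant, equalizing "how enriched" pathways
are regardless of size; the pathway is re-scored (blocks are unchanged —
blocking depends only on LD) and tested against the *unscaled* pool.
Scaling the pool too would leave relative ranks untouched and destroy
the experiment, so scaling is pathway-local by design. Power is the
fraction detected at α = 0.05 and is non-decreasing in the target
fraction.

## The synthetic fixtures

`generate_fixture()` emulates the statistical structure the method
relies on, not human genetics: genes laid out along chromosomes with
non-overlapping ±15 kb windows; each gene a few LD blocks; each block a
latent biallelic signal copied into its SNPs with flip noise calibrated
so the expected within-block dosage r² matches the declared value
(dosage correlation (1−2e)⁴ for flip probability e); an optional
fraction of adjacent gene pairs sharing a block, which is what separates
pathway-scope from gene-scope behaviour; and null statistics that are
marginally uniform but share a per-block signal (`ld_coupled`), so block
minima behave like real LD-shared associations. Fixtures are written in
exactly the dialects the readers parse, so integration tests exercise
the real parsers end to end.

What the fixtures do *not* emulate: allele-frequency spectra, LD decay
with distance, haplotype structure from demography, overlapping genes,
or annotation errors. Passing tests therefore demonstrate the method's
internal correctness and calibration under stylized block LD, not
performance on any particular real cohort.

Problem sizes used by the packaged checks (the package's own choices):
calibration and scope comparisons use fixtures of 30–200 genes with
10⁴-stage permutation schedules and 150–1,000 random pathways; oracle
equivalence uses pools of ≤ 8 blocks with exhaustive enumeration and 200
random ≤ 50-SNP matrices against a Warshall transitive-closure oracle;
end-to-end recovery uses 20 seeds of a 100-gene fixture with one
pathway enriched to an 80% significant-SNP fraction.

## Known limitations

- r² from dosages is the squared Pearson correlation; haplotype-phase
  (EM) r² is not implemented, so values can differ slightly from
  phased-panel outputs.
- Single-linkage blocking can chain weakly linked SNPs through
  intermediates; the rule is the package's reading of a pairwise r²
  grouping criterion and is swappable behind `block_snps()`.
- Gene symbols must match between annotation and GMT; no alias
  resolution is attempted.
- In gene scope, a SNP inside two overlapping member genes contributes
  to both genes' blocks (flagged in the block table); whether to
  deduplicate is genuinely ambiguous and the duplicated reading matches
  per-gene blocking.
- The permutation pool is rebuilt per configuration; scores from one
  scope or threshold are never compared against another's pool.

## A minimal run

```{r, eval = FALSE}
fx <- generate_fixture(fixture_spec(seed = 1))
res <- run_pathway_test(fx$snps, fx$isoforms, fx$pathways, fx$ld,
                        schedule = c(1e3, 1e4), seed = 1)
head(res)
```
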