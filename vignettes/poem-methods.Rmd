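---
title: "Mapping pairwise additive eQTL effects on expression modules"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping pairwise additive eQTL effects on expression modules}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(poemr)
```

## The problem

In a panel of genotyped homozygous recombinant inbred strains (or haploid
individuals), the expression of a gene under a stimulus — an *expression
trait* — may be controlled jointly by two loci whose effects simply add.
Single-trait stepwise mappers can in principle find such pairs, but
trans-acting effects are individually weak, and methods that search gene
*modules* for joint effects have concentrated on epistatic (allele-specific)
interactions. `poemr` implements an iterative, residual-based modularization
method for the additive case: it finds *poeModules* — groups of traits
governed by one specific pair of eQTLs — together with the pair itself.

## Models and tests

**One-locus scan.** For trait $y_j$ ($n$ individuals) and variant $g_x$
coded $-1/+1$, the fixed-effect model is

$$y_j = \mu + g_x \beta_x + e, \qquad e \sim N(0, \sigma^2 I),$$

and the association score is $-\log_{10} P$ of the ANOVA F-test of
$\beta_x = 0$ on $(1, n-2)$ degrees of freedom (equivalently, a two-group
ANOVA between the allele classes). Scores are stored so that a trait's best
eQTL is the arg-max of its row in the $l \times m$ association matrix.

**Conditioned scan.** Given an eQTL map (one variant per mapped trait), each
mapped trait is replaced by the residuals of its one-locus fit,
$r_j = y_j - \hat\mu - g_v \hat\beta$, with $(\hat\mu, \hat\beta)$
re-estimated from the full data at every call so that iterations never
accumulate stale fits; unmapped traits pass through unchanged. Scanning the
residuals reveals a *secondary* locus after the *primary* one is removed —
the additive-model assumption that makes residual-based stepwise regression
(RBSR) appropriate here.

**Two-locus interaction test.** For a trait in a module with loci
$(v_1, v_2)$,

$$y = \mu + g_{v_1}\beta_1 + g_{v_2}\beta_2 + (g_{v_1} g_{v_2})\,
\beta_{12} + e,$$

and the epistasis score is the F-test P-value for $\beta_{12} \ne 0$ on
$(1, n-4)$ degrees of freedom. A design whose interaction column is
collinear with the main effects returns $P = 1$ with a flag.

## Co-association groups

A *co-association group* is a set of traits jointly associated with one
representative variant; the group score is $-\log_{10}$ of the *median*
association P of the members to the representative. Groups are built
agglomeratively from singletons (each gated trait with its best variant) by
greedy best-first merging. A merge of two groups is admissible when:

1. the merged score (median member score at the best candidate
   representative) clears the significance cutoff (default $P = 0.01$);
2. **every** member of the merged group is associated with the new
   representative above the cutoff;
3. the merged score is not below the weaker parent's score; and
4. candidate representatives are drawn from the *higher-scoring* parent's
   side — its representative, or, when variant coordinates are available,
   all variants within `window_bp` of it on the same chromosome (default
   2 Mbp, the scale of recombinant-inbred linkage blocks). With
   coordinates, two groups may merge only if their representatives are
   within the window; without coordinates (unlinked synthetic variants)
   any two groups may attempt a merge.

Rules 2–4 were driven by failure analysis during development. The median
alone has a 50% breakdown point: a strong group could absorb unrelated
traits one at a time without its median dropping below the gate (rule 2
stops this), and — more subtly — a chance-correlated proxy variant proposed
by a weak partner could "take over" a strong group's representative while
still passing the member gate at a permissive cutoff (rule 4 stops this:
an established group's locus wins). Rule 3 guarantees merge quality never
collapses. Ties in merge order, representative choice, and arg-max are all
broken toward the lowest variant index, so grouping is deterministic.

Groups induce a revised eQTL map in which every member trait is assigned
the group's representative. This is the grouping "rescue": a trait whose
own best-scoring variant was a noise variant is still mapped to the locus
its group supports, which is where the modularization gains power over
single-trait stepwise mapping.

## The iterative algorithm

Initialization runs a plain scan and groups it into primary groups. Each
iteration then (stage 2) scans residuals conditioned on the primary map to
learn secondary groups, and (stage 1, between iterations) re-learns primary
groups conditioned on the secondary map, always using the most recent map
(Gauss–Seidel style). `k = 1` is the non-iterative variant — exactly two
sequential scans, which at the single-trait level reduces to RBSR. The
default `k = 6` follows standard practice for this method; the fit records
group and trait counts after every stage in an iteration trace.

## poeModules

Every (primary group, secondary group) pair with *distinct* representatives
is tested for trait overlap with the one-sided hypergeometric upper tail
over all $l$ traits. For a symmetric additive pair the primary/secondary
roles are arbitrary — the stepwise order merely reflects which locus a
trait's scan happened to find first — so the two mirrored role assignments
of the same unordered variant pair are consolidated into one module: trait
set = union of the ordered intersections, overlap P = the smaller ordered
test, orientation from the more significant one. Without consolidation a
collection of dual-effect traits splits roughly binomially between the two
mirrored modules and no single module represents the pair.

Modules of exactly two traits must pass $P < 10^{-6}$, larger modules
$P < 10^{-3}$ (permissive grouping, stringent overlap). Modules whose trait
set is a strict subset of another's are removed; identical trait sets keep
the smaller overlap P. Surviving modules are classified *epistatic* if any
member trait has an interaction-test FDR q (Benjamini–Hochberg, pooled over
all module traits) below 0.01, and otherwise *additive*; with gene
locations available, a locus within 10 Mbp of a trait's gene on the same
chromosome is *cis*, each trait is classed cis-cis / cis-trans /
trans-trans, and a module is trans-acting (cis-acting) when its trans-trans
fraction among locatable traits is strictly above (below) 0.66 —
`unannotated` covers both the boundary and modules with no locatable
traits. The permutation FDR reruns the whole pipeline on datasets with
strain labels reshuffled (each permutation on its own derived seed) and
reports mean permuted count over real count, for module counts and module
trait counts separately.

## The synthetic benchmark

`simulate_collection()` plants two causal variants among `m_variants = 100`
unlinked variants with alleles $\pm 1$ at equal probability (monomorphic
draws are resampled), and generates 10 dual-effect traits from the
two-locus model (additive: $\beta_1 = \beta_2 = \gamma$, $\beta_{12} = 0$;
epistatic/co-adaptive: $\beta_1 = \beta_2 = 0$, $\beta_{12} = \gamma$),
10 + 10 single-effect traits, and 50 unassociated noise traits, with
Gaussian errors of variance $\sigma^2 = 0.5$. A dataset is a list of
independent collections with per-collection seeds derived from one master
seed. The generator emulates the benchmark conditions, not real data: no
linkage disequilibrium, no minor-allele-frequency variation, no dominance
or covariates, homoscedastic Gaussian noise. Passing tests on it
demonstrates correct behaviour under those assumptions only.

## Accuracy scoring

A trait is *predicted positive* at a cutoff when its predicted pair equals
the planted pair (order-free identity; a coordinate window is available for
real-data use) and its pair P — the larger of the primary and secondary
P-values — is at or below the cutoff. Sweeping the achieved pair P values
pools (TPR, FPR) points over all collections of a dataset; the *accuracy
score* is the trapezoidal area under the achieved points anchored at
$(0,0)$ and extended as a step function (horizontal at the last achieved
TPR out to FPR = 1) — the curve is never interpolated toward $(1,1)$. Under
this reading a mapper that names the true pair for every dual trait scores
1, one that never names it scores 0, and a score of 0.5 indicates a large
recovered fraction rather than chance performance, since naming the exact
pair by chance is vanishingly rare. For the POEM mappers the swept pair P
is each trait's association P to its two group representatives — the
grouping cutoff at which the trait would enter both groups — so the sweep
emulates tightening the grouping gate.

A note on operating characteristics under the default benchmark
conditions: the marginal F statistic of a planted locus is approximately
$n\gamma^2 / (\gamma^2 + \sigma^2)$, about 42 at $\gamma = 0.6$,
$\sigma^2 = 0.5$, $n = 100$ — strong enough that every stepwise mapper
recovers essentially all dual traits and accuracy scores saturate near 1.
Differences between methods therefore surface at smaller sample sizes or
effect sizes, which is where the test suite probes the method orderings
(grouping and iteration help on additive data; partition-based mapping
helps on epistatic data).

## Numerical and scale choices

* P-values are floored at $10^{-300}$ (score 300) so scores stay finite;
  exact fits are reported at the floor.
* Monomorphic variants keep their matrix column with score 0; monomorphic
  within-partition scans in the partition-based baseline contribute no
  secondary candidate, and partitions below 4 individuals are skipped.
* All arg-max and merge ties break toward the lowest variant index.
* The test suite and the acceptance script use 200 collections per
  benchmark panel (Monte-Carlo error on a pooled accuracy well under 0.05),
  100 planted-recovery seeds, 20–40 permutations for FDR checks, and 2,000
  replicates for null-calibration checks.

## Limitations

* Designed for homozygous/haploid binary genotypes; heterozygotes,
  dominance, covariates and population structure are out of scope.
* The grouping reimplements the agglomerative co-association idea from its
  published description; it is not a bit-for-bit port of the original C++
  tool, and merge-order details (greedy best-first with the rules above)
  are this package's own, chosen for determinism.
* Exactly two loci per program; higher-order programs are not searched.
* Permutation FDR reshuffles the strain labels of the whole expression
  matrix, which preserves trait–trait correlations. A very strongly
  co-expressed trait cluster (e.g. dual traits planted at a large effect
  size, pairwise r near 0.9) can re-group on a chance variant after
  permutation and regenerate spurious modules, inflating the estimated FDR.
  At the default benchmark effect size this does not occur, but permutation
  FDR should be interpreted cautiously when modules are dominated by one
  large co-expression factor.
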