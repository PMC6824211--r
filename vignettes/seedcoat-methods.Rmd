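---
title: "Methods: the seedcoat three-locus pattern model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the seedcoat three-locus pattern model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seedcoat)
```

## The genetic model and its assumptions

Seed-coat pattern in cowpea is modeled as a deterministic penetrance map
over three unlinked loci. *Color Factor* (C, Vu07) carries three alleles
with a partial dominance order (C2 > C0, C2 > C1; the C1/C0 relation is
unknown). *Watson* (W, Vu09) and *Holstein* (H, Vu10) are biallelic with
complete dominance (W1 > W0, H1 > H0). The epistasis is hierarchical: an
expressed C0 or C1 fixes the phenotype (No Color, Eye 1) regardless of the
expansion loci; expressed C2 exposes the four combinations of expressed
W/H as Eye 2, Holstein, Watson and Full Coat.

Assumptions inherited from this formulation:

* **Determinism.** Every resolvable genotype maps to exactly one of six
  classes; there is no incomplete penetrance. Scoring noise is modeled
  separately (see the confusion rate below).
* **No parent-of-origin effects.** Genotype pairs are unordered;
  reciprocal crosses are equivalent.
* **Unresolved dominance is an error, not a guess.** A C1/C0 heterozygote
  raises; of the 54 unordered three-locus genotypes, the 9 containing that
  pair are the only unresolvable ones (`check_exhaustive()`).
* **Extensibility by rule order.** The rule list is first-match, so a
  hypothetical extra allele (e.g. a Blue-grey Ring variant) can be added
  by prepending a rule; the six canonical classes are always retained.
  Patterns outside the three-locus system (Speckled, Starry Night,
  Blue-grey Ring) and seed-coat *color* are out of scope.

Two open modeling questions were closed as follows: C0 is represented as
a plain third allele (it may in reality be a regulatory loss-of-function
variant invisible to the genotyping platform), and Holstein is one locus
(the data cannot separate one locus from two tightly linked ones).

## Segregation ratios in exact arithmetic

Class proportions are carried as integer numerators over a common integer
denominator and reduced by gcd, so predictions such as 192:5:35:35:245/512
are exact; floating point enters only in the chi-square. Per-locus
genotype distributions are:

* **F2**: 1/4, 1/2, 1/4;
* **RIL, k selfing generations after the F1** (default k = 7, i.e. F8):
  heterozygote residue $(1/2)^k$, homozygotes $(1-(1/2)^k)/2$ each,
  verified against a selfing transition-matrix oracle;
* **MAGIC, idealized** (default): each founder's homozygote with weight
  1/8;
* **MAGIC, finite-k**: the two haplotypes of a line trace two *distinct*
  founders — under a random funnel the ordered founder pair is uniform on
  the 56 ordered pairs — followed by the $(1/2)^k$ selfing residue.

Joint distributions are products of per-locus distributions, which
requires unlinked loci; linked loci are refused analytically and handled
by the simulator. For the MAGIC design this product is provably exact at
complete fixation even under the funnel model, because per-locus fixation
probabilities are constant across funnel splits; at finite k the
cross-locus dependence through the shared funnel is $O(4^{-k})$ and is
neglected.

**The idealization switch.** `expected_phenotype_ratio(idealized = TRUE)`
(the default) treats RIL and MAGIC lines as fully inbred. This is the
convention under which the canonical predictions — 1:1:1:1, 4:1:1:1:1 and
192:5:35:35:245 — are exact, and is what the chi-square tests use.
`idealized = FALSE` keeps the residual heterozygosity and collapses
heterozygotes through the dominance series; for an F8 RIL the Eye 1
proportion is then 127/256 rather than 1/2. The difference is at most a
few parts per thousand but matters when validating the simulator, which
lives in the finite-k world.

**Chi-square conventions**, all three required to reproduce the published
statistics: Pearson $\sum (O-E)^2/E$ with no continuity correction;
expected counts scaled to the *observed* total (e.g. 296 scored MAGIC
lines of 305); df = classes − 1. Upper-tail p-values come from
`stats::pchisq` (infrastructure, not contribution); the statistic itself
is dual-checked against `stats::chisq.test` in the tests.

## The forward simulator

Meiosis uses the Haldane map function, $r = (1 - e^{-2d/100})/2$, with no
crossover interference; chromosomes assort independently (adjacent map
rows on different chromosomes get r = 0.5). Haldane was chosen because no
map function is stated for the system being emulated; the recombination
model is isolated in one internal function so Kosambi could be added.
RILs use single-seed descent (one offspring per line per generation);
MAGIC lines each get an independent random funnel (four 2-way, two 4-way,
one 8-way cross) unless a fixed pedigree matrix is supplied, because the
real population's funnel layout is not described. Haplotypes store
founder-origin labels, so multi-allelic pattern loci and biallelic
markers coexist; allele content is a lookup into the founder matrix. All
randomness flows through explicit `seed` arguments (restoring the
caller's RNG state), giving bit-identical populations per seed.

## What the synthetic data emulates — and what it does not

`fixture_spec()` defaults describe a desk-scale genotyping experiment:

| parameter | default | rationale |
|---|---|---|
| chromosomes | 11 (Vu01..Vu11) | cowpea karyotype |
| markers/chromosome | 45 (~500 total) | desk-scale stand-in for a ~50k array; a spec field, raised where density matters |
| chromosome length | 100 cM at 400 kb/cM | round numbers of the right order for cowpea |
| pattern loci | C\@Vu07, W\@Vu09, H\@Vu10, 50 cM | the mapped chromosomes |
| polymorphic fraction | 0.8 | typical informative fraction after parent filtering |
| genotyping error | 0.005 | plausible array error; not stated for the real platform, documented assumption |
| Eye1↔Watson confusion | 0.05 | the two patterns are hard to distinguish on pale seeds |
| bulk size | 20 | the pooling actually used |

For bulked-segregant work the 45-marker default is deliberately overridden
to 970 markers/chromosome: 970 × 11 × 0.8 ≈ 8,540 parent-polymorphic
markers, the count reported for the very F2 cross being emulated. This is
not a free dial — the categorical zygosity scan needs the ~±2.5 cM
recombination-free window around a causal locus (20-individual bulks, 40
meioses) to span at least `min_run` markers, and the real experiment had
~17 SNPs/cM.

**Noise placement.** Genotyping error applies to whatever was assayed as
one DNA sample. For line populations that is each line's call vector
(`corrupt_population()`); for phenotype bulks it is the *pooled* call
(`corrupt_calls()` on the bulk table), since pooled DNA is genotyped
once. Corrupting 20 individuals and then pooling digitally would inflate
the per-marker bulk error to $1-(1-e)^{20} \approx 9.5\%$, which
mismodels array genotyping of a pool. Phenotype confusion is applied
before bulking — a misphenotyped individual enters the wrong bulk, which
is the biologically real failure mode.

A green synthetic test therefore establishes that the algorithms are
correct *under this stated world*: unlinked causal loci, no segregation
distortion, no selection or mortality, no allele-frequency noise within
pools, idealized array behavior. It does not establish performance on
real cluster-called intensities, real funnel replication structure, or
linked/partially-penetrant loci.

## BSA scan and haplotype blocks

`bsa_scan()` is the categorical zygosity contrast (recessive bulk
homozygous for a constant parental allele, dominant bulk heterozygous) —
deliberately *not* an allele-frequency BSA statistic. Runs need at least
`min_run = 5` supporting markers; up to `max_gap = 1` consecutive
discordant markers (wrong zygosity, wrong allele, or missing) are
bridged. The spreadsheet-and-eyeball procedure this replaces published no
thresholds; both values are explicit parameters, and the scan runs once
per candidate recessive allele so that a single miscalled
opposite-homozygote cannot split a block irreparably. Coordinates are
1-based inclusive with length = end − start + 1; BED export converts to
0-based half-open (round-trip tested). `haplotype_block()` covers the
inbred-line variant — runs of markers whose calls separate two phenotype
groups, with `max_mismatch` lines of slack per marker for genotyping
error and phenotype misassignment — and `intersect_blocks()` takes
[max(starts), min(ends)], erroring on disjoint input.

## The marker scan is deliberately simplified

`single_marker_scan()` regresses each trait on genotype dosage {0, 1, 2}
marker by marker, with a genome-wide threshold from permuting trait
labels jointly across markers (preserving LD); monomorphic markers are
flagged with p = 1. It is a stand-in sufficient for synthetic-data
validation, *not* a reimplementation of multiparent mixed-model mapping
or hidden-Markov interval mapping, which exist in published packages and
are out of scope. Trait encoding follows the field's masking convention:
in strict mode Eye 1 lines are missing for the other four traits (Eye 1
is epistatic to W/H, so scoring them 0 would bias mapping); in magic mode
they are 0 because multiparent software tolerates little missingness.
`coded_correlation()` implements the ±1 phenotype / +1,0,−1 genotype
Pearson test with the closed-form t p-value on n − 2 df.

## Numerical choices and degenerate inputs

* Rational reductions use gcd on exact integer doubles (safe to $2^{53}$;
  the largest denominator in practice is $56 \cdot 2^{k+1}$ per locus).
* Ratio predictions drop zero-probability classes; `chi_square_gof()`
  errors on a nonzero count for a zero-expectation class and silently
  drops classes that are zero on both sides; df counts only retained
  classes.
* Monomorphic loci collapse to point masses; monomorphic parents give a
  single-class prediction rather than an error.
* `bulk_call()` returns `NA` only for all-missing input; a single
  discordant individual makes the pool heterozygous (pooled alleles
  contain both).
* Marker tables re-sort internally, so every scan is row-order invariant;
  ties between a pattern locus and a grid marker are resolved at map
  construction by forcing strictly increasing bp.
* Permutation thresholds use the empirical α-quantile of genome-wide
  minimum p-values; with all-monomorphic input the scan errors rather
  than returning an empty threshold.

## Known limitations

Linked pattern loci have no analytic path (simulator only). The finite-k
MAGIC analytic model assumes equal founder weights. The funnel's
replication structure in the real population is unknown, so simulator
funnels are randomized per line. The acceptance check of simulator
agreement compares simulated frequencies to the exact finite-k analytic
prediction and separately bounds that prediction's distance to the
idealized printed ratios (< 0.01 per class); testing 50,000 F8 lines
directly against idealized ratios would conflate a real
residual-heterozygosity deviation with sampling noise. Published genomic
results that depend on unavailable genotype data (QTL positions, real
haplotype-block sizes, the 28-accession correlation) are covered only by
property-based surrogates on synthetic data.
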