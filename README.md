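# seedcoat

Seed-coat pattern is a major consumer trait in cowpea (*Vigna unguiculata*
[L.] Walp.): markets pay premiums for specific eye shapes or for uncolored
seed. Pattern is controlled by an epistatic three-locus system — *Color
Factor* (**C**, chromosome Vu07), *Watson* (**W**, Vu09) and *Holstein*
(**H**, Vu10). `seedcoat` is an R package for geneticists and breeders
working with this system (or any small set of unlinked epistatic loci): it
predicts segregation ratios for biparental and multiparent crosses, tests
observed class counts, simulates the crosses forward, and provides
algorithmic versions of the bulked-segregant scan and haplotype-block
intersection used to map such loci.

## The model

Each locus has an allelic series:

| locus | chromosome | alleles | dominance |
|---|---|---|---|
| C | Vu07 | C0, C1, C2 | C2 > C0, C2 > C1; C1 vs C0 unresolved |
| W | Vu09 | W0, W1 | W1 > W0 |
| H | Vu10 | H0, H1 | H1 > H0 |

C is a "constriction" factor and is epistatic over the two "expansion"
factors: an expressed C0 gives **No Color** and an expressed C1 gives
**Eye 1**, both regardless of W and H. Only expressed C2 reveals the
expansion loci: (W0, H0) → **Eye 2**, (W0, H1) → **Holstein**,
(W1, H0) → **Watson**, (W1, H1) → **Full Coat**.

For a cross design, the expected class ratio is the product of independent
per-locus genotype distributions (the loci sit on three different
chromosomes), pushed through the genotype→phenotype map:
P(genotype) = P_C · P_W · P_H. All analytic proportions are kept in exact
integer rational arithmetic. For the eight-founder MAGIC population (3
founders carrying C1, one carrying W0 and H0), this gives the
Eye1 : Eye2 : Holstein : Watson : FullCoat ratio **192 : 5 : 35 : 35 : 245**
over 512, and e.g. the Holstein genotype C2C2 W0W0 H1H1 has probability
(5/8)(1/8)(7/8) = 35/512. Observed counts are tested by Pearson's
goodness-of-fit chi-square, Σ(O−E)²/E, with expected counts scaled to the
observed total and df = classes − 1.

## Worked example

```r
library(seedcoat)
model <- cwh_model()

# analytic ratio for the 8-founder MAGIC design
pred <- expected_phenotype_ratio(magic_design(), model)
pred
#> <ratio_prediction> Eye1:Eye2:Holstein:Watson:FullCoat = 192:5:35:35:245  (den 512)

# test the observed MAGIC class counts (296 of 305 lines scored)
chi_square_gof(c(Eye1 = 121, Eye2 = 0, Holstein = 21, Watson = 13,
                 FullCoat = 141), pred)
#> <gof_result> X-squared = 6.41, df = 4, p = 0.1706
#>          Eye1 Eye2 Holstein Watson FullCoat
#> observed  121 0.00    21.00  13.00   141.00
#> expected  111 2.89    20.23  20.23   141.64
```

The statistic 6.41 (p ≈ 0.17) says the 296 scored lines are consistent
with the three-locus model's 192:5:35:35:245 expectation. Simulating the
same design forward and re-deriving the ratio empirically:

```r
spec <- fixture_spec(markers_per_chrom = 3)      # minimal map
fs   <- make_founders(spec, magic_founders(), seed = 1)
pop  <- make_magic(fs, n = 50000, seed = 2)      # funnel + 7 selfings
round(table(assign_phenotypes(pop, model)) / 50000, 4)
#>   Eye1     Eye2 FullCoat Holstein   Watson
#> 0.3749   0.0102   0.4807   0.0671   0.0671
```

which matches 192/512 = 0.375, 5/512 ≈ 0.0098, 245/512 ≈ 0.4785, 35/512 ≈
0.0684 (twice) to within sampling noise. A complete bulked-segregant
experiment — simulate an F2, pool 20 individuals per phenotype class,
genotype the pools, scan for markers where the recessive bulk is
homozygous and the dominant bulk heterozygous — is one call:

```r
res <- simulate_bulk_scan(fixture_spec(markers_per_chrom = 970),
                          cowpea_parents()[c("CB27", "B21")],
                          classes = c("NoColor", "Eye2"), n = 150, seed = 9)
res$regions[, c("chrom", "start", "end", "n_markers")]
#>   chrom    start      end n_markers
#> 1  Vu07 18947369 24355006       106
```

The reported Vu07 interval contains the planted C locus (bp 20,000,001).

## Command line

An installed `seedcoat` script (see `system.file("exec", "seedcoat")`)
exposes `predict-ratio`, `gof`, `simulate`, `make-fixtures`, `bsa-scan`
and `marker-scan`; run `seedcoat help` for usage.

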