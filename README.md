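# epistable

Penetrance tables for high-order epistasis models, with a prescribed
prevalence or heritability.

## What it does, and for whom

Researchers benchmarking epistasis-detection methods simulate case–control
genotype data with a known embedded interaction. The interaction is
specified by a **penetrance table**: for `k` biallelic loci, the
probability `P(D|g_i)` of disease for each of the `3^k` genotype
combinations `g_i`. Simulators (e.g. GAMETES) consume such tables but do
not let you dictate the epidemiological summaries that make a benchmark
realistic:

```
P(D) = Σ_i P(D|g_i) P(g_i)                                   (prevalence)
h²   = Σ_i (P(D|g_i) − P(D))² P(g_i) / (P(D)(1 − P(D)))      (heritability)
```

with `P(g_i)` the Hardy–Weinberg genotype frequency implied by the
per-locus minor allele frequencies (MAFs). Fixing *both* `P(D)` and `h²`
is usually incompatible, so `epistable` fixes **one** and maximizes the
other by solving the constrained nonlinear system

```
Σ_i f_i(x, y) P(g_i) = P(D)         (or the h² equation)
max_i f_i(x, y)      = 1
```

for the model parameters `(x, y)`, where `f_i(x, y)` are the model's
symbolic penetrance expressions (`x` = baseline penetrance, `y` = effect
size). Accepted solutions carry a guaranteed maximum deviation of `1e-8`
between the realized and requested parameter; in practice residuals sit
near `1e-16`. Generalized threshold, additive and multiplicative families
(the classic two-locus models extended to any order) are bundled, and the
solver handles threshold/additive models through order 10 and
multiplicative models through order 8. An independent bisection oracle
cross-checks every solution path.

## Worked example

The fourth-order multiplicative model with a fixed prevalence of 0.6 and
MAFs 0.2, 0.3, 0.3, 0.4 (heritability is maximized):

```r
library(epistable)

model <- readModelCsv(system.file("extdata", "multiplicative_4.csv",
                                  package = "epistable"))
sys <- buildSystem(model, c(0.2, 0.3, 0.3, 0.4), "prevalence", 0.6)
sol <- solveSystem(sys)
sol
#> PenetranceSolution: x = 0.597678800733109, y = 0.0326918729882594 (residual 1.11e-16, attempt 1)

tab <- buildTable(model, c(0.2, 0.3, 0.3, 0.4), sol)
realizedPrevalence(tab)    # 0.6 (recovered to 1e-16)
realizedHeritability(tab)  # 0.0005646971 -- the maximized heritability
writeGametes(tab, "multiplicative_4_p06.txt")
```

`x` is the penetrance of genotypes with no interacting minor alleles
(here ≈ 0.598) and each genotype's penetrance is `x(1+y)^e` with `e` the
product of its per-locus minor-allele counts; the all-minor corner is
pinned at exactly 1. The same run from a shell:

```sh
Rscript inst/scripts/epistable inst/extdata/multiplicative_4.csv \
    --max_her 0.6 0.2 0.3 0.3 0.4 --gametes
```

Exit status is 0 on success, 1 for usage errors, 2 for unsolvable or
timed-out configurations, 3 for I/O errors. `--max_prev <h2> <mafs>...`
fixes the heritability and maximizes prevalence instead; `--timeout`
accepts `none`, `auto` (the order heuristic `60(order+1)²` seconds) or a
number of seconds.

Arbitrary models are accepted as two-column CSV (`genotype,expression`,
no header), e.g. the bundled `additive_2.csv` begins:

```
AABB,x
AABb,x * (1 + y)
AAbb,x * (1 + y)^2
```

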