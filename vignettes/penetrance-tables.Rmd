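---
title: "Calculating penetrance tables for high-order epistasis models"
author: "epistable"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calculating penetrance tables for high-order epistasis models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epistable)
```

## The problem

Benchmarking methods that detect gene–gene interactions requires simulated
case–control data in which the embedded interaction is known exactly. The
standard way to specify such an interaction is a *penetrance table*: for
`k` biallelic loci, the probability `P(D | g_i)` of expressing the disease
phenotype for each of the `3^k` multi-locus genotypes `g_i`. Simulators
such as GAMETES consume these tables directly; what they do not do is
produce a table with a *prescribed* population prevalence or heritability,
which is what a realistic benchmark needs.

Two population-level summaries follow from a table once genotype
frequencies are known:

- prevalence, the frequency-weighted mean penetrance
  $$P(D) = \sum_i P(D \mid g_i)\, P(g_i),$$
- heritability (variance explained on the observed scale)
  $$h^2 = \frac{\sum_i \big(P(D \mid g_i) - P(D)\big)^2 P(g_i)}
               {P(D)\,(1 - P(D))}.$$

Requiring *both* a target prevalence and a target heritability generally
yields an incompatible system. The approach implemented here fixes **one**
of the two and maximizes the other by adding the constraint that the
largest penetrance equals 1. For a fixed prevalence the system in the two
unknowns `(x, y)` is

$$\sum_i f_i(x, y)\, P(g_i) = P(D), \qquad \max_i f_i(x, y) = 1,$$

and for a fixed heritability the first equation is replaced by the `h^2`
ratio above with `P(D)` expanded as the weighted sum of the `f_i`. Here
`f_i(x, y)` are the model's symbolic penetrance expressions: `x` is a
baseline penetrance and `y` an effect size.

## Genotype frequencies

Frequencies come from the per-locus minor allele frequencies (MAFs) under
Hardy–Weinberg equilibrium, with independence (linkage equilibrium)
assumed between all loci: each locus contributes `(1-m)^2`, `2m(1-m)` or
`m^2` and the genotype frequency is the product over loci. MAFs are
restricted to `(0, 0.5]`: above 0.5 the allele would not be minor, and 0
degenerates the system. Uppercase letters denote major alleles; the
all-lowercase corner (`aabb...`) is the all-minor-homozygote genotype at
which the bundled model families reach their maximum penetrance.

## Model families

The bundled bank generalizes the three classic two-locus interaction
families to any order, writing `g_i` for the minor-allele count (0, 1, 2)
at locus `i`:

| family         | penetrance expression                                  |
|----------------|--------------------------------------------------------|
| threshold      | `x(1+y)` if every locus carries a minor allele, else `x` |
| additive       | `x(1+y)^(g_1 + ... + g_k)`                             |
| multiplicative | `x(1+y)^(g_1 * ... * g_k)`                             |

Arbitrary models are accepted from a two-column CSV (genotype, expression;
no header; `#` comments; `^` or `**` for powers). Expressions may use only
`x`, `y`, numbers and `+ - * / ^`; on construction each distinct
expression is probed on a fixed grid (`x` in {0.01, 1}, `y` in
{0.1, 1, 10, 100}) and must be nonnegative and non-NaN there (overflow of
very high powers past double range at the largest probes is tolerated for
high-order models). The same grid establishes which expression dominates
all others — the one pinned to 1 by the constraint. If no single
expression dominates across the grid the maximization constraint is
ill-posed and the model is rejected.

## How the solver works

The constraint `max_i f_i(x, y) = 1` implicitly defines `x` as a function
of `y`. The solver exploits this to reduce the 2-D system to one scalar
equation:

1. **Simplification.** Identical expressions are grouped and their
   genotype frequencies summed, so an order-8 additive model collapses
   from 6561 weighted terms to 17. The simplified system is required (and
   tested) to agree with the raw weighted sum at random probe points.
2. **Elimination.** For a given `y`, `x(y)` is found by Newton iteration
   on the constraint; when the constraint is linear in `x` — true for
   every bank model, where it is `x·u(y)` — a single step is exact.
3. **Root location.** The reduced residual
   `F(y) = main(x(y), y) − target` is evaluated on a 400-point
   logarithmic grid of `y` spanning from `1e-9` up to the largest `y` at
   which the system is evaluable in double precision. Every sign change
   is refined by bracket-safeguarded Newton iteration, using analytic
   derivatives: each term's partials come from symbolic differentiation
   (`stats::D`) and `dx/dy` from the implicit-function rule
   `−c_y / c_x` on the constraint.
4. **Root selection.** Roots are filtered to `x > 0` with all penetrances
   inside `[0, 1 + E_tol]`; among admissible roots the smallest residual
   wins, ties broken by smallest `y`. This makes output deterministic
   when the polynomial system has several admissible solutions. If `y`
   does not occur in the system at all, the canonical `y = 0` is
   reported.

**Tolerance relaxation.** Convergence is accepted against a schedule of
tolerances, strictest first: `1e-15, 1e-12, 1e-10, 1e-8`. The index at
which the root was accepted is reported in the solution (`attemptsUsed`),
so a value above 1 signals that the strict tolerance had to be relaxed.
The last entry equals `E_max`, beyond which a configuration counts as
unsolved. All arithmetic is IEEE double precision; sums accumulate in
extended precision via R's built-in `sum`. In practice the safeguarded
Newton iteration converges to machine precision, and residuals across the
bank battery sit near `1e-16`, far below every acceptance threshold — the
relaxed rungs of the schedule exist for ill-conditioned user models.

**Acceptance of a solution.** The residual — the absolute deviation of
the fixed parameter recomputed at `(x, y)` from its target — is checked
against the order-dependent *tolerable error*
`E_tol(order) = min(10^order · E_0, E_max)` with `E_0 = 1e-16` and
`E_max = 1e-8`. The base error grows with order because the system grows
more ill-conditioned; the cap guarantees a maximum deviation of `1e-8`
for any accepted table. A residual above `E_tol` raises a warning (the
solution is "considered invalid"), never an error: only the main
equation's residual is checked, since the constraint is enforced
structurally by the elimination step.

**Timeouts.** Some configurations are genuinely infeasible (e.g. a target
prevalence below the all-carrier genotype frequency of a threshold
model); others converge slowly. The time budget defaults to the
order-based heuristic `60·(order+1)^2` seconds, can be set in seconds, or
disabled. The deadline is checked cooperatively between solver stages;
there is no separate watchdog process, which suits a single-threaded R
session and keeps the solver embeddable.

**Numerical range.** `x` can be extremely small at high orders (the
order-10 additive solution has `x ≈ 1e-30`); this is representable
without difficulty. The practical ceiling is the multiplicative family,
whose maximum exponent is `2^order`: beyond the `y` at which
`(1+y)^(2^order)` overflows double range the reduced equation cannot be
evaluated, and the scan grid is truncated there. All fixed-heritability
targets on the bundled battery have their root well inside the
representable region — the multiplicative family solves through order 8
with uniform MAFs on the 0.1–0.5 grid.

## The verification oracle

An independent check accompanies the solver: `oracleSolve` requires the
constraint to have the form `x·u(y)`, eliminates `x = 1/u(y)` in closed
form, and locates the root by plain bisection on the *full, unsimplified*
`3^k` enumeration — none of the main solver's machinery is reused. For a
fixed prevalence the reduced function is monotone in `y` (each penetrance
`t^(e_i − e_max)` with `t = 1+y` is nonincreasing) and the bracket is
found by geometric expansion of the upper bound, doubling from 10 up to
`2^40`; a fixed-heritability system need not be monotone, so a
logarithmic grid of `10^4` points is scanned and the smallest admissible
root is taken, matching the main solver's selection policy. Bisection
runs to a relative `y` width of `1e-15`. Failure to bracket is reported
as an unsolvable configuration — evidence, not proof, of infeasibility.
The test suite requires the two routes to agree to `1e-9` in `y` and
entrywise in the table across the bank battery.

## Output formats

`writeTableCsv` emits one `genotype,penetrance` line per genotype in
canonical order with 12 significant digits (internal values are full
doubles; formatting is the only loss). `writeGametes` emits a GAMETES
model-style file: attribute names and MAFs, the solved `x`/`y`, realized
prevalence and heritability, then the penetrance block in rows of three
(last locus fastest) with a blank line between successive 3×3 blocks.
The layout is pinned by golden-file tests; byte-level compatibility with
a specific GAMETES release has not been verified. Both writers emit
identical numeric values. Tiny negative penetrances from rounding (within
`1e-12`) are clamped to 0 when a table is materialized; larger violations
are an error.

## Design choices on open points

- *Which allele case is minor* is a convention: lowercase minor, so that
  risk escalates toward the all-lowercase corner, matching how the
  additive family's largest exponent sits at `aa...bb`.
- *Genotype order* is row-major with the last locus fastest, which makes
  an order-2 CSV read exactly like the classic two-locus table row by
  row.
- *Exponent syntax*: both `^` and `**` are accepted on input; canonical
  output prints `^`.
- *Root multiplicity*: the smallest-residual-then-smallest-`y` rule was
  chosen over "first root found" to make batch output reproducible.
- *Fixed prevalence of exactly 1* is admitted (a degenerate flat model is
  the only way to attain it); a fixed heritability must be strictly below
  1.

## What the test battery does and does not show

The suite solves the three bank families over orders 2–8 (orders 2–4
in the dense residual battery with MAFs {0.1, 0.4} and targets
{0.1, 0.8} in both directions — 72 configurations, chosen to keep the
default run around half a minute), checks every accepted table's realized
parameter to `1e-8`, cross-validates solver against oracle at `1e-9`, and
verifies a hand-derived closed form (order 1, MAF 0.5, prevalence 0.5
gives `y = √2`, `x = 3 − 2√2`, `h² ≈ 0.372583`). These are exact
mathematical properties of the model families; passing them says nothing
about whether any family is a *biologically faithful* description of a
real interaction, about linkage disequilibrium between loci (assumed
absent), or about non-biallelic markers (unsupported).

## Known limitations

- Expressions are limited to two free variables; models parameterized
  differently must be rewritten in `(x, y)`.
- The interaction-order cap is 10 (59049 genotypes); above that, model
  construction cost and double-range overflow make results unreliable.
- The oracle requires the `x·u(y)` constraint shape; for models whose
  dominating expression is not linear in `x` only the main solver runs.
- Heritability-fixed systems with several admissible roots return the
  smallest-`y` root by policy; other roots are valid tables too and are
  not enumerated.
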