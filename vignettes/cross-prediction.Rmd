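---
title: "Predicting cross means and segregation variances from marker effects"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting cross means and segregation variances from marker effects}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crossvar)
```

## The problem

In each cycle of a line or hybrid breeding program a handful of crosses must
be chosen from among all pairs of candidate parents. A cross is well
characterised by the usefulness criterion $U = \mu + i\,\sigma_g\,h$, where
$\mu$ is the expected genotypic value of the homozygous lines derived from
the cross, $\sigma_g$ their standard deviation (the *segregation variance*
is $\sigma_g^2$), $i$ the selection intensity and $h$ the square root of the
heritability; dropping $h$ gives the superior progeny value
$s = \mu + i\,\sigma_g$. The mean is easy — it is the midpoint of the
parents' predicted values — but $\sigma_g^2$ couples every pair of linked
loci and has traditionally been obtained by simulating progeny.
`crossvar` computes both moments in closed form from genome-wide marker
effects, a linkage map, and the parents' marker genotypes, and ships the
simulators that verify the formulas.

## The model

Let the two parents be fully homozygous. The genotypic value of a derived
line is modelled additively, $Z = \beta_0 + \sum_c \sum_j Z_j$, where the
inner sum runs over the marker loci of chromosome $c$ and $Z_j$ equals
$g_j$ (twice the additive effect of the maternal allele, i.e. maternal
dosage $\times$ effect $u_j$) or $h_j$ (paternal analog), each with
probability $1/2$. Then

$$\mu = \beta_0 + \sum_c\sum_j \tfrac12 (g_j + h_j), \qquad
\sigma_g^2 = \sum_c \sum_{j,k} \Big(\tfrac{q_{jk}}{2} - \tfrac14\Big)
  (g_j - h_j)(g_k - h_k),$$

with the double sum over *all ordered pairs including $j = k$* — the
diagonal, where $q_{jj} = 1$, contributes the single-locus variances
$(g_j-h_j)^2/4$. A pairs-only reading would silently drop those terms; the
inclusive reading is forced by $\mathrm{var}(\sum_j Z_j) = \sum_{j,k}
\mathrm{cov}(Z_j, Z_k)$. `cross_variance()` iterates unordered pairs and
doubles the off-diagonal terms.

$q_{jk}$ is the probability that locus $k$ carries the maternal allele
given that locus $j$ does. It is linked to the expected LD $D_{jk}$ of the
parental-origin indicators (marginal frequencies $1/2$) by
$q_{jk} = \tfrac12 + 2 D_{jk}$, so any mating system for which the expected
LD is known plugs straight in:

* **DH lines**, derived after $t$ generations of random intermating of the
  F1: $D_{jk} = \tfrac{1-2r_{jk}}{4}(1-r_{jk})^t$. Each intermating
  generation multiplies the LD by $(1-r)$.
* **SSD lines** (recombinant inbreds by single-seed descent from the
  F2-equivalent stage of the same population): the selfing generations
  additionally shrink the LD by the Haldane–Waddington factor
  $1/(1+2r_{jk})$, giving
  $D_{jk} = \tfrac{1-2r_{jk}}{4(1+2r_{jk})}(1-r_{jk})^t$.

Recombination frequencies come from Haldane's mapping function
$r = (1 - e^{-2d})/2$ ($d$ in Morgans; positions are stored in cM and
converted exactly once, inside `haldane_r()`). The `map_fun` argument of
`q_jk()`, `cross_variance()` and `predict_all_crosses()` accepts any other
distance-to-$r$ function (e.g. Kosambi) — Haldane is the only shipped
default because it is the exact counterpart of the no-interference
simulation model below. Loci on different chromosomes assort independently
($D = 0$, $q = 1/2$) and are skipped.

Markers monomorphic between the two parents contribute $(g_j+h_j)/2$ to
$\mu$ and automatically nothing to $\sigma_g^2$.

## Marker effects

Effects are estimated by RR-BLUP from a training panel: the mixed-model
equations with an explicit intercept block and a common ridge penalty
$\lambda = \sigma_e^2/\sigma_u^2$ on the marker block. Dosages enter *raw*
(0/1/2, not column-centered); the intercept absorbs the means, which keeps
$g_j$ literally "dosage times effect". The solver uses a direct symmetric
solve of the $(m+1)$-dimensional system, or the algebraically identical
dual $n$-dimensional form when markers heavily outnumber lines; the test
suite checks both against an independent generic ridge closed form.

$\lambda$ is estimated by REML by default (`choose_lambda()`), profiling
the restricted likelihood over $\log\lambda \in [-10, 10]$ (tolerance
$10^{-8}$) via one eigendecomposition of the intercept-projected
$ZZ'$. A boundary optimum — which genuinely occurs when the data carry
essentially no genetic (or no residual) variance — returns the boundary
value with a warning rather than failing, so that downstream prediction
stays usable; a fixed-$\lambda$ policy is available for exact
reproducibility. Residual missing dosages are mean-imputed
(`impute_missing()`); users with a better imputation should pre-impute.

## Quality control

Following common practice for diversity-panel SNP data, the training panel
is filtered to polymorphic markers with *less than* 10% missing values
(strict, so a marker at exactly 10% is removed) and gene diversity
$1 - \sum p_i^2 \ge 0.1$; lines are dropped when *more than* 10% of their
marker data are missing (a line at exactly 10% is kept). These boundary
conventions mirror the usual phrasing of such filters; since filter order
is rarely stated, `crossvar` fixes it — lines first, then markers, each
marker counted once under the first failed criterion in the order
polymorphism, missingness, diversity — so results are reproducible.
Heterozygous calls (dosage 1) are legal in the training panel and
contribute one allele of each type to the frequencies; candidate *parents*,
by contrast, must be fully homozygous and any heterozygous call there is an
error.

## The simulators

`simulate_population()` is the package's independent check on the formulas
(and a PopVar-style alternative for mating systems without a closed form).
Meiosis follows the count-location process: the crossover count on a
chromosome is Poisson with mean equal to the mapped length in Morgans,
locations are i.i.d. uniform, and the starting haplotype is a fair coin.
This is exactly the process whose two-locus statistics reproduce Haldane's
mapping function, so simulation and formula share one model and no
interference (PopVar's chi-square crossover model is deliberately not
replicated). Crossovers are drawn over the marker span only — crossovers
outside it cannot change marker genotypes.

Intermating generations are simulated in a *finite* population
(`n_im`, default 200, the size a breeder would actually intermate); the
formulas assume the infinite-population expected LD, so validation tests
use `n_im = 2000` to suppress drift and compare against the empirical
standard error over replicates rather than asserting exact equality. SSD
lines are selfed for `n_self = 10` generations (residual heterozygosity
per locus $2^{-10} \approx 0.1\%$) and then closed to complete
homozygosity by a fair coin per remaining heterozygous locus — unbiased
for allele frequency, matching the $F_\infty$ target of the formulas.

Two exact oracles need no randomness at all: `exhaustive_dh_variance()`
enumerates all $2^L$ gametes of an F1 chromosome with their exact
probabilities (capped at 20 loci; the Markov property of the
no-interference crossover pattern gives the probability as a product over
adjacent intervals), and `two_locus_selfing_fixpoint()` iterates the exact
ten-state diplotype recursion under selfing to fixation, reproducing the
Haldane–Waddington attrition $D/(1+2r)$ to $10^{-8}$.

## Synthetic data

`generate_dataset()` emulates the statistical structure the method
consumes: founder haplotypes (allele frequencies uniform on $[0.1, 0.9]$)
are recombined through a few generations of random mating with the
package's own meiosis engine — this induces realistic marker–marker LD,
which matters because both effect estimation and the variance formula are
LD-sensitive; independently drawn markers would make every downstream test
too easy. Training lines and candidate parents are derived as doubled
haploids from the pool, hence fully homozygous. Phenotypes are
$y = \beta_0 + Zu + e$ with the residual variance set from the target
heritability.

`nam_like_preset()` mirrors the dimensions of the maize
nested-association-mapping setting often used to benchmark such methods:
10 chromosomes x 140 cM (1400 cM genome), 325 markers (~4.3 cM spacing),
258 training lines, 26 homozygous parents of which the first plays the
role of the common parent crossed with the other 25. The trait scale is
flowering-time-like (intercept 100, 40 QTL with effect SD 0.5 per allele
dose, $h^2 = 0.8$, 3% missing genotype calls) — chosen once as realistic
values for a diversity panel of moderate size. What the generator does
*not* emulate: population structure and family relatedness within the
training set, ascertainment bias of SNP panels, genotyping error, and
non-additive gene action. Tests passing on these data therefore validate
the mathematics and the implementation, not the field performance of
genomic prediction on any particular crop.

## Validation layout

The test suite verifies, among others:

* exact agreement (to $10^{-10}$) of `cross_mean()`/`cross_variance()`
  with exhaustive enumeration on 50 random one-chromosome F1-DH cases of
  up to 12 loci;
* the composition identity $q = \tfrac12 + 2D$ to $10^{-12}$ over 1000
  random distance/scheme/$t$ draws, and $q = 1 - r$ for F1-DH from first
  principles;
* the SSD fixpoint grid (11 values of $r$ x 3 of $D$, tolerance
  $10^{-8}$);
* the RR-BLUP solver against an independent ridge closed form on 100
  random systems ($10^{-8}$), plus shift and shrinkage-limit properties;
* Monte-Carlo consistency for DH and SSD at $t \in \{0,1,2\}$ — 30 seeded
  cases of 10 linked loci, 20 replicates x 1000 progeny each
  (`n_im = 2000`), analytical variance within 4 empirical SE;
* an end-to-end NAM-like comparison (`validate_against_simulation()`):
  25 crosses of the common parent, closed-form variance vs the average of
  25 replicate variances from 200 simulated DH progeny per cross with
  identical RR-BLUP effects, requiring a Pearson correlation of at least
  0.98 across crosses.

The problem sizes above (200 progeny, 25 replicates, 20 000 progeny for
the consistency grid) are the package's chosen validation conditions; the
NAM-like run completes in seconds because the meiosis engine is fully
vectorised.

## Numerical choices and degenerate inputs

* $\sigma_g^2$ is mathematically a quadratic form in a covariance matrix,
  hence nonnegative; floating-point assembly may produce a tiny negative
  residue, which is clamped to 0 with a warning down to $-10^{-9}$ and is
  a hard error below that (it would indicate a real bug).
* `sigma = sqrt(max(sigma2, 0))`; ranking ties on $s$ are broken by the
  lexicographic parent pair, making `predict_all_crosses()` fully
  deterministic.
* Same-position markers: two distinct markers at identical positions get
  $r = 0$, $q = 1$ — they are treated as one perfectly linked block, which
  is the correct limit of the formulas.
* The variance is computed exactly over all within-chromosome pairs
  ($O(L_c^2)$ per chromosome) with no distance cutoff.
* `two_locus_selfing_fixpoint()` declares fixation at total heterozygosity
  $< 10^{-12}$ (heterozygosity halves each generation, so this takes ~40
  iterations) and errors after $10^4$ iterations.
* All stochastic components accept an integer seed; replicate seeds are
  `seed + replicate - 1`, so any replicate can be reproduced in isolation.

## Limitations

The formulas give the expected moments for an infinite population of
derived lines under additive gene action; finite families realise less
than the full segregation variance, epistasis and dominance (in the
heterozygous intermediate generations) are outside the model, and the
accuracy of the predicted $\sigma_g^2$ is bounded by the accuracy of the
marker-effect estimates — shrinkage of effect estimates propagates into a
systematic scaling of predicted variances, which is why cross *ranking* is
the intended use. The command-line pipeline (`synth`, `qc`,
`estimate-effects`, `predict-crosses`, `simulate`, `compare`; see
`crossvar_main()`) covers the standard workflow; pedigree file formats,
multi-allelic markers and phased VCF input are out of scope.
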