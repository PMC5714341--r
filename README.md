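# crossvar

Closed-form prediction of the **mean** and **segregation variance** of the
genotypic values of homozygous lines derived from a biparental cross, for
selecting crossing partners in line and hybrid breeding programs.

## What it computes

Breeders can rarely make and evaluate all pairwise crosses among their
candidate parents. A cross is characterised by the usefulness criterion

    U = mu + i * sigma_g * h        (superior progeny value: s = mu + i * sigma_g)

where `mu` and `sigma_g` are the mean and standard deviation of the
genotypic values of the lines derived from the cross, `i` the selection
intensity and `h` the square root of the heritability. With additive
genome-wide marker effects `u_j` (RR-BLUP), parental contributions
`g_j` (maternal dosage x `u_j`) and `h_j` (paternal), and `q_jk` the
probability that locus `k` carries the maternal allele given locus `j`
does,

    mu       = beta0 + sum_j (g_j + h_j) / 2
    sigma_g2 = sum_c sum_{j,k} (q_jk/2 - 1/4) (g_j - h_j)(g_k - h_k)

with the pair sum running within chromosomes and including `j = k`
(`q_jj = 1`). `q_jk = 1/2 + 2 D_jk` follows from the expected linkage
disequilibrium of the mating system:

* DH lines after `t` intermating generations: `D = (1-2r)/4 * (1-r)^t`
* SSD (recombinant inbred) lines: `D = (1-2r) / (4(1+2r)) * (1-r)^t`

with `r` from Haldane's mapping function `r = (1 - exp(-2d))/2` (`d` in
Morgans; other mapping functions can be plugged in). No progeny simulation
is needed — but the package also ships a count-location (Poisson crossover)
meiosis simulator, an exact `2^L` gamete enumeration and an exact
two-locus selfing recursion, which independently verify the formulas.

## Worked example

```r
library(crossvar)

cfg <- synth_config(seed = 42)             # small synthetic breeding dataset
dat <- generate_dataset(cfg)

geno  <- impute_missing(filter_markers(filter_lines(dat$training)$geno)$geno)
pheno <- dat$pheno[dat$pheno$line %in% rownames(geno), ]
lambda <- choose_lambda(geno, pheno, "reml")
eff <- rrblup_solve(geno, pheno, lambda)
eff
#> marker_effects: 57 markers, intercept 99.963, lambda 12.09212

pred <- predict_all_crosses(dat$parents[1:5, ], eff, dat$map,
                            mating_scheme("dh", 0), p = 0.05, h = 1)
head(as.data.frame(pred), 5)
#>   parent1 parent2 scheme t    mu sigma2  sigma     s     U
#> 1    P002    P005     dh 0 104.5 0.5114 0.7151 106.0 106.0
#> 2    P001    P002     dh 0 103.0 1.8087 1.3449 105.8 105.8
#> 3    P002    P003     dh 0 102.2 2.5458 1.5955 105.5 105.5
#> 4    P002    P004     dh 0 103.6 0.5855 0.7652 105.2 105.2
#> 5    P001    P005     dh 0 102.4 1.0153 1.0076 104.5 104.5
```

Each row is one candidate cross: `mu` is the predicted family mean (here on
a flowering-time-like scale of ~100 days), `sigma2` the predicted
segregation variance among derived DH lines, and `s`/`U` the superior
progeny value and usefulness at 5% selected fraction — the ranking
criterion. Note how P002 x P005 ranks first through its high mean while
P002 x P003 nearly catches up on a much larger segregation variance: this
mean/variance trade-off is exactly what the criterion formalises.

The same workflow is available from the shell via the launcher in
`inst/exec/crossvar` (subcommands `synth`, `qc`, `estimate-effects`,
`predict-crosses`, `simulate`, `compare`; every subcommand accepts
`--config config.yaml`).

See `vignettes/cross-prediction.Rmd` for the model, its assumptions, and
all numerical conventions.

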