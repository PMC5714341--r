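# Small in-code fixtures shared across test files.

# map of L markers on one chromosome, uniform random positions
toy_map <- function(L, len_cM = 100, chrom = "1", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  linkage_map(sprintf("m%02d", seq_len(L)), chrom, sort(runif(L, 0, len_cM)))
}

# random F1-DH test case: map, effects, two homozygous parents
random_cross_case <- function(L, seed, len_cM = 100, beta0 = 10) {
  set.seed(seed)
  map <- linkage_map(sprintf("m%02d", seq_len(L)), "1", sort(runif(L, 0, len_cM)))
  u <- stats::setNames(rnorm(L), map$marker)
  eff <- marker_effects(beta0, u, 1)
  repeat {                       # ensure at least one polymorphic locus
    p1 <- stats::setNames(sample(c(0, 2), L, replace = TRUE), map$marker)
    p2 <- stats::setNames(sample(c(0, 2), L, replace = TRUE), map$marker)
    if (any(p1 != p2)) break
  }
  list(map = map, effects = eff,
       cpe = cross_parent_effects(p1, p2, eff), p1 = p1, p2 = p2)
}

# independent generic ridge closed form: u = (Z'MZ + lambda I)^-1 Z'My,
# M the intercept-projection; beta0 recovered from the means
ridge_oracle <- function(Z, y, lambda) {
  n <- nrow(Z)
  M <- diag(n) - matrix(1 / n, n, n)
  u <- solve(crossprod(Z, M %*% Z) + lambda * diag(ncol(Z)),
             crossprod(Z, M %*% y))
  b0 <- mean(y) - sum(colMeans(Z) * u)
  unname(c(b0, drop(u)))
}

# random training system for solver tests
random_ridge_system <- function(seed, n = NULL, m = NULL) {
  set.seed(seed)
  if (is.null(n)) n <- sample(5:15, 1)
  if (is.null(m)) m <- sample(2:8, 1)
  Z <- matrix(sample(0:2, n * m, replace = TRUE), n, m,
              dimnames = list(sprintf("L%02d", seq_len(n)), sprintf("m%02d", seq_len(m))))
  y <- rnorm(n)
  list(geno = Z, pheno = data.frame(line = rownames(Z), value = y,
                                    stringsAsFactors = FALSE),
       lambda = runif(1, 0.1, 10))
}

# parental-origin LD between the first two markers of a homozygous progeny
# dosage matrix, coding parent1 = all 2s
sim_ld <- function(dosage) {
  h <- dosage / 2
  mean(h[, 1] == 1 & h[, 2] == 1) - mean(h[, 1]) * mean(h[, 2])
}

# map distance (cM) giving recombination frequency r under Haldane
dist_for_r <- function(r) -50 * log(1 - 2 * r)
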