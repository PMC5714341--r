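# The simulators are themselves verified here (two-locus statistics, exact
# enumerations, reproducibility) before they serve as oracles elsewhere.

two_locus_parents <- function(d_cM) {
  map <- linkage_map(c("a", "b"), "1", c(0, d_cM))
  parents <- rbind(c(a = 2, b = 2), c(a = 0, b = 0))
  list(map = map, parents = parents)
}

test_that("a zero-length chromosome transmits one parental haplotype intact", {
  map <- linkage_map(c("a", "b", "c"), "1", c(5, 5, 5))
  h1 <- c(a = 1, b = 1, c = 1); h2 <- c(a = 0, b = 0, c = 0)
  for (seed in 1:10) {
    gam <- simulate_gamete(list(h1, h2), map, seed = seed)
    expect_true(all(gam == 1) || all(gam == 0))
  }
})

test_that("gamete two-locus statistics match the Haldane model within 4 SE", {
  n <- 1e5
  for (r in c(0.05, 0.2, 0.35)) {
    tw <- two_locus_parents(dist_for_r(r))
    pop <- simulate_population(tw$parents, tw$map, mating_scheme("dh", 0), n,
                               seed = round(1000 * r))
    hap <- pop$dosage / 2
    rec_frac <- mean(hap[, 1] != hap[, 2])
    expect_lt(abs(rec_frac - r), 4 * sqrt(r * (1 - r) / n))
    # both-maternal gamete frequency (1 - r) / 2
    both <- mean(hap[, 1] == 1 & hap[, 2] == 1)
    p_exp <- (1 - r) / 2
    expect_lt(abs(both - p_exp), 4 * sqrt(p_exp * (1 - p_exp) / n))
  }
})

test_that("recombinant fraction at 50 cM approaches (1 - exp(-1))/2", {
  n <- 1e5
  tw <- two_locus_parents(50)
  pop <- simulate_population(tw$parents, tw$map, mating_scheme("dh", 0), n, seed = 50)
  hap <- pop$dosage / 2
  r <- haldane_r(50)
  expect_lt(abs(mean(hap[, 1] != hap[, 2]) - r), 4 * sqrt(r * (1 - r) / n))
})

test_that("identical parents breed identical progeny under both schemes", {
  map <- toy_map(5, seed = 61)
  p <- setNames(c(2, 0, 2, 2, 0), map$marker)
  parents <- rbind(p, p)
  for (kind in c("dh", "ssd")) {
    pop <- simulate_population(parents, map, mating_scheme(kind, 1), 50,
                               n_im = 20, seed = 62)
    expect_true(all(t(pop$dosage) == p))
  }
})

test_that("SSD progeny LD matches the Haldane-Waddington expectation", {
  n <- 1e5
  r <- 0.2
  tw <- two_locus_parents(dist_for_r(r))
  pop <- simulate_population(tw$parents, tw$map, mating_scheme("ssd", 0), n, seed = 63)
  D <- sim_ld(pop$dosage)
  expect_lt(abs(D - ld_ssd(r, 0)), 4 * sqrt(0.25 / n) * 2)
})

test_that("intermating reduces LD by (1 - r)^t (large population)", {
  r <- 0.2
  tw <- two_locus_parents(dist_for_r(r))
  for (t in 1:2) {
    reps <- vapply(1:5, function(rep) {
      pop <- simulate_population(tw$parents, tw$map, mating_scheme("dh", t),
                                 2e4, n_im = 2000, seed = 100 * t + rep)
      sim_ld(pop$dosage)
    }, numeric(1))
    se <- sd(reps) / sqrt(length(reps))
    expect_lt(abs(mean(reps) - ld_dh(r, t)), 4 * se + 1e-4)
  }
})

test_that("exhaustive enumeration reproduces hand-computable DH cases", {
  # 1 locus, g = 1, h = -1: equiprobable +/-1
  map1 <- linkage_map("a", "1", 0)
  ex <- exhaustive_dh_variance(list(g = c(a = 1), h = c(a = -1), beta0 = 0), map1)
  expect_equal(ex$mean, 0)
  expect_equal(ex$variance, 1)
  # 2 unlinked loci: variances add
  map2 <- linkage_map(c("a", "b"), c("1", "2"), c(0, 0))
  ex2 <- exhaustive_dh_variance(list(g = c(a = 1, b = 2), h = c(a = -1, b = 0),
                                     beta0 = 3), map2)
  expect_equal(ex2$mean, 3 + 0 + 1)
  expect_equal(ex2$variance, 1 + 1)
  # refuses over-long chromosomes
  big <- random_cross_case(10, seed = 64)
  expect_error(exhaustive_dh_variance(big$cpe, big$map, max_loci = 8),
               "Monte Carlo")
})

test_that("exhaustive enumeration agrees with a second, independent summation", {
  # independent oracle: loop over integer bit patterns, explicit probability
  naive_dh <- function(cpe, map) {
    ord <- order(map$pos_cM)
    g <- cpe$g[map$marker[ord]]; h <- cpe$h[map$marker[ord]]
    r <- haldane_r(diff(map$pos_cM[ord]))
    L <- length(g)
    m1 <- 0; m2 <- 0
    for (code in 0:(2^L - 1)) {
      bits <- as.integer(intToBits(code))[1:L]
      p <- 0.5
      for (i in seq_len(L - 1))
        p <- p * if (bits[i + 1] != bits[i]) r[i] else 1 - r[i]
      val <- cpe$beta0 + sum(ifelse(bits == 0, g, h))
      m1 <- m1 + p * val
      m2 <- m2 + p * val^2
    }
    list(mean = m1, variance = m2 - m1^2)
  }
  for (seed in 71:74) {
    case <- random_cross_case(8, seed = seed)
    a <- exhaustive_dh_variance(case$cpe, case$map)
    b <- naive_dh(case$cpe, case$map)
    expect_equal(a$mean, b$mean, tolerance = 1e-12)
    expect_equal(a$variance, b$variance, tolerance = 1e-12)
  }
})

test_that("selfing recursion fixpoint matches closed-form limits", {
  expect_equal(two_locus_selfing_fixpoint(0, 0.15), 0.15, tolerance = 1e-10)
  expect_equal(two_locus_selfing_fixpoint(0.5, 0.2), 0.1, tolerance = 1e-8)
  expect_equal(two_locus_selfing_fixpoint(0.2, 0.15), 0.15 / 1.4, tolerance = 1e-8)
  expect_error(two_locus_selfing_fixpoint(0.7, 0.1), "\\[0, 0.5\\]")
  expect_error(two_locus_selfing_fixpoint(0.1, 0.3), "\\[-0.25, 0.25\\]")
})

test_that("Monte Carlo variance estimation is calibrated on a known case", {
  # single locus, |g - h| = 2 -> true DH variance 1, true mean = beta0
  map <- linkage_map("a", "1", 0)
  parents <- rbind(c(a = 2), c(a = 0))
  eff <- marker_effects(5, c(a = 1), 1)   # g = 2, h = 0: var (g-h)^2/4 = 1
  pops <- simulate_cross_replicates(parents, map, mating_scheme("dh", 0),
                                    n_progeny = 200, n_reps = 25, seed = 81)
  est <- mc_variance_estimate(pops, eff)
  expect_lt(abs(est$variance - 1), 4 * est$se_variance)
  expect_lt(abs(est$mean - 6), 4 * sd(est$rep_means) / 5)
  # replicate-averaged mean equals the pooled mean for equal sizes
  pooled <- mean(unlist(lapply(pops, genotypic_values, effects = eff)))
  expect_equal(est$mean, pooled, tolerance = 1e-12)
})

test_that("simulations are reproducible from their seed", {
  tw <- two_locus_parents(30)
  a <- simulate_population(tw$parents, tw$map, mating_scheme("ssd", 1), 100,
                           n_im = 50, seed = 91)
  b <- simulate_population(tw$parents, tw$map, mating_scheme("ssd", 1), 100,
                           n_im = 50, seed = 91)
  expect_identical(a$dosage, b$dosage)
  c2 <- simulate_population(tw$parents, tw$map, mating_scheme("ssd", 1), 100,
                            n_im = 50, seed = 92)
  expect_false(identical(a$dosage, c2$dosage))
})

test_that("simulated progeny are always fully homozygous", {
  case <- random_cross_case(6, seed = 93)
  parents <- rbind(case$p1, case$p2)
  colnames(parents) <- case$map$marker
  for (kind in c("dh", "ssd")) {
    pop <- simulate_population(parents, case$map, mating_scheme(kind, 1), 200,
                               n_im = 30, seed = 94)
    expect_true(all(pop$dosage %in% c(0, 2)))
  }
})
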