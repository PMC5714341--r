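test_that("cross mean is the parental midpoint", {
  map <- toy_map(1, seed = 1)
  eff <- marker_effects(10, setNames(1, map$marker), 1)
  # single marker with g = 1, h = -1 would need effects of opposite sign per
  # parent; use two effects u = 0.5, dosages 2/0 -> g = 1, h = 0... instead
  # construct directly:
  cpe <- list(g = c(m01 = 1), h = c(m01 = -1), beta0 = 10)
  expect_equal(cross_mean(cpe), 10)

  # degenerate cross of a parent with itself
  u <- setNames(c(0.3, -0.2, 0.5), sprintf("m%02d", 1:3))
  eff <- marker_effects(2, u, 1)
  p <- setNames(c(2, 0, 2), names(u))
  cpe2 <- cross_parent_effects(p, p, eff)
  expect_equal(cross_mean(cpe2), 2 + sum(p * u))

  # random 20-marker parents: midpoint of the two parental predicted values
  set.seed(5)
  u20 <- setNames(rnorm(20), sprintf("m%02d", 1:20))
  eff20 <- marker_effects(-3, u20, 1)
  p1 <- setNames(sample(c(0, 2), 20, TRUE), names(u20))
  p2 <- setNames(sample(c(0, 2), 20, TRUE), names(u20))
  cpe3 <- cross_parent_effects(p1, p2, eff20)
  gv <- function(p) -3 + sum(p * u20)
  expect_equal(cross_mean(cpe3), (gv(p1) + gv(p2)) / 2, tolerance = 1e-12)
})

test_that("pair covariance factors as (q/2 - 1/4)(g_j - h_j)(g_k - h_k)", {
  expect_equal(pair_covariance(3, 3, 1, -1, 0.9), 0)    # monomorphic locus j
  expect_equal(pair_covariance(1, -1, 2, 0, 0.5), 0)    # linkage equilibrium
  expect_equal(pair_covariance(1, -1, 1, -1, 1), 1)     # perfect coupling
  expect_error(pair_covariance(1, -1, 1, -1, 1.2), "\\[0, 1\\]")
})

test_that("segregation variance handles degenerate crosses", {
  map <- linkage_map(c("a", "b"), "1", c(0, 10))
  dh0 <- mating_scheme("dh", 0)
  # all loci monomorphic between the parents -> 0
  cpe <- list(g = c(a = 1, b = -2), h = c(a = 1, b = -2), beta0 = 0)
  expect_equal(cross_variance(cpe, map, dh0), 0)
  # single polymorphic locus with |g - h| = 2 -> diagonal term 1
  cpe2 <- list(g = c(a = 1), h = c(a = -1), beta0 = 0)
  expect_equal(cross_variance(cpe2, linkage_map("a", "1", 0), dh0), 1)
})

test_that("unlinked loci give the sum of single-locus variances for both schemes", {
  L <- 6
  set.seed(9)
  map <- linkage_map(sprintf("m%02d", 1:L), as.character(1:L), rep(0, L))
  g <- setNames(rnorm(L), map$marker)
  h <- setNames(rnorm(L), map$marker)
  cpe <- list(g = g, h = h, beta0 = 0)
  expected <- sum((g - h)^2 / 4)
  for (kind in c("dh", "ssd"))
    expect_equal(cross_variance(cpe, map, mating_scheme(kind, 1)), expected,
                 tolerance = 1e-9)
})

test_that("variance is symmetric in the parents and mean shifts with beta0 only", {
  case <- random_cross_case(10, seed = 21)
  dh0 <- mating_scheme("dh", 0)
  swapped <- list(g = case$cpe$h, h = case$cpe$g, beta0 = case$cpe$beta0)
  expect_equal(cross_variance(case$cpe, case$map, dh0),
               cross_variance(swapped, case$map, dh0), tolerance = 1e-12)
  expect_equal(cross_mean(case$cpe), cross_mean(swapped), tolerance = 1e-12)
  shifted <- list(g = case$cpe$g, h = case$cpe$h, beta0 = case$cpe$beta0 + 5)
  expect_equal(cross_variance(shifted, case$map, dh0),
               cross_variance(case$cpe, case$map, dh0))
  expect_equal(cross_mean(shifted), cross_mean(case$cpe) + 5)
})

test_that("SSD shows less coupling-phase variance than DH for linked loci", {
  # coupling phase: one parent carries all plus alleles, so every pairwise
  # term is positive and the weaker SSD LD must lower the variance
  set.seed(31)
  for (rep in 1:5) {
    map <- toy_map(8, seed = 31 + rep)
    u <- setNames(abs(rnorm(8)) + 0.1, map$marker)
    eff <- marker_effects(0, u, 1)
    p1 <- setNames(rep(2, 8), map$marker)
    p2 <- setNames(rep(0, 8), map$marker)
    cpe <- cross_parent_effects(p1, p2, eff)
    v_dh <- cross_variance(cpe, map, mating_scheme("dh", 0))
    v_ssd <- cross_variance(cpe, map, mating_scheme("ssd", 0))
    expect_lt(v_ssd, v_dh)
  }
})

test_that("selection intensity is the truncated-normal mean", {
  expect_equal(selection_intensity(1), 0)
  expect_equal(selection_intensity(0.5), dnorm(0) / 0.5)
  expect_equal(selection_intensity(0.05), 2.062713, tolerance = 1e-6)
  p <- c(0.01, 0.05, 0.2, 0.5, 0.9, 1)
  expect_true(all(diff(selection_intensity(p)) < 0))
  expect_error(selection_intensity(0), "\\(0, 1\\]")
  expect_error(selection_intensity(1.1), "\\(0, 1\\]")
})

test_that("superior progeny value and usefulness combine mu, sigma, i, h", {
  expect_equal(superior_progeny_value(5, 0, 2), 5)
  expect_equal(superior_progeny_value(5, 2, 0), 5)
  expect_equal(superior_progeny_value(100, 2, 2.0627), 104.1254)
  expect_equal(usefulness(100, 2, 2.0627, 1), superior_progeny_value(100, 2, 2.0627))
  expect_equal(usefulness(100, 2, 2.0627, 0), 100)
  expect_equal(usefulness(100, 2, 2.0627, 0.5), 102.0627)
  expect_error(usefulness(1, 1, 1, 1.2), "\\[0, 1\\]")
  expect_error(superior_progeny_value(1, -0.1, 1), ">= 0")
})

test_that("predict_all_crosses enumerates pairs and ranks by s", {
  # 6 unlinked loci with equal effects; every parent carries three plus
  # homozygotes, so all cross means coincide and ranking is by variance:
  # the fully complementary pair A x B segregates at all six loci
  map <- linkage_map(sprintf("m%02d", 1:6), as.character(1:6), rep(0, 6))
  u <- setNames(rep(0.5, 6), map$marker)
  eff <- marker_effects(0, u, 1)
  parents <- rbind(
    A = c(2, 0, 2, 0, 2, 0), B = c(0, 2, 0, 2, 0, 2),
    C = c(2, 2, 0, 0, 2, 0), D = c(0, 2, 2, 0, 0, 2))
  colnames(parents) <- map$marker
  pred <- predict_all_crosses(parents, eff, map, mating_scheme("dh", 0),
                              p = 0.05, h = 1)
  expect_equal(nrow(pred), 6)                      # choose(4, 2)
  expect_true(all(diff(pred$s) <= 1e-12))          # sorted descending
  # the complementary pair has every locus polymorphic -> top variance and s
  # (all crosses share nearly equal means here since effects enter via dosage)
  expect_setequal(c(pred$parent1[1], pred$parent2[1]), c("A", "B"))
  expect_equal(max(pred$sigma2), pred$sigma2[1])

  # two parents -> a single cross; five parents -> 10 crosses
  expect_equal(nrow(predict_all_crosses(parents[1:2, ], eff, map,
                                        mating_scheme("dh", 0))), 1)
  p5 <- rbind(parents, E = rep(c(2, 0), 3))
  expect_equal(nrow(predict_all_crosses(p5, eff, map, mating_scheme("dh", 0))), 10)
})

test_that("heterozygous parents are rejected with line and marker named", {
  map <- toy_map(3, seed = 42)
  eff <- marker_effects(0, setNames(rep(0.5, 3), map$marker), 1)
  parents <- rbind(A = c(2, 1, 0), B = c(0, 2, 2))
  colnames(parents) <- map$marker
  expect_error(predict_all_crosses(parents, eff, map, mating_scheme("dh", 0)),
               "parent A is not homozygous at marker m02")
})

test_that("markers with missing parental dosage are excluded with a warning", {
  map <- toy_map(3, seed = 43)
  eff <- marker_effects(0, setNames(c(1, 1, 1), map$marker), 1)
  p1 <- setNames(c(2, NA, 0), map$marker)
  p2 <- setNames(c(0, 2, 2), map$marker)
  expect_warning(cpe <- cross_parent_effects(p1, p2, eff), "missing parental dosage")
  expect_equal(names(cpe$g), map$marker[c(1, 3)])
})
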