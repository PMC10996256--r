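test_that("standardization centers, whitens, and fails on rank-deficient traits", {
  ## q = 1: proportional to the classic (-1, 0, 1) pattern, scaled by the
  ## divisor-n normalisation
  st1 <- standardize(phenotype_matrix(matrix(c(1, 2, 3), 3, 1)))
  expect_equal(as.vector(st1$Z), c(-1, 0, 1) * sqrt(3 / 2), tolerance = 1e-12)
  ## general: Z'Z/n = I and column means 0
  Y <- make_null_pheno(make_geno(60, 3, seed = 21), 4, rho = 0.5, seed = 22)
  st <- standardize(Y)
  expect_equal(colMeans(st$Z), rep(0, 4), tolerance = 1e-10)
  expect_equal(crossprod(st$Z) / nrow(Y), diag(4), tolerance = 1e-8, ignore_attr = TRUE)
  ## transform fields are mutually consistent
  W <- st$transform$inv_sqrt
  expect_equal(W %*% st$transform$cov %*% W, diag(4), tolerance = 1e-8, ignore_attr = TRUE)
  ## duplicated column -> singular covariance
  Ydup <- phenotype_matrix(cbind(unclass(Y), unclass(Y)[, 1]))
  expect_error(standardize(Ydup), "singular")
  expect_error(standardize(phenotype_matrix(matrix(rnorm(6), 2, 3))), "n > q")
})

test_that("exhaustive slicing counts observed genotype patterns", {
  g1 <- genotype_matrix(matrix(c(0, 0, 1, 2, 2, 2), 6, 1))
  plan <- slice_exhaustive(g1)
  expect_equal(plan$H, 3)
  expect_equal(sort(plan$proportions), sort(c(1 / 3, 1 / 6, 1 / 2)))
  expect_equal(sum(plan$proportions), 1)
  ## k = 2 with all 9 patterns present -> H = 9
  pat <- as.matrix(expand.grid(0:2, 0:2))
  g2 <- genotype_matrix(pat[c(seq_len(9), 1, 5), ])
  expect_equal(slice_exhaustive(g2)$H, 9)
  ## degenerate: one shared pattern
  g3 <- genotype_matrix(matrix(1, 4, 2))
  p3 <- slice_exhaustive(g3)
  expect_equal(p3$H, 1)
  expect_equal(p3$proportions, 1)
  ## cap guard points at the relatedness strategy
  gk <- make_geno(20, 12, seed = 23)
  expect_error(slice_exhaustive(gk), "relatedness")
})

test_that("GRM is the correlation between individuals' genotype vectors", {
  G <- genotype_matrix(matrix(c(0, 2, 0, 1, 1, 1, 1, 2, 0, 2, 2, 0), 4, 3,
                              dimnames = list(c("a", "b", "c", "d"), NULL)))
  R <- compute_grm(G)
  expect_equal(diag(unclass(R)), rep(1, 4), ignore_attr = TRUE)
  expect_equal(unclass(R), t(unclass(R)), ignore_attr = TRUE)
  expect_true(all(abs(unclass(R)) <= 1 + 1e-12))
  ## rows a=(0,1,0) and c=(0,1,2)? use explicit anti-correlated pair
  Gx <- genotype_matrix(rbind(a = c(0, 1, 2), b = c(2, 1, 0), c = c(0, 1, 2)))
  Rx <- unclass(compute_grm(Gx))
  expect_equal(Rx["a", "b"], -1)
  expect_equal(Rx["a", "c"], 1)
  Gc <- genotype_matrix(rbind(a = c(1, 1, 1), b = c(0, 1, 2), c = c(2, 1, 0)))
  expect_error(compute_grm(Gc), "constant genotype.*a")
})

test_that("relatedness slicing forms contiguous blocks and honours the minimum size", {
  G <- make_geno_grm(100, 8, seed = 31)
  plan <- slice_by_relatedness(G, target_slice_size = 10, min_slice_size = 5)
  expect_equal(plan$H, 10)
  expect_true(all(plan$counts == 10))
  expect_equal(plan$strategy, "relatedness")
  ## remainder of 3 merges into the single block of 10
  G13 <- make_geno_grm(13, 8, seed = 32)
  p13 <- slice_by_relatedness(G13, 10, 5)
  expect_equal(p13$H, 1)
  expect_equal(p13$counts, 13L)
  ## minimum-occupancy property across random sizes
  for (s in 1:5) {
    n <- sample(11:80, 1)
    pl <- slice_by_relatedness(make_geno_grm(n, 6, seed = 100 + s), 10, 5)
    expect_true(all(pl$counts >= 5))
    expect_equal(sum(pl$counts), n)
    expect_equal(sum(pl$proportions), 1)
  }
  expect_error(slice_by_relatedness(make_geno_grm(8, 5, seed = 33), 10, 5), "n >= 10")
})

test_that("slice moments: singleton covariance is zero, single slice gives identity", {
  G <- make_geno(40, 2, seed = 41)
  Z <- standardize(make_null_pheno(G, 3, seed = 42))$Z
  plan1 <- structure(list(assignment = rep(1L, 40), H = 1L, counts = 40L,
                          proportions = 1, strategy = "exhaustive"),
                     class = "slicing_plan")
  mom1 <- slice_moments(Z, plan1)
  expect_equal(mom1$slice_covs[[1]], diag(3), tolerance = 1e-8, ignore_attr = TRUE)
  expect_equal(pooled_within_cov(mom1$slice_covs, plan1$proportions), diag(3),
               tolerance = 1e-8, ignore_attr = TRUE)
  plan2 <- structure(list(assignment = c(1L, rep(2L, 39)), H = 2L,
                          counts = c(1L, 39L), proportions = c(1, 39) / 40,
                          strategy = "exhaustive"), class = "slicing_plan")
  mom2 <- slice_moments(Z, plan2)
  expect_equal(mom2$slice_covs[[1]], matrix(0, 3, 3), ignore_attr = TRUE)
})

test_that("within/between decomposition reproduces the law of total covariance", {
  ## hand-checkable 1-D example: two equal slices
  Y <- phenotype_matrix(matrix(c(-3, -1, 1, 3), 4, 1))
  st <- standardize(Y)
  plan <- structure(list(assignment = c(1L, 1L, 2L, 2L), H = 2L,
                         counts = c(2L, 2L), proportions = c(0.5, 0.5),
                         strategy = "exhaustive"), class = "slicing_plan")
  mom <- slice_moments(st$Z, plan)
  E <- pooled_within_cov(mom$slice_covs, plan$proportions)
  between <- sum(plan$proportions * mom$slice_means^2)
  expect_equal(as.vector(E) + between, 1, tolerance = 1e-12)
  ## and in general, for random data and plans
  G <- make_geno(80, 2, seed = 51)
  Yr <- make_null_pheno(G, 4, rho = 0.3, seed = 52)
  str <- standardize(Yr)
  pl <- slice_exhaustive(G)
  m <- slice_moments(str$Z, pl)
  Er <- pooled_within_cov(m$slice_covs, pl$proportions)
  expect_equal(Er + crossprod(sqrt(pl$proportions) * m$slice_means), diag(4),
               tolerance = 1e-8, ignore_attr = TRUE)
  ## equal covariances: convex combination returns the common value
  C <- matrix(c(2, 1, 1, 3), 2, 2)
  expect_equal(pooled_within_cov(list(C, C, C), c(0.2, 0.3, 0.5)), C)
})

test_that("pooled-covariance eigenvalues lie in [0, 1] for random plans", {
  for (s in 1:8) {
    G <- make_geno(60, sample(1:3, 1), seed = 200 + s)
    Y <- make_null_pheno(G, 3, rho = 0.4, seed = 300 + s)
    est <- sir_reduce(Y, G, run_config())
    expect_true(all(est$eigenvalues >= -1e-8))
    expect_true(all(est$eigenvalues <= 1 + 1e-8))
    expect_equal(eq5_deviation(est), 0, tolerance = 1e-8)
  }
})

test_that("directions are unit-norm, sign-fixed, and map back to the trait scale", {
  G <- make_geno(200, 2, seed = 61)
  Y <- make_null_pheno(G, 4, seed = 62)
  est <- sir_reduce(Y, G, run_config())
  expect_equal(sum(est$eta[, 1]^2), 1, tolerance = 1e-10)
  expect_gt(est$eta[which.max(abs(est$eta[, 1])), 1], 0)
  expect_equal(est$directions, t(est$eta) %*% est$transform$inv_sqrt)
  expect_equal(est$reduced_trait,
               as.vector((unclass(Y) %*% t(est$directions)) -
                           mean(unclass(Y) %*% t(est$directions))) +
                 mean(est$reduced_trait),
               tolerance = 1e-8)
  expect_error(estimate_directions(est$pooled_cov, est$transform, d0 = 9), "d0")
})

test_that("reduction is deterministic and equivariant under joint row permutation", {
  G <- make_geno(150, 3, seed = 71)
  B <- matrix(0, 3, 4); B[2, ] <- c(1, -0.5, 0.8, 0)
  Y <- simulate_phenotypes(G, B, rho = 0.2, seed = 72)
  cfg <- run_config()
  e1 <- sir_reduce(Y, G, cfg)
  e2 <- sir_reduce(Y, G, cfg)
  expect_identical(e1$pooled_cov, e2$pooled_cov)
  expect_identical(e1$reduced_trait, e2$reduced_trait)
  set.seed(73); perm <- sample(150)
  Gp <- genotype_matrix(unclass(G)[perm, , drop = FALSE])
  Yp <- phenotype_matrix(unclass(Y)[perm, , drop = FALSE])
  ep <- sir_reduce(Yp, Gp, cfg)
  expect_equal(ep$pooled_cov, e1$pooled_cov, tolerance = 1e-10)
  expect_equal(ep$reduced_trait, e1$reduced_trait[perm], tolerance = 1e-8)
})

test_that("the reduced trait is affine-invariant in the phenotypes", {
  G <- make_geno(300, 2, seed = 81)
  B <- matrix(0, 2, 5); B[1, ] <- c(1, 1, 0.5, 0, 0)
  Y <- simulate_phenotypes(G, B, rho = 0.3, seed = 82)
  est <- sir_reduce(Y, G, run_config())
  set.seed(83)
  A <- matrix(rnorm(25), 5, 5) + diag(5)   # invertible w.p. 1
  Ya <- phenotype_matrix(unclass(Y) %*% t(A))
  esta <- sir_reduce(Ya, G, run_config())
  expect_equal(abs(cor(est$reduced_trait, esta$reduced_trait)), 1, tolerance = 1e-6)
})

test_that("k = 1 exhaustive pooled covariance matches a brute-force computation", {
  G <- make_geno(120, 1, seed = 91)
  Y <- make_null_pheno(G, 3, rho = 0.5, seed = 92)
  est <- sir_reduce(Y, G, run_config())
  bf <- brute_force_sir(unclass(Y), unclass(G))
  expect_equal(est$pooled_cov, bf$E, tolerance = 1e-10, ignore_attr = TRUE)
  expect_equal(abs(sum(est$eta[, 1] * bf$eta)), 1, tolerance = 1e-8)
})
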