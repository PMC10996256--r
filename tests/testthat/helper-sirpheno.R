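## Fixture builders and independent reference implementations used
## across the test files. Everything is generated in code; no stored
## data.

make_geno <- function(n, k, seed = 1) simulate_genotypes(n, k, seed = seed)

## As make_geno, but guarantees no individual is constant across SNPs
## (precondition of the relatedness slicing).
make_geno_grm <- function(n, k, seed = 1) {
  G <- simulate_genotypes(n, k, seed = seed)
  Gv <- unclass(G)
  const <- apply(Gv, 1, function(r) length(unique(r)) == 1L)
  while (any(const)) {
    Gv[const, 1] <- (Gv[const, 1] + 1) %% 3   # deterministic nudge
    const <- apply(Gv, 1, function(r) length(unique(r)) == 1L)
  }
  genotype_matrix(Gv)
}

make_null_pheno <- function(G, q, rho = 0, seed = 2) {
  simulate_phenotypes(G, matrix(0, ncol(G), q), rho = rho, seed = seed)
}

write_tsv_fixture <- function(mat, ids, path) {
  df <- data.frame(sample_id = ids, mat, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

## Brute-force SIR reference, written independently of the package
## internals: standardize with the divisor-n covariance, pool the
## centered within-genotype-pattern covariances directly, take the
## eigenvector of the smallest eigenvalue, map back to the trait scale.
brute_force_sir <- function(Yv, Gv) {
  Yv <- as.matrix(Yv); Gv <- as.matrix(Gv)
  n <- nrow(Yv)
  Yc <- scale(Yv, center = TRUE, scale = FALSE)
  S <- t(Yc) %*% Yc / n
  es <- eigen(S, symmetric = TRUE)
  W <- es$vectors %*% diag(1 / sqrt(es$values), ncol(Yv)) %*% t(es$vectors)
  Z <- Yc %*% W
  pat <- apply(Gv, 1, paste, collapse = "/")
  E <- matrix(0, ncol(Yv), ncol(Yv))
  for (p in unique(pat)) {
    idx <- which(pat == p)
    Zh <- Z[idx, , drop = FALSE]
    Zc <- sweep(Zh, 2, colMeans(Zh))
    E <- E + (t(Zc) %*% Zc) / n          # sum over slices of n_h/n * v_h
  }
  ee <- eigen(E, symmetric = TRUE)
  eta <- ee$vectors[, ncol(Yv)]
  list(E = E, eta = eta, direction = as.vector(t(eta) %*% W))
}

## Deviation of the within/between decomposition from the identity.
eq5_deviation <- function(est) {
  q <- ncol(est$pooled_cov)
  between <- crossprod(sqrt(est$proportions) * est$slice_means)
  max(abs(est$pooled_cov + between - diag(q)))
}

## The 2000-replicate null study used by several acceptance checks is
## expensive; compute it once per test run and share.
acceptance_cache <- new.env(parent = emptyenv())

acceptance_null_study <- function() {
  if (is.null(acceptance_cache$null_study)) {
    spec <- scenario_spec(1, 1, rho = 0, n = 1000, null_model = TRUE)
    cfg <- run_config(n_permutations = 200L, seed = 20240404L)
    acceptance_cache$null_study <- run_experiment(
      spec, c("SIR", "SIR-S", "PCA1", "PCFisher", "PCMinp"),
      replicates = 2000L, cfg = cfg)
  }
  acceptance_cache$null_study
}
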