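## Association tests on the SIR-reduced trait with permutation-calibrated
## p-values, plus classical multivariate Wald baselines.
##
## The permutation null reassigns genotype rows to phenotype rows and
## recomputes the whole pipeline (slicing, reduction, regression) on each
## permuted dataset. Because the slice assignment is a function of the
## genotype rows alone, the assignment of the permuted dataset is exactly
## the observed assignment re-indexed by the permutation, and X'X of the
## genotype design is permutation-invariant; the engine below exploits
## both, which is algebraically identical to a full recompute.

new_test_result <- function(method, statistic, p_value, n_permutations = NA_integer_,
                            df = NA_integer_, per_snp = NULL, seed = NA_integer_) {
  structure(list(method = method, statistic = statistic, p_value = p_value,
                 n_permutations = n_permutations, df = df, per_snp = per_snp,
                 seed = seed),
            class = "sir_test_result")
}

#' @export
print.sir_test_result <- function(x, ...) {
  cat(sprintf("%s test: statistic = %.4g, p = %.4g", x$method, x$statistic, x$p_value))
  if (!is.na(x$n_permutations)) cat(sprintf(" (%d permutations)", x$n_permutations))
  if (!is.na(x$df)) cat(sprintf(" (chi-square, %d df)", x$df))
  cat("\n")
  if (!is.null(x$per_snp)) {
    cat("per-SNP results:\n")
    print(x$per_snp, row.names = FALSE)
  }
  invisible(x)
}

#' Ordinary least squares of the reduced trait on all SNPs
#'
#' Fits y-tilde on the k genotype columns with an intercept and returns
#' the slope vector with its estimated covariance (intercept
#' marginalized out).
#'
#' @param y_tilde n-vector of reduced traits.
#' @param G a `genotype_matrix`.
#' @return list with `beta` (k slopes) and `cov` (k x k).
#' @export
fit_reduced_global <- function(y_tilde, G) {
  Gv <- unclass(as.matrix(G))
  n <- nrow(Gv); k <- ncol(Gv)
  if (n <= k + 1L) stop("need n > k + 1 for the global regression", call. = FALSE)
  X <- cbind(`(Intercept)` = 1, Gv)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    drop_cols <- colnames(X)[qrX$pivot[-seq_len(qrX$rank)]]
    stop("rank-deficient design; collinear columns: ",
         paste(drop_cols, collapse = ", "), call. = FALSE)
  }
  XtXinv <- chol2inv(qr.R(qrX))
  beta_all <- qr.coef(qrX, y_tilde)
  res <- y_tilde - X %*% beta_all
  sigma2 <- sum(res^2) / (n - k - 1L)
  beta <- beta_all[-1]
  V <- sigma2 * XtXinv[-1, -1, drop = FALSE]
  dimnames(V) <- list(colnames(Gv), colnames(Gv))
  names(beta) <- colnames(Gv)
  list(beta = beta, cov = V)
}

#' Wald quadratic form
#'
#' T = beta' Cov(beta)^{-1} beta, nonnegative.
#'
#' @param beta coefficient vector.
#' @param cov its symmetric positive-definite covariance.
#' @return scalar statistic.
#' @export
wald_statistic <- function(beta, cov) {
  ch <- tryCatch(chol(cov), error = function(e)
    stop("covariance matrix is singular", call. = FALSE))
  drop(crossprod(backsolve(ch, beta, transpose = TRUE)))
}

## ---- fast permutation engine ------------------------------------------

## Precompute everything permutation-invariant once.
sir_engine_prep <- function(Y, G, cfg) {
  Gv <- unclass(as.matrix(G))
  n <- nrow(Gv); k <- ncol(Gv)
  st <- standardize(Y)
  plan <- switch(cfg$slicing,
                 exhaustive = slice_exhaustive(G),
                 relatedness = slice_by_relatedness(G, cfg$target_slice_size, cfg$min_slice_size))
  Z <- st$Z
  q <- ncol(Z)
  CzzN <- crossprod(Z) / n
  gbar <- colMeans(Gv)
  Sxx <- colSums(Gv^2) - n * gbar^2
  const_snp <- Sxx <= 1e-12
  if (any(const_snp)) {
    warning("constant SNP column(s): ", paste(colnames(Gv)[const_snp], collapse = ", "),
            "; per-SNP p set to 1; excluded from the global design", call. = FALSE)
  }
  active <- which(!const_snp)
  X <- cbind(1, Gv[, active, drop = FALSE])
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    stop("rank-deficient genotype design; collinear columns: ",
         paste(c("(Intercept)", colnames(Gv)[active])[qrX$pivot[-seq_len(qrX$rank)]],
               collapse = ", "), call. = FALSE)
  }
  XtXinv <- chol2inv(qr.R(qrX))
  Vinv <- solve(XtXinv[-1, -1, drop = FALSE])  # information for slopes
  list(G = Gv, n = n, k = k, q = q, Z = Z, transform = st$transform,
       plan = plan, labels = plan$assignment, nh = plan$counts,
       sqrtp = sqrt(plan$proportions), CzzN = CzzN, XtXinv = XtXinv,
       Vinv = Vinv, gbar = gbar, Sxx = Sxx, const_snp = const_snp,
       active = active)
}

## One pipeline evaluation for permutation `perm` (identity = observed):
## re-estimate the reduction, then the global Wald statistic and the k
## per-SNP statistics. Returns c(T_global, T_1..T_k).
sir_engine_stats <- function(prep, perm = NULL) {
  n <- prep$n; k <- prep$k; q <- prep$q
  lab <- if (is.null(perm)) prep$labels else prep$labels[perm]
  M <- rowsum(prep$Z, lab) / prep$nh
  E <- prep$CzzN - crossprod(prep$sqrtp * M)
  eig <- eigen(E, symmetric = TRUE)
  eta <- fix_sign(eig$vectors[, q])
  yt <- as.vector(prep$Z %*% eta)
  yt <- yt - mean(yt)
  ## regressions use the permuted genotype rows: align yt back onto the
  ## original row order so X'X and Sxx stay reusable
  yo <- yt
  if (!is.null(perm)) yo[perm] <- yt
  gty <- as.vector(crossprod(prep$G, yo))    # per-SNP cross-products
  Syy <- sum(yt^2)
  ## global Wald over the non-constant SNPs
  ka <- length(prep$active)
  Xty <- c(sum(yt), gty[prep$active])
  beta_all <- as.vector(prep$XtXinv %*% Xty)
  sigma2 <- (Syy - sum(beta_all * Xty)) / (n - ka - 1L)
  bs <- beta_all[-1]
  Tg <- sum(bs * (prep$Vinv %*% bs)) / sigma2
  ## per-SNP simple regressions (yt centered, so Sxy = gty)
  b <- ifelse(prep$const_snp, 0, gty / prep$Sxx)
  s2 <- (Syy - b^2 * prep$Sxx) / (n - 2L)
  Tsnp <- ifelse(prep$const_snp, 0, b^2 * prep$Sxx / s2)
  unname(c(Tg, Tsnp))
}

#' Global SIR test and per-SNP SIR-S test in one permutation pass
#'
#' Runs the SIR reduction and both association tests, sharing the
#' permutation stream: for each of B permutations of the genotype rows
#' the full pipeline (slicing, reduction, regressions) is re-estimated
#' and the global Wald statistic and the k per-SNP statistics recorded.
#' P-values use the add-one estimator (1 + #\{T_b >= T_obs\}) / (1 + B);
#' per-SNP p-values are Bonferroni-adjusted across the k SNPs.
#'
#' @param Y a `phenotype_matrix`.
#' @param G a row-aligned `genotype_matrix`.
#' @param cfg a [run_config()]; `cfg$seed` seeds the permutations.
#' @return list with elements `global` and `per_snp`, both
#'   `sir_test_result`s (methods "SIR" and "SIR-S"). The SIR-S overall
#'   p-value is the smallest Bonferroni-adjusted per-SNP p-value.
#' @export
sir_tests <- function(Y, G, cfg = run_config()) {
  if (nrow(Y) != nrow(G)) stop("Y and G must be row-aligned (see align_samples)", call. = FALSE)
  prep <- sir_engine_prep(Y, G, cfg)
  B <- cfg$n_permutations
  obs <- sir_engine_stats(prep)
  perms <- draw_permutations(prep$n, B, cfg$seed)
  exceed <- integer(length(obs))
  for (b in seq_len(B)) {
    stat_b <- sir_engine_stats(prep, perms[, b])
    exceed <- exceed + (stat_b >= obs)
  }
  pvals <- (1 + exceed) / (1 + B)
  snp_ids <- colnames(prep$G) %||% paste0("snp", seq_len(prep$k))
  p_raw <- pvals[-1]
  p_raw[prep$const_snp] <- 1
  per_snp <- data.frame(snp_id = snp_ids, statistic = obs[-1], p = p_raw,
                        p_adjusted = pmin(1, prep$k * p_raw),
                        stringsAsFactors = FALSE)
  list(global = new_test_result("SIR", obs[1], pvals[1], B, per_snp = NULL,
                                seed = cfg$seed),
       per_snp = new_test_result("SIR-S", max(obs[-1]), min(per_snp$p_adjusted),
                                 B, per_snp = per_snp, seed = cfg$seed))
}

#' Global SIR association test
#'
#' Reduction, global regression of the reduced trait on all SNPs, Wald
#' statistic, permutation p-value.
#'
#' @inheritParams sir_tests
#' @return A `sir_test_result` with method "SIR".
#' @export
sir_global_test <- function(Y, G, cfg = run_config()) {
  sir_tests(Y, G, cfg)$global
}

#' Per-SNP SIR-S association test
#'
#' Simple regression of the reduced trait on each SNP, permutation
#' p-value per SNP (the reduction is re-estimated on every permuted
#' dataset), Bonferroni adjustment across the k SNPs.
#'
#' @inheritParams sir_tests
#' @return A `sir_test_result` with method "SIR-S" and `per_snp` table.
#' @export
sirs_test <- function(Y, G, cfg = run_config()) {
  sir_tests(Y, G, cfg)$per_snp
}

#' Generic permutation p-value for an arbitrary statistic
#'
#' Reference route used to validate the fast engine: the statistic
#' callable receives the phenotypes and the row-permuted genotypes and
#' must run whatever pipeline it embodies from scratch. Shares the
#' permutation stream with [sir_tests()] for a given seed.
#'
#' @param Y a `phenotype_matrix`.
#' @param G a `genotype_matrix`.
#' @param cfg a [run_config()].
#' @param statistic function(Y, G, cfg) returning a scalar.
#' @param method label for the result.
#' @return A `sir_test_result`.
#' @export
permutation_pvalue <- function(Y, G, cfg, statistic, method = "custom") {
  n <- nrow(G)
  B <- cfg$n_permutations
  t_obs <- statistic(Y, G, cfg)
  perms <- draw_permutations(n, B, cfg$seed)
  count <- 0L
  for (b in seq_len(B)) {
    Gp <- genotype_matrix(unclass(G)[perms[, b], , drop = FALSE],
                          sample_ids = rownames(Y))
    if (statistic(Y, Gp, cfg) >= t_obs) count <- count + 1L
  }
  new_test_result(method, t_obs, (1 + count) / (1 + B), B, seed = cfg$seed)
}

#' Bonferroni adjustment
#'
#' @param p raw p-values.
#' @param k number of tests (default `length(p)`).
#' @return `pmin(1, k * p)`.
#' @export
bonferroni <- function(p, k = length(p)) pmin(1, k * p)

## ---- classical multivariate Wald baselines -----------------------------

#' Per-SNP multivariate Wald test (all traits on one SNP)
#'
#' Regresses the q traits on SNP j (with intercept); the Wald statistic
#' for the q-vector of slopes is referred to chi-square with q degrees
#' of freedom.
#'
#' @param Y a `phenotype_matrix`.
#' @param G a `genotype_matrix`.
#' @param j SNP index.
#' @return A `sir_test_result` with method "T1".
#' @export
wald_T1 <- function(Y, G, j = 1L) {
  Yv <- unclass(as.matrix(Y)); g <- unclass(as.matrix(G))[, j]
  n <- nrow(Yv); q <- ncol(Yv)
  if (n <= q + 1L) stop("need n > q + 1", call. = FALSE)
  gc <- g - mean(g)
  Sxx <- sum(gc^2)
  if (Sxx <= 1e-12) stop("SNP ", j, " is constant; covariance singular", call. = FALSE)
  Yc <- sweep(Yv, 2, colMeans(Yv))
  beta <- as.vector(crossprod(Yc, gc)) / Sxx            # slopes, length q
  res <- Yc - outer(gc, beta)
  Sigma <- crossprod(res) / (n - 2L)
  T1 <- Sxx * wald_statistic(beta, Sigma)
  new_test_result("T1", T1, pchisq(T1, df = q, lower.tail = FALSE), df = q)
}

#' Joint multivariate Wald test (all traits on all SNPs)
#'
#' Multivariate regression of the q traits on all k SNPs; the Wald
#' statistic over all kq slope coefficients is referred to chi-square
#' with kq degrees of freedom.
#'
#' @param Y a `phenotype_matrix`.
#' @param G a `genotype_matrix`.
#' @return A `sir_test_result` with method "T2".
#' @export
wald_T2 <- function(Y, G) {
  Yv <- unclass(as.matrix(Y)); Gv <- unclass(as.matrix(G))
  n <- nrow(Yv); q <- ncol(Yv); k <- ncol(Gv)
  if (n <= k * q) stop("need n > k*q for estimability", call. = FALSE)
  X <- cbind(1, Gv)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) stop("rank-deficient genotype design", call. = FALSE)
  Bhat <- qr.coef(qrX, Yv)              # (k+1) x q
  res <- Yv - X %*% Bhat
  Sigma <- crossprod(res) / (n - k - 1L)
  XtXinv <- chol2inv(qr.R(qrX))
  Cinv <- solve(XtXinv[-1, -1, drop = FALSE])
  Bs <- Bhat[-1, , drop = FALSE]        # k x q slopes
  ## vec(Bs) has covariance Sigma (x) C; quadratic form via trace
  T2 <- sum(diag(solve(Sigma, t(Bs) %*% Cinv %*% Bs)))
  new_test_result("T2", T2, pchisq(T2, df = k * q, lower.tail = FALSE), df = k * q)
}
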