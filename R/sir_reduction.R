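## Sliced inverse regression of standardized phenotypes on genotype
## slices: standardization, slicing plans, within/between slice moments,
## and estimation of the effective dimension-reduction (e.d.r.)
## directions that project q traits to a single index carrying the
## regression information about the SNPs.

#' Standardize a phenotype matrix
#'
#' Affine transform z_i = Sigma^{-1/2} (y_i - ybar) using the
#' divisor-n (maximum-likelihood) sample covariance, so that the
#' standardized data have exactly mean zero and identity second moment:
#' Z'Z/n = I. This normalisation makes the within/between-slice
#' decomposition of the identity exact in-sample (law of total
#' covariance), which the reduction step relies on.
#'
#' @param Y a `phenotype_matrix` (or plain numeric matrix), n > q.
#' @return list with `Z` (n x q standardized matrix) and `transform`, a
#'   `standardization_transform` holding `mean`, `cov` and `inv_sqrt`.
#' @export
standardize <- function(Y) {
  Yv <- unclass(as.matrix(Y))
  n <- nrow(Yv); q <- ncol(Yv)
  if (n <= q) stop("standardization needs n > q (sample covariance must be invertible)", call. = FALSE)
  mu <- colMeans(Yv)
  Yc <- sweep(Yv, 2, mu)
  S <- crossprod(Yc) / n   # divisor n: see note above
  W <- sym_inv_sqrt(S)
  Z <- Yc %*% W
  transform <- structure(list(mean = mu, cov = S, inv_sqrt = W),
                         class = "standardization_transform")
  list(Z = Z, transform = transform)
}

#' Exhaustive genotype-pattern slicing
#'
#' One slice per distinct genotype vector observed in the data (the
#' natural choice of at most 3^k slices when each of k SNPs takes values
#' in {0,1,2}); unobserved patterns contribute no slice.
#'
#' @param G a `genotype_matrix`.
#' @param cap refuse if 3^k exceeds this (default 3^10): with that many
#'   potential patterns almost all slices would be empty; use
#'   [slice_by_relatedness()] instead.
#' @return A `slicing_plan`: integer `assignment` in 1..H, `H`,
#'   `proportions` (n_h / n), `strategy`.
#' @export
slice_exhaustive <- function(G, cap = 3^10) {
  Gv <- unclass(as.matrix(G))
  k <- ncol(Gv)
  if (3^k > cap) {
    stop(sprintf("3^%d genotype patterns exceed the cap (%s); use slicing strategy 'relatedness'",
                 k, format(cap, scientific = FALSE)), call. = FALSE)
  }
  code <- as.vector(Gv %*% 3^(seq_len(k) - 1))
  assignment <- as.integer(factor(code))
  new_slicing_plan(assignment, "exhaustive")
}

new_slicing_plan <- function(assignment, strategy) {
  n <- length(assignment)
  nh <- tabulate(assignment)
  if (any(nh == 0L)) stop("internal: empty slice in plan", call. = FALSE)
  structure(list(assignment = assignment, H = length(nh),
                 counts = nh, proportions = nh / n, strategy = strategy),
            class = "slicing_plan")
}

#' Genetic relatedness matrix
#'
#' Empirical correlation between individuals' genotype vectors across
#' the k SNPs.
#'
#' @param G a `genotype_matrix` with k >= 2 SNPs.
#' @return An n x n symmetric `grm` matrix with unit diagonal.
#' @export
compute_grm <- function(G) {
  Gv <- unclass(as.matrix(G))
  if (ncol(Gv) < 2L) stop("relatedness needs k >= 2 SNPs", call. = FALSE)
  sds <- apply(Gv, 1, sd)
  if (any(sds == 0)) {
    stop("individual(s) with constant genotype across all SNPs (correlation undefined): ",
         paste(rownames(Gv)[sds == 0], collapse = ", "), call. = FALSE)
  }
  R <- cor(t(Gv))
  dimnames(R) <- list(rownames(Gv), rownames(Gv))
  structure(R, class = c("grm", "matrix"))
}

## Leading eigenvector of a symmetric matrix by power iteration with a
## deterministic start; enough for an ordering of individuals.
leading_eigenvector <- function(S, tol = 1e-10, max_iter = 1000L) {
  n <- nrow(S)
  v <- S[, 1]
  if (sqrt(sum(v^2)) < tol) v <- rep(1, n)
  v <- v / sqrt(sum(v^2))
  for (i in seq_len(max_iter)) {
    w <- S %*% v
    nw <- sqrt(sum(w^2))
    if (nw < tol) break
    w <- as.vector(w) / nw
    if (max(abs(w - v)) < tol || max(abs(w + v)) < tol) { v <- w; break }
    v <- w
  }
  fix_sign(v)
}

#' Relatedness-based slicing
#'
#' For SNP panels too large for exhaustive pattern slices: order
#' individuals along the leading eigenvector of the genetic relatedness
#' matrix (ties broken by input order), cut the ordering into contiguous
#' blocks of `target_slice_size`, then merge adjacent blocks
#' left-to-right until every slice holds at least `min_slice_size`
#' individuals.
#'
#' @param G a `genotype_matrix`.
#' @param target_slice_size initial block size (default 10).
#' @param min_slice_size minimum slice occupancy after merging
#'   (default 5).
#' @return A `slicing_plan` with strategy `"relatedness"`.
#' @export
slice_by_relatedness <- function(G, target_slice_size = 10L, min_slice_size = 5L) {
  Gv <- unclass(as.matrix(G))
  n <- nrow(Gv)
  if (n < 2L * min_slice_size) {
    stop(sprintf("need n >= %d for relatedness slicing with min_slice_size %d",
                 2L * min_slice_size, min_slice_size), call. = FALSE)
  }
  R <- compute_grm(G)
  v <- leading_eigenvector(unclass(R))
  ord <- order(v, seq_len(n))          # ties broken by input order
  nblock <- ceiling(n / target_slice_size)
  sizes <- rep(target_slice_size, nblock)
  rem <- n - target_slice_size * (nblock - 1L)
  sizes[nblock] <- rem
  ## merge left-to-right until every slice has >= min_slice_size
  h <- 1L
  while (h <= length(sizes) && length(sizes) > 1L) {
    if (sizes[h] < min_slice_size) {
      if (h < length(sizes)) {        # merge into the next block
        sizes[h + 1L] <- sizes[h + 1L] + sizes[h]
        sizes <- sizes[-h]
      } else {                         # last block: merge into previous
        sizes[h - 1L] <- sizes[h - 1L] + sizes[h]
        sizes <- sizes[-h]
        h <- h - 1L
      }
    } else h <- h + 1L
  }
  assignment <- integer(n)
  assignment[ord] <- rep(seq_along(sizes), times = sizes)
  new_slicing_plan(assignment, "relatedness")
}

#' Within-slice moments of standardized phenotypes
#'
#' Slice means z_h-bar and centered within-slice covariances
#' v_h = (1/n_h) sum_{i in h} (z_i - zbar_h)(z_i - zbar_h)'. A singleton
#' slice contributes a zero covariance.
#'
#' @param Z standardized n x q matrix from [standardize()].
#' @param plan a `slicing_plan` covering all n rows.
#' @return list with `slice_means` (H x q) and `slice_covs` (list of H
#'   q x q matrices).
#' @export
slice_moments <- function(Z, plan) {
  Z <- as.matrix(Z)
  if (nrow(Z) != length(plan$assignment)) stop("plan does not cover the data rows", call. = FALSE)
  lab <- plan$assignment
  nh <- plan$counts
  M <- rowsum(Z, lab) / nh
  covs <- vector("list", plan$H)
  for (h in seq_len(plan$H)) {
    Zh <- Z[lab == h, , drop = FALSE]
    Zc <- sweep(Zh, 2, M[h, ])
    covs[[h]] <- crossprod(Zc) / nh[h]
  }
  list(slice_means = M, slice_covs = covs)
}

#' Pooled within-slice covariance
#'
#' The proportion-weighted mean E-hat = sum_h p_h v_h, the sample
#' analogue of E[Cov(z | g)].
#'
#' @param slice_covs list of q x q within-slice covariances.
#' @param proportions slice proportions n_h / n.
#' @return symmetric positive semi-definite q x q matrix.
#' @export
pooled_within_cov <- function(slice_covs, proportions) {
  stopifnot(length(slice_covs) == length(proportions))
  E <- Reduce(`+`, Map(`*`, slice_covs, proportions))
  (E + t(E)) / 2
}

#' Estimate e.d.r. directions from the pooled within-slice covariance
#'
#' The standardized directions eta_m are the eigenvectors of E-hat for
#' the d0 smallest eigenvalues (equivalently the leading eigenvectors of
#' the between-slice part I - E-hat). Each is transformed back to the
#' original trait scale as S_m = eta_m' Sigma^{-1/2}. Signs are fixed by
#' making each eta_m's largest-magnitude coordinate positive.
#'
#' @param E pooled within-slice covariance from [pooled_within_cov()].
#' @param transform the `standardization_transform` used to build Z.
#' @param d0 number of directions (default 1).
#' @param Z optional standardized data; if supplied, the reduced trait
#'   y-tilde (projection on the first direction) is returned.
#' @param slice_means,proportions optional, stored for inspection.
#' @return A `sir_estimate`: `pooled_cov`, `eigenvalues` (ascending),
#'   `eta` (q x d0 standardized directions), `directions` (d0 x q rows
#'   on the original scale), `reduced_trait` (n-vector or NULL), plus
#'   slice bookkeeping.
#' @export
estimate_directions <- function(E, transform, d0 = 1L, Z = NULL,
                                slice_means = NULL, proportions = NULL) {
  q <- ncol(E)
  if (d0 > q) stop("d0 cannot exceed the number of traits", call. = FALSE)
  eig <- eigen(E, symmetric = TRUE)          # eigenvalues descending
  values <- rev(eig$values)                  # ascending
  vecs <- eig$vectors[, rev(seq_len(q)), drop = FALSE]
  eta <- vecs[, seq_len(d0), drop = FALSE]
  eta <- apply(eta, 2, fix_sign)
  eta <- matrix(eta, nrow = q)
  directions <- t(eta) %*% transform$inv_sqrt   # rows S_m, original scale
  reduced <- if (!is.null(Z)) as.vector(as.matrix(Z) %*% eta[, 1]) else NULL
  structure(list(pooled_cov = E, slice_means = slice_means,
                 proportions = proportions, eigenvalues = values,
                 eta = eta, directions = directions,
                 reduced_trait = reduced, transform = transform),
            class = "sir_estimate")
}

#' Full SIR reduction pipeline
#'
#' standardize -> slice (strategy per `cfg`) -> within-slice moments ->
#' pooled covariance -> directions; deterministic given inputs and
#' configuration.
#'
#' @param Y a `phenotype_matrix`.
#' @param G a `genotype_matrix`, row-aligned with `Y`.
#' @param cfg a [run_config()].
#' @return A `sir_estimate` including the `slicing_plan` used (element
#'   `plan`) and the reduced trait.
#' @export
sir_reduce <- function(Y, G, cfg = run_config()) {
  if (nrow(Y) != nrow(G)) stop("Y and G must be row-aligned (see align_samples)", call. = FALSE)
  st <- standardize(Y)
  plan <- switch(cfg$slicing,
                 exhaustive = slice_exhaustive(G),
                 relatedness = slice_by_relatedness(G, cfg$target_slice_size, cfg$min_slice_size))
  mom <- slice_moments(st$Z, plan)
  E <- pooled_within_cov(mom$slice_covs, plan$proportions)
  est <- estimate_directions(E, st$transform, cfg$d0, Z = st$Z,
                             slice_means = mom$slice_means,
                             proportions = plan$proportions)
  est$plan <- plan
  est
}

#' @export
print.sir_estimate <- function(x, ...) {
  cat("SIR reduction estimate\n")
  cat(sprintf("  traits: %d, directions retained: %d\n", ncol(x$pooled_cov), ncol(x$eta)))
  cat("  smallest eigenvalues of pooled within-slice covariance:",
      paste(signif(utils::head(x$eigenvalues, 3), 4), collapse = ", "), "\n")
  if (!is.null(x$plan)) cat(sprintf("  slices: %d (%s)\n", x$plan$H, x$plan$strategy))
  invisible(x)
}
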