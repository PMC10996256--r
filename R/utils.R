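## Internal helpers shared across modules.

#' @keywords internal
"_PACKAGE"

#' @importFrom stats cor cov ks.test pchisq pt rbinom rnorm runif sd
#' @importFrom utils read.table write.table
NULL

sp_log <- function(fmt, ..., verbose = getOption("sirpheno.verbose", FALSE)) {
  if (isTRUE(verbose)) message(sprintf(fmt, ...))
  invisible(NULL)
}

## Symmetric inverse square root with a hard floor on the spectrum.
## A near-singular trait covariance is an error, not a pseudo-inverse:
## silently dropping directions would change the null distribution of
## every downstream test.
sym_inv_sqrt <- function(S, floor_frac = 1e-10) {
  eig <- eigen(S, symmetric = TRUE)
  lmax <- max(eig$values)
  if (lmax <= 0 || any(eig$values < floor_frac * lmax)) {
    stop("covariance matrix is singular or near-singular (smallest eigenvalue < ",
         format(floor_frac), " x largest); reduce the trait dimension first",
         call. = FALSE)
  }
  V <- eig$vectors
  V %*% (t(V) / sqrt(eig$values))
}

## Deterministic sign convention for eigen/loading vectors: the entry
## largest in absolute value is made positive.
fix_sign <- function(v) {
  i <- which.max(abs(v))
  if (v[i] < 0) -v else v
}

## Derive independent sub-seeds from one master seed (kept below 2^31).
derive_seeds <- function(seed, n) {
  stopifnot(is.numeric(seed), length(seed) == 1L, n >= 1L)
  old <- globalenv()$.Random.seed
  set.seed(as.integer(seed))
  s <- sample.int(.Machine$integer.max - 1L, n)
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  s
}

## Shared permutation stream so that the fast engine and the generic
## re-fitting route see identical permutations for a given seed.
draw_permutations <- function(n, B, seed) {
  set.seed(as.integer(seed))
  matrix(replicate(B, sample.int(n)), nrow = n, ncol = B)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
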