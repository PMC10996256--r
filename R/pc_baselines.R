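## Principal-component competitor tests: per SNP, the q PC scores of the
## phenotype matrix are each regressed on the SNP, and the per-PC
## p-values are combined -- first PC only (PCA1), Fisher's chi-square
## combination (PCFisher), or the Sidak-corrected minimum (PCMinp) --
## with Bonferroni across the k SNPs for the family-wise decision.

#' Principal-component decomposition of the phenotypes
#'
#' Centered PCA with the deterministic sign convention (the
#' largest-magnitude loading of each component is positive).
#'
#' @param Y a `phenotype_matrix`, n > q.
#' @return A `pc_decomposition`: `scores` (n x q), `loadings` (q x q),
#'   `eigenvalues` (descending, of the divisor-(n-1) covariance).
#' @export
pc_decompose <- function(Y) {
  Yv <- unclass(as.matrix(Y))
  n <- nrow(Yv); q <- ncol(Yv)
  if (n <= q) stop("PCA needs n > q", call. = FALSE)
  Yc <- sweep(Yv, 2, colMeans(Yv))
  eig <- eigen(crossprod(Yc) / (n - 1L), symmetric = TRUE)
  L <- apply(eig$vectors, 2, fix_sign)
  L <- matrix(L, nrow = q)
  structure(list(scores = Yc %*% L, loadings = L, eigenvalues = eig$values),
            class = "pc_decomposition")
}

#' Per-PC p-values for one SNP
#'
#' Two-sided t-test of the slope in the simple regression of each PC
#' score on the SNP dosage.
#'
#' @param scores n x q matrix of PC scores.
#' @param g n-vector of genotype dosages.
#' @return q-vector of p-values (all 1, with a warning, for a constant
#'   SNP).
#' @export
pc_single_snp_pvalues <- function(scores, g) {
  scores <- as.matrix(scores)
  n <- nrow(scores)
  if (sd(g) == 0) {
    warning("constant SNP: per-PC p-values set to 1", call. = FALSE)
    return(rep(1, ncol(scores)))
  }
  r <- suppressWarnings(as.vector(cor(scores, g)))
  r[is.na(r)] <- 0                      # zero-variance score column
  r <- pmin(pmax(r, -1 + 1e-15), 1 - 1e-15)
  tstat <- r * sqrt((n - 2) / (1 - r^2))
  2 * pt(-abs(tstat), df = n - 2)
}

pc_combined <- function(Y, G, combine, method) {
  pc <- pc_decompose(Y)
  Gv <- unclass(as.matrix(G))
  k <- ncol(Gv)
  snp_ids <- colnames(Gv) %||% paste0("snp", seq_len(k))
  raw <- vapply(seq_len(k), function(j) {
    combine(pc_single_snp_pvalues(pc$scores, Gv[, j]))
  }, numeric(2))
  per_snp <- data.frame(snp_id = snp_ids, statistic = raw[1, ], p = raw[2, ],
                        p_adjusted = bonferroni(raw[2, ], k),
                        stringsAsFactors = FALSE)
  best <- which.min(per_snp$p_adjusted)
  new_test_result(method, per_snp$statistic[best], min(per_snp$p_adjusted),
                  per_snp = per_snp)
}

#' First-principal-component test
#'
#' Per SNP, the p-value of the regression of PC1 on the SNP; Bonferroni
#' across SNPs.
#'
#' @param Y a `phenotype_matrix`.
#' @param G a `genotype_matrix`.
#' @param cfg unused, accepted for registry compatibility.
#' @return A `sir_test_result` with per-SNP table.
#' @export
pca1_test <- function(Y, G, cfg = NULL) {
  pc_combined(Y, G, function(p) c(p[1], p[1]), "PCA1")
}

#' Fisher combination of PC p-values
#'
#' Per SNP, X = -2 sum log p_m referred to chi-square with 2q degrees of
#' freedom (PC scores are uncorrelated, and the per-PC p-values treated
#' as independent); Bonferroni across SNPs.
#'
#' @inheritParams pca1_test
#' @return A `sir_test_result` with per-SNP table.
#' @export
pcfisher_test <- function(Y, G, cfg = NULL) {
  pc_combined(Y, G, function(p) {
    x <- -2 * sum(log(pmax(p, 1e-300)))
    c(x, pchisq(x, df = 2 * length(p), lower.tail = FALSE))
  }, "PCFisher")
}

#' Minimum-p combination of PC p-values
#'
#' Per SNP, the Sidak-corrected minimum 1 - (1 - min_m p_m)^q;
#' Bonferroni across SNPs.
#'
#' @inheritParams pca1_test
#' @return A `sir_test_result` with per-SNP table.
#' @export
pcminp_test <- function(Y, G, cfg = NULL) {
  pc_combined(Y, G, function(p) {
    m <- min(p)
    c(m, 1 - (1 - m)^length(p))
  }, "PCMinp")
}
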