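## Generative models and experiment harness for the type-I-error and
## power studies: Hardy-Weinberg genotypes with per-SNP minor-allele
## frequency drawn uniformly from (0.3, 0.5), and multivariate normal
## traits Y = G B + E with AR(1) error covariance.

#' Simulate Hardy-Weinberg genotypes
#'
#' Each SNP's minor-allele frequency p is drawn from
#' Uniform(maf_range); genotype counts follow HWE, i.e. Binomial(2, p)
#' with P(0) = (1-p)^2, P(1) = 2p(1-p), P(2) = p^2, independently across
#' SNPs and individuals.
#'
#' @param n individuals.
#' @param k SNPs.
#' @param maf_range lower/upper bound of the MAF distribution.
#' @param seed optional seed.
#' @return A `genotype_matrix` with attribute `"maf"`.
#' @export
simulate_genotypes <- function(n, k, maf_range = c(0.3, 0.5), seed = NULL) {
  if (length(maf_range) != 2 || maf_range[1] <= 0 || maf_range[2] > 0.5 ||
      maf_range[1] > maf_range[2]) {
    stop("maf_range must be within (0, 0.5]", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(as.integer(seed))
  maf <- runif(k, maf_range[1], maf_range[2])
  vals <- vapply(maf, function(p) rbinom(n, 2L, p), numeric(n))
  vals <- matrix(vals, nrow = n)
  colnames(vals) <- paste0("snp", seq_len(k))
  G <- genotype_matrix(vals)
  attr(G, "maf") <- maf
  G
}

#' AR(1) covariance matrix
#'
#' Sigma_lm = rho^|l-m|, the autoregressive correlation structure used
#' for the trait errors.
#'
#' @param q dimension.
#' @param rho correlation parameter, |rho| < 1.
#' @return q x q symmetric positive-definite matrix.
#' @export
ar1_covariance <- function(q, rho) {
  if (abs(rho) >= 1) stop("|rho| must be < 1", call. = FALSE)
  rho^abs(outer(seq_len(q), seq_len(q), `-`))
}

#' Simulate phenotypes from the linear model
#'
#' y_i = B' g_i + e_i with e_i ~ N(0, Sigma), Sigma the AR(1) matrix,
#' i.i.d. across individuals.
#'
#' @param G a `genotype_matrix`.
#' @param B k x q effect matrix (rows = SNPs).
#' @param rho AR(1) correlation of the errors.
#' @param seed optional seed.
#' @param noise set `FALSE` to suppress the error term (Y = G B exactly).
#' @return A `phenotype_matrix`.
#' @export
simulate_phenotypes <- function(G, B, rho = 0, seed = NULL, noise = TRUE) {
  Gv <- unclass(as.matrix(G))
  B <- as.matrix(B)
  if (nrow(B) != ncol(Gv)) stop("effect matrix must have one row per SNP", call. = FALSE)
  if (!is.null(seed)) set.seed(as.integer(seed))
  n <- nrow(Gv); q <- ncol(B)
  mu <- Gv %*% B
  if (noise) {
    Sigma <- ar1_covariance(q, rho)
    E <- matrix(rnorm(n * q), n, q) %*% chol(Sigma)
    mu <- mu + E
  }
  colnames(mu) <- paste0("trait", seq_len(q))
  phenotype_matrix(mu, sample_ids = rownames(Gv))
}

#' Effect matrices of the simulation scenarios
#'
#' Returns the k x q effect matrix B for the named scenario/case: only
#' the third and fourth SNP rows are nonzero; the third SNP affects the
#' first five traits with effect 1.10 (all positive, or alternating
#' signs in the "mixed" cases) and the fourth SNP affects only the
#' second trait with effect 0.02.
#'
#' Scenario 1 (low q, low k): case 1 k=5,q=5; case 2 k=5,q=10;
#' case 3 k=10,q=5; case 4 k=10,q=10 (mixed signs).
#' Scenario 2 (high q, low k): case 1 k=10,q=50; case 2 k=10,q=50
#' (mixed); case 3 k=10,q=100.
#' Scenario 3 (high q, high k; all mixed): case 1 k=40,q=50;
#' case 2 k=40,q=100; case 3 k=100,q=50; case 4 k=100,q=100.
#'
#' @param scenario 1, 2 or 3.
#' @param case case number within the scenario.
#' @return k x q matrix with attributes `"k"`, `"q"`,
#'   `"nonzero_rows"` (= c(3, 4)).
#' @export
scenario_effects <- function(scenario, case) {
  dims <- scenario_dims(scenario, case)
  k <- dims$k; q <- dims$q; mixed <- dims$mixed
  B <- matrix(0, k, q)
  b3 <- rep(1.10, 5)
  if (mixed) b3 <- b3 * c(1, -1, 1, -1, 1)
  B[3, seq_len(5)] <- b3
  B[4, 2] <- 0.02
  attr(B, "k") <- k; attr(B, "q") <- q; attr(B, "nonzero_rows") <- c(3L, 4L)
  B
}

scenario_dims <- function(scenario, case) {
  key <- paste(scenario, case, sep = ".")
  tab <- list(
    "1.1" = list(k = 5L,   q = 5L,   mixed = FALSE),
    "1.2" = list(k = 5L,   q = 10L,  mixed = FALSE),
    "1.3" = list(k = 10L,  q = 5L,   mixed = FALSE),
    "1.4" = list(k = 10L,  q = 10L,  mixed = TRUE),
    "2.1" = list(k = 10L,  q = 50L,  mixed = FALSE),
    "2.2" = list(k = 10L,  q = 50L,  mixed = TRUE),
    "2.3" = list(k = 10L,  q = 100L, mixed = FALSE),
    "3.1" = list(k = 40L,  q = 50L,  mixed = TRUE),
    "3.2" = list(k = 40L,  q = 100L, mixed = TRUE),
    "3.3" = list(k = 100L, q = 50L,  mixed = TRUE),
    "3.4" = list(k = 100L, q = 100L, mixed = TRUE))
  if (is.null(tab[[key]])) {
    stop("unknown scenario/case; valid: ", paste(names(tab), collapse = ", "),
         call. = FALSE)
  }
  tab[[key]]
}

#' Scenario specification
#'
#' Bundles the generative settings of one simulation cell. The default
#' slicing strategy follows the SNP-panel size: exhaustive
#' genotype-pattern slices for k = 5, relatedness slices for k >= 10
#' (3^k patterns would leave almost all slices empty at these sample
#' sizes).
#'
#' @param scenario,case scenario/case as in [scenario_effects()].
#' @param rho AR(1) trait correlation (presets 0, 0.2, 0.5, 0.7).
#' @param n sample size.
#' @param null_model if `TRUE`, force B = 0 (type-I-error setting).
#' @param effect_scale multiplier applied to the effect matrix.
#' @param maf_range MAF bounds.
#' @return A `scenario_spec`.
#' @export
scenario_spec <- function(scenario, case, rho = 0, n = 1000L,
                          null_model = FALSE, effect_scale = 1,
                          maf_range = c(0.3, 0.5)) {
  dims <- scenario_dims(scenario, case)
  B <- scenario_effects(scenario, case) * effect_scale
  if (null_model) B[] <- 0
  structure(list(scenario = scenario, case = case, n = as.integer(n),
                 k = dims$k, q = dims$q, rho = rho, maf_range = maf_range,
                 B = B, null_model = null_model,
                 slicing = if (dims$k >= 10L) "relatedness" else "exhaustive"),
            class = "scenario_spec")
}

#' Registered test methods
#'
#' Named list of callables `function(Y, G, cfg) -> sir_test_result`
#' usable with [run_experiment()]. "SIR" and "SIR-S" share one
#' permutation pass when requested together.
#'
#' @return named list of functions.
#' @export
method_registry <- function() {
  list(
    "SIR"      = function(Y, G, cfg) sir_tests(Y, G, cfg)$global,
    "SIR-S"    = function(Y, G, cfg) sir_tests(Y, G, cfg)$per_snp,
    "PCA1"     = pca1_test,
    "PCFisher" = pcfisher_test,
    "PCMinp"   = pcminp_test,
    "T1"       = function(Y, G, cfg) {
      k <- ncol(G)
      res <- lapply(seq_len(k), function(j) wald_T1(Y, G, j))
      p <- vapply(res, `[[`, numeric(1), "p_value")
      best <- which.min(p)
      new_test_result("T1", res[[best]]$statistic, min(bonferroni(p, k)),
                      df = res[[best]]$df,
                      per_snp = data.frame(snp_id = colnames(G),
                                           statistic = vapply(res, `[[`, numeric(1), "statistic"),
                                           p = p, p_adjusted = bonferroni(p, k),
                                           stringsAsFactors = FALSE))
    },
    "T2"       = function(Y, G, cfg) wald_T2(Y, G))
}

#' Run a type-I-error or power experiment
#'
#' For each replicate, a fresh genotype and phenotype dataset is drawn
#' from the scenario specification and every requested method is run;
#' the rejection (p-value <= alpha, already family-wise for the per-SNP
#' methods) is recorded. Per-replicate seeds are derived from the master
#' seed, so results are reproducible and independent of execution order.
#' "SIR" and "SIR-S" share a single permutation pass per replicate.
#'
#' @param spec a [scenario_spec()].
#' @param methods character vector of registry names, or a named list of
#'   callables.
#' @param replicates number of simulated datasets.
#' @param cfg a [run_config()]; `cfg$seed` is the master seed and
#'   `cfg$n_permutations` the permutations per test.
#' @return A `sir_experiment` data frame: method, rejections,
#'   replicates, proportion, and binomial standard error; attributes
#'   carry the spec, alpha, permutation count and seed.
#' @export
run_experiment <- function(spec, methods = c("SIR", "SIR-S"),
                           replicates = 100L, cfg = run_config()) {
  if (is.character(methods)) {
    reg <- method_registry()
    unknown <- setdiff(methods, names(reg))
    if (length(unknown)) stop("unknown methods: ", paste(unknown, collapse = ", "), call. = FALSE)
    fns <- reg[methods]
  } else fns <- methods
  mnames <- names(fns)
  cfg$slicing <- spec$slicing
  seeds <- matrix(derive_seeds(cfg$seed, 3L * replicates), ncol = 3L)
  sir_pair <- all(c("SIR", "SIR-S") %in% mnames)
  rej <- matrix(0L, replicates, length(fns), dimnames = list(NULL, mnames))
  pmat <- matrix(NA_real_, replicates, length(fns), dimnames = list(NULL, mnames))
  for (r in seq_len(replicates)) {
    G <- simulate_genotypes(spec$n, spec$k, spec$maf_range, seed = seeds[r, 1])
    Y <- simulate_phenotypes(G, spec$B, spec$rho, seed = seeds[r, 2])
    cfg_r <- cfg; cfg_r$seed <- seeds[r, 3]
    if (sir_pair) {
      both <- sir_tests(Y, G, cfg_r)
      pmat[r, "SIR"] <- both$global$p_value
      pmat[r, "SIR-S"] <- both$per_snp$p_value
    }
    for (m in mnames) {
      if (sir_pair && m %in% c("SIR", "SIR-S")) next
      pmat[r, m] <- fns[[m]](Y, G, cfg_r)$p_value
    }
    rej[r, ] <- as.integer(pmat[r, ] <= cfg$alpha)
  }
  out <- data.frame(method = mnames,
                    rejections = colSums(rej),
                    replicates = replicates,
                    proportion = colMeans(rej),
                    se = sqrt(colMeans(rej) * (1 - colMeans(rej)) / replicates),
                    stringsAsFactors = FALSE)
  structure(out, class = c("sir_experiment", "data.frame"),
            spec = spec, alpha = cfg$alpha, n_permutations = cfg$n_permutations,
            seed = cfg$seed, p_values = pmat)
}

#' @export
print.sir_experiment <- function(x, ...) {
  spec <- attr(x, "spec")
  cat(sprintf("Experiment: scenario %s case %s, n=%d k=%d q=%d rho=%g (%s)\n",
              spec$scenario, spec$case, spec$n, spec$k, spec$q, spec$rho,
              if (spec$null_model) "null model" else "alternative"))
  cat(sprintf("alpha=%g, %d permutations, seed %d\n",
              attr(x, "alpha"), attr(x, "n_permutations"), attr(x, "seed")))
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}
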