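## Data model and readers/writers for genotype and phenotype tables.
##
## Genotypes are minor-allele counts in {0,1,2} for n individuals at k
## SNPs; phenotypes are q continuous traits on the same individuals.
## Both are stored as plain numeric matrices with sample ids as rownames
## and SNP/trait ids as colnames, wrapped in light S3 classes.

#' Construct a genotype matrix
#'
#' @param values integer-like n x k matrix of minor-allele counts, each
#'   entry 0, 1 or 2.
#' @param sample_ids character vector of n unique sample identifiers.
#' @param snp_ids character vector of k unique SNP identifiers.
#' @return An object of class `genotype_matrix` (a numeric matrix with
#'   dimnames).
#' @export
genotype_matrix <- function(values, sample_ids = rownames(values),
                            snp_ids = colnames(values)) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  n <- nrow(values); k <- ncol(values)
  if (n < 2L || k < 1L) stop("genotype matrix needs n >= 2 samples and k >= 1 SNPs", call. = FALSE)
  if (is.null(sample_ids)) sample_ids <- paste0("S", seq_len(n))
  if (is.null(snp_ids)) snp_ids <- paste0("snp", seq_len(k))
  check_unique_ids(sample_ids, "sample")
  check_unique_ids(snp_ids, "SNP")
  bad <- which(!(values %in% c(0, 1, 2)) | !is.finite(values))
  if (length(bad)) {
    i <- ((bad[1] - 1) %% n) + 1; j <- ((bad[1] - 1) %/% n) + 1
    stop(sprintf("genotype entry at sample '%s', SNP '%s' is %s; must be 0, 1 or 2",
                 sample_ids[i], snp_ids[j], format(values[i, j])), call. = FALSE)
  }
  dimnames(values) <- list(sample_ids, snp_ids)
  structure(values, class = c("genotype_matrix", "matrix"))
}

#' Construct a phenotype matrix
#'
#' @param values numeric n x q matrix of continuous trait values.
#' @param sample_ids,trait_ids identifiers; defaults taken from dimnames.
#' @return An object of class `phenotype_matrix`.
#' @export
phenotype_matrix <- function(values, sample_ids = rownames(values),
                             trait_ids = colnames(values)) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  n <- nrow(values); q <- ncol(values)
  if (n < 2L || q < 1L) stop("phenotype matrix needs n >= 2 samples and q >= 1 traits", call. = FALSE)
  if (is.null(sample_ids)) sample_ids <- paste0("S", seq_len(n))
  if (is.null(trait_ids)) trait_ids <- paste0("trait", seq_len(q))
  check_unique_ids(sample_ids, "sample")
  check_unique_ids(trait_ids, "trait")
  if (any(!is.finite(values))) {
    bad <- which(!is.finite(values))[1]
    i <- ((bad - 1) %% n) + 1; j <- ((bad - 1) %/% n) + 1
    stop(sprintf("non-finite phenotype at sample '%s', trait '%s'",
                 sample_ids[i], trait_ids[j]), call. = FALSE)
  }
  dimnames(values) <- list(sample_ids, trait_ids)
  structure(values, class = c("phenotype_matrix", "matrix"))
}

check_unique_ids <- function(ids, what) {
  if (anyDuplicated(ids)) {
    stop(sprintf("duplicate %s ids: %s", what,
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")), call. = FALSE)
  }
  invisible(ids)
}

#' Read a genotype or phenotype matrix from delimited text
#'
#' Expects a header row of column ids and a first column of sample ids;
#' tab- or comma-delimited (sniffed from the header line, or forced via
#' `sep`). Missing values are handled per `missing`: the default mirrors
#' complete-case preprocessing (rows with any missing entry dropped);
#' `"error"` fails; `"mean-impute"` replaces by the column mean (rounded
#' to the nearest valid count for genotypes).
#'
#' @param path file path.
#' @param kind `"genotype"` or `"phenotype"`.
#' @param missing missing-data policy.
#' @param sep field separator; `NULL` to sniff `\t` vs `,`.
#' @return A `genotype_matrix` or `phenotype_matrix`.
#' @export
read_matrix <- function(path, kind = c("genotype", "phenotype"),
                        missing = c("complete-case", "error", "mean-impute"),
                        sep = NULL) {
  kind <- match.arg(kind)
  missing <- match.arg(missing)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(sep)) {
    header <- readLines(path, n = 1L)
    sep <- if (grepl("\t", header)) "\t" else ","
  }
  df <- read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE,
                   check.names = FALSE, na.strings = c("NA", ""))
  if (ncol(df) < 2L) stop("expected a sample-id column plus at least one data column", call. = FALSE)
  ids <- as.character(df[[1]])
  check_unique_ids(ids, "sample")
  vals <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(vals)) {
    bad <- which(is.na(suppressWarnings(apply(vals, 2, as.numeric))) & !is.na(vals))
    storage.mode(vals) <- "double"
    if (length(bad)) stop("non-numeric entries in ", path, call. = FALSE)
  }
  vals <- handle_missing(vals, ids, missing, kind)
  ids <- rownames(vals)
  if (kind == "genotype") genotype_matrix(vals, ids, colnames(vals))
  else phenotype_matrix(vals, ids, colnames(vals))
}

handle_missing <- function(vals, ids, missing, kind) {
  rownames(vals) <- ids
  nmiss <- sum(is.na(vals))
  if (nmiss == 0) return(vals)
  if (missing == "error") {
    bad <- which(is.na(vals), arr.ind = TRUE)[1, ]
    stop(sprintf("missing %s value at sample '%s', column '%s' (policy 'error')",
                 kind, ids[bad[1]], colnames(vals)[bad[2]]), call. = FALSE)
  }
  if (missing == "complete-case") {
    keep <- stats::complete.cases(vals)
    sp_log("dropped %d of %d samples with missing %s values", sum(!keep), nrow(vals), kind)
    return(vals[keep, , drop = FALSE])
  }
  ## mean-impute
  for (j in seq_len(ncol(vals))) {
    na <- is.na(vals[, j])
    if (any(na)) {
      m <- mean(vals[!na, j])
      if (kind == "genotype") m <- max(0, min(2, round(m)))
      vals[na, j] <- m
    }
  }
  vals
}

#' Write a genotype or phenotype matrix to delimited text
#'
#' Inverse of [read_matrix()]: header row of column ids, first column of
#' sample ids.
#'
#' @param x a `genotype_matrix` or `phenotype_matrix`.
#' @param path output path.
#' @param sep field separator.
#' @export
write_matrix <- function(x, path, sep = "\t") {
  df <- data.frame(sample_id = rownames(x), unclass(x), check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read genotypes from a VCF as alternate-allele dosages
#'
#' Biallelic sites only: multi-allelic records are skipped with a
#' warning. The genotype is the count of alternate alleles in the GT
#' field. Set `flip_to_minor = TRUE` to recode sites where the alternate
#' allele is the major allele (count flipped 0<->2) so that counts are of
#' the minor allele.
#'
#' @param path VCF file path.
#' @param missing policy for missing GT calls (`"error"` default,
#'   `"complete-case"`, `"mean-impute"`).
#' @param flip_to_minor flip columns whose alternate-allele frequency
#'   exceeds 0.5.
#' @return A `genotype_matrix`.
#' @export
read_vcf_dosages <- function(path, missing = c("error", "complete-case", "mean-impute"),
                             flip_to_minor = FALSE) {
  missing <- match.arg(missing)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  alt <- v@fix[, "ALT"]
  multi <- grepl(",", alt)
  if (any(multi)) {
    warning(sprintf("skipping %d multi-allelic site(s): %s", sum(multi),
                    paste(v@fix[multi, "ID"], collapse = ", ")), call. = FALSE)
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  gt <- gt[!multi, , drop = FALSE]
  if (nrow(gt) == 0L) stop("no biallelic sites with GT in ", path, call. = FALSE)
  ids <- v@fix[!multi, "ID"]
  ids[is.na(ids) | ids == "."] <- paste0(v@fix[!multi, "CHROM"], ":", v@fix[!multi, "POS"])[is.na(ids) | ids == "."]
  dose <- apply(gt, c(1, 2), function(g) {
    if (is.na(g) || g %in% c("./.", ".|.", ".")) return(NA_real_)
    sum(strsplit(g, "[/|]")[[1]] == "1")
  })
  vals <- t(dose)  # samples x sites
  colnames(vals) <- ids
  vals <- handle_missing(vals, rownames(vals), missing, "genotype")
  if (flip_to_minor) {
    af <- colMeans(vals) / 2
    flip <- af > 0.5
    vals[, flip] <- 2 - vals[, flip]
    if (any(flip)) sp_log("flipped %d site(s) to minor-allele counts", sum(flip))
  }
  genotype_matrix(vals, rownames(vals), colnames(vals))
}

#' Align genotype and phenotype matrices by sample id
#'
#' Restricts both matrices to the intersection of their sample ids, in
#' the order the ids appear in the genotype matrix. Idempotent.
#'
#' @param G a `genotype_matrix`.
#' @param Y a `phenotype_matrix`.
#' @return A list with elements `G` and `Y`, row-aligned.
#' @export
align_samples <- function(G, Y) {
  common <- intersect(rownames(G), rownames(Y))
  if (length(common) == 0L) stop("no samples in common between genotype and phenotype matrices", call. = FALSE)
  dropped <- (nrow(G) - length(common)) + (nrow(Y) - length(common))
  if (dropped > 0) sp_log("align_samples: dropped %d unmatched sample row(s)", dropped)
  list(G = genotype_matrix(unclass(G)[common, , drop = FALSE]),
       Y = phenotype_matrix(unclass(Y)[common, , drop = FALSE]))
}

#' Run configuration
#'
#' Holds the tuning parameters shared by the association tests and the
#' simulation harness.
#'
#' @param alpha nominal significance level, in (0,1).
#' @param n_permutations permutations for the null calibration
#'   (default 1000).
#' @param slicing `"exhaustive"` (one slice per observed genotype
#'   pattern, feasible for small k) or `"relatedness"` (slices from the
#'   genetic relatedness matrix, for larger SNP panels).
#' @param target_slice_size initial block size for relatedness slicing.
#' @param min_slice_size minimum individuals per slice after merging.
#' @param d0 number of reduction directions retained (tests use 1).
#' @param seed master seed for all stochastic steps.
#' @return An object of class `run_config`.
#' @export
run_config <- function(alpha = 0.05, n_permutations = 1000L,
                       slicing = c("exhaustive", "relatedness"),
                       target_slice_size = 10L, min_slice_size = 5L,
                       d0 = 1L, seed = 1L) {
  slicing <- match.arg(slicing)
  stopifnot(alpha > 0, alpha < 1, n_permutations >= 1, min_slice_size >= 2,
            d0 >= 1, target_slice_size >= min_slice_size)
  structure(list(alpha = alpha, n_permutations = as.integer(n_permutations),
                 slicing = slicing,
                 target_slice_size = as.integer(target_slice_size),
                 min_slice_size = as.integer(min_slice_size),
                 d0 = as.integer(d0), seed = as.integer(seed)),
            class = "run_config")
}

#' Read a run configuration from YAML or JSON
#'
#' Keys map one-to-one onto the arguments of [run_config()]; unknown
#' keys are an error.
#'
#' @param path a `.yaml`/`.yml` or `.json` file.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  cfg <- if (grepl("\\.json$", path)) jsonlite::read_json(path, simplifyVector = TRUE)
         else yaml::read_yaml(path)
  known <- names(formals(run_config))
  extra <- setdiff(names(cfg), known)
  if (length(extra)) stop("unknown run_config keys: ", paste(extra, collapse = ", "), call. = FALSE)
  do.call(run_config, cfg)
}
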