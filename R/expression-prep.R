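# Raw counts (genes + HERV loci) -> filtered, normalized,
# covariate-adjusted expression ready for weight construction and network
# analysis. Counts matrices are features x samples throughout.

#' Transcripts per million
#'
#' tpm_fs = (count_fs / length_f) / sum_f(count_fs / length_f) * 1e6.
#' HERV locus length is the annotated interval length.
#'
#' @param counts features x samples count matrix
#' @param lengths per-feature length in bp (named or in row order)
#' @return TPM matrix of the same shape; columns sum to 1e6
#' @export
compute_tpm <- function(counts, lengths) {
  if (!is.null(names(lengths))) lengths <- lengths[rownames(counts)]
  if (length(lengths) != nrow(counts)) stop_config("one length per feature required")
  if (any(lengths <= 0)) stop_config("zero or negative feature length")
  rate <- counts / lengths
  sweep(rate, 2L, colSums(rate), "/") * 1e6
}

#' Expression filter on joint count and TPM thresholds
#'
#' A feature is kept iff the fraction of samples in which, jointly,
#' count >= min_count AND tpm >= min_tpm reaches `min_fraction`. The two
#' conditions are evaluated per sample together (the stricter, GTEx-style
#' reading of "in at least 20% of samples").
#'
#' @param counts,tpm matrices of identical shape (features x samples)
#' @param min_count,min_tpm,min_fraction thresholds; defaults 6 / 0.1 / 0.2
#' @return character vector of kept feature ids (row names)
#' @export
filter_expressed <- function(counts, tpm, min_count = 6, min_tpm = 0.1,
                             min_fraction = 0.2) {
  if (!identical(dim(counts), dim(tpm))) stop_config("counts/tpm shape mismatch")
  ok <- (counts >= min_count) & (tpm >= min_tpm)
  frac <- rowMeans(ok)
  rownames(counts)[frac >= min_fraction]
}

#' TMM normalization factors
#'
#' Trimmed mean of M-values between-sample factors (doubly trimmed,
#' precision-weighted mean of log-ratios against a reference sample chosen
#' by upper-quartile proximity to the mean upper quartile), as implemented
#' in edgeR. Factors are rescaled to geometric mean 1.
#'
#' @param counts features x samples count matrix
#' @param trim_M log-ratio trim fraction (default 0.30)
#' @param trim_A absolute-intensity trim fraction (default 0.05)
#' @return object of class `norm_factors`: list with `factors` (per-sample,
#'   geometric mean 1), `lib_size`, `reference_sample`, `trim_M`, `trim_A`
#' @export
tmm_factors <- function(counts, trim_M = 0.30, trim_A = 0.05) {
  ns <- ncol(counts)
  lib <- colSums(counts)
  if (any(lib <= 0)) stop_config("every sample needs positive total counts")
  if (ns < 2) {
    warning("single sample: identity normalization factor")
    f <- stats::setNames(1, colnames(counts))
    return(structure(list(factors = f, lib_size = lib,
                          reference_sample = colnames(counts)[1],
                          trim_M = trim_M, trim_A = trim_A),
                     class = "norm_factors"))
  }
  uq <- apply(counts, 2L, function(x) stats::quantile(x[x > 0] / sum(x), 0.75))
  ref <- which.min(abs(uq - mean(uq)))
  f <- edgeR::calcNormFactors(counts, lib.size = lib, method = "TMM",
                              refColumn = ref, logratioTrim = trim_M,
                              sumTrim = trim_A, doWeighting = TRUE)
  names(f) <- colnames(counts)
  structure(list(factors = f, lib_size = lib,
                 reference_sample = colnames(counts)[ref] %||% ref,
                 trim_M = trim_M, trim_A = trim_A),
            class = "norm_factors")
}

#' @export
print.norm_factors <- function(x, ...) {
  cat("TMM factors for", length(x$factors), "samples; reference:",
      x$reference_sample, "\n")
  print(round(x$factors, 4))
  invisible(x)
}

#' log2 counts per million on TMM-effective library sizes
#'
#' log2((count + prior_count) / (effective library + 2 * prior_count) * 1e6)
#' with effective library = raw library size * TMM factor.
#'
#' @param counts features x samples count matrix
#' @param factors a [tmm_factors()] result (or NULL for raw library sizes)
#' @param prior_count shrinkage pseudo-count (default 0.5)
#' @return logCPM matrix
#' @export
logcpm <- function(counts, factors = NULL, prior_count = 0.5) {
  lib <- colSums(counts)
  f <- if (is.null(factors)) rep(1, ncol(counts)) else factors$factors
  if (any(f <= 0)) stop_config("normalization factors must be positive")
  eff <- lib * f
  t(log2(t(counts + prior_count) / (eff + 2 * prior_count) * 1e6))
}

#' Genotype principal components
#'
#' SNPs are greedily LD-pruned (a SNP is kept if its squared correlation
#' with every previously kept SNP on the same chromosome stays below
#' `prune_r2`), standardized by sqrt(2 p (1 - p)), and the top-k left
#' singular vectors of the sample x SNP matrix are returned.
#'
#' @param G a [geno_matrix()]
#' @param k number of components (default 10)
#' @param prune_r2 LD pruning threshold on r^2 (default 0.2)
#' @return samples x k orthonormal matrix of PC loadings
#' @export
genotype_pcs <- function(G, k = 10, prune_r2 = 0.2) {
  X <- G$dosage
  p <- colMeans(X, na.rm = TRUE) / 2
  keep_poly <- p > 0 & p < 1
  X <- X[, keep_poly, drop = FALSE]
  p <- p[keep_poly]
  Xs <- sweep(sweep(X, 2L, 2 * p, "-"), 2L, sqrt(2 * p * (1 - p)), "/")
  Xs[is.na(Xs)] <- 0
  chroms <- G$map$chrom[keep_poly]
  kept <- logical(ncol(Xs))
  for (ch in unique(chroms)) {
    idx <- which(chroms == ch)
    sel <- integer(0)
    for (j in idx) {
      if (length(sel) == 0L) { sel <- j; kept[j] <- TRUE; next }
      r <- drop(crossprod(Xs[, sel, drop = FALSE], Xs[, j])) / (nrow(Xs) - 1L)
      if (max(r^2) < prune_r2) { sel <- c(sel, j); kept[j] <- TRUE }
    }
  }
  Xp <- Xs[, kept, drop = FALSE]
  r <- min(nrow(Xp) - 1L, ncol(Xp))
  if (k > r) {
    warning("requested ", k, " PCs but rank allows ", r)
    k <- r
  }
  sv <- svd(scale(Xp, scale = FALSE), nu = k, nv = 0)
  pcs <- sv$u[, seq_len(k), drop = FALSE]
  rownames(pcs) <- rownames(G$dosage)
  colnames(pcs) <- paste0("PC", seq_len(k))
  pcs
}

#' Surrogate-variable count as a function of sample size
#'
#' 30 for 150 <= N <= 250 and 60 for N > 350, interpolated linearly (and
#' floored) in between; 15 below 150 (the tier below the quoted rule).
#'
#' @param n_samples cohort size
#' @return integer number of surrogate variables
#' @export
sv_count <- function(n_samples) {
  n <- n_samples
  if (n < 150) return(15L)
  if (n <= 250) return(30L)
  if (n > 350) return(60L)
  as.integer(floor(30 + 30 * (n - 250) / 100))
}

#' Residualize expression on known covariates and surrogate variables
#'
#' Per-feature OLS residuals on the column space of the known-covariate
#' design plus surrogate vectors. Surrogate vectors are the top principal
#' components (sample-space singular vectors) of the expression matrix
#' already residualized on the known covariates — a deterministic proxy for
#' iterative surrogate-variable estimation. Collinear design columns are
#' dropped by pivoted QR before fitting.
#'
#' @param expr features x samples expression matrix (e.g. logCPM)
#' @param covariates samples x q data frame (factors allowed) or matrix;
#'   NULL for intercept-only (centering)
#' @param n_sv number of surrogate vectors; default [sv_count()] of the
#'   sample size; 0 disables
#' @return features x samples matrix of residuals, with the surrogate
#'   vectors in attribute `"sv"` and dropped design columns in
#'   `"dropped_columns"`
#' @export
residualize <- function(expr, covariates = NULL, n_sv = NULL) {
  n <- ncol(expr)
  design <- if (is.null(covariates)) {
    matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  } else {
    stats::model.matrix(~ ., data = as.data.frame(covariates))
  }
  qrD <- qr(design)
  dropped <- character(0)
  if (qrD$rank < ncol(design)) {
    keep <- qrD$pivot[seq_len(qrD$rank)]
    dropped <- colnames(design)[-keep]
    design <- design[, keep, drop = FALSE]
    qrD <- qr(design)
    if (qrD$rank < ncol(design)) {
      stop_config("design still rank deficient after dropping: ",
                  paste(dropped, collapse = ", "))
    }
  }
  resid_known <- t(qr.resid(qrD, t(expr)))
  n_sv <- n_sv %||% sv_count(n)
  n_sv <- min(n_sv, n - ncol(design) - 1L)
  if (n_sv > 0) {
    sv <- svd(scale(t(resid_known), scale = FALSE), nu = n_sv, nv = 0)$u
    colnames(sv) <- paste0("SV", seq_len(ncol(sv)))
    full <- cbind(design, sv)
    out <- t(qr.resid(qr(full), t(expr)))
  } else {
    sv <- NULL
    out <- resid_known
  }
  dimnames(out) <- dimnames(expr)
  attr(out, "sv") <- sv
  attr(out, "dropped_columns") <- dropped
  out
}
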