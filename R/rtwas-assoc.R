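# Summary-statistic association of genetically predicted expression with a
# trait, Bonferroni correction over tested features, and the report
# fractions printed in cohort summaries.

#' LD correlation matrix from a reference panel
#'
#' @param G a [geno_matrix()]
#' @param snps SNP ids (must exist in the panel)
#' @param ridge_eps convex ridge toward the identity:
#'   (1 - eps) R + eps I, preserving the unit diagonal
#' @return correlation matrix with attribute `"ridge_eps"`
#' @export
ld_matrix <- function(G, snps, ridge_eps = 0) {
  idx <- match(snps, G$map$snp)
  if (anyNA(idx)) stop_config("SNPs absent from the LD panel: ",
                              paste(utils::head(snps[is.na(idx)]), collapse = ", "))
  R <- stats::cor(G$dosage[, idx, drop = FALSE])
  R[is.na(R)] <- 0
  diag(R) <- 1
  if (ridge_eps > 0) R <- (1 - ridge_eps) * R + diag(ridge_eps, nrow(R))
  dimnames(R) <- list(snps, snps)
  attr(R, "ridge_eps") <- ridge_eps
  R
}

#' TWAS association statistic from summary data
#'
#' Z = w'z / sqrt(w' R w); P = 2 * pnorm(-|Z|). The degenerate-variance
#' check uses the unridged quadratic form; when `ridge_eps > 0` the
#' denominator is computed on (1 - eps) R + eps I.
#'
#' @param w weight vector
#' @param z harmonized SNP z-scores on the identical, allele-aligned SNP set
#' @param R LD correlation matrix on the same set
#' @param ridge_eps ridge toward the identity applied to the denominator
#'   (default 0)
#' @return list with `z` (the association Z), `p`, `var` (the quadratic
#'   form used), and `degenerate` flag (TRUE when w'Rw <= 1e-8, in which
#'   case z and p are NA)
#' @export
twas_stat <- function(w, z, R, ridge_eps = 0) {
  stopifnot(length(w) == length(z), all(dim(R) == length(w)))
  raw_var <- drop(t(w) %*% R %*% w)
  if (raw_var <= 1e-8) {
    return(list(z = NA_real_, p = NA_real_, var = raw_var, degenerate = TRUE))
  }
  v <- if (ridge_eps > 0) (1 - ridge_eps) * raw_var + ridge_eps * sum(w^2)
       else raw_var
  Z <- sum(w * z) / sqrt(v)
  list(z = Z, p = 2 * stats::pnorm(-abs(Z)), var = v, degenerate = FALSE)
}

#' Bonferroni adjustment
#'
#' @param p nominal p-value(s) in [0, 1]
#' @param m number of tests (>= 1)
#' @return min(1, p * m)
#' @export
bonferroni_adjust <- function(p, m) {
  if (any(p < 0 | p > 1)) stop_config("p must lie in [0, 1]")
  if (m < 1) stop_config("m must be >= 1")
  pmin(1, p * m)
}

#' Transcriptome-wide significance threshold
#'
#' @param m number of tested genetic features
#' @param alpha family-wise error rate (default 0.05)
#' @return the per-feature two-sided p-value cut-off alpha / m
#' @export
significance_threshold <- function(m, alpha = 0.05) {
  if (m < 1) stop_config("m must be >= 1")
  alpha / m
}

#' Run the rTWAS over a weight store
#'
#' One row per usable feature. m for the Bonferroni correction is the
#' number of features actually tested (genes and HERV loci under a single
#' threshold). Features with fewer than `min_coverage` of their weight
#' SNPs present in the harmonized summary statistics are flagged
#' low-coverage but retained.
#'
#' @param store a `weight_store` from [compute_weights()]
#' @param ss harmonized summary statistics ([harmonize_sumstats()])
#' @param ld_source a [geno_matrix()] LD reference (the weight panel)
#' @param ridge_eps LD ridge used in the association denominator
#'   (default 0.1)
#' @param min_coverage low-coverage flag threshold (default 0.5)
#' @return data frame of class `twas_result`: id, class, chr, p0, p1,
#'   best_model, nsnp, twas_z, twas_p, bonf_p, flags; attributes `m`,
#'   `threshold`, `ridge_eps`
#' @export
run_rtwas <- function(store, ss, ld_source, ridge_eps = 0.1,
                      min_coverage = 0.5) {
  rows <- list()
  for (fid in names(store$weights)) {
    wset <- store$weights[[fid]]
    w <- wset$w
    use <- which(w != 0)
    if (length(use) == 0) next
    snps <- wset$snps[use]
    hit <- match(snps, ss$snp)
    coverage <- mean(!is.na(hit))
    ok <- !is.na(hit)
    if (!any(ok)) next
    snps <- snps[ok]
    wv <- w[use][ok]
    zv <- ss$z[hit[ok]]
    R <- ld_matrix(ld_source, snps)
    st <- twas_stat(wv, zv, R, ridge_eps = ridge_eps)
    flags <- c(if (coverage < min_coverage) "low_coverage",
               if (st$degenerate) "degenerate_variance")
    if (st$degenerate) next
    rows[[fid]] <- data.frame(
      id = fid, class = wset$class %||% NA_character_,
      chr = wset$chrom %||% NA_character_,
      p0 = wset$start %||% NA_integer_, p1 = wset$end %||% NA_integer_,
      best_model = wset$best_method, nsnp = length(snps),
      twas_z = st$z, twas_p = st$p, bonf_p = NA_real_,
      flags = paste(flags, collapse = ";"),
      stringsAsFactors = FALSE)
  }
  if (length(rows) == 0) stop_config("zero usable features in the rTWAS")
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  m <- nrow(res)
  res$bonf_p <- bonferroni_adjust(res$twas_p, m)
  attr(res, "m") <- m
  attr(res, "threshold") <- significance_threshold(m)
  attr(res, "ridge_eps") <- ridge_eps
  class(res) <- c("twas_result", class(res))
  res
}

#' Class composition of significant associations, and table-to-table change
#'
#' Counts and integer-rounded percentages of HERV vs gene features among
#' Bonferroni-significant hits; optionally the integer-rounded percent
#' change in significant-hit counts against a second result table.
#'
#' @param results a `twas_result` table (or any data frame with `class` and
#'   `bonf_p` columns)
#' @param alpha Bonferroni significance level (default 0.05)
#' @param other optional second result table to compare counts against
#' @return list: n_sig, n_herv, n_gene, pct_herv, pct_gene, and (when
#'   `other` is given) pct_change of n_sig relative to `results`
#' @export
report_fractions <- function(results, alpha = 0.05, other = NULL) {
  if (nrow(results) == 0) stop_config("empty result table")
  sig <- results[results$bonf_p < alpha, , drop = FALSE]
  n_sig <- nrow(sig)
  n_herv <- sum(sig$class == "herv")
  n_gene <- sum(sig$class == "gene")
  out <- list(n_sig = n_sig, n_herv = n_herv, n_gene = n_gene,
              pct_herv = if (n_sig > 0) fraction_pct(n_herv, n_sig) else NA_integer_,
              pct_gene = if (n_sig > 0) fraction_pct(n_gene, n_sig) else NA_integer_)
  if (!is.null(other)) {
    n_other <- sum(other$bonf_p < alpha)
    out$n_sig_other <- n_other
    out$pct_change <- percent_change(n_sig, n_other, denom = "a")
  }
  out
}
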