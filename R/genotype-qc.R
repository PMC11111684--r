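# Variant/sample quality control and GWAS summary-statistic harmonization
# against the weight/LD panel.

#' Hardy-Weinberg equilibrium chi-square test
#'
#' 1-df goodness-of-fit of observed genotype counts against the
#' Hardy-Weinberg expectation at the sample allele frequency. Monomorphic
#' sites return p = 1.
#'
#' @param nAA,nAa,naa genotype counts
#' @return two-sided p-value
#' @export
hwe_test <- function(nAA, nAa, naa) {
  n <- nAA + nAa + naa
  if (n <= 0) stop_config("empty genotype table")
  p <- (2 * nAA + nAa) / (2 * n)
  if (p <= 0 || p >= 1) return(1)
  e <- n * c(p^2, 2 * p * (1 - p), (1 - p)^2)
  x2 <- sum((c(nAA, nAa, naa) - e)^2 / e)
  stats::pchisq(x2, df = 1, lower.tail = FALSE)
}

is_strand_ambiguous <- function(a1, a2) {
  (a1 == "A" & a2 == "T") | (a1 == "T" & a2 == "A") |
  (a1 == "C" & a2 == "G") | (a1 == "G" & a2 == "C")
}

#' Variant-level QC mask
#'
#' Keeps variants with MAF > `maf_min`, Hardy-Weinberg p >= `hwe_p_min` and
#' missing rate < `miss_max`; optionally drops strand-ambiguous (A/T, C/G)
#' variants regardless of other metrics.
#'
#' @param G a [geno_matrix()]
#' @param maf_min,hwe_p_min,miss_max thresholds (defaults 0.05 / 5e-6 / 0.05)
#' @param drop_ambiguous drop A/T and C/G variants (default TRUE)
#' @return logical keep-mask over variants, with a per-filter tally in
#'   attribute `"report"`
#' @export
variant_qc <- function(G, maf_min = 0.05, hwe_p_min = 5e-6, miss_max = 0.05,
                       drop_ambiguous = TRUE) {
  X <- G$dosage
  miss <- colMeans(is.na(X))
  p <- colMeans(X, na.rm = TRUE) / 2
  maf <- pmin(p, 1 - p)
  hard <- round(X)
  hwe <- vapply(seq_len(ncol(X)), function(j) {
    g <- hard[, j]
    hwe_test(sum(g == 2, na.rm = TRUE), sum(g == 1, na.rm = TRUE),
             sum(g == 0, na.rm = TRUE))
  }, numeric(1))
  amb <- is_strand_ambiguous(G$map$a1, G$map$a2)
  keep <- maf > maf_min & hwe >= hwe_p_min & miss < miss_max
  if (drop_ambiguous) keep <- keep & !amb
  attr(keep, "report") <- data.frame(
    filter = c("maf", "hwe", "missing", "ambiguous"),
    n_failed = c(sum(maf <= maf_min), sum(hwe < hwe_p_min),
                 sum(miss >= miss_max), if (drop_ambiguous) sum(amb) else 0L))
  keep
}

#' Method-of-moments IBD proportion between two samples
#'
#' Estimates P(IBD = 0/1/2) from observed identity-by-state counts and the
#' panel allele frequencies, and returns pihat = P(IBD=1)/2 + P(IBD=2),
#' clamped to [0, 1]. Dosages are rounded to hard genotypes.
#'
#' @param G a [geno_matrix()]
#' @param i,j sample indices or ids
#' @param min_shared minimum number of jointly non-missing variants
#' @param freqs optional reference allele frequencies (per variant, for the
#'   dosage allele); defaults to the panel's own sample frequencies, which
#'   is adequate for cohort-sized panels only
#' @return pihat in [0, 1]
#' @export
ibd_pihat <- function(G, i, j, min_shared = 100L, freqs = NULL) {
  X <- round(G$dosage)
  if (is.character(i)) i <- match(i, rownames(X))
  if (is.character(j)) j <- match(j, rownames(X))
  gi <- X[i, ]; gj <- X[j, ]
  ok <- !is.na(gi) & !is.na(gj)
  p <- freqs %||% (colMeans(X, na.rm = TRUE) / 2)
  ok <- ok & p > 0.01 & p < 0.99
  if (sum(ok) < min_shared) {
    stop_config("fewer than ", min_shared, " shared variants")
  }
  gi <- gi[ok]; gj <- gj[ok]; p <- p[ok]; q <- 1 - p
  ibs <- 2 - abs(gi - gj)
  n0 <- sum(ibs == 0); n1 <- sum(ibs == 1); n2 <- sum(ibs == 2)
  # expected IBS-state probabilities per SNP given IBD state
  e0_ibd0 <- sum(2 * p^2 * q^2)
  e1_ibd0 <- sum(4 * p^3 * q + 4 * p * q^3)
  e2_ibd0 <- sum(p^4 + q^4 + 4 * p^2 * q^2)
  e1_ibd1 <- sum(2 * p^2 * q + 2 * p * q^2)
  e2_ibd1 <- sum(p^3 + q^3 + p^2 * q + p * q^2)
  m <- length(p)
  P0 <- n0 / e0_ibd0
  P1 <- (n1 - P0 * e1_ibd0) / e1_ibd1
  P2 <- (n2 - P0 * e2_ibd0 - P1 * e2_ibd1) / m
  P <- pmax(c(P0, P1, P2), 0)
  P <- P / sum(P)
  min(max(P[2] / 2 + P[3], 0), 1)
}

#' All-pairs pihat matrix (vectorized method of moments)
#'
#' Same estimator as [ibd_pihat()], computed for every sample pair at once
#' from identity-by-state tallies built with indicator cross-products.
#' Missing genotypes are not supported here (drop or impute first).
#'
#' @param G a [geno_matrix()]
#' @param freqs optional reference allele frequencies, as in [ibd_pihat()]
#' @return symmetric n x n pihat matrix (diagonal 1)
#' @export
pihat_matrix <- function(G, freqs = NULL) {
  X <- round(G$dosage)
  if (anyNA(X)) stop_config("pihat_matrix requires complete genotypes")
  p <- freqs %||% (colMeans(X) / 2)
  ok <- p > 0.01 & p < 0.99
  X <- X[, ok, drop = FALSE]
  p <- p[ok]; q <- 1 - p
  I0 <- (X == 0) * 1; I1 <- (X == 1) * 1; I2 <- (X == 2) * 1
  N02 <- tcrossprod(I0, I2)
  n_ibs0 <- N02 + t(N02)
  N01 <- tcrossprod(I0, I1); N12 <- tcrossprod(I1, I2)
  n_ibs1 <- N01 + t(N01) + N12 + t(N12)
  m <- ncol(X)
  n_ibs2 <- m - n_ibs0 - n_ibs1
  e0_ibd0 <- sum(2 * p^2 * q^2)
  e1_ibd0 <- sum(4 * p^3 * q + 4 * p * q^3)
  e2_ibd0 <- sum(p^4 + q^4 + 4 * p^2 * q^2)
  e1_ibd1 <- sum(2 * p^2 * q + 2 * p * q^2)
  e2_ibd1 <- sum(p^3 + q^3 + p^2 * q + p * q^2)
  P0 <- pmax(n_ibs0 / e0_ibd0, 0)
  P1 <- pmax((n_ibs1 - P0 * e1_ibd0) / e1_ibd1, 0)
  P2 <- pmax((n_ibs2 - P0 * e2_ibd0 - P1 * e2_ibd1) / m, 0)
  tot <- P0 + P1 + P2
  ph <- (P1 / 2 + P2) / tot
  ph[ph < 0] <- 0; ph[ph > 1] <- 1
  diag(ph) <- 1
  dimnames(ph) <- list(rownames(G$dosage), rownames(G$dosage))
  ph
}

#' Sample-level QC
#'
#' Removes samples with heterozygosity beyond `het_sd` standard deviations
#' of the cohort mean, missingness above `miss_max`, and one member of each
#' pair with pihat above `pihat_max` (the member with higher missingness;
#' ties resolved against the later sample id).
#'
#' @param G a [geno_matrix()]
#' @param het_sd,miss_max,pihat_max thresholds (defaults 3 / 0.05 / 0.2)
#' @return character vector of kept sample ids, with removals tallied in
#'   attribute `"report"`
#' @export
sample_qc <- function(G, het_sd = 3, miss_max = 0.05, pihat_max = 0.2) {
  X <- round(G$dosage)
  n <- nrow(X)
  if (n < 3) stop_config("at least 3 samples required")
  ids <- rownames(X)
  miss <- rowMeans(is.na(X))
  het <- rowMeans(X == 1, na.rm = TRUE)
  s <- stats::sd(het)
  het_out <- if (is.na(s) || s < .Machine$double.eps) rep(FALSE, n) else
    abs(het - mean(het)) > het_sd * s
  miss_out <- miss > miss_max
  rel_out <- rep(FALSE, n)
  alive <- which(!het_out & !miss_out)
  if (length(alive) >= 2) {
    ph <- if (anyNA(X)) {
      out <- matrix(0, n, n)
      for (a in alive) for (b in alive[alive > a]) {
        out[a, b] <- out[b, a] <-
          tryCatch(ibd_pihat(G, a, b), error = function(e) 0)
      }
      out
    } else pihat_matrix(G)
    for (a in alive) {
      if (rel_out[a]) next
      for (b in alive[alive > a]) {
        if (rel_out[b]) next
        if (ph[a, b] > pihat_max) {
          drop <- if (miss[a] > miss[b]) a else if (miss[b] > miss[a]) b else max(a, b)
          rel_out[drop] <- TRUE
          if (drop == a) break
        }
      }
    }
  }
  keep <- !het_out & !miss_out & !rel_out
  out <- ids[keep]
  attr(out, "report") <- data.frame(
    filter = c("heterozygosity", "missing", "relatedness"),
    n_removed = c(sum(het_out), sum(miss_out), sum(rel_out)))
  out
}

complement_base <- function(x) c(A = "T", C = "G", G = "C", T = "A")[x]

#' Harmonize GWAS summary statistics with a genotype panel
#'
#' Intersects variants with the panel by id, aligns alleles (exact match
#' keeps Z; swapped alleles flip the Z sign; strand-ambiguous A/T and C/G
#' variants and irreconcilable allele pairs are dropped), and applies MAF /
#' imputation-INFO filters when those columns are present.
#'
#' @param ss summary-statistic data frame with columns snp, a1, a2, z and
#'   optionally chrom, pos, n, maf, info
#' @param panel a [geno_matrix()]
#' @param maf_min minimum MAF when a `maf` column is present (default 0.05)
#' @param info_min minimum imputation score when an `info` column is
#'   present (default 0.80)
#' @return harmonized summary statistics restricted to panel variants with
#'   Z aligned to the panel's a1 dosage allele; action counts in attribute
#'   `"report"`
#' @export
harmonize_sumstats <- function(ss, panel, maf_min = 0.05, info_min = 0.80) {
  idx <- match(ss$snp, panel$map$snp)
  present <- !is.na(idx)
  if (!any(present)) stop_config("no overlap between sumstats and panel")
  ss2 <- ss[present, , drop = FALSE]
  pm <- panel$map[idx[present], ]
  amb <- is_strand_ambiguous(ss2$a1, ss2$a2)
  exact <- ss2$a1 == pm$a1 & ss2$a2 == pm$a2
  swap <- ss2$a1 == pm$a2 & ss2$a2 == pm$a1
  # strand flips for non-ambiguous pairs
  f1 <- complement_base(ss2$a1); f2 <- complement_base(ss2$a2)
  flip_exact <- f1 == pm$a1 & f2 == pm$a2
  flip_swap <- f1 == pm$a2 & f2 == pm$a1
  keep <- !amb & (exact | swap | flip_exact | flip_swap)
  sign_flip <- !amb & !exact & !flip_exact & (swap | flip_swap)
  maf_fail <- if ("maf" %in% names(ss2)) !is.na(ss2$maf) & ss2$maf <= maf_min else FALSE
  info_fail <- if ("info" %in% names(ss2)) !is.na(ss2$info) & ss2$info <= info_min else FALSE
  keep <- keep & !maf_fail & !info_fail
  out <- ss2[keep, , drop = FALSE]
  pmk <- pm[keep, ]
  out$z <- ifelse(sign_flip[keep], -out$z, out$z)
  out$a1 <- pmk$a1
  out$a2 <- pmk$a2
  rownames(out) <- NULL
  attr(out, "report") <- data.frame(
    action = c("absent_from_panel", "strand_ambiguous", "irreconcilable",
               "sign_flipped", "maf_filtered", "info_filtered", "kept"),
    n = c(sum(!present), sum(amb),
          sum(!amb & !(exact | swap | flip_exact | flip_swap)),
          sum(sign_flip & keep), sum(maf_fail & !amb),
          sum(info_fail & !amb), nrow(out)))
  out
}
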