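# Per-feature cis-heritability with a likelihood-ratio gate, and
# cross-validated SNP expression weights (top eQTL, lasso, elastic net,
# BLUP), following the FUSION-style selection logic.

#' Cis-window variant subset for a feature
#'
#' Variants on the feature's chromosome with position in
#' [start - window_bp, end + window_bp], inclusive bounds.
#'
#' @param feature one row of a [feature_annotation()] table
#' @param map variant map (data frame with chrom, pos), sorted by position
#' @param window_bp half-window (default 5e5, i.e. ~1 Mb total)
#' @return integer indices into `map`; empty with attribute
#'   `"skip_reason"` when no variant falls in the window
#' @export
cis_snps <- function(feature, map, window_bp = 5e5) {
  idx <- which(map$chrom == feature$chrom &
               map$pos >= feature$start - window_bp &
               map$pos <= feature$end + window_bp)
  if (length(idx) == 0) {
    attr(idx, "skip_reason") <- "no variants in cis window"
  }
  idx
}

#' Single-component REML cis-heritability with boundary-mixture LRT
#'
#' Fits y ~ N(0, s2g * K + s2e * I) with K = X X' / m on column-standardized
#' cis dosages, by 1-D profile likelihood over h2 = s2g / (s2g + s2e) using
#' the eigendecomposition of K. The likelihood-ratio test against s2g = 0
#' uses the boundary mixture 0.5 chi2_0 + 0.5 chi2_1.
#'
#' @param y adjusted expression vector (centered internally)
#' @param X samples x m cis dosage matrix (standardized internally)
#' @return object of class `h2_estimate`: h2, sigma2_g, sigma2_e, lrt_stat,
#'   lrt_p, loglik
#' @export
reml_h2 <- function(y, X) {
  if (!all(is.finite(y))) stop_config("non-finite expression values")
  n <- length(y)
  y <- y - mean(y)
  Xs <- standardize_cols(as.matrix(X))
  Xs <- Xs[, !attr(Xs, "constant"), drop = FALSE]
  m <- ncol(Xs)
  if (m == 0) stop_config("no polymorphic cis SNPs")
  K <- tcrossprod(Xs) / m
  ev <- eigen(K, symmetric = TRUE)
  lam <- pmax(ev$values, 0)
  yr <- drop(crossprod(ev$vectors, y))
  ll_h2 <- function(h2) {
    d <- h2 * lam + (1 - h2)
    s2 <- mean(yr^2 / d)
    -0.5 * (n * log(2 * pi * s2) + sum(log(d)) + n)
  }
  opt <- stats::optimize(ll_h2, c(0, 1), maximum = TRUE, tol = 1e-8)
  ll0 <- ll_h2(0)
  # guard the optimizer against boundary misses
  h2 <- opt$maximum
  ll1 <- opt$objective
  if (ll0 > ll1) { h2 <- 0; ll1 <- ll0 }
  lrt <- max(0, 2 * (ll1 - ll0))
  p <- if (lrt <= 0) 1 else 0.5 * stats::pchisq(lrt, df = 1, lower.tail = FALSE)
  d <- h2 * lam + (1 - h2)
  s2 <- mean(yr^2 / d)
  structure(list(h2 = h2, sigma2_g = s2 * h2, sigma2_e = s2 * (1 - h2),
                 lrt_stat = lrt, lrt_p = p, loglik = ll1, n = n, m = m),
            class = "h2_estimate")
}

#' @export
print.h2_estimate <- function(x, ...) {
  cat(sprintf("h2_cis = %.3f (s2g = %.3f, s2e = %.3f); LRT = %.2f, p = %.3g\n",
              x$h2, x$sigma2_g, x$sigma2_e, x$lrt_stat, x$lrt_p))
  invisible(x)
}

#' Fit a single expression weight vector
#'
#' Weights are on the column-standardized genotype scale. Methods: `top1`
#' places the marginal regression coefficient at the SNP with the largest
#' absolute marginal z and zeros elsewhere; `lasso` / `enet` (mixing 0.5)
#' use glmnet coordinate descent with the penalty chosen by inner
#' cross-validation among path points whose in-sample R^2 does not exceed
#' the feature's h2; `blup` is the ridge closed form
#' w = (X'X + m (1 - h2) / h2 I)^-1 X'y.
#'
#' @param y expression vector (centered internally)
#' @param X samples x m cis dosages (standardized internally; constant
#'   columns dropped with a warning)
#' @param method one of `"top1"`, `"lasso"`, `"enet"`, `"blup"`
#' @param h2 the feature's cis heritability estimate (required for `blup`
#'   and the penalized in-sample cap)
#' @param seed seed fixing inner CV folds
#' @param nlambda glmnet path length
#' @param inner_folds inner CV folds for penalty selection (default 3,
#'   keeping the nested CV affordable)
#' @return weight vector of length m (named by SNP when X has colnames)
#' @export
fit_weights <- function(y, X, method = c("top1", "lasso", "enet", "blup"),
                        h2 = NULL, seed = 1L, nlambda = 20L,
                        inner_folds = 3L) {
  method <- match.arg(method)
  X <- as.matrix(X)
  y <- y - mean(y)
  Xs <- standardize_cols(X)
  const <- attr(Xs, "constant")
  if (any(const)) warning(sum(const), " constant SNP column(s) dropped")
  w <- stats::setNames(rep(0, ncol(X)), colnames(X))
  act <- which(!const)
  Xa <- Xs[, act, drop = FALSE]
  n <- nrow(Xa); m <- ncol(Xa)
  if (m == 0) return(w)
  if (method == "top1") {
    bhat <- drop(crossprod(Xa, y)) / (n - 1L)
    j <- which.max(abs(bhat))
    w[act[j]] <- bhat[j]
    return(w)
  }
  if (method == "blup") {
    if (is.null(h2) || h2 <= 0) stop_config("blup requires h2 > 0")
    ridge <- m * (1 - h2) / h2
    w[act] <- drop(solve(crossprod(Xa) + diag(ridge, m), crossprod(Xa, y)))
    return(w)
  }
  mix <- if (method == "lasso") 1 else 0.5
  cv <- with_seed(seed, glmnet::cv.glmnet(
    Xa, y, alpha = mix, nfolds = inner_folds, nlambda = nlambda,
    standardize = FALSE, intercept = FALSE))
  fit <- cv$glmnet.fit
  r2_path <- fit$dev.ratio
  eligible <- if (is.null(h2)) rep(TRUE, length(r2_path)) else r2_path <= h2
  cvm <- cv$cvm[match(fit$lambda, cv$lambda)]
  pick <- if (any(eligible)) {
    cand <- which(eligible)
    cand[which.min(cvm[cand])]
  } else 1L
  w[act] <- as.numeric(fit$beta[, pick])
  w
}

method_order <- c("top1", "lasso", "enet", "blup")

#' Cross-validated weight-method selection for one feature
#'
#' k-fold cross-validation with folds fixed by the seed; genotype
#' standardization is refit inside each training fold. Per method, cv_r2
#' is the squared correlation between out-of-fold predictions and y; the
#' winner is the method with the highest cv_r2 (ties broken toward fewer
#' nonzero weights, then the fixed order top1, lasso, enet, blup), refit on
#' the full data.
#'
#' @param y expression vector
#' @param X samples x m cis dosages
#' @param h2rec an `h2_estimate` from [reml_h2()] (already past the gate)
#' @param methods subset of `c("top1","lasso","enet","blup")`
#' @param k_folds number of folds (default 5)
#' @param seed fold seed
#' @return object of class `weight_set`: feature-level weights for every
#'   method, per-method `cv_r2`, `best_method`, the winning weight vector
#'   `w`, the h2 record, and a `usable` flag (FALSE when every cv_r2 <= 0)
#' @export
cv_select <- function(y, X, h2rec, methods = method_order, k_folds = 5,
                      seed = 1L) {
  X <- as.matrix(X)
  n <- length(y)
  if (n < k_folds) stop_config("need at least k_folds samples")
  h2 <- if (inherits(h2rec, "h2_estimate")) h2rec$h2 else h2rec
  h2 <- min(max(h2, 0.01), 0.99)  # keep the blup ridge finite and positive
  folds <- with_seed(seed, sample(rep_len(seq_len(k_folds), n)))
  preds <- matrix(NA_real_, n, length(methods),
                  dimnames = list(NULL, methods))
  for (fk in seq_len(k_folds)) {
    te <- folds == fk
    ytr <- y[!te]
    Xtr <- X[!te, , drop = FALSE]
    ctr <- colMeans(Xtr)
    str_ <- apply(Xtr, 2L, stats::sd)
    ok <- str_ > .Machine$double.eps
    Xte <- sweep(sweep(X[te, , drop = FALSE], 2L, ctr, "-"), 2L,
                 ifelse(ok, str_, 1), "/")
    Xte[, !ok] <- 0
    for (mth in methods) {
      wtr <- fit_weights(ytr, Xtr, mth, h2 = max(h2, 0.01),
                         seed = seed + fk)
      preds[te, mth] <- drop(Xte %*% wtr) + mean(ytr)
    }
  }
  cv_r2 <- vapply(methods, function(mth) {
    r <- suppressWarnings(stats::cor(preds[, mth], y))
    if (is.na(r)) 0 else r^2
  }, numeric(1))
  full_w <- lapply(stats::setNames(methods, methods), function(mth)
    fit_weights(y, X, mth, h2 = max(h2, 0.01), seed = seed))
  nnz <- vapply(full_w, function(w) sum(w != 0), numeric(1))
  ord <- order(-cv_r2, nnz, match(methods, method_order))
  best <- methods[ord[1]]
  usable <- any(cv_r2 > 0)
  structure(list(weights = full_w, cv_r2 = cv_r2, best_method = best,
                 w = full_w[[best]], h2 = h2rec, usable = usable,
                 snps = colnames(X), k_folds = k_folds, seed = seed),
            class = "weight_set")
}

#' @export
print.weight_set <- function(x, ...) {
  cat("weight_set:", length(x$snps), "cis SNPs; best:", x$best_method,
      sprintf("(cv R2 = %.3f)\n", x$cv_r2[[x$best_method]]))
  invisible(x)
}

#' Build the weight store across features
#'
#' Runs the cis window, REML heritability gate (LRT p < `gate_p`) and
#' [cv_select()] for every feature; gated-out or unusable features never
#' enter the store.
#'
#' @param expr_adj features x samples adjusted expression matrix
#' @param G a [geno_matrix()] for the same samples
#' @param annotation a [feature_annotation()] table
#' @param window_bp cis half-window (default 5e5)
#' @param gate_p heritability LRT gate (default 0.01)
#' @param min_snps minimum cis SNPs required (default 2)
#' @param methods weight methods to fit
#' @param seed fold seed fan-out base
#' @return object of class `weight_store`: list with `weights` (named list
#'   of `weight_set`), `h2_table` (per-feature h2/LRT rows incl. gated-out
#'   features), `skipped` (feature -> reason)
#' @export
compute_weights <- function(expr_adj, G, annotation, window_bp = 5e5,
                            gate_p = 0.01, min_snps = 2L,
                            methods = method_order, seed = 1L) {
  feats <- intersect(rownames(expr_adj), annotation$feature_id)
  weights <- list()
  skipped <- character(0)
  h2_rows <- list()
  for (fid in feats) {
    fa <- annotation[annotation$feature_id == fid, ]
    idx <- cis_snps(fa, G$map, window_bp)
    if (length(idx) < min_snps) {
      skipped[fid] <- attr(idx, "skip_reason") %||% "too few cis SNPs"
      next
    }
    y <- expr_adj[fid, ]
    X <- G$dosage[, idx, drop = FALSE]
    h2rec <- reml_h2(y, X)
    h2_rows[[fid]] <- data.frame(feature_id = fid, class = fa$class,
                                 h2 = h2rec$h2, lrt_stat = h2rec$lrt_stat,
                                 lrt_p = h2rec$lrt_p, n_snps = length(idx))
    if (h2rec$lrt_p >= gate_p) {
      skipped[fid] <- "failed heritability gate"
      next
    }
    ws <- cv_select(y, X, h2rec, methods = methods,
                    seed = seed + match(fid, feats))
    if (!ws$usable) {
      skipped[fid] <- "no method achieved positive cv R2"
      next
    }
    ws$feature_id <- fid
    ws$class <- fa$class
    ws$chrom <- fa$chrom
    ws$start <- fa$start
    ws$end <- fa$end
    ws$alleles <- G$map[idx, c("snp", "a1", "a2")]
    weights[[fid]] <- ws
  }
  structure(list(weights = weights,
                 h2_table = do.call(rbind, h2_rows),
                 skipped = skipped, gate_p = gate_p,
                 window_bp = window_bp),
            class = "weight_store")
}

#' @export
print.weight_store <- function(x, ...) {
  cat("weight_store:", length(x$weights), "features with weights;",
      length(x$skipped), "skipped (gate p <", x$gate_p, ")\n")
  invisible(x)
}

#' Count expressed vs cis-heritable features by class
#'
#' The tabulation mirrors cohort reports of expressed and cis-regulated
#' genes and HERV loci, with integer-rounded percentages.
#'
#' @param store a `weight_store`
#' @param expressed_ids ids of all expressed features considered
#' @param annotation a [feature_annotation()] table
#' @return data frame: class, n_expressed, n_cis, pct_cis
#' @export
heritability_report <- function(store, expressed_ids, annotation) {
  cls <- annotation$class[match(expressed_ids, annotation$feature_id)]
  cis_ids <- names(store$weights)
  out <- lapply(unique(cls), function(cc) {
    ids <- expressed_ids[cls == cc]
    ncis <- sum(cis_ids %in% ids)
    data.frame(class = cc, n_expressed = length(ids), n_cis = ncis,
               pct_cis = fraction_pct(ncis, length(ids)))
  })
  do.call(rbind, out)
}
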