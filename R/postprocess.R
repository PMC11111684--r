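# Conditional/joint analysis within loci, Bayesian fine-mapping of
# correlated predicted-expression signals, and high-confidence risk-feature
# classification.

#' Correlation of predicted expression between features
#'
#' Omega_ij = w_i' R w_j / sqrt(w_i' R w_i * w_j' R w_j) over the union of
#' the features' weight SNPs (missing weights are zero). Degenerate
#' features (zero predicted variance) are excluded and recorded in the
#' `"excluded"` attribute.
#'
#' @param weightsets named list of `weight_set` objects (or a
#'   `weight_store`, in which case its `weights` element is used)
#' @param G a [geno_matrix()] LD reference covering the SNP union
#' @param ridge_eps optional LD ridge (default 0)
#' @return feature x feature correlation matrix of class `pred_expr_cor`
#' @export
pred_expr_cor <- function(weightsets, G, ridge_eps = 0) {
  if (inherits(weightsets, "weight_store")) weightsets <- weightsets$weights
  if (length(weightsets) == 0) stop_config("no weight sets supplied")
  snp_union <- unique(unlist(lapply(weightsets, function(ws)
    ws$snps[ws$w != 0])))
  if (length(snp_union) == 0) stop_config("empty SNP universe across weight sets")
  R <- ld_matrix(G, snp_union, ridge_eps = ridge_eps)
  W <- vapply(weightsets, function(ws) {
    w <- stats::setNames(rep(0, length(snp_union)), snp_union)
    keep <- ws$snps %in% snp_union
    w[ws$snps[keep]] <- ws$w[keep]
    w
  }, numeric(length(snp_union)))
  V <- crossprod(W, R %*% W)
  sd_ <- sqrt(diag(V))
  ok <- sd_ > 1e-8
  excluded <- colnames(W)[!ok]
  V <- V[ok, ok, drop = FALSE]
  sd_ <- sd_[ok]
  Om <- V / tcrossprod(sd_)
  Om <- (Om + t(Om)) / 2
  diag(Om) <- 1
  Om[Om > 1] <- 1; Om[Om < -1] <- -1
  attr(Om, "snp_universe") <- snp_union
  attr(Om, "excluded") <- excluded
  class(Om) <- c("pred_expr_cor", class(Om))
  Om
}

#' Partition significant features into loci
#'
#' Bonferroni-significant features whose cis windows (coordinates padded by
#' `merge_bp`) overlap on the same chromosome are merged transitively into
#' loci (connected components of the overlap graph).
#'
#' @param results a `twas_result` table with coordinates
#' @param alpha significance level on `bonf_p` (default 0.05)
#' @param merge_bp window padding in bp (default 1e5)
#' @return list of character vectors of feature ids, one per locus
#' @export
define_loci <- function(results, alpha = 0.05, merge_bp = 1e5) {
  sig <- results[results$bonf_p < alpha, , drop = FALSE]
  if (nrow(sig) == 0) return(list())
  sig <- sig[order(sig$chr, sig$p0), ]
  lo <- sig$p0 - merge_bp
  hi <- sig$p1 + merge_bp
  comp <- integer(nrow(sig))
  cur <- 0L
  for (i in seq_len(nrow(sig))) {
    if (i == 1L || sig$chr[i] != sig$chr[i - 1L] || lo[i] > max_hi) {
      cur <- cur + 1L
      max_hi <- hi[i]
    } else {
      max_hi <- max(max_hi, hi[i])
    }
    comp[i] <- cur
  }
  unname(split(sig$id, comp))
}

solve_ridge <- function(A, b, eps = 1e-6) {
  tryCatch(solve(A, b), error = function(e)
    solve(A + diag(eps, nrow(A)), b))
}

#' Greedy conditional/joint analysis of one locus
#'
#' Forward selection: repeatedly add the feature with the smallest
#' conditional p given the current set S while that p stays below
#' `entry_p`. Conditional Z of feature j given S is
#' (Z_j - Omega_jS Omega_SS^-1 Z_S) / sqrt(1 - Omega_jS Omega_SS^-1
#' Omega_Sj); candidates with conditional variance below `collinear_tol`
#' are skipped and flagged. Joint statistics re-evaluate the members as
#' generalized-least-squares effects: b = Omega_SS^-1 Z_S with joint
#' Z_j = b_j / sqrt((Omega_SS^-1)_jj).
#'
#' @param locus_results `twas_result` rows for the locus features
#' @param Omega predicted-expression correlation ([pred_expr_cor()])
#'   covering the locus features
#' @param entry_p selection threshold (the per-trait Bonferroni threshold
#'   by default must be supplied by the caller)
#' @param collinear_tol conditional-variance cutoff (default 1e-4)
#' @return object of class `joint_result`: `selected` (ids in selection
#'   order), `joint` (data frame id/joint_z/joint_p), `conditional` (data
#'   frame for non-selected features: id, cond_z, cond_p, collinear flag)
#' @export
joint_conditional <- function(locus_results, Omega, entry_p,
                              collinear_tol = 1e-4) {
  ids <- locus_results$id
  stopifnot(all(ids %in% rownames(Omega)))
  Z <- stats::setNames(locus_results$twas_z, ids)
  Om <- Omega[ids, ids, drop = FALSE]
  S <- character(0)
  collinear <- character(0)
  cond_stats <- function(j, S) {
    if (length(S) == 0) return(c(z = unname(Z[j]), v = 1))
    OSSi_z <- solve_ridge(Om[S, S, drop = FALSE], Z[S])
    OSSi_o <- solve_ridge(Om[S, S, drop = FALSE], Om[S, j])
    v <- 1 - drop(Om[j, S, drop = FALSE] %*% OSSi_o)
    zc <- (Z[j] - drop(Om[j, S, drop = FALSE] %*% OSSi_z)) /
      sqrt(max(v, .Machine$double.eps))
    c(z = unname(zc), v = v)
  }
  repeat {
    cand <- setdiff(ids, c(S, collinear))
    if (length(cand) == 0) break
    st <- vapply(cand, cond_stats, c(z = 0, v = 0), S = S)
    bad <- st["v", ] < collinear_tol
    collinear <- c(collinear, cand[bad])
    cand <- cand[!bad]
    if (length(cand) == 0) break
    zc <- st["z", !bad, drop = TRUE]
    pc <- 2 * stats::pnorm(-abs(zc))
    best <- which.min(pc)
    if (pc[best] >= entry_p) break
    S <- c(S, cand[best])
  }
  if (length(S) == 0) {
    # locus retains its marginal top feature for reporting
    joint <- data.frame(id = character(0), joint_z = numeric(0),
                        joint_p = numeric(0))
  } else {
    OSS <- Om[S, S, drop = FALSE]
    b <- solve_ridge(OSS, Z[S])
    Vinv <- tryCatch(solve(OSS), error = function(e)
      solve(OSS + diag(1e-6, nrow(OSS))))
    jz <- b / sqrt(pmax(diag(Vinv), .Machine$double.eps))
    joint <- data.frame(id = S, joint_z = unname(jz),
                        joint_p = 2 * stats::pnorm(-abs(unname(jz))),
                        stringsAsFactors = FALSE)
  }
  rest <- setdiff(ids, S)
  cond <- if (length(rest) > 0) {
    st <- vapply(rest, cond_stats, c(z = 0, v = 0), S = S)
    data.frame(id = rest, cond_z = st["z", ],
               cond_p = 2 * stats::pnorm(-abs(st["z", ])),
               collinear = rest %in% collinear, stringsAsFactors = FALSE)
  } else {
    data.frame(id = character(0), cond_z = numeric(0), cond_p = numeric(0),
               collinear = logical(0))
  }
  structure(list(selected = S, joint = joint, conditional = cond,
                 entry_p = entry_p, ids = ids, Z = Z, Omega = Om),
            class = "joint_result")
}

#' Condition SNP z-scores on jointly selected expression signals
#'
#' Per SNP k: z'_k = z_k - rho_kS Omega_SS^-1 Z_S with
#' rho_kj = (R w_j)_k / sqrt(w_j' R w_j).
#'
#' @param z_snps named SNP z-score vector over the locus SNPs
#' @param G a [geno_matrix()] LD reference covering those SNPs and the
#'   selected features' weight SNPs
#' @param joint a `joint_result` with non-empty selection
#' @param weightsets named list of `weight_set` objects for the selected
#'   features
#' @return named vector of conditioned z-scores
#' @export
condition_snp_z <- function(z_snps, G, joint, weightsets) {
  S <- joint$selected
  if (length(S) == 0) stop_config("no selected features to condition on")
  snps <- names(z_snps)
  wsnps <- unique(unlist(lapply(weightsets[S], function(ws)
    ws$snps[ws$w != 0])))
  universe <- unique(c(snps, wsnps))
  R <- ld_matrix(G, universe)
  rho <- vapply(S, function(fid) {
    ws <- weightsets[[fid]]
    w <- stats::setNames(rep(0, length(universe)), universe)
    w[ws$snps[ws$w != 0]] <- ws$w[ws$w != 0]
    Rw <- drop(R %*% w)
    Rw[snps] / sqrt(drop(t(w) %*% R %*% w))
  }, numeric(length(snps)))
  rho <- matrix(rho, nrow = length(snps),
                dimnames = list(snps, S))
  adj <- drop(rho %*% solve_ridge(joint$Omega[S, S, drop = FALSE],
                                  joint$Z[S]))
  z_snps - adj
}

#' Bayesian fine-mapping of correlated expression signals
#'
#' Enumerates all causal configurations c with |c| <= `max_causal` (plus
#' the null). The locus Z vector is modelled as N(0, Omega + v *
#' Omega[, c] Omega[c, ]) under configuration c, with prior
#' prior_p^|c| (1 - prior_p)^(K - |c|). PIP_j sums the posterior over
#' configurations containing j; the credible set is the smallest
#' PIP-ranked feature set F with P(causal set within F) >= `cred_level`.
#'
#' @param Z named locus Z-score vector
#' @param Omega predicted-expression correlation over the same features
#' @param prior_p per-feature prior causal probability (default 1e-3)
#' @param v prior variance multiplier of causal effects (default 40)
#' @param max_causal maximum configuration size (default 3)
#' @param cred_level credible-set level (default 0.9)
#' @return object of class `finemap_result`: `pip` (named vector),
#'   `credible_set`, `posterior` (per-configuration data frame),
#'   `prior_p`, `v`
#' @export
finemap_pip <- function(Z, Omega, prior_p = 1e-3, v = 40, max_causal = 3,
                        cred_level = 0.9) {
  K <- length(Z)
  ids <- names(Z) %||% paste0("f", seq_len(K))
  names(Z) <- ids
  if (K > 25 && max_causal >= 3) {
    stop_config("enumeration over ", K, " features is refused; ",
                "split the block or lower max_causal")
  }
  if (is.null(rownames(Omega))) dimnames(Omega) <- list(ids, ids)
  Om <- Omega[ids, ids, drop = FALSE]
  configs <- list(integer(0))
  for (sz in seq_len(min(max_causal, K))) {
    configs <- c(configs, utils::combn(K, sz, simplify = FALSE))
  }
  logpost <- vapply(configs, function(cc) {
    V <- Om
    if (length(cc) > 0) {
      Oc <- Om[, cc, drop = FALSE]
      V <- Om + v * tcrossprod(Oc)
    }
    lp <- length(cc) * log(prior_p) + (K - length(cc)) * log(1 - prior_p)
    lp + dmvnorm0_log(Z, V)
  }, numeric(1))
  logpost <- logpost - max(logpost)
  post <- exp(logpost)
  post <- post / sum(post)
  pip <- vapply(seq_len(K), function(j)
    sum(post[vapply(configs, function(cc) j %in% cc, logical(1))]),
    numeric(1))
  names(pip) <- ids
  ord <- order(pip, decreasing = TRUE)
  cred <- character(0)
  for (r in seq_len(K)) {
    F_ <- ord[seq_len(r)]
    pF <- sum(post[vapply(configs, function(cc) all(cc %in% F_), logical(1))])
    if (pF >= cred_level) { cred <- ids[F_]; break }
  }
  if (length(cred) == 0) cred <- ids[ord]
  cfg_df <- data.frame(
    config = vapply(configs, function(cc)
      if (length(cc) == 0) "(null)" else paste(ids[cc], collapse = "+"),
      character(1)),
    size = lengths(configs), posterior = post, stringsAsFactors = FALSE)
  structure(list(pip = pip, credible_set = cred, posterior = cfg_df,
                 prior_p = prior_p, v = v, max_causal = max_causal),
            class = "finemap_result")
}

#' High-confidence risk-feature classification
#'
#' A feature is high confidence iff it is jointly selected with joint
#' p <= `entry_p` AND attains fine-mapping PIP > `pip_min`. Intermediate
#' tiers (Bonferroni-only, joint-only, PIP-only) are also emitted.
#'
#' @param twas a `twas_result` table
#' @param joints list of `joint_result` objects (one per locus)
#' @param finemaps list of `finemap_result` objects (one per locus)
#' @param entry_p joint-significance threshold
#' @param pip_min PIP threshold (default 0.5)
#' @param alpha Bonferroni level for the base tier (default 0.05)
#' @return data frame: id, class, twas_z, twas_p, bonf_p, joint_z, joint_p,
#'   pip, tier, high_confidence
#' @export
classify_high_confidence <- function(twas, joints, finemaps, entry_p,
                                     pip_min = 0.5, alpha = 0.05) {
  jt <- do.call(rbind, lapply(joints, `[[`, "joint"))
  pip_all <- unlist(lapply(finemaps, `[[`, "pip"))
  out <- twas[, c("id", "class", "twas_z", "twas_p", "bonf_p")]
  names(out)[3:5] <- c("twas_z", "twas_p", "bonf_p")
  out$joint_z <- if (!is.null(jt)) jt$joint_z[match(out$id, jt$id)] else NA_real_
  out$joint_p <- if (!is.null(jt)) jt$joint_p[match(out$id, jt$id)] else NA_real_
  out$pip <- if (is.null(pip_all)) NA_real_ else unname(pip_all[out$id])
  bonf_sig <- out$bonf_p < alpha
  joint_sig <- !is.na(out$joint_p) & out$joint_p <= entry_p
  pip_sig <- !is.na(out$pip) & out$pip > pip_min
  out$high_confidence <- joint_sig & pip_sig
  out$tier <- ifelse(out$high_confidence, "high_confidence",
              ifelse(joint_sig, "joint_only",
              ifelse(pip_sig, "pip_only",
              ifelse(bonf_sig, "bonferroni_only", "none"))))
  out
}
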