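# Predicted-expression correlation, locus definition, conditional/joint
# analysis, SNP-level conditioning, fine-mapping, and high-confidence
# classification.

mk_weightset <- function(id, snps, w, class = "gene") {
  structure(list(feature_id = id, snps = snps,
                 w = stats::setNames(w, snps), class = class,
                 best_method = "top1"), class = "weight_set")
}

test_that("predicted-expression correlation matches dense arithmetic", {
  G <- toy_genotypes(n = 500, m = 12, seed = 201, rho = 0.5)
  snps <- G$map$snp
  wss <- list(
    A = mk_weightset("A", snps[1:4], c(0.5, -0.2, 0.1, 0.4)),
    B = mk_weightset("B", snps[3:8], c(0.3, 0.3, -0.5, 0.2, 0.1, 0.2)),
    C = mk_weightset("C", snps[9:12], c(1, 0, 0, -1)))
  Om <- pred_expr_cor(wss, G)
  expect_equal(unname(diag(Om)), rep(1, 3))
  expect_true(isSymmetric(unname(unclass(Om))))
  # dense oracle over the SNP union
  R <- stats::cor(G$dosage)
  W <- matrix(0, 12, 3, dimnames = list(snps, c("A", "B", "C")))
  W[1:4, 1] <- wss$A$w; W[3:8, 2] <- wss$B$w; W[9:12, 3] <- wss$C$w
  V <- t(W) %*% R %*% W
  orc <- V / tcrossprod(sqrt(diag(V)))
  expect_lt(max(abs(unclass(Om)[rownames(orc), colnames(orc)] - orc)), 1e-10)
  # identical weights give correlation one
  ws_dup <- list(A = wss$A, A2 = mk_weightset("A2", snps[1:4], wss$A$w))
  expect_equal(unname(pred_expr_cor(ws_dup, G)["A", "A2"]), 1,
               tolerance = 1e-12)
})

test_that("loci merge transitively within chromosomes", {
  res <- data.frame(
    id = paste0("F", 1:6),
    chr = c("1", "1", "1", "2", "2", "3"),
    p0 = c(1e6, 1.15e6, 3e6, 1e6, 1.05e6, 1e6),
    p1 = c(1.05e6, 1.2e6, 3.05e6, 1.02e6, 1.1e6, 1.01e6),
    bonf_p = 0.01)
  loci <- define_loci(res, merge_bp = 1e5)
  # windows F1/F2 overlap (150 kb apart, padded by 100 kb each side)
  got <- lapply(loci, sort)
  expect_true(list(c("F1", "F2")) %in% got ||
                any(vapply(got, identical, logical(1), c("F1", "F2"))))
  expect_length(loci, 4)
  # hand-computed connected components
  expect_setequal(vapply(got, paste, character(1), collapse = "+"),
                  c("F1+F2", "F3", "F4+F5", "F6"))
  expect_length(define_loci(res[res$bonf_p > 0.5, ]), 0)
})

test_that("joint/conditional selection handles identity, orthogonality and collinearity", {
  entry <- 1e-3
  # single feature: joint equals marginal
  one <- data.frame(id = "A", twas_z = 6, twas_p = 2 * pnorm(-6))
  Om1 <- matrix(1, 1, 1, dimnames = list("A", "A"))
  j1 <- joint_conditional(one, Om1, entry_p = entry)
  expect_identical(j1$selected, "A")
  expect_equal(j1$joint$joint_z, 6, tolerance = 1e-12)
  # orthogonal features: conditional equals marginal
  two <- data.frame(id = c("A", "B"), twas_z = c(6, 5),
                    twas_p = 2 * pnorm(-c(6, 5)))
  Om2 <- diag(2); dimnames(Om2) <- list(c("A", "B"), c("A", "B"))
  j2 <- joint_conditional(two, Om2, entry_p = entry)
  expect_setequal(j2$selected, c("A", "B"))
  expect_equal(sort(j2$joint$joint_z), c(5, 6), tolerance = 1e-9)
  # identical features: the second is flagged collinear
  Om3 <- matrix(1, 2, 2, dimnames = list(c("A", "B"), c("A", "B")))
  three <- data.frame(id = c("A", "B"), twas_z = c(5, 5),
                      twas_p = 2 * pnorm(-5))
  j3 <- joint_conditional(three, Om3, entry_p = entry)
  expect_identical(j3$selected, "A")
  expect_true(j3$conditional$collinear[j3$conditional$id == "B"])
  # members of S have conditional Z equal to zero
  S <- j2$selected
  zc <- j2$Z[S] - Om2[S, S] %*% solve(Om2[S, S]) %*% j2$Z[S]
  expect_lt(max(abs(zc)), 1e-8)
})

test_that("entry_p = Inf reproduces the generalized-least-squares joint fit", {
  set.seed(202)
  K <- 4
  L <- matrix(rnorm(K * K), K)
  Om <- stats::cov2cor(crossprod(L) + diag(0.5, K))
  dimnames(Om) <- list(paste0("F", 1:K), paste0("F", 1:K))
  Z <- c(4, 3, -2, 1)
  res <- data.frame(id = paste0("F", 1:K), twas_z = Z,
                    twas_p = 2 * pnorm(-abs(Z)))
  jj <- joint_conditional(res, Om, entry_p = Inf)
  expect_setequal(jj$selected, paste0("F", 1:K))
  b <- solve(Om, Z)
  jz <- b / sqrt(diag(solve(Om)))
  got <- jj$joint$joint_z[match(paste0("F", 1:K), jj$joint$id)]
  expect_equal(got, unname(jz), tolerance = 1e-8)
})

test_that("SNP-level conditioning removes mediated signal", {
  G <- toy_genotypes(n = 600, m = 30, seed = 203, rho = 0.5, spacing = 20000)
  ann <- feature_annotation("MED", "1", 200000, 205000, class = "herv")
  sim <- simulate_expression(G, ann, expr_arch(h2_cis = 0.5, n_causal = 2),
                             seed = 204)
  store <- compute_weights(t(scale(t(sim$truth$latent))), G, ann, seed = 205)
  ss <- simulate_gwas_sumstats(G, sim$truth, alpha = 0.2, N_gwas = 50000,
                               seed = 206)
  ssh <- harmonize_sumstats(ss, G)
  res <- run_rtwas(store, ssh, G, ridge_eps = 0)
  jj <- joint_conditional(res, pred_expr_cor(store, G), entry_p = 0.05)
  expect_identical(jj$selected, "MED")
  z_snps <- stats::setNames(ssh$z, ssh$snp)
  z_cond <- condition_snp_z(z_snps, G, jj, store$weights)
  expect_lt(mean(abs(z_cond)), mean(abs(z_snps)))  # strict signal removal
  # direct dense-formula oracle: z' = z - rho_kS OmSS^-1 Z_S
  w <- store$weights$MED$w
  R <- stats::cor(G$dosage)[names(z_snps), store$weights$MED$snps]
  rho <- drop(R %*% w) / sqrt(drop(t(w) %*% stats::cor(G$dosage)[
    store$weights$MED$snps, store$weights$MED$snps] %*% w))
  adj <- rho * drop(solve(jj$Omega["MED", "MED", drop = FALSE], jj$Z["MED"]))
  expect_equal(unname(z_cond), unname(z_snps - adj), tolerance = 1e-8)
  # a SNP with zero predicted-expression correlation passes through
  expect_equal(unname(z_cond[abs(rho) < 1e-12]),
               unname(z_snps[abs(rho) < 1e-12]), tolerance = 1e-12)
})

test_that("fine-mapping matches the closed form and brute-force enumeration", {
  # single feature at z = 0: closed-form PIP
  fm0 <- finemap_pip(c(F1 = 0), matrix(1, 1, 1), prior_p = 1e-3, v = 40)
  bf <- sqrt(1 / 41)
  want <- 1e-3 * bf / (1e-3 * bf + (1 - 1e-3))
  expect_equal(unname(fm0$pip), want, tolerance = 1e-10)
  expect_equal(unname(fm0$pip), 1.56e-4, tolerance = 1e-2)
  expect_lt(abs(unname(fm0$pip) - 1.56e-4), 1e-6)
  # posterior over configurations sums to one
  expect_equal(sum(fm0$posterior$posterior), 1, tolerance = 1e-9)
  # symmetric pair: equal PIPs
  Om2 <- diag(2)
  fm2 <- finemap_pip(c(A = 3, B = -3), Om2)
  expect_equal(unname(fm2$pip[1]), unname(fm2$pip[2]), tolerance = 1e-12)
  # brute-force agreement for K <= 4 under correlation
  set.seed(208)
  for (K in 2:4) {
    L <- matrix(rnorm(K * K), K)
    Om <- stats::cov2cor(crossprod(L) + diag(0.3, K))
    Z <- rnorm(K, 0, 2)
    names(Z) <- paste0("F", 1:K)
    dimnames(Om) <- list(names(Z), names(Z))
    fm <- finemap_pip(Z, Om)
    expect_equal(unname(fm$pip), finemap_oracle(Z, Om), tolerance = 1e-10)
    expect_equal(sum(fm$posterior$posterior), 1, tolerance = 1e-9)
    expect_true(all(fm$pip >= 0 & fm$pip <= 1))
  }
  big <- stats::setNames(rnorm(30), paste0("F", 1:30))
  expect_error(finemap_pip(big, diag(30)), "refused")
})

test_that("high-confidence labels require joint selection AND PIP > 0.5", {
  twas <- data.frame(id = c("A", "B", "C"), class = "herv",
                     twas_z = c(6, 5, 5.5), twas_p = 1e-8, bonf_p = 1e-4)
  joints <- list(structure(list(
    selected = c("A", "C"),
    joint = data.frame(id = c("A", "C"), joint_z = c(6, 5.5),
                       joint_p = c(1e-9, 1e-8))), class = "joint_result"))
  finemaps <- list(structure(list(
    pip = c(A = 1.00, B = 0.97, C = 0.40)), class = "finemap_result"))
  out <- classify_high_confidence(twas, joints, finemaps, entry_p = 1e-6)
  expect_true(out$high_confidence[out$id == "A"])    # PIP 1.00 + joint
  expect_false(out$high_confidence[out$id == "B"])   # PIP 0.97, not joint
  expect_false(out$high_confidence[out$id == "C"])   # joint, PIP 0.40
  expect_identical(out$tier[out$id == "B"], "pip_only")
  expect_identical(out$tier[out$id == "C"], "joint_only")
})
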