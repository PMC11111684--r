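# Independent oracles, coded straight from definitions and kept free of
# the package's own implementation paths.

# Loop-based EM for fragment reassignment: plain fixed-point iteration over
# a dense fragment x category likelihood table (categories = features plus
# the trailing no-feature slot).
em_oracle <- function(hits, feats, prior_strength = 1e-3, score_scale = 20,
                      nofeature_score = NULL, n_iter = 2000) {
  frag_ids <- unique(hits$fragment_id)
  N <- length(frag_ids)
  Kc <- length(feats) + 1L
  nofeature_score <- if (is.null(nofeature_score))
    min(hits$score) - 2 * score_scale else nofeature_score
  L <- matrix(0, N, Kc)
  for (r in seq_len(nrow(hits))) {
    i <- match(hits$fragment_id[r], frag_ids)
    j <- match(hits$feature_id[r], feats)
    L[i, j] <- exp(hits$score[r] / score_scale)
  }
  L[, Kc] <- exp(nofeature_score / score_scale)
  pi <- rep(1 / Kc, Kc)
  for (it in seq_len(n_iter)) {
    P <- sweep(L, 2, pi, "*")
    P <- P / rowSums(P)
    pi_new <- (colSums(P) + prior_strength) / (N + Kc * prior_strength)
    if (max(abs(pi_new - pi)) < 1e-13) { pi <- pi_new; break }
    pi <- pi_new
  }
  P <- sweep(L, 2, pi, "*")
  P <- P / rowSums(P)
  rownames(P) <- frag_ids
  colnames(P) <- c(feats, "__nofeature__")
  list(pi = stats::setNames(pi, colnames(P)), posterior = P)
}

# TMM from its published definition: doubly trimmed, precision-weighted
# mean of M-values against a reference column, factors scaled to geometric
# mean one.
tmm_oracle <- function(counts, ref = NULL, trim_M = 0.30, trim_A = 0.05) {
  lib <- colSums(counts)
  uq <- apply(counts, 2, function(x) stats::quantile(x[x > 0] / sum(x), 0.75))
  if (is.null(ref)) ref <- which.min(abs(uq - mean(uq)))
  one <- function(j) {
    obs <- counts[, j]; rf <- counts[, ref]
    nO <- lib[j]; nR <- lib[ref]
    M <- log2((obs / nO) / (rf / nR))
    A <- (log2(obs / nO) + log2(rf / nR)) / 2
    v <- (nO - obs) / (nO * obs) + (nR - rf) / (nR * rf)
    fin <- is.finite(M) & is.finite(A)
    M <- M[fin]; A <- A[fin]; v <- v[fin]
    if (max(abs(M)) < 1e-6) return(1)
    n <- length(M)
    loM <- floor(n * trim_M) + 1; hiM <- n + 1 - loM
    loA <- floor(n * trim_A) + 1; hiA <- n + 1 - loA
    keep <- rank(M) >= loM & rank(M) <= hiM & rank(A) >= loA & rank(A) <= hiA
    2^(sum(M[keep] / v[keep]) / sum(1 / v[keep]))
  }
  f <- vapply(seq_len(ncol(counts)), one, numeric(1))
  f / exp(mean(log(f)))
}

# TOM from the triple-loop definition.
tom_oracle <- function(A) {
  n <- nrow(A)
  TOM <- diag(n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    l <- 0
    for (u in seq_len(n)) if (u != i && u != j) l <- l + A[i, u] * A[u, j]
    ki <- sum(A[i, -i]); kj <- sum(A[j, -j])
    TOM[i, j] <- (l + A[i, j]) / (min(ki, kj) + 1 - A[i, j])
  }
  TOM
}

# Upper-tail hypergeometric p by explicit enumeration of overlap counts.
hyper_tail_oracle <- function(k, term, universe, module) {
  ks <- k:min(term, module)
  sum(choose(term, ks) * choose(universe - term, module - ks)) /
    choose(universe, module)
}

# Hardy-Weinberg exact test (full enumeration over heterozygote counts,
# summing probabilities <= the observed configuration's).
hwe_exact_oracle <- function(nAA, nAa, naa) {
  n <- nAA + nAa + naa
  nA <- 2 * nAA + nAa
  het_parity <- nAa %% 2
  hets <- seq(het_parity, min(nA, 2 * n - nA), by = 2)
  logp <- vapply(hets, function(h) {
    a <- (nA - h) / 2; b <- n - a - h
    lgamma(n + 1) - lgamma(a + 1) - lgamma(h + 1) - lgamma(b + 1) +
      h * log(2) + lgamma(nA + 1) + lgamma(2 * n - nA + 1) - lgamma(2 * n + 1)
  }, numeric(1))
  p <- exp(logp - max(logp)); p <- p / sum(p)
  obs <- which(hets == nAa)
  sum(p[p <= p[obs] + 1e-12])
}

# Mean-zero multivariate normal log-density, written independently of the
# package's internal helper (determinant + solve, no Cholesky).
dmvn_oracle <- function(z, V) {
  -0.5 * (length(z) * log(2 * pi) + determinant(V)$modulus +
            drop(t(z) %*% solve(V) %*% z))
}

# Brute-force fine-mapping enumeration for small K.
finemap_oracle <- function(Z, Omega, prior_p = 1e-3, v = 40,
                           max_causal = 3) {
  K <- length(Z)
  configs <- list(integer(0))
  for (sz in seq_len(min(max_causal, K)))
    configs <- c(configs, utils::combn(K, sz, simplify = FALSE))
  w <- vapply(configs, function(cc) {
    V <- Omega
    if (length(cc) > 0)
      V <- Omega + v * Omega[, cc, drop = FALSE] %*% t(Omega[, cc, drop = FALSE])
    length(cc) * log(prior_p) + (K - length(cc)) * log(1 - prior_p) +
      dmvn_oracle(Z, V)
  }, numeric(1))
  w <- exp(w - max(w)); w <- w / sum(w)
  vapply(seq_len(K), function(j)
    sum(w[vapply(configs, function(cc) j %in% cc, logical(1))]), numeric(1))
}

# Small genotype fixture shared across tests.
toy_genotypes <- function(n = 200, m = 40, rho = 0.4, seed = 42,
                          maf = c(0.1, 0.5), chrom = "1", spacing = 10000) {
  simulate_genotypes(n, list(ld_block(m, maf_range = maf, rho = rho,
                                      chrom = chrom, spacing_bp = spacing)),
                     seed = seed)
}
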