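# Synthetic-data generators: determinism, marginals, LD targeting,
# heritability structure, mediated summary statistics, fragment sampling.

test_that("genotype simulation is deterministic and respects marginals", {
  blocks <- list(ld_block(60, maf_range = c(0.1, 0.4), rho = 0.5, chrom = "1"),
                 ld_block(40, maf_range = c(0.2, 0.5), rho = 0, chrom = "2"))
  G1 <- simulate_genotypes(1500, blocks, seed = 7)
  G2 <- simulate_genotypes(1500, blocks, seed = 7)
  expect_identical(G1$dosage, G2$dosage)
  expect_identical(G1$map, G2$map)
  expect_true(all(G1$dosage %in% 0:2))
  # empirical MAF within 3 binomial SE of target (2n haplotypes)
  emp <- colMeans(G1$dosage) / 2
  se <- sqrt(G1$map$maf * (1 - G1$map$maf) / (2 * 1500))
  expect_true(all(abs(emp - G1$map$maf) < 3.8 * se))
  expect_error(simulate_genotypes(1500, list(), seed = 1), "block")
})

test_that("adjacent-SNP correlation targets rho; blocks are independent", {
  G0 <- simulate_genotypes(2000, list(ld_block(40, rho = 0, chrom = "1")),
                           seed = 11)
  cc0 <- vapply(1:39, function(j)
    stats::cor(G0$dosage[, j], G0$dosage[, j + 1]), numeric(1))
  expect_lt(mean(abs(cc0)), 0.05)
  # feasible high-LD case: fixed MAF 0.5
  G9 <- simulate_genotypes(2000,
    list(ld_block(40, maf_range = c(0.5, 0.5), rho = 0.9, chrom = "1")),
    seed = 12)
  cc9 <- vapply(1:39, function(j)
    stats::cor(G9$dosage[, j], G9$dosage[, j + 1]), numeric(1))
  expect_lt(abs(mean(cc9) - 0.9), 0.05)
  # across-block independence
  Gx <- simulate_genotypes(2000,
    list(ld_block(20, rho = 0.8, chrom = "1"),
         ld_block(20, rho = 0.8, chrom = "2")), seed = 13)
  cross <- stats::cor(Gx$dosage[, 1:20], Gx$dosage[, 21:40])
  expect_lt(mean(abs(cross)), 0.05)
})

make_ann_grid <- function(K, chrom = "1", spacing = 20000, len = 5000,
                          class = "gene") {
  start <- seq(10000, by = spacing, length.out = K)
  feature_annotation(sprintf("F%03d", seq_len(K)), chrom, start, start + len,
                     class = class)
}

test_that("expression heritability structure matches the architecture", {
  G <- toy_genotypes(n = 500, m = 120, seed = 21, spacing = 5000)
  ann <- make_ann_grid(50, spacing = 12000)
  # null case: h2 = 0 -> latent uncorrelated with any genetic value
  sim0 <- simulate_expression(G, ann, expr_arch(h2_cis = 0), seed = 22)
  expect_true(all(sim0$truth$genetic == 0))
  expect_true(all(sim0$counts >= 0) && all(sim0$counts == round(sim0$counts)))
  # h2 = 0.5: R^2 of latent on true genetic value near 0.5 across features
  sim5 <- simulate_expression(G, ann, expr_arch(h2_cis = 0.5, n_causal = 2),
                              seed = 23)
  r2 <- vapply(seq_len(50), function(f) {
    g <- sim5$truth$genetic[f, ]
    if (stats::sd(g) == 0) return(NA_real_)
    summary(stats::lm(sim5$truth$latent[f, ] ~ g))$r.squared
  }, numeric(1))
  expect_lt(abs(mean(r2, na.rm = TRUE) - 0.5), 0.07)
  expect_error(simulate_expression(G, ann, expr_arch(h2_cis = 1.5), seed = 1),
               "h2")
})

test_that("HERV-class features are generated at lower abundance than genes", {
  G <- toy_genotypes(n = 300, m = 40, seed = 31)
  ann <- rbind(make_ann_grid(20, class = "gene"),
               make_ann_grid(20, class = "herv"))
  ann$feature_id <- sprintf("F%03d", seq_len(40))
  sim <- simulate_expression(G, ann, expr_arch(h2_cis = 0.2), seed = 32)
  mg <- mean(sim$counts[ann$class == "gene", ])
  mh <- mean(sim$counts[ann$class == "herv", ])
  expect_gt(mg, 5 * mh)
})

test_that("planted co-expression modules raise within-module correlation", {
  G <- toy_genotypes(n = 400, m = 40, seed = 41)
  ann <- make_ann_grid(120, spacing = 5000)
  spec <- list(list(features = ann$feature_id[1:50], strength = 0.5),
               list(features = ann$feature_id[51:100], strength = 0.5))
  sim <- simulate_expression(G, ann,
                             expr_arch(h2_cis = 0, module_spec = spec),
                             seed = 42)
  lat <- sim$truth$latent
  cc <- stats::cor(t(lat))
  within <- c(cc[1:50, 1:50][upper.tri(diag(50))],
              cc[51:100, 51:100][upper.tri(diag(50))])
  between <- cc[1:50, 51:100]
  expect_gt(mean(abs(within)), mean(abs(between)) + 0.2)
  expect_error(
    simulate_expression(G, ann, expr_arch(module_spec = list(
      list(features = ann$feature_id[1:10]),
      list(features = ann$feature_id[5:15]))), seed = 1),
    "disjoint")
})

test_that("null GWAS summary statistics are calibrated", {
  blocks <- lapply(1:25, function(b)
    ld_block(40, rho = 0.4, chrom = as.character(b)))
  G <- simulate_genotypes(600, blocks, seed = 51)
  ann <- make_ann_grid(10)
  sim <- simulate_expression(G, ann, expr_arch(h2_cis = 0.3), seed = 52)
  ss <- simulate_gwas_sumstats(G, sim$truth, alpha = 0, N_gwas = 50000,
                               seed = 53)
  m <- nrow(ss)  # 1000 SNPs, correlated within blocks of 40
  expect_lt(abs(mean(ss$z)), 3 * sqrt(40 / m))     # conservative SE under LD
  expect_lt(abs(stats::var(ss$z) - 1), 3 * sqrt(2 * 40 / m))
  ss2 <- simulate_gwas_sumstats(G, sim$truth, alpha = 0, N_gwas = 50000,
                                seed = 53)
  expect_identical(ss, ss2)
  expect_error(simulate_gwas_sumstats(G, sim$truth, alpha = 0, N_gwas = 0,
                                      seed = 1), "N_gwas")
})

test_that("mediated z at the causal SNP matches its analytic expectation", {
  G <- toy_genotypes(n = 800, m = 30, seed = 61)
  ann <- make_ann_grid(1)
  sim <- simulate_expression(G, ann, expr_arch(h2_cis = 0.4, n_causal = 1),
                             seed = 62)
  causal <- sim$truth$causal[[1]]$snps
  alpha <- 0.3; N <- 10000
  zrep <- vapply(1:200, function(r)
    simulate_gwas_sumstats(G, sim$truth, alpha = alpha, N_gwas = N,
                           seed = 100 + r)$z[match(causal, G$map$snp)],
    numeric(1))
  # single causal SNP: the standardized eQTL loading is +/-1 depending on
  # the drawn effect sign, so E[z] = sqrt(N) * alpha * sign(effect)
  b_eqtl <- sign(sim$truth$causal[[1]]$effects)
  expect_lt(abs(mean(zrep) - sqrt(N) * alpha * b_eqtl), 3 / sqrt(200) + 0.25)
})

test_that("fragment simulation honours pi, ambiguity and exact counts", {
  ann <- feature_annotation(c("A", "B", "C"), "1", c(0, 5000, 10000),
                            c(1000, 6000, 11000), class = "herv",
                            family = "F1")
  # single feature: every fragment unique
  one <- simulate_fragments(ann[1, ], pi_true = 1, n_frags = 200, seed = 71)
  expect_equal(nrow(one$alignments$hits), 200)
  # binomial check on the true source fraction
  two <- simulate_fragments(ann[1:2, ], homology_groups = list(c("A", "B")),
                            pi_true = c(0.8, 0.2), n_frags = 10000, seed = 72)
  frac <- mean(two$truth$source == "A")
  expect_lt(abs(frac - 0.8), 3 * sqrt(0.8 * 0.2 / 10000))
  # ambiguity_rate 1 within a group: every fragment >= 2 candidates
  full <- simulate_fragments(ann, homology_groups = list(c("A", "B", "C")),
                             pi_true = c(0.5, 0.3, 0.2),
                             score_model = list(ambiguity_rate = 1),
                             n_frags = 500, seed = 73)
  ncand <- table(full$alignments$hits$fragment_id)
  expect_true(all(ncand >= 2))
  expect_error(simulate_fragments(ann, pi_true = c(0.5, 0.2, 0.2),
                                  n_frags = 10, seed = 1), "simplex")
  # exact counts reproduce the per-feature source tallies
  ex <- simulate_fragments(ann, homology_groups = list(c("A", "B", "C")),
                           seed = 74, exact_counts = c(A = 30, B = 12, C = 5))
  tab <- table(ex$truth$source)
  expect_equal(as.integer(tab[c("A", "B", "C")]), c(30L, 12L, 5L))
})
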