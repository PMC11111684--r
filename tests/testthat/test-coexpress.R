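# Signed network construction, scale-free power selection, topological
# overlap, module detection + eigengenes, GO enrichment, composition.

planted_expr <- function(sizes = c(60, 60), n_noise = 30, n_samples = 80,
                         r = 0.7, seed = 301) {
  set.seed(seed)
  mk_block <- function(k) {
    f <- rnorm(n_samples)
    t(sapply(seq_len(k), function(i)
      sqrt(r) * f + sqrt(1 - r) * rnorm(n_samples)))
  }
  expr <- do.call(rbind, c(lapply(sizes, mk_block),
                           list(matrix(rnorm(n_noise * n_samples), n_noise))))
  rownames(expr) <- sprintf("F%03d", seq_len(nrow(expr)))
  truth <- c(rep(seq_along(sizes), sizes), rep(0, n_noise))
  list(expr = expr, truth = truth)
}

test_that("signed adjacency follows its formula", {
  expect_equal(signed_adjacency(matrix(c(1, 1, 1, 1), 2), 6)[1, 2], 1)
  expect_equal(signed_adjacency(matrix(c(1, -1, -1, 1), 2), 6)[1, 2], 0)
  expect_equal(signed_adjacency(matrix(c(1, 0, 0, 1), 2), 12)[1, 2],
               0.5^12, tolerance = 1e-12)
  expect_equal(signed_adjacency(matrix(c(1, 0, 0, 1), 2), 12)[1, 2],
               2.4414e-4, tolerance = 1e-4)
  set.seed(302)
  cc <- stats::cov2cor(crossprod(matrix(rnorm(16), 4)) + diag(0.2, 4))
  A <- signed_adjacency(cc, 7)
  expect_equal(A - diag(diag(A)) + diag(4) * 0,
               ((1 + cc) / 2)^7 - diag(diag(((1 + cc) / 2)^7)) + 0 * diag(4),
               tolerance = 1e-12)
  expect_true(all(A >= 0 & A <= 1))
})

test_that("soft-threshold selection is monotone in connectivity and reproducible", {
  pe <- planted_expr()
  pb1 <- pick_beta(pe$expr)
  pb2 <- pick_beta(pe$expr)
  expect_identical(pb1$beta, pb2$beta)
  expect_true(all(diff(pb1$fit_table$mean_connectivity) < 0))
  # regression oracle for the fit statistic at one power
  A <- signed_adjacency(pb1$corr, 6)
  k <- colSums(A) - 1
  k <- k[k > 0]
  br <- seq(min(k), max(k), length.out = 11)
  bin <- cut(k, br, include.lowest = TRUE)
  freq <- tapply(k, bin, length); mk <- tapply(k, bin, mean)
  ok <- !is.na(freq) & freq > 0
  fit <- stats::lm(log10(freq[ok]) ~ log10(mk[ok]))
  r2 <- summary(fit)$r.squared * sign(-coef(fit)[2])
  expect_equal(pb1$fit_table$scale_free_r2[pb1$fit_table$power == 6],
               unname(r2), tolerance = 1e-10)
})

test_that("TOM matches the triple-loop oracle and its fixed points", {
  expect_true(all(abs(tom_similarity(diag(5)) - diag(5)) < 1e-12))
  # identical (binary) neighbourhoods with a_ij = 1 give TOM_ij = 1
  A <- diag(4)
  A[1, 2] <- A[2, 1] <- 1
  A[1, 3] <- A[2, 3] <- A[3, 1] <- A[3, 2] <- 1
  expect_equal(tom_similarity(A)[1, 2], 1, tolerance = 1e-12)
  set.seed(303)
  B <- stats::cov2cor(crossprod(matrix(rnorm(25), 5)) + diag(0.3, 5))
  AB <- signed_adjacency(B, 4)
  expect_lt(max(abs(tom_similarity(AB) - tom_oracle(AB))), 1e-12)
  TOM <- tom_similarity(AB)
  expect_true(all(TOM >= 0 & TOM <= 1 + 1e-12))
})

test_that("planted modules are recovered exactly and noise goes grey", {
  pe <- planted_expr(sizes = c(70, 50))
  pb <- pick_beta(pe$expr)
  A <- signed_adjacency(pb$corr, pb$beta)
  mods <- detect_modules(tom_similarity(A), pe$expr, min_module_size = 20)
  non_grey <- setdiff(unique(mods$colours), "grey")
  expect_length(non_grey, 2)
  # the larger planted block takes the first palette colour
  expect_identical(names(sort(table(mods$colours[mods$colours != "grey"]),
                              decreasing = TRUE))[1], "turquoise")
  expect_true(all(mods$colours[pe$truth == 1] == "turquoise"))
  ari <- mclust::adjustedRandIndex(mods$colours[pe$truth > 0],
                                   pe$truth[pe$truth > 0])
  expect_equal(ari, 1)
  expect_true(all(mods$colours[pe$truth == 0] == "grey"))
  # invariance to feature order
  perm <- sample(nrow(pe$expr))
  A2 <- signed_adjacency(stats::cor(t(pe$expr[perm, ])), pb$beta)
  mods2 <- detect_modules(tom_similarity(A2), pe$expr[perm, ],
                          min_module_size = 20)
  expect_equal(mclust::adjustedRandIndex(
    mods2$colours[rownames(pe$expr)], mods$colours[rownames(pe$expr)]), 1)
  # pure-noise input: everything grey
  noise <- matrix(rnorm(60 * 50), 60,
                  dimnames = list(sprintf("N%02d", 1:60), NULL))
  pbn <- pick_beta(noise, powers = c(6, 12))
  An <- signed_adjacency(pbn$corr, 12)
  modsn <- detect_modules(tom_similarity(An), noise, min_module_size = 30)
  expect_true(all(modsn$colours == "grey"))
})

test_that("module eigengenes are oriented, unit norm, and match the SVD", {
  set.seed(304)
  base <- rnorm(40)
  mod <- rbind(base, base, base) + matrix(rnorm(120, 0, 1e-6), 3)
  rownames(mod) <- paste0("f", 1:3)
  eg <- module_eigengene(mod)
  expect_equal(sum(eg$eigengene^2), 1, tolerance = 1e-12)
  expect_gt(abs(cor(eg$eigengene, base)), 0.999)
  expect_gt(cor(eg$eigengene, rowMeans(scale(t(mod)))), 0)
  # flipping all rows leaves the orientation rule's output aligned with
  # the (flipped) module mean
  eg2 <- module_eigengene(-mod)
  expect_gt(cor(eg2$eigengene, rowMeans(scale(t(-mod)))), 0)
  expect_equal(eg$var_explained, 1, tolerance = 1e-6)
  m2 <- rbind(rnorm(30), rnorm(30), rnorm(30), rnorm(30))
  rownames(m2) <- paste0("g", 1:4)
  e2 <- module_eigengene(m2)
  sv <- svd(t(scale(t(m2))))
  expect_equal(e2$var_explained, sv$d[1]^2 / sum(sv$d^2), tolerance = 1e-10)
})

test_that("GO enrichment equals exact hypergeometric enumeration", {
  colours <- stats::setNames(c(rep("turquoise", 4), rep("grey", 16)),
                             paste0("g", 1:20))
  classes <- stats::setNames(rep("gene", 20), paste0("g", 1:20))
  assignment <- structure(list(colours = colours), class = "module_assignment")
  sets <- list(T1 = paste0("g", 1:5),      # overlap 3 with module g1..g4? no:
               T2 = paste0("g", 10:12))    # zero overlap
  sets$T1 <- paste0("g", c(1, 2, 3, 8, 9)) # overlap 3 of term 5
  out <- go_enrich(assignment, sets, background = paste0("g", 1:20),
                   classes = classes)
  p1 <- out$p[out$term == "T1"]
  expect_equal(p1, hyper_tail_oracle(3, 5, 20, 4), tolerance = 1e-12)
  expect_equal(out$p[out$term == "T2"], 1)  # P(X >= 0) = 1
  expect_equal(out$enrichment_ratio[out$term == "T1"], 3 / (5 * 4 / 20),
               tolerance = 1e-12)
  expect_equal(out$bonf_p, pmin(1, out$p * nrow(out)), tolerance = 1e-12)
  # module identical to a term in a large universe: minimal p
  colours2 <- stats::setNames(c(rep("blue", 4), rep("grey", 26)),
                              paste0("h", 1:30))
  classes2 <- stats::setNames(rep("gene", 30), paste0("h", 1:30))
  a2 <- structure(list(colours = colours2), class = "module_assignment")
  out2 <- go_enrich(a2, list(T = paste0("h", 1:4)), paste0("h", 1:30),
                    classes2)
  expect_equal(out2$p, 1 / choose(30, 4), tolerance = 1e-12)
  expect_equal(out2$enrichment_ratio, 30 / 4, tolerance = 1e-12)
  # HERV-class features never enter universe or modules
  classes3 <- classes2; classes3[c("h1", "h5")] <- "herv"
  out3 <- go_enrich(a2, list(T = paste0("h", 1:4)), paste0("h", 1:30),
                    classes3)
  expect_equal(out3$module_genes, 3)
  expect_equal(out3$p, hyper_tail_oracle(3, 3, 28, 3), tolerance = 1e-12)
  expect_error(go_enrich(a2, list(T = "x"), character(0), classes2),
               "background")
})

test_that("module composition rounds class percentages as printed", {
  ids <- sprintf("x%04d", 1:5213)
  colours <- stats::setNames(rep("turquoise", 5213), ids)
  classes <- stats::setNames(c(rep("herv", 3815), rep("gene", 1398)), ids)
  a <- structure(list(colours = colours,
                      sizes = table(colours)), class = "module_assignment")
  comp <- module_composition(a, classes)
  expect_equal(comp$pct_herv, 73L)
  expect_equal(comp$pct_gene, 27L)
  expect_lte(abs(comp$pct_herv + comp$pct_gene - 100), 1)
  # all-gene module
  a2 <- structure(list(colours = stats::setNames(rep("blue", 10),
                                                 paste0("g", 1:10)),
                       sizes = table(rep("blue", 10))),
                  class = "module_assignment")
  comp2 <- module_composition(
    a2, stats::setNames(rep("gene", 10), paste0("g", 1:10)))
  expect_equal(comp2$pct_herv, 0L)
})
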