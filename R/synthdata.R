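# Synthetic data with known ground truth: LD-structured genotypes,
# cis-regulated expression of lowly expressed HERV loci alongside genes,
# expression-mediated GWAS z-scores, and multi-mapped sequencing fragments
# from homologous loci. Every generator takes an explicit seed and restores
# the caller's RNG state.

#' Specify an LD block
#'
#' Describes one independent linkage-disequilibrium block: adjacent SNPs are
#' generated from a latent AR(1) Gaussian per haplotype, thresholded at the
#' allele frequency, so the haplotype (and hence dosage) correlation between
#' neighbours targets `rho`.
#'
#' @param n_snps number of SNPs in the block (>= 1)
#' @param maf_range length-2 interval in (0, 0.5] from which per-SNP minor
#'   allele frequencies are drawn uniformly
#' @param rho target adjacent-SNP dosage correlation in [0, 1)
#' @param chrom chromosome label
#' @param start_bp 1-based position of the first SNP
#' @param spacing_bp distance between adjacent SNPs in bp
#' @return an object of class `ld_block`
#' @export
ld_block <- function(n_snps, maf_range = c(0.05, 0.5), rho = 0.5,
                     chrom = "1", start_bp = 1L, spacing_bp = 1000L) {
  if (n_snps < 1) stop_config("n_snps must be >= 1")
  if (rho < 0 || rho >= 1) stop_config("rho must lie in [0, 1)")
  if (length(maf_range) != 2L || maf_range[1] <= 0 || maf_range[2] > 0.5 ||
      maf_range[1] > maf_range[2]) {
    stop_config("maf_range must be an interval within (0, 0.5]")
  }
  structure(list(n_snps = as.integer(n_snps), maf_range = maf_range,
                 rho = rho, chrom = as.character(chrom),
                 start_bp = as.integer(start_bp),
                 spacing_bp = as.integer(spacing_bp)),
            class = "ld_block")
}

#' Construct a genotype matrix container
#'
#' @param dosage samples x SNPs numeric matrix of allele dosages (0/1/2,
#'   `NA` for missing)
#' @param map data frame with columns `snp`, `chrom`, `pos`, `a1`, `a2` and
#'   optionally `block`
#' @return an object of class `geno_matrix`
#' @export
geno_matrix <- function(dosage, map) {
  stopifnot(is.matrix(dosage), nrow(map) == ncol(dosage))
  need <- c("snp", "chrom", "pos", "a1", "a2")
  if (!all(need %in% names(map))) {
    stop_config("map must have columns ", paste(need, collapse = ", "))
  }
  colnames(dosage) <- map$snp
  if (is.null(rownames(dosage))) {
    rownames(dosage) <- sprintf("S%04d", seq_len(nrow(dosage)))
  }
  structure(list(dosage = dosage, map = map), class = "geno_matrix")
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat("geno_matrix:", nrow(x$dosage), "samples x", ncol(x$dosage), "variants\n")
  invisible(x)
}

non_ambiguous_allele_pairs <- function() {
  # all ordered ref/alt pairs excluding strand-ambiguous A/T and C/G
  pairs <- expand.grid(a1 = c("A", "C", "G", "T"), a2 = c("A", "C", "G", "T"),
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$a1 != pairs$a2, ]
  amb <- (pairs$a1 == "A" & pairs$a2 == "T") | (pairs$a1 == "T" & pairs$a2 == "A") |
         (pairs$a1 == "C" & pairs$a2 == "G") | (pairs$a1 == "G" & pairs$a2 == "C")
  pairs[!amb, ]
}

#' Simulate LD-structured genotype dosages
#'
#' Two haplotypes per individual are drawn independently from a latent AR(1)
#' Gaussian chain and thresholded at each SNP's allele frequency; the latent
#' step correlation is pre-compensated (tetrachoric inversion) so that the
#' realised adjacent-SNP dosage correlation targets the block's `rho`.
#' Blocks are mutually independent. Alleles are drawn from the
#' non-strand-ambiguous pairs, emulating a post-imputation-QC panel.
#'
#' @param n_samples number of individuals (>= 2)
#' @param blocks list of [ld_block()] specifications
#' @param seed integer RNG seed
#' @return a [geno_matrix()] whose `map` carries chrom/pos/a1/a2/block and the
#'   target MAF per SNP
#' @export
simulate_genotypes <- function(n_samples, blocks, seed) {
  if (length(blocks) == 0) stop_config("at least one LD block is required")
  if (inherits(blocks, "ld_block")) blocks <- list(blocks)
  if (n_samples < 2) stop_config("n_samples must be >= 2")
  with_seed(seed, {
    per_block <- lapply(seq_along(blocks), function(bi) {
      b <- blocks[[bi]]
      m <- b$n_snps
      maf <- stats::runif(m, b$maf_range[1], b$maf_range[2])
      thr <- stats::qnorm(maf)
      # latent step correlations compensating threshold attenuation
      rstep <- if (m > 1) {
        vapply(seq_len(m - 1L), function(j) {
          tetrachoric_latent_r(b$rho, maf[j], maf[j + 1L])
        }, numeric(1))
      } else numeric(0)
      hap <- function() {
        Z <- matrix(stats::rnorm(n_samples * m), n_samples, m)
        if (m > 1) {
          for (j in 2:m) {
            r <- rstep[j - 1L]
            Z[, j] <- r * Z[, j - 1L] + sqrt(1 - r^2) * Z[, j]
          }
        }
        sweep(Z, 2L, thr, "<") * 1L
      }
      dos <- hap() + hap()
      ap <- non_ambiguous_allele_pairs()
      pick <- sample.int(nrow(ap), m, replace = TRUE)
      map <- data.frame(
        snp = sprintf("rs%s_%d", bi, seq_len(m)),
        chrom = b$chrom,
        pos = b$start_bp + (seq_len(m) - 1L) * b$spacing_bp,
        a1 = ap$a1[pick], a2 = ap$a2[pick],
        maf = maf, block = bi,
        stringsAsFactors = FALSE
      )
      list(dos = dos, map = map)
    })
    dosage <- do.call(cbind, lapply(per_block, `[[`, "dos"))
    map <- do.call(rbind, lapply(per_block, `[[`, "map"))
    storage.mode(dosage) <- "double"
    geno_matrix(dosage, map)
  })
}

#' Build a feature annotation table
#'
#' Intervals are 0-based half-open (BED convention); `length = end - start`.
#'
#' @param feature_id,chrom,start,end,class vectors of equal length; `class`
#'   must be `"gene"` or `"herv"`
#' @param family repeat family label (hervs) or `NA`
#' @param strand `"+"`/`"-"`
#' @return data frame with a `length` column added
#' @export
feature_annotation <- function(feature_id, chrom, start, end,
                               class = "gene", family = NA_character_,
                               strand = "+") {
  if (any(start >= end)) stop_config("start must be < end for all features")
  if (!all(class %in% c("gene", "herv"))) {
    stop_config("feature class must be 'gene' or 'herv'")
  }
  data.frame(feature_id = as.character(feature_id), chrom = as.character(chrom),
             start = as.integer(start), end = as.integer(end),
             class = rep_len(class, length(feature_id)),
             family = rep_len(as.character(family), length(feature_id)),
             strand = rep_len(strand, length(feature_id)),
             length = as.integer(end - start), stringsAsFactors = FALSE)
}

#' Architecture of simulated expression
#'
#' @param h2_cis per-feature cis heritability; scalar recycled or vector,
#'   each in [0, 1]
#' @param n_causal number of causal cis SNPs per feature; scalar or vector;
#'   defaults to 1-3 drawn per feature
#' @param mean_log_expression named vector of natural-log mean counts per
#'   feature class; HERV loci sit well below genes by default
#' @param sigma_log lognormal SD of the latent on the log-count scale
#' @param module_spec optional list of planted co-expression modules, each a
#'   list with `features` (ids) and `strength` (share of non-genetic latent
#'   variance carried by the shared factor, in [0,1))
#' @param covariates optional list with `data` (samples x q data frame of
#'   numeric covariates) and `effects` (q-vector); contribution is added to
#'   the non-genetic latent part
#' @param alpha per-feature trait-mediation effect (scalar recycled or
#'   vector); stored in the truth table for [simulate_gwas_sumstats()]
#' @return list of class `expr_arch`
#' @export
expr_arch <- function(h2_cis = 0.2, n_causal = NULL,
                      mean_log_expression = c(gene = 5.0, herv = 2.5),
                      sigma_log = 0.6, module_spec = NULL,
                      covariates = NULL, alpha = 0) {
  if (any(h2_cis < 0 | h2_cis > 1)) stop_config("h2_cis must lie in [0, 1]")
  structure(list(h2_cis = h2_cis, n_causal = n_causal,
                 mean_log_expression = mean_log_expression,
                 sigma_log = sigma_log, module_spec = module_spec,
                 covariates = covariates, alpha = alpha),
            class = "expr_arch")
}

#' Simulate cis-regulated expression counts with known truth
#'
#' Per feature, causal SNPs are drawn inside the feature's cis window, a
#' genetic value g = X beta is formed on standardized dosages and scaled so
#' that Var(g) / Var(latent) = h2_cis. The non-genetic remainder optionally
#' shares planted module factors and covariate effects. Counts follow a
#' Poisson-lognormal around the latent, with class-specific mean log
#' abundance (HERV loci lower than genes).
#'
#' @param G a [geno_matrix()]
#' @param annotation a [feature_annotation()] table
#' @param arch an [expr_arch()]
#' @param seed integer RNG seed
#' @param window_bp cis window half-width for causal SNP placement
#' @return list with `counts` (features x samples integer matrix) and
#'   `truth` (class `truth_table`)
#' @export
simulate_expression <- function(G, annotation, arch = expr_arch(), seed,
                                window_bp = 5e5) {
  stopifnot(inherits(G, "geno_matrix"), inherits(arch, "expr_arch"))
  n <- nrow(G$dosage)
  K <- nrow(annotation)
  h2 <- rep_len(arch$h2_cis, K)
  alpha <- rep_len(arch$alpha, K)
  if (any(h2 < 0 | h2 > 1)) stop_config("h2_cis must lie in [0, 1]")
  with_seed(seed, {
    Xs <- standardize_cols(G$dosage)
    # planted module factors
    mod_of <- rep(NA_integer_, K)
    names(mod_of) <- annotation$feature_id
    mod_strength <- numeric(0)
    Fmat <- NULL
    if (!is.null(arch$module_spec)) {
      ids <- unlist(lapply(arch$module_spec, `[[`, "features"))
      if (anyDuplicated(ids)) stop_config("planted modules must be disjoint")
      Fmat <- matrix(stats::rnorm(n * length(arch$module_spec)), n)
      for (mi in seq_along(arch$module_spec)) {
        ms <- arch$module_spec[[mi]]
        mod_of[ms$features] <- mi
        mod_strength[mi] <- ms$strength %||% 0.5
      }
    }
    cov_part <- 0
    if (!is.null(arch$covariates)) {
      Cm <- as.matrix(arch$covariates$data)
      cov_part <- drop(scale(Cm) %*% arch$covariates$effects)
    }
    counts <- matrix(0L, K, n,
                     dimnames = list(annotation$feature_id, rownames(G$dosage)))
    latent <- matrix(0, K, n, dimnames = dimnames(counts))
    genetic <- matrix(0, K, n, dimnames = dimnames(counts))
    causal <- vector("list", K)
    names(causal) <- annotation$feature_id
    lib <- stats::rnorm(n, 0, 0.15)  # sample depth wobble on log scale
    for (f in seq_len(K)) {
      fa <- annotation[f, ]
      in_win <- which(G$map$chrom == fa$chrom &
                      G$map$pos >= fa$start - window_bp &
                      G$map$pos <= fa$end + window_bp)
      g <- rep(0, n)
      eff <- numeric(0); cs <- integer(0)
      if (h2[f] > 0 && length(in_win) > 0) {
        nc <- if (is.null(arch$n_causal)) sample(1:3, 1) else
          rep_len(arch$n_causal, K)[f]
        nc <- min(nc, length(in_win))
        cs <- sort(sample(in_win, nc))
        eff <- stats::rnorm(nc)
        g <- drop(Xs[, cs, drop = FALSE] %*% eff)
        if (stats::sd(g) < .Machine$double.eps) { g <- rep(0, n); cs <- integer(0); eff <- numeric(0) }
      }
      has_g <- length(cs) > 0 && h2[f] > 0
      gs <- if (has_g) (g - mean(g)) / stats::sd(g) else rep(0, n)
      mi <- mod_of[f]
      e <- if (!is.na(mi)) {
        s <- mod_strength[mi]
        sqrt(s) * Fmat[, mi] + sqrt(1 - s) * stats::rnorm(n)
      } else stats::rnorm(n)
      e <- e + cov_part
      e <- (e - mean(e)) / stats::sd(e)
      z <- if (has_g) sqrt(h2[f]) * gs + sqrt(1 - h2[f]) * e else e
      mu_class <- arch$mean_log_expression[[fa$class]]
      lam <- exp(mu_class + lib + arch$sigma_log * z)
      counts[f, ] <- stats::rpois(n, lam)
      latent[f, ] <- z
      genetic[f, ] <- if (has_g) sqrt(h2[f]) * gs else 0
      causal[[f]] <- list(snps = G$map$snp[cs], effects = eff,
                          effects_std = if (length(eff)) eff / stats::sd(g) else numeric(0))
    }
    truth <- structure(list(
      feature_id = annotation$feature_id,
      class = annotation$class,
      h2_cis = h2, alpha = alpha, causal = causal,
      latent = latent, genetic = genetic,
      modules = mod_of, annotation = annotation
    ), class = "truth_table")
    list(counts = counts, truth = truth)
  })
}

#' Simulate GWAS summary statistics mediated by expression
#'
#' Marginal standardized SNP effects are composed from the truth table's
#' standardized eQTL effect vectors and per-feature trait effects alpha:
#' b = sum_f alpha_f R u_f, with u_f the unit-variance genetic-expression
#' loading. Per LD block, z = sqrt(N) b + MVN(0, R) with R the empirical
#' dosage correlation, matching the model the association stage assumes.
#'
#' @param G a [geno_matrix()] (also the LD source)
#' @param truth a `truth_table` from [simulate_expression()]
#' @param alpha optional per-feature trait effects overriding the truth
#'   table's (named or positional)
#' @param N_gwas GWAS sample size (>= 1)
#' @param seed integer RNG seed
#' @return data frame with columns snp, chrom, pos, a1, a2, z, n, maf
#' @export
simulate_gwas_sumstats <- function(G, truth, alpha = NULL, N_gwas, seed) {
  stopifnot(inherits(G, "geno_matrix"))
  if (N_gwas < 1) stop_config("N_gwas must be >= 1")
  K <- length(truth$feature_id)
  a <- alpha %||% truth$alpha
  a <- rep_len(a, K)
  m <- ncol(G$dosage)
  blocks <- G$map$block %||% rep(1L, m)
  with_seed(seed, {
    b <- rep(0, m)
    names(b) <- G$map$snp
    Xs <- standardize_cols(G$dosage)
    for (f in seq_len(K)) {
      if (a[f] == 0) next
      cz <- truth$causal[[f]]
      if (length(cz$snps) == 0) next
      idx <- match(cz$snps, G$map$snp)
      bl <- blocks[idx[1]]
      in_bl <- which(blocks == bl)
      Rcb <- crossprod(Xs[, in_bl, drop = FALSE],
                       Xs[, idx, drop = FALSE]) / (nrow(Xs) - 1L)
      gsd <- stats::sd(drop(Xs[, idx, drop = FALSE] %*% cz$effects))
      u <- cz$effects / gsd
      b[in_bl] <- b[in_bl] + a[f] * drop(Rcb %*% u)
    }
    z <- rep(NA_real_, m)
    for (bl in unique(blocks)) {
      in_bl <- which(blocks == bl)
      Rb <- stats::cor(G$dosage[, in_bl, drop = FALSE])
      ch <- tryCatch(chol(Rb), error = function(e)
        chol(Rb + diag(1e-6, nrow(Rb))))
      eps <- drop(crossprod(ch, stats::rnorm(length(in_bl))))
      z[in_bl] <- sqrt(N_gwas) * b[in_bl] + eps
    }
    emp_maf <- colMeans(G$dosage, na.rm = TRUE) / 2
    emp_maf <- pmin(emp_maf, 1 - emp_maf)
    data.frame(snp = G$map$snp, chrom = G$map$chrom, pos = G$map$pos,
               a1 = G$map$a1, a2 = G$map$a2, z = z,
               n = as.integer(N_gwas), maf = emp_maf,
               stringsAsFactors = FALSE)
  })
}

#' Simulate candidate alignments for multi-mapping fragments
#'
#' Each fragment draws a true source feature from `pi_true`. Fragments from
#' a homology group are, with probability `ambiguity_rate`, reported with
#' candidate alignments to every group member; otherwise (and always for
#' singleton features) the fragment aligns uniquely to its source.
#'
#' Ambiguous candidate scores are Gaussian with standard deviation
#' `score_sd`: the source member has mean `match_score`, non-source members
#' have mean `match_score - mismatch_penalty`. With
#' `score_sd = sqrt(mismatch_penalty * s)` this is the exponential tilting
#' of a symmetric Gaussian base measure by exp(score / s), so a softmax
#' reassignment likelihood with scale `s` (the quantifier's default, 20)
#' is exactly the generative model and EM recovery of `pi_true` is a
#' consistency check rather than an approximation.
#'
#' @param annotation a [feature_annotation()] table
#' @param homology_groups list of feature-id vectors forming homology
#'   groups (features absent from every group are singletons)
#' @param pi_true numeric simplex over the annotation's features (named or
#'   in annotation order)
#' @param score_model list with `match_score`, `mismatch_penalty`,
#'   `ambiguity_rate` and optionally `score_sd` (default
#'   `sqrt(mismatch_penalty * 20)`)
#' @param n_frags number of fragments
#' @param seed integer RNG seed
#' @param exact_counts optional named per-feature fragment counts; when
#'   given, exactly that many fragments originate from each feature
#'   (shuffled order) instead of a fresh categorical draw, so an upstream
#'   count matrix is reproduced without extra multinomial noise;
#'   `pi_true`/`n_frags` are then ignored
#' @return list with `alignments` (an `alignment_set`) and `truth`
#'   (per-fragment true source ids)
#' @export
simulate_fragments <- function(annotation, homology_groups = list(),
                               pi_true,
                               score_model = list(match_score = 60,
                                                  mismatch_penalty = 8,
                                                  ambiguity_rate = 0.9),
                               n_frags, seed, exact_counts = NULL) {
  K <- nrow(annotation)
  if (is.null(exact_counts)) {
    if (is.null(names(pi_true))) names(pi_true) <- annotation$feature_id
    pi_true <- pi_true[annotation$feature_id]
    if (abs(sum(pi_true) - 1) > 1e-9 || any(pi_true < 0)) {
      stop_config("pi_true must be a simplex over the annotated features")
    }
  }
  group_of <- rep(NA_integer_, K)
  names(group_of) <- annotation$feature_id
  for (gi in seq_along(homology_groups)) {
    group_of[homology_groups[[gi]]] <- gi
  }
  ms <- score_model$match_score %||% 60
  mp <- score_model$mismatch_penalty %||% 8
  ar <- score_model$ambiguity_rate %||% 0.9
  ssd <- score_model$score_sd %||% sqrt(mp * 20)
  with_seed(seed, {
    if (is.null(exact_counts)) {
      src <- sample.int(K, n_frags, replace = TRUE, prob = pi_true)
    } else {
      cnt <- exact_counts[annotation$feature_id]
      cnt[is.na(cnt)] <- 0
      src <- sample(rep(seq_len(K), cnt))
      n_frags <- length(src)
    }
    frag_id <- sprintf("frag%06d", seq_len(n_frags))
    grp <- group_of[src]
    grp_size <- lengths(homology_groups)
    ambiguous <- !is.na(grp) & grp_size[pmax(grp, 1L)] > 1L &
      stats::runif(n_frags) < ar
    # unique alignments: one row per unambiguous fragment
    uniq <- which(!ambiguous)
    blocks <- list(data.frame(fragment_id = frag_id[uniq],
                              feature_id = annotation$feature_id[src[uniq]],
                              score = rep(ms, length(uniq)),
                              stringsAsFactors = FALSE))
    # ambiguous fragments: expand to all group members, per group
    for (gi in seq_along(homology_groups)) {
      fr <- which(ambiguous & grp == gi)
      if (length(fr) == 0) next
      members <- match(homology_groups[[gi]], annotation$feature_id)
      nm <- length(members)
      fidx <- rep(fr, each = nm)
      midx <- rep(members, times = length(fr))
      is_src <- midx == src[fidx]
      sc <- stats::rnorm(length(midx), ifelse(is_src, ms, ms - mp), ssd)
      blocks[[length(blocks) + 1L]] <- data.frame(
        fragment_id = frag_id[fidx],
        feature_id = annotation$feature_id[midx],
        score = sc, stringsAsFactors = FALSE)
    }
    hits <- do.call(rbind, blocks)
    hits <- hits[order(hits$fragment_id), ]
    rownames(hits) <- NULL
    aln <- alignment_set(hits, annotation$feature_id)
    list(alignments = aln,
         truth = data.frame(fragment_id = frag_id,
                            source = annotation$feature_id[src],
                            stringsAsFactors = FALSE))
  })
}
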