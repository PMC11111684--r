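# Signed weighted co-expression network: soft-threshold selection by
# scale-free fit, topological overlap, hierarchical module detection with
# eigengene merging, and hypergeometric GO enrichment of module genes.

module_palette <- c(
  "turquoise", "blue", "brown", "yellow", "green", "red", "black", "pink",
  "magenta", "purple", "greenyellow", "tan", "salmon", "cyan",
  "midnightblue", "lightcyan", "grey60", "lightgreen", "lightyellow",
  "royalblue", "darkred", "darkgreen", "darkturquoise", "darkgrey",
  "orange", "darkorange", "white", "skyblue", "saddlebrown", "steelblue",
  "paleturquoise", "violet", "darkolivegreen", "darkmagenta")

#' Signed adjacency from a correlation matrix
#'
#' a_ij = ((1 + cor_ij) / 2)^beta, diagonal forced to 1. Signed: negative
#' correlations map below 0.5 before powering, so anti-correlated features
#' are never adjacent.
#'
#' @param corr correlation matrix in [-1, 1]
#' @param beta soft-threshold power
#' @return adjacency matrix in [0, 1]
#' @export
signed_adjacency <- function(corr, beta) {
  if (any(corr < -1 - 1e-9 | corr > 1 + 1e-9)) stop_config("corr outside [-1, 1]")
  A <- ((1 + corr) / 2)^beta
  diag(A) <- 1
  A
}

#' Scale-free-topology soft-threshold selection
#'
#' For each candidate power, computes per-feature connectivity k_i =
#' sum_{j != i} a_ij, bins log10(k), regresses log10(frequency) on
#' log10(mean k) per bin, and signs the fit R^2 by the negated slope.
#' The chosen power is the smallest reaching `target_r2`, else the power
#' with the maximum fit (noted in the `"note"` attribute).
#'
#' @param expr features x samples expression matrix
#' @param powers candidate powers (default 1..20 with even steps above 10)
#' @param target_r2 scale-free fit target (default 0.8)
#' @param n_bins connectivity histogram bins (default 10)
#' @return list: `beta`, `fit_table` (power, scale_free_r2,
#'   mean_connectivity), `corr` (the correlation matrix, reusable)
#' @export
pick_beta <- function(expr, powers = c(1:10, seq(12, 20, 2)),
                      target_r2 = 0.8, n_bins = 10) {
  keep <- apply(expr, 1L, stats::sd) > .Machine$double.eps
  if (!all(keep)) {
    warning(sum(!keep), " constant feature(s) dropped")
    expr <- expr[keep, , drop = FALSE]
  }
  if (nrow(expr) < 50) stop_config("at least 50 features required")
  corr <- stats::cor(t(expr))
  fit <- vapply(powers, function(b) {
    A <- signed_adjacency(corr, b)
    k <- colSums(A) - 1
    c(scale_free_fit(k, n_bins), mean(k))
  }, numeric(2))
  fit_table <- data.frame(power = powers, scale_free_r2 = fit[1L, ],
                          mean_connectivity = fit[2L, ])
  hit <- which(fit_table$scale_free_r2 >= target_r2)
  note <- NULL
  if (length(hit) > 0) {
    beta <- powers[hit[1L]]
  } else {
    beta <- powers[which.max(fit_table$scale_free_r2)]
    note <- "no power reached target_r2; using the best fit"
  }
  out <- list(beta = beta, fit_table = fit_table, corr = corr)
  attr(out, "note") <- note
  out
}

#' Signed scale-free fit statistic for a connectivity vector
#' @noRd
scale_free_fit <- function(k, n_bins = 10) {
  k <- k[k > 0]
  if (length(k) < n_bins) return(NA_real_)
  br <- seq(min(k), max(k), length.out = n_bins + 1L)
  bin <- cut(k, br, include.lowest = TRUE)
  freq <- tapply(k, bin, length)
  mk <- tapply(k, bin, mean)
  ok <- !is.na(freq) & freq > 0
  if (sum(ok) < 3) return(NA_real_)
  x <- log10(mk[ok]); y <- log10(freq[ok])
  fit <- stats::lm.fit(cbind(1, x), y)
  r2 <- 1 - sum(fit$residuals^2) / sum((y - mean(y))^2)
  r2 * sign(-fit$coefficients[2L])
}

#' Topological overlap matrix
#'
#' TOM_ij = (l_ij + a_ij) / (min(k_i, k_j) + 1 - a_ij) for i != j with
#' l_ij = sum_{u != i,j} a_iu a_uj and k_i = sum_{u != i} a_iu; TOM_ii = 1.
#'
#' @param A symmetric adjacency with unit diagonal
#' @return TOM similarity matrix in [0, 1]
#' @export
tom_similarity <- function(A) {
  stopifnot(isSymmetric(unname(A)), all(abs(diag(A) - 1) < 1e-12))
  k <- colSums(A) - 1
  # l_ij = (A^2)_ij - a_ii a_ij - a_ij a_jj = (A^2)_ij - 2 a_ij  (unit diag)
  L <- A %*% A - 2 * A
  kmin <- outer(k, k, pmin)
  TOM <- (L + A) / (kmin + 1 - A)
  diag(TOM) <- 1
  TOM
}

#' Module eigengene
#'
#' First principal component of the standardized module expression across
#' samples, unit norm, sign-oriented to correlate positively with the mean
#' module expression profile.
#'
#' @param expr_mod module features x samples expression matrix (>= 2 rows)
#' @return named list: `eigengene` (length = samples, unit norm),
#'   `var_explained`
#' @export
module_eigengene <- function(expr_mod) {
  keep <- apply(expr_mod, 1L, stats::sd) > .Machine$double.eps
  expr_mod <- expr_mod[keep, , drop = FALSE]
  if (nrow(expr_mod) < 2) stop_config("module needs >= 2 non-constant features")
  Xs <- t(scale(t(expr_mod)))
  sv <- svd(Xs, nu = 0, nv = 1)
  e <- sv$v[, 1L]
  if (stats::cor(e, colMeans(Xs)) < 0) e <- -e
  list(eigengene = e / sqrt(sum(e^2)),
       var_explained = sv$d[1L]^2 / sum(svd(Xs, nu = 0, nv = 0)$d^2))
}

#' Detect co-expression modules from a TOM
#'
#' Average-linkage hierarchical clustering on 1 - TOM with a static tree
#' cut at `cut_height`; clusters below `min_module_size` fall into the
#' grey module; modules whose eigengenes correlate above
#' 1 - merge_cut_height are merged iteratively until stable. Colours are
#' assigned by descending module size from the standard palette (largest =
#' turquoise; unassigned = grey).
#'
#' @param TOM topological overlap matrix ([tom_similarity()])
#' @param expr features x samples expression matrix (same feature order),
#'   used for eigengene merging
#' @param min_module_size smallest retained module (default 30)
#' @param cut_height static cut height on 1 - TOM (default 0.99)
#' @param merge_cut_height eigengene-dissimilarity merge threshold
#'   (default 0.25)
#' @return object of class `module_assignment`: `colours` (named by
#'   feature), `sizes`, `eigengenes` (samples x modules)
#' @export
detect_modules <- function(TOM, expr, min_module_size = 30,
                           cut_height = 0.99, merge_cut_height = 0.25) {
  ids <- rownames(expr) %||% paste0("f", seq_len(nrow(expr)))
  n <- nrow(expr)
  if (n < min_module_size) {
    warning("fewer features than min_module_size; everything is grey")
    col <- stats::setNames(rep("grey", n), ids)
    return(structure(list(colours = col, sizes = c(grey = n),
                          eigengenes = NULL), class = "module_assignment"))
  }
  d <- stats::as.dist(1 - TOM)
  hc <- stats::hclust(d, method = "average")
  cl <- stats::cutree(hc, h = cut_height)
  sizes <- table(cl)
  small <- as.integer(names(sizes)[sizes < min_module_size])
  cl[cl %in% small] <- 0L
  # iterative eigengene merging
  repeat {
    mods <- setdiff(unique(cl), 0L)
    if (length(mods) < 2) break
    egs <- vapply(mods, function(mm)
      module_eigengene(expr[cl == mm, , drop = FALSE])$eigengene,
      numeric(ncol(expr)))
    ec <- stats::cor(egs)
    diag(ec) <- -Inf
    top <- which(ec == max(ec), arr.ind = TRUE)[1L, ]
    if (max(ec) <= 1 - merge_cut_height) break
    cl[cl == mods[top[2L]]] <- mods[top[1L]]
  }
  mods <- setdiff(unique(cl), 0L)
  ord <- mods[order(-tabulate(match(cl, mods)))]
  colour_of <- stats::setNames(module_palette[seq_along(ord)], ord)
  col <- ifelse(cl == 0L, "grey", colour_of[as.character(cl)])
  names(col) <- ids
  mods_col <- setdiff(unique(col), "grey")
  egs <- if (length(mods_col) > 0) {
    m <- vapply(mods_col, function(cc)
      module_eigengene(expr[col == cc, , drop = FALSE])$eigengene,
      numeric(ncol(expr)))
    colnames(m) <- mods_col
    m
  } else NULL
  structure(list(colours = col, sizes = sort(table(col), decreasing = TRUE),
                 eigengenes = egs),
            class = "module_assignment")
}

#' @export
print.module_assignment <- function(x, ...) {
  cat("module_assignment:", length(x$colours), "features in",
      sum(names(x$sizes) != "grey"), "modules (+ grey)\n")
  print(x$sizes)
  invisible(x)
}

#' Hypergeometric GO enrichment of module genes
#'
#' Upper-tail hypergeometric p of the overlap between each module's
#' gene-class members and each term, Bonferroni-corrected over all
#' module x term tests. HERV-class features are excluded from both the
#' modules and the universe: term inference rests on canonical genes only.
#'
#' @param assignment a `module_assignment` (grey excluded)
#' @param genesets named list of character vectors (e.g. from
#'   [read_gmt()])
#' @param background character vector: the gene universe (post-filter
#'   expressed gene-class features)
#' @param classes named class vector (`"gene"`/`"herv"`) for the
#'   assignment's features
#' @return data frame: module, term, overlap, module_genes, term_genes,
#'   p, bonf_p, enrichment_ratio
#' @export
go_enrich <- function(assignment, genesets, background, classes) {
  if (length(background) == 0) stop_config("empty background universe")
  bg <- unique(background[classes[background] == "gene"])
  N <- length(bg)
  mods <- setdiff(unique(assignment$colours), "grey")
  rows <- list()
  for (mm in mods) {
    members <- names(assignment$colours)[assignment$colours == mm]
    genes <- intersect(members, bg)
    if (length(genes) == 0) next
    for (tt in names(genesets)) {
      term <- intersect(genesets[[tt]], bg)
      k <- length(intersect(genes, term))
      p <- stats::phyper(k - 1, length(term), N - length(term),
                         length(genes), lower.tail = FALSE)
      expd <- length(term) * length(genes) / N
      rows[[paste(mm, tt)]] <- data.frame(
        module = mm, term = tt, overlap = k,
        module_genes = length(genes), term_genes = length(term),
        p = p, bonf_p = NA_real_,
        enrichment_ratio = if (expd > 0) k / expd else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) return(NULL)
  rownames(out) <- NULL
  out$bonf_p <- bonferroni_adjust(out$p, nrow(out))
  out
}

#' Per-module HERV/gene composition
#'
#' @param assignment a `module_assignment`
#' @param classes named class vector for the assignment's features
#' @return data frame: module, n_total, n_herv, n_gene, pct_herv, pct_gene
#' @export
module_composition <- function(assignment, classes) {
  mods <- names(assignment$sizes)
  rows <- lapply(mods, function(mm) {
    members <- names(assignment$colours)[assignment$colours == mm]
    nh <- sum(classes[members] == "herv")
    ng <- sum(classes[members] == "gene")
    data.frame(module = mm, n_total = length(members), n_herv = nh,
               n_gene = ng, pct_herv = fraction_pct(nh, length(members)),
               pct_gene = fraction_pct(ng, length(members)),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
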