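# Locus-resolved quantification of repeat-element expression: Bayesian EM
# reassignment of ambiguously mapped fragments to their most probable
# source locus, in the style of Telescope-class quantifiers.

#' Construct an alignment set
#'
#' Holds candidate alignments per fragment (long format) plus the ordered
#' feature index. A reserved "no-feature" slot is appended at EM time to
#' absorb off-target fragments.
#'
#' @param hits data frame with columns `fragment_id`, `feature_id`, `score`
#' @param feature_index ordered character vector of feature ids (K features)
#' @return object of class `alignment_set`
#' @export
alignment_set <- function(hits, feature_index) {
  stopifnot(all(c("fragment_id", "feature_id", "score") %in% names(hits)))
  if (!all(is.finite(hits$score))) stop_config("alignment scores must be finite")
  if (!all(hits$feature_id %in% feature_index)) {
    stop_config("hits reference features absent from the feature index")
  }
  structure(list(hits = hits, feature_index = as.character(feature_index)),
            class = "alignment_set")
}

#' @export
print.alignment_set <- function(x, ...) {
  nf <- length(unique(x$hits$fragment_id))
  cat("alignment_set:", nf, "fragments,", nrow(x$hits), "candidate hits,",
      length(x$feature_index), "features\n")
  invisible(x)
}

#' EM reassignment of ambiguously mapped fragments
#'
#' Mixture model over source features: the E-step sets
#' P(source = j | fragment i) proportional to pi_j * exp(score_ij /
#' score_scale) over the fragment's candidates (plus the no-feature slot);
#' the MAP M-step is pi_j = (sum_i p_ij + alpha) / (N + K * alpha) with a
#' symmetric Dirichlet prior of strength `prior_strength` over all K
#' categories (features plus the no-feature slot). Iterates until the
#' log-posterior change drops below `tol`.
#'
#' @param alignments an [alignment_set()]
#' @param prior_strength Dirichlet prior strength alpha per category (>= 0)
#' @param score_scale softmax temperature mapping alignment scores to
#'   likelihoods via exp(score / score_scale)
#' @param tol convergence tolerance on the log-posterior change
#' @param max_iter iteration cap; hitting it returns `converged = FALSE`
#'   with a warning
#' @param nofeature_score pseudo-score of the reserved no-feature slot;
#'   default is the minimum candidate score minus 2 * score_scale
#' @return object of class `abundance_estimate` with elements `pi`
#'   (simplex over features + `"__nofeature__"`), `posteriors` (long data
#'   frame matching the candidate hits plus no-feature rows), `loglik_trace`
#'   (log-posterior per iteration, non-decreasing), `n_iter`, `converged`,
#'   `n_fragments`, `n_ambiguous`
#' @export
em_reassign <- function(alignments, prior_strength = 1e-3, score_scale = 20,
                        tol = 1e-6, max_iter = 200L,
                        nofeature_score = NULL) {
  stopifnot(inherits(alignments, "alignment_set"))
  if (tol <= 0) stop_config("tol must be positive")
  if (score_scale <= 0) stop_config("score_scale must be positive")
  if (prior_strength < 0) stop_config("prior_strength must be non-negative")
  hits <- alignments$hits
  feats <- alignments$feature_index
  if (nrow(hits) == 0) stop_config("no candidate alignments supplied")
  frag_ids <- unique(hits$fragment_id)
  N <- length(frag_ids)
  nofeature_score <- nofeature_score %||% (min(hits$score) - 2 * score_scale)
  nofeat <- "__nofeature__"
  cats <- c(feats, nofeat)
  Kc <- length(cats)

  frag <- match(hits$fragment_id, frag_ids)
  feat <- match(hits$feature_id, feats)
  # append the no-feature candidate for every fragment
  frag <- c(frag, seq_len(N))
  feat <- c(feat, rep(Kc, N))
  score <- c(hits$score, rep(nofeature_score, N))
  # likelihood weights, rescaled within fragment for numerical head-room
  lw <- score / score_scale
  mx <- tapply(lw, frag, max)[as.character(frag)]
  w <- exp(lw - as.numeric(mx))
  log_rescale <- sum(as.numeric(tapply(lw, frag, max)))

  n_cand <- tabulate(frag, N)     # includes the no-feature candidate
  n_ambiguous <- sum(n_cand > 2L) # >1 genuine candidate

  pi <- rep(1 / Kc, Kc)
  trace <- numeric(0)
  log_prior <- function(pi) sum(prior_strength * log(pmax(pi, 1e-300)))
  converged <- FALSE
  post <- NULL
  for (it in seq_len(max_iter)) {
    num <- pi[feat] * w
    denom <- rowsum(num, frag)[, 1L]
    post <- num / denom[frag]
    lp <- sum(log(denom)) + log_rescale + log_prior(pi)
    trace <- c(trace, lp)
    if (it > 1 && abs(lp - trace[it - 1L]) < tol) { converged <- TRUE; break }
    cnt <- rep(0, Kc)
    agg <- rowsum(post, feat)
    cnt[as.integer(rownames(agg))] <- agg[, 1L]
    pi <- (cnt + prior_strength) / (N + Kc * prior_strength)
  }
  if (!converged) warning("EM hit max_iter without meeting tol; returning last estimate")
  names(pi) <- cats
  posteriors <- data.frame(fragment_id = frag_ids[frag],
                           feature_id = cats[feat],
                           posterior = post, stringsAsFactors = FALSE)
  structure(list(pi = pi, posteriors = posteriors, loglik_trace = trace,
                 n_iter = length(trace), converged = converged,
                 n_fragments = N, n_ambiguous = n_ambiguous,
                 feature_index = feats, prior_strength = prior_strength,
                 score_scale = score_scale),
            class = "abundance_estimate")
}

#' @export
print.abundance_estimate <- function(x, ...) {
  cat("abundance_estimate:", x$n_fragments, "fragments,",
      length(x$feature_index), "features;",
      x$n_iter, "EM iterations,",
      if (x$converged) "converged" else "NOT converged", "\n")
  invisible(x)
}

#' Materialize per-feature fragment counts from an abundance estimate
#'
#' @param est an `abundance_estimate` from [em_reassign()]
#' @param mode `"best"` assigns each fragment once to its argmax-posterior
#'   feature (ties broken toward the lowest feature index and tallied in the
#'   `n_ties` attribute); `"fractional"` sums posterior mass; `"unique"`
#'   counts only fragments with a single genuine candidate. Fragments won by
#'   the no-feature slot are not counted, so counts sum to at most the
#'   number of fragments.
#' @return named numeric vector of per-feature counts (over the K features;
#'   the no-feature slot is excluded)
#' @export
assign_counts <- function(est, mode = c("best", "fractional", "unique")) {
  mode <- match.arg(mode)
  if (!est$converged) {
    warning("abundance estimate had not converged; counts reflect the last iterate")
  }
  feats <- est$feature_index
  po <- est$posteriors
  cats <- c(feats, "__nofeature__")
  fi <- match(po$feature_id, cats)
  counts <- stats::setNames(rep(0, length(feats)), feats)
  if (mode == "fractional") {
    agg <- rowsum(po$posterior, po$feature_id)
    keep <- intersect(rownames(agg), feats)
    counts[keep] <- agg[keep, 1L]
    return(counts)
  }
  sp <- split(seq_len(nrow(po)), po$fragment_id)
  n_ties <- 0L
  if (mode == "best") {
    for (rows in sp) {
      p <- po$posterior[rows]
      top <- rows[abs(p - max(p)) < 1e-12]
      if (length(top) > 1L) {
        n_ties <- n_ties + 1L
        top <- top[which.min(fi[top])]  # lowest feature index wins
      }
      j <- fi[top]
      if (j <= length(feats)) counts[j] <- counts[j] + 1
    }
    attr(counts, "n_ties") <- n_ties
    return(counts)
  }
  # unique: fragments whose only genuine candidate is one feature
  for (rows in sp) {
    genuine <- rows[fi[rows] <= length(feats)]
    if (length(genuine) == 1L) {
      j <- fi[genuine]
      counts[j] <- counts[j] + 1
    }
  }
  counts
}

#' Quantification run report
#'
#' @param est an `abundance_estimate`
#' @return one-row data frame: fragments, ambiguous fragments, iterations,
#'   final log-posterior, convergence flag
#' @export
quant_report <- function(est) {
  data.frame(n_fragments = est$n_fragments, n_ambiguous = est$n_ambiguous,
             n_iter = est$n_iter,
             final_log_posterior = est$loglik_trace[length(est$loglik_trace)],
             converged = est$converged)
}
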