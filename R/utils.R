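# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a fixed RNG seed
#'
#' Restores the caller's RNG state afterwards, so generator functions are
#' deterministic without clobbering the session stream.
#' @noRd
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(as.integer(seed))
  force(expr)
}

stop_config <- function(...) stop(..., call. = FALSE)

#' Column-standardize a matrix, dropping nothing
#'
#' Constant columns get zero (not NaN) output; callers that must drop them
#' do so explicitly. Returns centers/scales as attributes for refitting.
#' @noRd
standardize_cols <- function(X, center = NULL, scale_ = NULL) {
  center <- center %||% colMeans(X)
  Xc <- sweep(X, 2L, center, "-")
  scale_ <- scale_ %||% sqrt(colSums(Xc^2) / max(1, nrow(X) - 1L))
  ok <- scale_ > .Machine$double.eps
  Xs <- sweep(Xc, 2L, ifelse(ok, scale_, 1), "/")
  Xs[, !ok] <- 0
  attr(Xs, "center") <- center
  attr(Xs, "scale") <- scale_
  attr(Xs, "constant") <- !ok
  Xs
}

#' Log-density of a mean-zero multivariate normal via Cholesky
#' @noRd
dmvnorm0_log <- function(z, V) {
  ch <- tryCatch(chol(V), error = function(e) chol(V + diag(1e-8, nrow(V))))
  u <- backsolve(ch, z, transpose = TRUE)
  -0.5 * (length(z) * log(2 * pi) + 2 * sum(log(diag(ch))) + sum(u^2))
}

#' Standard normal bivariate CDF P(Z1 < h, Z2 < k) with correlation r
#'
#' One-dimensional Gauss-Legendre reduction; smooth for all |r| < 1.
#' @noRd
pbvnorm <- function(h, k, r) {
  if (abs(r) >= 1) r <- sign(r) * (1 - 1e-12)
  # 64-point Gauss-Legendre on [-8, h]
  gl <- gauss_legendre_64()
  a <- -8
  if (h <= a) return(0)
  mid <- (h + a) / 2
  half <- (h - a) / 2
  z <- mid + half * gl$nodes
  vals <- stats::dnorm(z) * stats::pnorm((k - r * z) / sqrt(1 - r^2))
  half * sum(gl$weights * vals)
}

gauss_legendre_64 <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    # Golub-Welsch from the Jacobi matrix of Legendre polynomials
    n <- 64L
    i <- seq_len(n - 1L)
    b <- i / sqrt(4 * i^2 - 1)
    J <- matrix(0, n, n)
    J[cbind(i, i + 1L)] <- b
    J[cbind(i + 1L, i)] <- b
    e <- eigen(J, symmetric = TRUE)
    cache <<- list(nodes = rev(e$values), weights = rev(2 * e$vectors[1L, ]^2))
    cache
  }
})

#' Latent Gaussian correlation whose thresholded-binary correlation equals rho
#'
#' Thresholds t1 = qnorm(p1), t2 = qnorm(p2). Returns the capped maximum
#' when the target is infeasible for the given margins.
#' @noRd
tetrachoric_latent_r <- function(rho, p1, p2) {
  if (rho <= 0) return(rho)
  t1 <- stats::qnorm(p1); t2 <- stats::qnorm(p2)
  s1 <- sqrt(p1 * (1 - p1)); s2 <- sqrt(p2 * (1 - p2))
  fn <- function(r) (pbvnorm(t1, t2, r) - p1 * p2) / (s1 * s2) - rho
  hi <- 1 - 1e-7
  if (fn(hi) < 0) return(hi)  # target infeasible for these margins; cap
  stats::uniroot(fn, c(0, hi), tol = 1e-9)$root
}

#' Round a ratio to integer percent, as printed in study reports
#'
#' @param a numerator count
#' @param b denominator count
#' @return `round(100 * a / b)` as an integer; `NA` if `b` is zero.
#' @export
fraction_pct <- function(a, b) {
  if (length(b) != length(a) && length(b) != 1L) stop("a and b must be conformable")
  out <- ifelse(b == 0, NA_real_, round(100 * a / b))
  as.integer(out)
}

#' Integer-rounded percent change between two counts
#'
#' @param a first count (e.g. before)
#' @param b second count (e.g. after)
#' @param denom which count the change is expressed relative to
#' @return `round(100 * (b - a) / denom)` as an integer.
#' @export
percent_change <- function(a, b, denom = c("a", "b")) {
  denom <- match.arg(denom)
  d <- if (denom == "a") a else b
  if (d == 0) return(NA_integer_)
  as.integer(round(100 * (b - a) / d))
}
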