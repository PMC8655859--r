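#' Estimate surrogate variables protecting the primary outcome
#'
#' Iteratively reweighted surrogate variable estimation. The data are first
#' residualized on the full model (which contains the primary variable), and
#' the top right-singular vectors of the residual matrix serve as initial
#' candidate surrogate variables. Each iteration then (1) computes, per
#' probe, a p-value of association with the candidate surrogate variables
#' given the full model and a p-value of association with the primary
#' variable, (2) converts both to empirical posterior probabilities through a
#' density-based local false discovery rate, (3) weights each probe by the
#' probability that it is associated with the surrogate variables but not
#' with the primary variable, and (4) recomputes the singular value
#' decomposition of the row-weighted centered data matrix. Down-weighting
#' primary-associated probes protects the outcome-methylation relationship
#' while still letting surrogate variables absorb confounder-outcome overlap.
#'
#' @param y Probe-by-sample matrix (beta or M values).
#' @param design Full model matrix (samples x terms) including the primary
#'   variable.
#' @param design0 Null model matrix without the primary variable (default:
#'   intercept only).
#' @param k_max Number of candidate surrogate variables to return.
#' @param iterations Reweighting iterations (default 5).
#' @return List of class `surrogate_set`: `sv` (sample-by-k score matrix,
#'   orthonormal columns), `singular_values`, `probe_weights`, `iterations`,
#'   `k_max`.
#' @export
estimate_svs <- function(y, design, design0 = NULL, k_max = 10, iterations = 5) {
  n <- ncol(y)
  if (k_max <= 0) stop2("k_max must be positive")
  if (is.null(design0)) design0 <- matrix(1, n, 1)
  design <- as.matrix(design); design0 <- as.matrix(design0)
  if (nrow(design) != n) stop2("design rows must match samples")
  if (k_max >= n - qr(design)$rank) stop2("k_max must be below residual degrees of freedom")
  keep <- apply(y, 1L, stats::sd) > 0
  if (!all(keep)) {
    warning(sum(!keep), " constant probe(s) dropped before surrogate variable estimation")
    y <- y[keep, , drop = FALSE]
  }

  H <- design %*% solve(crossprod(design), t(design))
  resid <- y - y %*% H
  sv <- svd(resid, nu = 0)$v[, seq_len(k_max), drop = FALSE]
  d <- rep(NA_real_, k_max)
  pw <- rep(1, nrow(y))
  for (it in seq_len(iterations)) {
    p_sv <- f_pvalues(y, cbind(design0, sv), design0)
    p_prim <- f_pvalues(y, cbind(design, sv), cbind(design0, sv))
    prob_sv <- 1 - edge_lfdr(p_sv)      # P(associated with the candidate SVs)
    prob_not_prim <- edge_lfdr(p_prim)  # P(no primary association given the SVs)
    pw <- prob_sv * prob_not_prim
    wdat <- y * pw
    wdat <- wdat - rowMeans(wdat)
    s <- svd(wdat, nu = 0)
    sv <- s$v[, seq_len(k_max), drop = FALSE]
    d <- s$d[seq_len(k_max)]
  }
  colnames(sv) <- paste0("SV", seq_len(k_max))
  structure(list(sv = sv, singular_values = d, probe_weights = pw,
                 iterations = iterations, k_max = k_max),
            class = "surrogate_set")
}

# Per-probe F-test p-values comparing nested linear models, vectorized.
f_pvalues <- function(y, mod, mod0) {
  n <- ncol(y)
  q1 <- qr(mod); q0 <- qr(mod0)
  df1 <- q1$rank; df0 <- q0$rank
  H1 <- tcrossprod(qr.Q(q1)[, seq_len(df1), drop = FALSE])
  H0 <- tcrossprod(qr.Q(q0)[, seq_len(df0), drop = FALSE])
  rss1 <- rowSums((y - y %*% H1)^2)
  rss0 <- rowSums((y - y %*% H0)^2)
  fstat <- ((rss0 - rss1) / (df1 - df0)) / (rss1 / (n - df1))
  fstat[rss1 <= 0] <- Inf
  p <- stats::pf(fstat, df1 - df0, n - df1, lower.tail = FALSE)
  pmin(pmax(p, .Machine$double.xmin), 1)
}

# Density-based local FDR of a p-value vector (logit-kernel estimate with a
# conservative pi0 from the upper tail); values in [0,1], monotone in p.
edge_lfdr <- function(p, lambda = 0.8, adjust = 1.5, eps = 1e-8) {
  pi0 <- mean(p >= lambda) / (1 - lambda)
  pi0 <- min(max(pi0, 1e-3), 1)
  x <- log((p + eps) / (1 - p + eps))
  dens <- stats::density(x, adjust = adjust)
  fit <- stats::smooth.spline(dens$x, dens$y)
  y <- pmax(stats::predict(fit, x)$y, 1e-12)
  dx <- exp(x) / (1 + exp(x))^2          # dp/dx, converts density scales
  lfdr <- pi0 * dx / y
  lfdr <- pmin(lfdr, 1)
  o <- order(p)
  lfdr[o] <- cummax(lfdr[o])
  pmin(lfdr, 1)
}

#' Choose the number of surrogate variables by inflation lambda
#'
#' For k = 0..k_max fits the site-wise association model with the first k
#' surrogate variables and computes the genomic inflation factor
#' \eqn{\lambda(k)} of the primary-variable p-values. Selected is the
#' smallest k whose \eqn{|\lambda(k) - 1|} comes within `tol` of the best
#' achieved value, i.e. the model closest to a lambda of 1.0 with preference
#' for fewer surrogate variables when several models are comparably
#' calibrated (exact ties always resolve to the smaller k).
#'
#' @param y Probe-by-sample matrix.
#' @param design Full model matrix including the primary variable.
#' @param design0 Null model without the primary variable.
#' @param svs `surrogate_set` from [estimate_svs()] (or a bare score matrix).
#' @param k_max Largest k to consider (default: all available columns).
#' @param ewas_fn Function `(y, design, design0) -> p-values`; the default
#'   uses the nested-model F-test, which for a single-column primary term is
#'   the two-sided t-test of that coefficient.
#' @param tol Calibration band: models whose `|lambda - 1|` lies within `tol`
#'   of the minimum count as equally calibrated and the smallest such k wins.
#' @return List with `k_selected` and `lambda_by_k` (named vector, k = 0..k_max).
#' @export
select_k_by_lambda <- function(y, design, design0, svs, k_max = NULL,
                               ewas_fn = f_pvalues, tol = 0.1) {
  sv <- if (inherits(svs, "surrogate_set")) svs$sv else as.matrix(svs)
  if (is.null(k_max)) k_max <- ncol(sv)
  k_max <- min(k_max, ncol(sv))
  lambdas <- vapply(0:k_max, function(k) {
    extra <- if (k > 0) sv[, seq_len(k), drop = FALSE] else NULL
    p <- ewas_fn(y, cbind(design, extra), cbind(design0, extra))
    if (all(is.na(p))) stop2("all p-values missing at k = ", k)
    inflation_lambda(p)
  }, numeric(1))
  names(lambdas) <- paste0("k", 0:k_max)
  dev <- abs(lambdas - 1)
  k_selected <- (0:k_max)[which(dev <= min(dev) + tol)[1]]
  list(k_selected = k_selected, lambda_by_k = lambdas)
}
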