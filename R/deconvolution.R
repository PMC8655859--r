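#' Select cell-type-discriminating probes from a full reference
#'
#' For each cell type computes the one-vs-rest mean beta difference and keeps
#' the `per_type` most hypermethylated and `per_type` most hypomethylated
#' probes; the returned probe list is the union over cell types. Ties are
#' broken by probe id (lexicographic), so selection is deterministic.
#'
#' @param reference_full Cell-type-by-probe beta matrix.
#' @param per_type Probes to keep per cell type and direction.
#' @param min_contrast Minimum absolute one-vs-rest difference for a probe to
#'   qualify; if no probe qualifies for any type an error is raised.
#' @return Character vector of probe ids.
#' @export
select_discriminating_probes <- function(reference_full, per_type = 50,
                                         min_contrast = 0) {
  if (per_type < 1) stop2("per_type must be at least 1")
  K <- nrow(reference_full)
  if (K < 2L) stop2("need at least 2 cell types")
  probes <- colnames(reference_full)
  if (is.null(probes)) stop2("reference needs probe ids as column names")
  sel <- character(0)
  any_contrast <- FALSE
  for (k in seq_len(K)) {
    d <- reference_full[k, ] - colMeans(reference_full[-k, , drop = FALSE])
    ord_hi <- order(-d, probes)
    ord_lo <- order(d, probes)
    hi <- ord_hi[seq_len(min(per_type, length(d)))]
    lo <- ord_lo[seq_len(min(per_type, length(d)))]
    hi <- hi[d[hi] > min_contrast]
    lo <- lo[d[lo] < -min_contrast]
    if (length(hi) || length(lo)) any_contrast <- TRUE
    sel <- c(sel, probes[hi], probes[lo])
  }
  if (!any_contrast) stop2("no discriminating probes: cell-type profiles are identical")
  if (2 * per_type >= ncol(reference_full)) {
    warning("per_type exceeds available probes; returning all probes")
    return(probes)
  }
  sort(unique(sel))
}

#' Estimate cell-type proportions by constrained projection
#'
#' For each sample solves the nonnegative least-squares problem
#' \deqn{\hat w = \arg\min_w \|y - R^\top w\|^2 \quad \text{s.t. } w \ge 0,\
#'   \textstyle\sum_k w_k \le 1,} where `R` holds the reference profiles at
#' the panel probes. The sum constraint is handled by augmenting the design
#' with a slack column and a heavily weighted sum-to-one row, then running an
#' active-set nonnegative least-squares solve; the procedure is deterministic
#' (no random starts). Raw constrained estimates are returned without
#' renormalization.
#'
#' @param b Beta matrix with the panel probes among its rows.
#' @param ref List with `profiles` (cell-type-by-probe betas), e.g. from
#'   [make_reference_panel()], or a bare profile matrix.
#' @return Sample-by-cell-type matrix of proportions.
#' @export
estimate_proportions <- function(b, ref) {
  profiles <- if (is.list(ref)) ref$profiles else ref
  probes <- colnames(profiles)
  missing <- setdiff(probes, rownames(b))
  if (length(missing)) stop2("reference probes absent from beta matrix: ",
                             paste(utils::head(missing, 5), collapse = ", "))
  A <- t(profiles[, probes, drop = FALSE])           # probes x cell types
  K <- ncol(A)
  if (qr(A)$rank < K) {
    cc <- stats::cor(A)
    pairs <- which(abs(cc) > 0.9999 & upper.tri(cc), arr.ind = TRUE)
    coll <- if (nrow(pairs)) paste(rownames(cc)[pairs[, 1]], colnames(cc)[pairs[, 2]],
                                   sep = "~", collapse = ", ") else "unknown"
    stop2("reference is rank-deficient; collinear cell types: ", coll)
  }
  big <- 1e4 * max(abs(A))
  A_aug <- rbind(cbind(A, 0), c(rep(big, K), big))   # slack column + sum row
  Y <- b[probes, , drop = FALSE]
  W <- t(apply(Y, 2L, function(y) nnls_solve(A_aug, c(y, big))[seq_len(K)]))
  dimnames(W) <- list(colnames(b), rownames(profiles))
  W
}

# Lawson-Hanson active-set nonnegative least squares: min ||Ax - b||, x >= 0.
nnls_solve <- function(A, b, tol = NULL) {
  n <- ncol(A)
  x <- numeric(n)
  passive <- logical(n)
  w <- crossprod(A, b - A %*% x)
  if (is.null(tol)) tol <- 10 * .Machine$double.eps * sum(abs(A)) * max(dim(A))
  iter <- 0L
  while (any(!passive) && any(w[!passive] > tol) && iter < 30L * n) {
    iter <- iter + 1L
    j <- which(!passive)[which.max(w[!passive])]
    passive[j] <- TRUE
    repeat {
      z <- numeric(n)
      P <- which(passive)
      z[P] <- qr.coef(qr(A[, P, drop = FALSE]), b)
      z[P][is.na(z[P])] <- 0
      if (all(z[P] > tol)) { x <- z; break }
      neg <- P[z[P] <= tol]
      alpha <- min(x[neg] / (x[neg] - z[neg]))
      x <- x + alpha * (z - x)
      passive[P][x[P] <= tol] <- FALSE
      x[!passive] <- 0
    }
    w <- crossprod(A, b - A %*% x)
  }
  pmax(x, 0)
}
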