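#' Site-wise association of methylation with diagnosis
#'
#' Fits, at every probe, the ordinary least squares model
#' `methylation ~ intercept + group + adjustment terms` for the requested
#' pairwise contrast (the excluded third diagnostic group is dropped from
#' the fit, not dummy-coded), then applies empirical-Bayes variance
#' moderation to the per-probe residual variances. Effects are reported as
#' differences in percent methylation (coefficient x 100 on the beta scale;
#' on the M-value scale the coefficient is reported unscaled).
#'
#' @param y Probe-by-sample matrix (beta values, or M-values with
#'   `scale = "M"`).
#' @param sheet Sample sheet with `sample_id` and `outcome`.
#' @param adjustment Either a `surrogate_set`, a numeric sample-by-k matrix
#'   of covariate scores aligned to `colnames(y)`, a character vector of
#'   sheet column names (known-covariate model), or `NULL`.
#' @param contrast `"ASD-vs-TD"` or `"nonTD-vs-TD"`; the first level named is
#'   the case group, TD the reference.
#' @param scale `"beta"` (effects x 100) or `"M"`.
#' @param moderate Apply empirical-Bayes moderation (default `TRUE`).
#' @return `data.frame` with columns `probe_id`, `mean_percent`,
#'   `effect_percent`, `se_percent`, `t_moderated`, `p_value`, `fdr_q`,
#'   `n_used`; the moderation hyperparameters are attached as
#'   `attr(, "moderation")` and the contrast as `attr(, "contrast")`.
#' @export
fit_sitewise <- function(y, sheet, adjustment = NULL,
                         contrast = c("ASD-vs-TD", "nonTD-vs-TD"),
                         scale = c("beta", "M"), moderate = TRUE) {
  contrast <- match.arg(contrast)
  scale <- match.arg(scale)
  sheet <- validate_sample_sheet(sheet)
  case <- if (contrast == "ASD-vs-TD") "ASD" else "nonTD"

  sheet <- sheet[match(colnames(y), sheet$sample_id), ]
  in_contrast <- sheet$outcome %in% c(case, "TD")

  adj <- NULL
  if (!is.null(adjustment)) {
    if (inherits(adjustment, "surrogate_set")) {
      adj <- adjustment$sv
    } else if (is.character(adjustment)) {
      miss <- setdiff(adjustment, colnames(sheet))
      if (length(miss)) stop2("adjustment columns not in sheet: ", paste(miss, collapse = ", "))
      d <- as.data.frame(sheet[, adjustment, drop = FALSE])
      cc <- stats::complete.cases(d)
      mm <- stats::model.matrix(~ ., data = d[cc, , drop = FALSE])[, -1, drop = FALSE]
      # samples with missing covariates are dropped from this model (complete case)
      adj <- matrix(NA_real_, nrow(sheet), ncol(mm), dimnames = list(NULL, colnames(mm)))
      adj[cc, ] <- mm
    } else {
      adj <- as.matrix(adjustment)
      if (nrow(adj) != ncol(y)) stop2("adjustment matrix rows must match samples")
    }
  }
  complete <- in_contrast & (if (is.null(adj)) TRUE else stats::complete.cases(adj))
  if (sum(complete) < 3L) stop2("fewer than 3 usable samples for contrast ", contrast)

  yy <- y[, complete, drop = FALSE]
  grp <- as.numeric(sheet$outcome[complete] == case)
  X <- cbind(`(Intercept)` = 1, group = grp)
  if (!is.null(adj)) X <- cbind(X, adj[complete, , drop = FALSE])
  qX <- qr(X)
  if (qX$rank < ncol(X)) {
    aliased <- colnames(X)[qX$pivot[seq(qX$rank + 1L, ncol(X))]]
    stop2("design is rank-deficient; aliased terms: ", paste(aliased, collapse = ", "))
  }
  n <- nrow(X)
  df_resid <- n - ncol(X)
  if (df_resid < 1L) stop2("no residual degrees of freedom")

  XtXi <- chol2inv(chol(crossprod(X)))
  dimnames(XtXi) <- list(colnames(X), colnames(X))
  coefs <- yy %*% X %*% XtXi                 # probes x terms
  fitted <- coefs %*% t(X)
  rss <- rowSums((yy - fitted)^2)
  s2 <- rss / df_resid
  u_g <- sqrt(XtXi["group", "group"])        # unscaled SE of the group coefficient
  beta_g <- coefs[, "group"]

  if (moderate) {
    mod <- moderate_variances(s2, rep(df_resid, length(s2)))
    se <- u_g * sqrt(mod$post_var)
    tstat <- beta_g / se
    df_total <- mod$d0 + df_resid
  } else {
    mod <- list(d0 = 0, s0_sq = NA_real_, post_var = s2)
    se <- u_g * sqrt(s2)
    tstat <- beta_g / se
    df_total <- df_resid
  }
  tstat[se == 0] <- 0
  p <- 2 * stats::pt(-abs(tstat), df = df_total)
  p[!is.finite(p)] <- NA_real_

  mult <- if (scale == "beta") 100 else 1
  res <- data.frame(
    probe_id = rownames(y),
    mean_percent = rowMeans(yy) * mult,
    effect_percent = beta_g * mult,
    se_percent = se * mult,
    t_moderated = tstat,
    p_value = p,
    fdr_q = bh_fdr(p),
    n_used = n,
    stringsAsFactors = FALSE
  )
  attr(res, "moderation") <- mod[c("d0", "s0_sq")]
  attr(res, "contrast") <- contrast
  attr(res, "scale") <- scale
  res
}

#' Empirical-Bayes moderation of per-probe variances
#'
#' Fits a scaled inverse-chi-square prior with df `d0` and scale `s0^2` to
#' the observed residual variances by matching the moments of `log(s^2)`
#' (digamma/trigamma relations for the log of a scaled F variate), then
#' forms posterior variances \deqn{\tilde s^2_j = (d_0 s_0^2 + d_j s_j^2) /
#' (d_0 + d_j).} With homogeneous variances the estimated `d0` is infinite
#' and every posterior variance equals the common value.
#'
#' @param s2 Per-probe residual variances.
#' @param dfs Per-probe residual degrees of freedom.
#' @return List with `d0`, `s0_sq` and `post_var` (same length as `s2`;
#'   non-finite or zero input variances keep their ordinary value and are
#'   excluded from hyperparameter estimation).
#' @export
moderate_variances <- function(s2, dfs) {
  if (length(dfs) == 1L) dfs <- rep(dfs, length(s2))
  ok <- is.finite(s2) & s2 > 0 & dfs > 0
  if (sum(ok) < 2L) stop2("need at least 2 positive finite variances")
  z <- log(s2[ok])
  d <- dfs[ok]
  e <- z - digamma(d / 2) + log(d / 2)
  emean <- mean(e)
  evar <- stats::var(e) - mean(trigamma(d / 2))
  if (is.finite(evar) && evar > 0) {
    d0 <- 2 * trigamma_inverse(evar)
    s0_sq <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
  } else {
    # homogeneous variances: point-mass prior at the common value
    d0 <- Inf
    s0_sq <- mean(s2[ok])
  }
  post <- s2
  if (is.finite(d0)) {
    post[ok] <- (d0 * s0_sq + dfs[ok] * s2[ok]) / (d0 + dfs[ok])
  } else {
    post[ok] <- s0_sq
  }
  list(d0 = d0, s0_sq = s0_sq, post_var = post)
}

#' Summarize a site-wise result table
#'
#' Counts probes below the nominal p-value cut, the share of those with
#' higher methylation in cases (hypermethylated), and returns a volcano-plot
#' table of effect size against -log10 p.
#'
#' @param res Result table from [fit_sitewise()].
#' @param p_cut Nominal p-value threshold (default 0.05).
#' @return List with `n_total`, `n_nominal`, `pct_hyper`, `pct_hypo` and
#'   `volcano` (data frame `effect_percent`, `neg_log10_p`).
#' @export
summarize_ewas <- function(res, p_cut = 0.05) {
  if (!nrow(res)) stop2("empty result table")
  nom <- !is.na(res$p_value) & res$p_value < p_cut
  hyper <- res$effect_percent[nom] > 0
  list(
    n_total = nrow(res),
    n_nominal = sum(nom),
    pct_hyper = if (any(nom)) 100 * mean(hyper) else NA_real_,
    pct_hypo = if (any(nom)) 100 * mean(!hyper) else NA_real_,
    volcano = data.frame(probe_id = res$probe_id,
                         effect_percent = res$effect_percent,
                         neg_log10_p = -log10(res$p_value))
  )
}

#' Pearson correlation of effect estimates between two result tables
#'
#' @param res_a,res_b Result tables from [fit_sitewise()] (or any data frames
#'   with `probe_id` and `effect_percent`).
#' @return Pearson correlation over the shared probes.
#' @export
cross_model_correlation <- function(res_a, res_b) {
  shared <- intersect(res_a$probe_id, res_b$probe_id)
  if (length(shared) < 2L) stop2("fewer than 2 shared probes")
  a <- res_a$effect_percent[match(shared, res_a$probe_id)]
  b <- res_b$effect_percent[match(shared, res_b$probe_id)]
  stats::cor(a, b, use = "complete.obs")
}
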