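#' Pearson chi-square test of independence
#'
#' Classic contingency-table test with expected counts
#' \eqn{E_{ij} = r_i c_j / N} and statistic \eqn{\sum (O-E)^2/E}. No
#' continuity correction is applied by default (2x2 tables included), which
#' reproduces printed cohort-table and enrichment p-values.
#'
#' @param counts Nonnegative integer matrix, at least 2x2.
#' @param continuity Apply the Yates correction on 2x2 tables.
#' @return List with `chi2`, `df`, `p_value` and `expected`.
#' @export
chi_square_test <- function(counts, continuity = FALSE) {
  counts <- as.matrix(counts)
  if (nrow(counts) < 2L || ncol(counts) < 2L) stop2("table must be at least 2x2")
  if (any(counts < 0)) stop2("counts must be nonnegative")
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0)) {
    stop2("table has a zero margin")
  }
  res <- suppressWarnings(stats::chisq.test(counts, correct = continuity))
  list(chi2 = unname(res$statistic), df = unname(res$parameter),
       p_value = unname(res$p.value), expected = res$expected)
}

#' Linear trend test across ordered groups
#'
#' For a categorical/binary variable, the linear-by-linear association
#' statistic \eqn{(n-1) r^2} (with `r` the Pearson correlation between group
#' scores and numeric variable codes) referred to chi-square with 1 df; for a
#' continuous variable, the t-test of the slope in a regression of the value
#' on the group score.
#'
#' @param group_scores Numeric ordinal codes per observation (e.g. 0/1/2 for
#'   TD/nonTD/ASD).
#' @param variable Values per observation (numeric, factor or character).
#' @return List with `statistic`, `p_value` and `type`.
#' @export
trend_test <- function(group_scores, variable) {
  keep <- !is.na(group_scores) & !is.na(variable)
  gs <- group_scores[keep]
  v <- variable[keep]
  if (length(unique(gs)) < 2L) stop2("need at least 2 groups with scores")
  continuous <- is.numeric(v) && length(unique(v)) > 6L
  if (continuous) {
    if (stats::sd(v) == 0) return(list(statistic = 0, p_value = 1, type = "continuous"))
    fit <- summary(stats::lm(v ~ gs))$coefficients
    list(statistic = fit["gs", "t value"], p_value = fit["gs", "Pr(>|t|)"],
         type = "continuous")
  } else {
    codes <- if (is.numeric(v)) v else as.numeric(factor(v))
    if (stats::sd(codes) == 0) return(list(statistic = 0, p_value = 1, type = "ordinal"))
    n <- length(codes)
    r <- stats::cor(gs, codes)
    stat <- (n - 1) * r^2
    list(statistic = stat,
         p_value = stats::pchisq(stat, 1, lower.tail = FALSE),
         type = "ordinal")
  }
}

#' Benjamini-Hochberg false discovery rate
#'
#' Step-up BH q-values: \eqn{q_{(i)} = \min_{j \ge i} m p_{(j)} / j}, clipped
#' at 1 and returned in input order. Missing p-values propagate as missing.
#'
#' @param p Vector of p-values in (0, 1\].
#' @return q-values, same length and order.
#' @export
bh_fdr <- function(p) {
  if (any(p <= 0 | p > 1, na.rm = TRUE)) stop2("p-values must lie in (0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Genomic inflation factor lambda
#'
#' \eqn{\lambda = \mathrm{median}(\chi^2_1\text{-quantile of } 1-p) / 0.4549364},
#' the ratio of the observed median association chi-square to its null
#' median; 1.0 indicates calibrated tests.
#'
#' @param p Vector of two-sided p-values (at least 100 for stability).
#' @return Lambda (scalar).
#' @export
inflation_lambda <- function(p) {
  p <- p[is.finite(p)]
  if (length(p) < 100L) warning("fewer than 100 p-values; lambda is unstable")
  chi <- stats::qchisq(p, df = 1, lower.tail = FALSE)
  chi <- chi[is.finite(chi)]
  stats::median(chi) / stats::qchisq(0.5, df = 1, lower.tail = FALSE)
}

#' Wallenius noncentral hypergeometric upper-tail test
#'
#' Probability of drawing at least `category_in_selected` category genes when
#' `universe_selected` genes are sampled without replacement from a universe
#' of `universe_total` genes of which `category_total` belong to the
#' category, with each category gene carrying sampling odds `odds` relative
#' to the rest (biased-urn model). The probability mass is evaluated by the
#' standard integral representation
#' \deqn{P(X=x) = \binom{m_1}{x}\binom{m_2}{n-x}\int_0^1
#'  (1-t^{\omega/D})^x (1-t^{1/D})^{n-x}\,dt,\quad
#'  D = \omega(m_1-x) + (m_2-(n-x)),}
#' computed in log space with a Laplace-stabilized substitution so that large
#' universes do not underflow. With `odds = 1` the distribution reduces to
#' the central hypergeometric.
#'
#' @param category_in_selected Observed overlap x.
#' @param category_total Category size in the universe (m1).
#' @param universe_selected Number of selected genes (n).
#' @param universe_total Universe size (N).
#' @param odds Sampling odds of category genes (positive scalar).
#' @return Upper-tail p-value `P(X >= x)`.
#' @export
wallenius_test <- function(category_in_selected, category_total,
                           universe_selected, universe_total, odds = 1) {
  x <- category_in_selected; m1 <- category_total
  n <- universe_selected; N <- universe_total
  if (odds <= 0) stop2("odds must be positive")
  if (m1 > N || n > N || x > min(m1, n) || x < 0) stop2("inconsistent counts")
  m2 <- N - m1
  xs <- max(x, max(0L, n - m2)):min(m1, n)
  if (!length(xs)) return(0)
  lp <- vapply(xs, function(xx) wallenius_log_pmf(xx, m1, m2, n, odds), numeric(1))
  min(1, exp(logsumexp(lp)))
}

# log P(X = x) for the Wallenius distribution, via t = exp(-v) substitution:
# integral_0^Inf exp(-v + x*log(1-exp(-vw/D)) + (n-x)*log(1-exp(-v/D))) dv,
# evaluated around its interior maximum for numerical stability.
wallenius_log_pmf <- function(x, m1, m2, n, w) {
  if (x < 0 || x > m1 || n - x > m2 || n - x < 0) return(-Inf)
  D <- w * (m1 - x) + (m2 - (n - x))
  lc <- lchoose(m1, x) + lchoose(m2, n - x)
  if (D <= 0) {
    # everything outside the selection is exhausted; the draw is forced
    return(if (x == m1 && (n - x) == m2) 0 else -Inf)
  }
  h <- function(v) {
    out <- -v
    if (x > 0) out <- out + x * log(-expm1(-v * w / D))       # log(1-t^(w/D))
    if (n - x > 0) out <- out + (n - x) * log(-expm1(-v / D)) # log(1-t^(1/D))
    out[!is.finite(out)] <- -Inf
    out
  }
  opt <- stats::optimize(h, interval = c(1e-12, 100 * D + 100 * n + 100), maximum = TRUE)
  vmax <- opt$maximum
  hmax <- opt$objective
  if (!is.finite(hmax)) return(-Inf)
  # integrate over a window holding all non-negligible mass around the peak
  step <- max(vmax / 4, 1)
  vlo <- vmax
  while (vlo > 0 && h(vlo) > hmax - 45) vlo <- vlo - step
  vlo <- max(vlo, 0)
  vhi <- vmax + step
  while (h(vhi) > hmax - 45) vhi <- vhi + step
  int <- stats::integrate(function(v) exp(h(v) - hmax), lower = vlo, upper = vhi,
                          rel.tol = 1e-10, abs.tol = 0)
  lc + hmax + log(int$value)
}

#' Cohort summary table with per-covariate association tests
#'
#' Produces a descriptive table by outcome group: N (\%) for categorical
#' covariates and mean (SD) for continuous covariates, with a chi-square
#' test of independence for nominal covariates and a linear trend test
#' (ordinal group scores TD = 0, nonTD = 1, ASD = 2) for ordinal/continuous
#' covariates. Missing values are counted separately and excluded from the
#' tests.
#'
#' @param sheet Sample sheet.
#' @param covariates Columns to summarize (default: all except ids/outcome).
#' @param nominal Covariates tested with the chi-square test (default sex,
#'   batch, site when present).
#' @return List with `table` (long-format summary data frame) and `p_values`
#'   (named vector, one per covariate).
#' @export
summarize_cohort <- function(sheet,
                             covariates = setdiff(colnames(sheet),
                                                  c("sample_id", "outcome", "recorded_sex")),
                             nominal = intersect(c("sex", "batch", "site"), colnames(sheet))) {
  sheet <- validate_sample_sheet(sheet)
  groups <- levels(sheet$outcome)
  score <- as.integer(sheet$outcome) - 1L   # TD 0, nonTD 1, ASD 2
  rows <- list()
  pvals <- stats::setNames(rep(NA_real_, length(covariates)), covariates)
  for (cv in covariates) {
    x <- sheet[[cv]]
    if (is.numeric(x)) {
      cells <- vapply(groups, function(g) {
        v <- x[sheet$outcome == g & !is.na(x)]
        sprintf("%.1f (%.2f)", mean(v), stats::sd(v))
      }, "")
      rows[[length(rows) + 1L]] <- data.frame(covariate = cv, level = "mean (SD)",
                                              t(cells), missing = sum(is.na(x)),
                                              check.names = FALSE)
      pvals[cv] <- trend_test(score, x)$p_value
    } else {
      f <- factor(x)
      tab <- table(f, sheet$outcome)
      for (lv in levels(f)) {
        cells <- vapply(groups, function(g) {
          n <- tab[lv, g]
          sprintf("%d (%.1f%%)", n, 100 * n / sum(tab[, g]))
        }, "")
        rows[[length(rows) + 1L]] <- data.frame(covariate = cv, level = lv,
                                                t(cells), missing = sum(is.na(x)),
                                                check.names = FALSE)
      }
      pvals[cv] <- if (cv %in% nominal) {
        chi_square_test(unclass(tab))$p_value
      } else {
        trend_test(score[!is.na(x)], as.character(x[!is.na(x)]))$p_value
      }
    }
  }
  tab <- do.call(rbind, rows)
  colnames(tab) <- c("covariate", "level", groups, "missing")
  rownames(tab) <- NULL
  list(table = tab, p_values = pvals)
}
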