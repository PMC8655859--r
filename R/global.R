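#' Per-sample global and region-stratified methylation means
#'
#' Averages beta values per sample across all autosomal probes and within
#' each region class (island, shore, shelf, open sea — a disjoint partition)
#' plus the overlapping enhancer flag, reported as percent (x 100). Sex
#' chromosome probes are excluded throughout.
#'
#' @param b Beta matrix.
#' @param ann CpG annotation covering the probes of `b`.
#' @return `data.frame` with one row per sample and columns `sample_id`,
#'   `overall`, `island`, `shore`, `shelf`, `open_sea`, `enhancer` (percent);
#'   per-stratum probe counts in `attr(, "n_probes")`.
#' @export
global_means <- function(b, ann) {
  ann <- ann[match(rownames(b), ann$probe_id), ]
  if (anyNA(ann$probe_id)) stop2("annotation does not cover all probes")
  auto <- !is_sex_chrom(ann$chrom)
  ba <- b[auto, , drop = FALSE]
  anna <- ann[auto, ]
  strata <- list(
    overall = rep(TRUE, nrow(ba)),
    island = anna$region_class == "island",
    shore = anna$region_class == "shore",
    shelf = anna$region_class == "shelf",
    open_sea = anna$region_class == "open_sea",
    enhancer = anna$enhancer
  )
  out <- data.frame(sample_id = colnames(b), stringsAsFactors = FALSE)
  n_probes <- integer(length(strata))
  names(n_probes) <- names(strata)
  for (s in names(strata)) {
    idx <- strata[[s]]
    n_probes[s] <- sum(idx)
    if (!any(idx)) {
      warning("empty stratum: ", s)
      out[[s]] <- NA_real_
    } else {
      out[[s]] <- colMeans(ba[idx, , drop = FALSE]) * 100
    }
  }
  attr(out, "n_probes") <- n_probes
  out
}

#' Test group differences in global methylation per stratum
#'
#' Linear model per stratum: `mean_percent ~ group + surrogate variables`,
#' reporting the case-minus-TD difference in percent methylation with its
#' standard error and p-value. Optionally stratified by sex; a sex stratum
#' with fewer than 3 samples per group is skipped with a warning.
#'
#' @param gm Output of [global_means()].
#' @param sheet Sample sheet.
#' @param svs `surrogate_set`, score matrix aligned to `gm$sample_id`, or `NULL`.
#' @param contrast `"ASD-vs-TD"` or `"nonTD-vs-TD"`.
#' @param stratify_sex If `TRUE`, fit separately within each sex.
#' @return `data.frame` with columns `stratum`, `sex`, `estimate`, `se`,
#'   `p_value`, `n`.
#' @export
test_global_difference <- function(gm, sheet, svs = NULL,
                                   contrast = c("ASD-vs-TD", "nonTD-vs-TD"),
                                   stratify_sex = FALSE) {
  contrast <- match.arg(contrast)
  case <- if (contrast == "ASD-vs-TD") "ASD" else "nonTD"
  sheet <- validate_sample_sheet(sheet)
  sheet <- sheet[match(gm$sample_id, sheet$sample_id), ]
  sv <- if (inherits(svs, "surrogate_set")) svs$sv else svs
  strata <- setdiff(colnames(gm), "sample_id")
  sexes <- if (stratify_sex) c("M", "F") else "all"
  rows <- list()
  for (sx in sexes) {
    keep_sex <- if (sx == "all") rep(TRUE, nrow(sheet)) else sheet$sex == sx
    for (s in strata) {
      use <- keep_sex & sheet$outcome %in% c(case, "TD") & !is.na(gm[[s]])
      grp <- as.numeric(sheet$outcome[use] == case)
      if (sum(grp == 1) < 3L || sum(grp == 0) < 3L) {
        warning("stratum ", s, " (", sx, ") skipped: fewer than 3 samples per group")
        next
      }
      X <- cbind(1, grp)
      if (!is.null(sv)) X <- cbind(X, sv[use, , drop = FALSE])
      fit <- stats::lm.fit(X, gm[[s]][use])
      df <- sum(use) - fit$rank
      s2 <- sum(fit$residuals^2) / df
      v <- chol2inv(chol(crossprod(X)))[2, 2]
      est <- fit$coefficients[2]
      se <- sqrt(s2 * v)
      degenerate <- se < 1e-10 * max(1, abs(mean(gm[[s]][use])))
      p <- if (degenerate) 1 else 2 * stats::pt(-abs(est / se), df)
      rows[[length(rows) + 1L]] <- data.frame(stratum = s, sex = sx,
                                              estimate = est, se = se,
                                              p_value = p, n = sum(use))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Permutation test on methylation cumulative density functions
#'
#' Each sample contributes its empirical CDF over the stratum's autosomal
#' probes, evaluated on a fixed beta grid; the statistic is the mean absolute
#' difference between the group-averaged CDFs of the two diagnosis groups
#' (an integrated absolute CDF difference). The p-value comes from
#' group-label permutation: `p = (1 + #\{perm >= obs\}) / (1 + n_perm)`, so it
#' is bounded below by `1 / (n_perm + 1)`.
#'
#' @param b Beta matrix.
#' @param ann CpG annotation.
#' @param sheet Sample sheet.
#' @param stratum One of `"overall"`, `"island"`, `"shore"`, `"shelf"`,
#'   `"open_sea"`, `"enhancer"`.
#' @param contrast `"ASD-vs-TD"` or `"nonTD-vs-TD"`.
#' @param n_perm Number of label permutations (>= 100 recommended).
#' @param seed Permutation seed.
#' @param grid Evaluation grid on \[0,1\] (default 101 equally spaced points).
#' @return List with `statistic`, `p_value`, `n_perm`, `grid`.
#' @export
cdf_difference_test <- function(b, ann, sheet, stratum = "overall",
                                contrast = c("ASD-vs-TD", "nonTD-vs-TD"),
                                n_perm = 999, seed = 1,
                                grid = seq(0, 1, length.out = 101)) {
  contrast <- match.arg(contrast)
  case <- if (contrast == "ASD-vs-TD") "ASD" else "nonTD"
  sheet <- validate_sample_sheet(sheet)
  sheet <- sheet[match(colnames(b), sheet$sample_id), ]
  ann <- ann[match(rownames(b), ann$probe_id), ]
  auto <- !is_sex_chrom(ann$chrom)
  idx <- switch(stratum,
                overall = auto,
                enhancer = auto & ann$enhancer,
                auto & ann$region_class == stratum)
  if (!any(idx)) stop2("empty stratum: ", stratum)
  use <- sheet$outcome %in% c(case, "TD")
  vals <- b[idx, use, drop = FALSE]
  grp <- sheet$outcome[use] == case
  if (sum(grp) < 2L || sum(!grp) < 2L) stop2("need at least 2 samples per group")
  # per-sample ECDF on the grid: fraction of stratum probes <= grid point
  ecdfs <- apply(vals, 2L, function(v) stats::ecdf(v)(grid))  # grid x samples
  if (all(apply(vals, 2L, stats::sd) == 0) &&
      length(unique(as.vector(vals))) == 1L) {
    return(list(statistic = 0, p_value = 1, n_perm = n_perm, grid = grid))
  }
  stat_fn <- function(g) mean(abs(rowMeans(ecdfs[, g, drop = FALSE]) -
                                  rowMeans(ecdfs[, !g, drop = FALSE])))
  obs <- stat_fn(grp)
  set.seed(as.integer(seed))
  perm <- replicate(n_perm, stat_fn(sample(grp)))
  list(statistic = obs, p_value = (1 + sum(perm >= obs)) / (1 + n_perm),
       n_perm = n_perm, grid = grid)
}
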