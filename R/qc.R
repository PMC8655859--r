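#' Probe-level quality control
#'
#' Removes probes whose detection p-value exceeds `det_p_cut` in strictly
#' more than `sample_frac_cut` of samples, then removes probes on the
#' cross-reactive list. Both cuts are strict inequalities, so a probe failing
#' in exactly 10\% of samples is retained.
#'
#' @param b Beta matrix (probes x samples).
#' @param detp Detection p-value matrix aligned to `b`.
#' @param crossreactive Character vector of cross-reactive probe ids.
#' @param det_p_cut Detection p-value above which a measurement is failed.
#' @param sample_frac_cut Fraction of failed samples above which a probe is
#'   removed.
#' @return List with `beta` (filtered) and `report` (counts removed).
#' @export
filter_probes <- function(b, detp, crossreactive = character(),
                          det_p_cut = 0.01, sample_frac_cut = 0.10) {
  if (!identical(dim(b), dim(detp)) ||
      !identical(rownames(b), rownames(detp)) ||
      !identical(colnames(b), colnames(detp))) {
    stop2("beta and detection p-value matrices are misaligned")
  }
  fail_frac <- rowMeans(detp > det_p_cut)
  fail_det <- fail_frac > sample_frac_cut
  keep1 <- rownames(b)[!fail_det]
  removed_cross <- intersect(keep1, crossreactive)
  keep <- setdiff(keep1, crossreactive)
  list(
    beta = b[keep, , drop = FALSE],
    report = list(
      probes_removed_detection = sum(fail_det),
      probes_removed_crossreactive = length(removed_cross),
      probes_kept = length(keep)
    )
  )
}

#' Sample-level quality control
#'
#' Drops samples with mean log2 array intensity below `intensity_cut`, with a
#' failed-detection fraction above `fail_frac_cut`, or whose methylation
#' predicted sex disagrees with the recorded sex. Sex is predicted from the
#' per-sample difference (median chrY beta - median chrX beta) split by a
#' deterministic two-cluster 1-D k-means; the cluster with the higher mean is
#' called male. If no X/Y probes are present the sex check is skipped with a
#' warning recorded in the report.
#'
#' @param b Beta matrix.
#' @param ann CpG annotation covering the probes of `b`.
#' @param sheet Sample sheet with `recorded_sex` (and `sample_id`).
#' @param detp Detection p-value matrix aligned to `b`.
#' @param intensity Per-sample mean log2 intensity (named by sample id); by
#'   default taken from the sheet column `mean_log2_intensity`.
#' @param intensity_cut,fail_frac_cut,det_p_cut QC thresholds.
#' @return List with `samples_kept`, `report` (counts and flags) and
#'   `predicted_sex`.
#' @export
filter_samples <- function(b, ann, sheet, detp, intensity = NULL,
                           intensity_cut = 10.5, fail_frac_cut = 0.20,
                           det_p_cut = 0.01) {
  sheet <- validate_sample_sheet(sheet)
  ids <- colnames(b)
  if (is.null(intensity)) {
    intensity <- stats::setNames(sheet$mean_log2_intensity, sheet$sample_id)[ids]
  }
  low_int <- ids[!is.na(intensity) & intensity < intensity_cut]
  fail_frac <- colMeans(detp > det_p_cut)
  high_fail <- ids[fail_frac > fail_frac_cut]

  ann <- ann[match(rownames(b), ann$probe_id), ]
  xi <- which(ann$chrom %in% c("X", "chrX", "23"))
  yi <- which(ann$chrom %in% c("Y", "chrY", "24"))
  sex_mismatch <- character(0)
  predicted_sex <- rep(NA_character_, length(ids))
  names(predicted_sex) <- ids
  sex_check_skipped <- FALSE
  if (length(xi) == 0L || length(yi) == 0L) {
    warning("no chrX/chrY probes present; sex check skipped")
    sex_check_skipped <- TRUE
  } else {
    d <- apply(b[yi, , drop = FALSE], 2L, stats::median) -
      apply(b[xi, , drop = FALSE], 2L, stats::median)
    cl <- two_cluster_split(d)
    predicted_sex <- ifelse(d > cl$threshold, "M", "F")
    names(predicted_sex) <- ids
    recorded <- stats::setNames(as.character(sheet$recorded_sex), sheet$sample_id)[ids]
    sex_mismatch <- ids[!is.na(recorded) & predicted_sex != recorded]
  }
  drop <- unique(c(low_int, high_fail, sex_mismatch))
  list(
    samples_kept = setdiff(ids, drop),
    predicted_sex = predicted_sex,
    report = list(
      samples_removed_intensity = length(low_int),
      samples_removed_detection = length(high_fail),
      samples_removed_sexmismatch = length(sex_mismatch),
      sex_check_skipped = sex_check_skipped
    )
  )
}

# Deterministic 1-D two-means: centers initialized at min and max.
two_cluster_split <- function(d) {
  c1 <- min(d); c2 <- max(d)
  if (c1 == c2) return(list(threshold = c1, centers = c(c1, c2)))
  for (i in 1:100) {
    lower <- abs(d - c1) <= abs(d - c2)
    n1 <- mean(d[lower]); n2 <- mean(d[!lower])
    if (is.nan(n1) || is.nan(n2)) break
    if (isTRUE(all.equal(c(n1, n2), c(c1, c2)))) { c1 <- n1; c2 <- n2; break }
    c1 <- n1; c2 <- n2
  }
  list(threshold = (c1 + c2) / 2, centers = c(c1, c2))
}

#' Pearson concordance between technical replicate pairs
#'
#' @param b Beta matrix.
#' @param pairs Two-column matrix or data frame of sample-id pairs.
#' @return Numeric vector of correlations, `NA` where a member is constant.
#' @export
replicate_concordance <- function(b, pairs) {
  pairs <- as.matrix(pairs)
  missing <- setdiff(unique(c(pairs)), colnames(b))
  if (length(missing)) stop2("replicate pair samples not in matrix: ",
                             paste(missing, collapse = ", "))
  apply(pairs, 1L, function(pr) {
    x <- b[, pr[1]]; y <- b[, pr[2]]
    if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
    stats::cor(x, y)
  })
}

#' Scan principal components against measured covariates
#'
#' Computes the top principal components of the centered beta matrix
#' (samples as observations) and the one-way ANOVA p-value of each PC
#' against each covariate; continuous covariates use the equivalent
#' single-regressor F-test. Covariates with a single level give missing
#' p-values.
#'
#' @param b Beta matrix.
#' @param sheet Sample sheet.
#' @param n_pcs Number of PCs (at most n_samples - 1).
#' @param covariates Sheet columns to scan (default: all but `sample_id`).
#' @return Matrix of p-values, PCs in rows, covariates in columns; the PC
#'   variance fractions are in `attr(, "var_explained")`.
#' @export
pc_covariate_scan <- function(b, sheet, n_pcs = 5,
                              covariates = setdiff(colnames(sheet), "sample_id")) {
  sheet <- sheet[match(colnames(b), sheet$sample_id), ]
  n_pcs <- min(n_pcs, ncol(b) - 1L)
  pr <- stats::prcomp(t(b), center = TRUE, scale. = FALSE, rank. = n_pcs)
  scores <- pr$x
  out <- matrix(NA_real_, n_pcs, length(covariates),
                dimnames = list(colnames(scores), covariates))
  for (cv in covariates) {
    x <- sheet[[cv]]
    if (is.numeric(x)) {
      if (length(unique(x[!is.na(x)])) < 2L) next
      for (k in seq_len(n_pcs)) {
        fit <- stats::lm(scores[, k] ~ x)
        out[k, cv] <- stats::anova(fit)[["Pr(>F)"]][1]
      }
    } else {
      f <- factor(x)
      if (nlevels(droplevels(f[!is.na(f)])) < 2L) next
      for (k in seq_len(n_pcs)) {
        fit <- stats::lm(scores[, k] ~ f)
        out[k, cv] <- stats::anova(fit)[["Pr(>F)"]][1]
      }
    }
  }
  attr(out, "var_explained") <- (pr$sdev^2 / sum(pr$sdev^2))[seq_len(n_pcs)]
  out
}
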