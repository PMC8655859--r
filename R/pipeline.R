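#' Build a pipeline configuration
#'
#' Collects every tunable threshold of the pipeline with its default. The
#' thresholds grid must be strictly increasing in (0, 1\]; the seed is
#' recorded in all outputs.
#'
#' @param seed Integer seed used for every stochastic step.
#' @param contrast `"ASD-vs-TD"` (primary) or `"nonTD-vs-TD"` (sensitivity).
#' @param model `"surrogate"` (surrogate-variable adjustment) or
#'   `"known-covariate"`.
#' @param known_covariates Sheet columns for the known-covariate model.
#' @param det_p_cut,sample_frac_cut Probe QC: detection p-value cut and the
#'   sample fraction above which a probe is removed.
#' @param intensity_cut,fail_frac_cut Sample QC cuts.
#' @param sv_max Maximum number of candidate surrogate variables.
#' @param thresholds Enrichment p-value threshold grid.
#' @param n_perm Random-gene-set permutations for enrichment.
#' @param cdf_n_perm Label permutations for the CDF test.
#' @param go_min_genes Minimum universe genes per ontology category.
#' @param nominal_p Nominal significance threshold.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1, contrast = "ASD-vs-TD",
                            model = c("surrogate", "known-covariate"),
                            known_covariates = c("sex", "batch", "maternal_age"),
                            det_p_cut = 0.01, sample_frac_cut = 0.10,
                            intensity_cut = 10.5, fail_frac_cut = 0.20,
                            sv_max = 10, thresholds = enrichment_thresholds(),
                            n_perm = 10, cdf_n_perm = 199, go_min_genes = 5,
                            nominal_p = 0.05) {
  model <- match.arg(model)
  if (any(diff(thresholds) <= 0) || any(thresholds <= 0) || any(thresholds > 1)) {
    stop2("thresholds must be strictly increasing in (0, 1]")
  }
  if (n_perm < 1) stop2("permutation count must be >= 1")
  structure(as.list(environment()), class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#' @param path YAML file whose keys match [pipeline_config()] arguments.
#' @return `pipeline_config` list.
#' @export
read_pipeline_config <- function(path) {
  vals <- yaml::read_yaml(path)
  keep <- intersect(names(vals), names(formals(pipeline_config)))
  do.call(pipeline_config, vals[keep])
}

#' Run the full analysis pipeline
#'
#' Executes QC, cell-type deconvolution, surrogate-variable estimation with
#' lambda-guided selection, site-wise EWAS with empirical-Bayes moderation,
#' global/region methylation tests, risk-gene enrichment curves with
#' permutation controls, and (when a category map is supplied) ontology
#' testing — in that order — writing one table per stage plus a run log to
#' `out_dir`. Outputs are a pure function of (inputs, config, seed); a stage
#' failure aborts with the stage name and cause.
#'
#' @param inputs List with elements `beta`, `detp` (matrices), `annotation`,
#'   `sheet` (data frames), `risk_genes` (gene set), and optionally
#'   `crossreactive` (probe ids), `reference` (cell reference panel),
#'   `go_map` (gene/category data frame), `meqtl_cpgs` (probe ids). File
#'   paths are accepted in place of objects for each element.
#' @param config `pipeline_config`.
#' @param out_dir Output directory.
#' @return Invisibly, a list of per-stage results.
#' @export
run_pipeline <- function(inputs, config = pipeline_config(), out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop2("pipeline stage '", name, "' failed: ", conditionMessage(e))
    })
  }
  log_lines <- c(
    paste0("perewas version: ", as.character(utils::packageVersion("perewas"))),
    paste0("seed: ", config$seed),
    paste0("contrast: ", config$contrast),
    paste0("model: ", config$model)
  )

  inp <- stage("read_inputs", load_pipeline_inputs(inputs))
  res <- list(config = config)

  ## --- QC ---------------------------------------------------------------
  qc <- stage("qc", {
    pf <- filter_probes(inp$beta, inp$detp, inp$crossreactive,
                        det_p_cut = config$det_p_cut,
                        sample_frac_cut = config$sample_frac_cut)
    fs <- filter_samples(pf$beta, inp$annotation, inp$sheet,
                         inp$detp[rownames(pf$beta), , drop = FALSE],
                         intensity_cut = config$intensity_cut,
                         fail_frac_cut = config$fail_frac_cut)
    list(beta = pf$beta[, fs$samples_kept, drop = FALSE],
         probe_report = pf$report, sample_report = fs$report)
  })
  res$qc <- qc[c("probe_report", "sample_report")]
  beta <- qc$beta
  sheet <- inp$sheet[inp$sheet$sample_id %in% colnames(beta), , drop = FALSE]
  log_lines <- c(log_lines,
    paste0("probes_removed_detection: ", qc$probe_report$probes_removed_detection),
    paste0("probes_removed_crossreactive: ", qc$probe_report$probes_removed_crossreactive),
    paste0("probes_kept: ", nrow(beta)),
    paste0("samples_kept: ", ncol(beta)))

  ## --- cell deconvolution ----------------------------------------------
  if (!is.null(inp$reference)) {
    props <- stage("deconvolution", estimate_proportions(beta, inp$reference))
    res$cell_proportions <- props
    write_beta_matrix(t(props), file.path(out_dir, "cell_proportions.tsv"),
                      id_col = "cell_type")
  }

  ## --- surrogate variables ----------------------------------------------
  case <- if (config$contrast == "ASD-vs-TD") "ASD" else "nonTD"
  use <- sheet$outcome %in% c(case, "TD")
  y_sub <- beta[, sheet$sample_id[use], drop = FALSE]
  grp <- as.numeric(sheet$outcome[use] == case)
  design <- cbind(1, grp)
  design0 <- matrix(1, sum(use), 1)
  adjustment <- NULL
  if (config$model == "surrogate") {
    sva_res <- stage("sva", {
      k_max <- min(config$sv_max, sum(use) - 3L)
      m_sub <- beta_to_m(y_sub)    # latent effects are near-linear on this scale
      svs <- estimate_svs(m_sub, design, design0, k_max = k_max)
      sel <- select_k_by_lambda(m_sub, design, design0, svs)
      list(svs = svs, k = sel$k_selected, lambda_by_k = sel$lambda_by_k)
    })
    res$sva <- sva_res[c("k", "lambda_by_k")]
    log_lines <- c(log_lines, paste0("sv_selected: ", sva_res$k))
    utils::write.table(
      data.frame(k = seq_along(sva_res$lambda_by_k) - 1L, lambda = sva_res$lambda_by_k),
      file.path(out_dir, "lambda_by_k.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
    if (sva_res$k > 0) {
      sv_sel <- sva_res$svs$sv[, seq_len(sva_res$k), drop = FALSE]
      full_sv <- matrix(NA_real_, ncol(beta), ncol(sv_sel),
                        dimnames = list(colnames(beta), colnames(sv_sel)))
      full_sv[sheet$sample_id[use], ] <- sv_sel
      adjustment <- full_sv
      write_beta_matrix(t(full_sv), file.path(out_dir, "surrogate_variables.tsv"),
                        id_col = "sv")
    }
  } else {
    adjustment <- config$known_covariates
  }

  ## --- site-wise EWAS ---------------------------------------------------
  ewas <- stage("ewas", fit_sitewise(beta, sheet, adjustment = adjustment,
                                     contrast = config$contrast))
  res$ewas <- ewas
  res$ewas_summary <- summarize_ewas(ewas, p_cut = config$nominal_p)
  ewas_out <- merge(ewas, inp$annotation[, c("probe_id", "genes", "chrom", "pos")],
                    by = "probe_id", sort = FALSE)
  ewas_out <- ewas_out[order(ewas_out$p_value), ]
  utils::write.table(ewas_out, file.path(out_dir, paste0("ewas_", config$contrast, ".tsv")),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  log_lines <- c(log_lines,
    paste0("ewas_lambda: ", format(inflation_lambda(ewas$p_value))),
    paste0("n_nominal: ", res$ewas_summary$n_nominal),
    paste0("pct_hyper: ", format(res$ewas_summary$pct_hyper)))

  ## --- global methylation -----------------------------------------------
  glob <- stage("global", {
    gm <- global_means(beta, inp$annotation)
    tests <- test_global_difference(gm, sheet, svs = adjustment_matrix(adjustment),
                                    contrast = config$contrast)
    cdf <- cdf_difference_test(beta, inp$annotation, sheet,
                               contrast = config$contrast,
                               n_perm = config$cdf_n_perm, seed = config$seed)
    list(means = gm, tests = tests, cdf = cdf)
  })
  res$global <- glob
  utils::write.table(glob$means, file.path(out_dir, "global_means.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(glob$tests, file.path(out_dir, "global_tests.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  ## --- enrichment -------------------------------------------------------
  enr <- stage("enrichment", enrichment_curve(ewas, inp$annotation, inp$risk_genes,
                                              grid = config$thresholds,
                                              n_perm = config$n_perm,
                                              seed = config$seed))
  res$enrichment <- enr
  utils::write.table(enr$curve, file.path(out_dir, "enrichment_curve.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(inp$meqtl_cpgs)) {
    enr_meqtl <- stage("enrichment_meqtl",
                       enrichment_curve(ewas, inp$annotation, inp$risk_genes,
                                        grid = config$thresholds,
                                        n_perm = config$n_perm,
                                        seed = config$seed,
                                        restrict_cpgs = inp$meqtl_cpgs))
    res$enrichment_meqtl <- enr_meqtl
    utils::write.table(enr_meqtl$curve, file.path(out_dir, "enrichment_curve_meqtl.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  ## --- ontology ----------------------------------------------------------
  if (!is.null(inp$go_map)) {
    onto <- stage("ontology", ontology_enrichment(ewas, inp$annotation, inp$go_map,
                                                  threshold = config$nominal_p,
                                                  min_genes = config$go_min_genes))
    res$ontology <- onto
    utils::write.table(onto, file.path(out_dir, "ontology.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  writeLines(log_lines, file.path(out_dir, "run_log.txt"))
  invisible(res)
}

adjustment_matrix <- function(adj) {
  if (is.null(adj) || is.character(adj)) NULL else adj
}

# Accept objects or file paths for each pipeline input element.
load_pipeline_inputs <- function(inputs) {
  get_mat <- function(x, range = TRUE) {
    if (is.character(x) && length(x) == 1L) read_beta_matrix(x, check_range = range) else x
  }
  list(
    beta = get_mat(inputs$beta),
    detp = get_mat(inputs$detp, range = FALSE),
    annotation = if (is.character(inputs$annotation)) read_cpg_annotation(inputs$annotation)
                 else validate_cpg_annotation(inputs$annotation),
    sheet = if (is.character(inputs$sheet)) read_sample_sheet(inputs$sheet)
            else validate_sample_sheet(inputs$sheet),
    risk_genes = if (is.character(inputs$risk_genes)) read_gene_set(inputs$risk_genes)
                 else inputs$risk_genes,
    crossreactive = if (is.character(inputs$crossreactive) &&
                        length(inputs$crossreactive) == 1L &&
                        file.exists(inputs$crossreactive)) {
      readLines(inputs$crossreactive)
    } else inputs$crossreactive %||% character(0),
    reference = if (is.character(inputs$reference) && length(inputs$reference) == 1L) {
      list(profiles = read_beta_matrix(inputs$reference, check_range = FALSE))
    } else inputs$reference,
    go_map = if (is.character(inputs$go_map)) {
      utils::read.table(inputs$go_map, header = TRUE, sep = "\t",
                        stringsAsFactors = FALSE)
    } else inputs$go_map,
    meqtl_cpgs = if (is.character(inputs$meqtl_cpgs) &&
                     length(inputs$meqtl_cpgs) == 1L &&
                     file.exists(inputs$meqtl_cpgs)) {
      readLines(inputs$meqtl_cpgs)
    } else inputs$meqtl_cpgs
  )
}
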