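#' Simulate a 450k-like multi-component methylation dataset
#'
#' Generates beta values as a logistic-scale sum of cell-type mixture signal,
#' latent batch-like factors, sex effects on dedicated X/Y probe blocks, a
#' diagnosis effect spiked preferentially into CpGs annotated to a designated
#' risk-gene set, and logit-normal noise:
#' \deqn{\beta_{ij} = \mathrm{logistic}\big(\mathrm{logit}(\sum_k w_{ik} r_{kj})
#'   + \sum_l f_{il}\lambda_{lj} + \mathrm{sex}_i s_j + \mathrm{dx}_i \delta_j
#'   + \epsilon_{ij}\big)}
#' The diagnosis effect \eqn{\delta_j} is nonzero only at `effect_cpgs`, a
#' random `spike_fraction` of the probes annotated to risk genes; its
#' logit-scale magnitude is calibrated so the induced beta-scale difference at
#' beta = 0.5 equals `delta`. Region classes are assigned with realistic 450k
#' proportions (about 31\% island, 23\% shore, 10\% shelf, 36\% open sea) and
#' the outcome is sampled with cohort-style prevalence (default 22\% ASD,
#' 43\% non-typically developing, 35\% typically developing). About
#' `detection_fail_rate` of detection p-values are set above 0.01 to emulate
#' failed measurements.
#'
#' @param n_samples,n_cpgs,n_celltypes,k_latent Dataset dimensions.
#' @param spike_fraction Fraction of risk-gene CpGs that carry the diagnosis
#'   effect (in (0, 1\]).
#' @param delta Intended beta-scale group difference at beta = 0.5 (proportion).
#' @param seed Integer seed; the generator is a pure function of its arguments.
#' @param noise_sd Logit-scale residual noise standard deviation.
#' @param latent_sd Logit-scale loading magnitude for latent factors.
#' @param latent_prob Fraction of probes loaded by each latent factor.
#' @param confounding Correlation-scale contribution of the diagnosis
#'   indicator to each latent factor score. At 0 (default) latent factors
#'   are independent of the outcome; positive values plant
#'   confounder-outcome overlap, inflating unadjusted association tests the
#'   way unmodeled batch/cell-composition structure does in cohort data.
#' @param detection_fail_rate Expected fraction of failed detection p-values.
#' @param prevalence Named outcome probabilities (ASD, nonTD, TD).
#' @param risk_gene_fraction Fraction of synthetic genes in the risk set.
#' @param n_batches,n_sites Numbers of technical batch and site labels.
#' @param cell_profile_sd Logit-scale spread of cell-type-specific deviations.
#' @return List with `beta` (CpG-by-sample matrix), `detp` (detection
#'   p-values, same shape), `annotation`, `sheet`, `risk_genes` and `truth`
#'   (cell profiles, mixing weights, latent scores/loadings, `effect_cpgs`,
#'   `delta`, `seed`).
#' @export
simulate_dataset <- function(n_samples = 120, n_cpgs = 10000, n_celltypes = 7,
                             k_latent = 2, spike_fraction = 0.3, delta = 0.05,
                             seed = 1, noise_sd = 0.15, latent_sd = 0.5,
                             latent_prob = 0.3, confounding = 0,
                             detection_fail_rate = 0.001,
                             prevalence = c(ASD = 0.22, nonTD = 0.43, TD = 0.35),
                             risk_gene_fraction = 0.10, n_batches = 2,
                             n_sites = 4, cell_profile_sd = 1.2) {
  if (n_samples < 2 || n_cpgs < 10 || n_celltypes < 1) stop2("all counts must be positive")
  if (spike_fraction <= 0 || spike_fraction > 1) stop2("spike_fraction must be in (0, 1]")
  if (delta < 0 || delta >= 1) stop2("delta must be a proportion below 1")
  if (0.5 + delta / 2 >= 0.98 || 0.5 - delta / 2 <= 0.02) {
    stop2("delta would push group means outside [0.02, 0.98]")
  }
  set.seed(as.integer(seed))

  probe_ids <- sprintf("cg%08d", seq_len(n_cpgs))
  sample_ids <- sprintf("S%04d", seq_len(n_samples))

  ## --- annotation: chromosomes with dedicated X/Y blocks at the end
  n_y <- max(10L, round(0.005 * n_cpgs))
  n_x <- max(20L, round(0.02 * n_cpgs))
  n_auto <- n_cpgs - n_x - n_y
  chrom <- c(as.character(sample(1:22, n_auto, replace = TRUE)),
             rep("X", n_x), rep("Y", n_y))
  pos <- sample.int(2e8, n_cpgs, replace = TRUE)

  n_genes <- max(30L, round(n_cpgs / 8))
  gene_names <- sprintf("GENE%05d", seq_len(n_genes))
  primary_gene <- sample(gene_names, n_cpgs, replace = TRUE)
  annotated <- stats::runif(n_cpgs) < 0.8
  second <- stats::runif(n_cpgs) < 0.10
  genes <- ifelse(annotated,
                  ifelse(second,
                         paste(primary_gene, sample(gene_names, n_cpgs, replace = TRUE), sep = ";"),
                         primary_gene),
                  "")
  genes <- vapply(split_genes(genes), paste, "", collapse = ";")
  region_class <- sample(c("island", "shore", "shelf", "open_sea"), n_cpgs,
                         replace = TRUE, prob = c(0.31, 0.23, 0.10, 0.36))
  enhancer <- stats::runif(n_cpgs) < 0.20
  annotation <- data.frame(probe_id = probe_ids, chrom = chrom, pos = pos,
                           genes = genes, region_class = region_class,
                           enhancer = enhancer, stringsAsFactors = FALSE)

  risk_genes <- gene_set(sample(gene_names, max(2L, round(risk_gene_fraction * n_genes))),
                         name = "synthetic_risk")

  ## --- cell-type reference profiles (bimodal 450k-like baseline)
  comp <- sample(3L, n_cpgs, replace = TRUE, prob = c(0.4, 0.4, 0.2))
  base <- numeric(n_cpgs)
  base[comp == 1L] <- stats::rbeta(sum(comp == 1L), 1.5, 10)
  base[comp == 2L] <- stats::rbeta(sum(comp == 2L), 10, 1.5)
  base[comp == 3L] <- stats::rbeta(sum(comp == 3L), 5, 5)
  base <- pmin(pmax(base, 0.03), 0.97)
  informative <- stats::runif(n_cpgs) < 0.25
  shift <- matrix(0, n_celltypes, n_cpgs)
  shift[, informative] <- stats::rnorm(n_celltypes * sum(informative), 0, cell_profile_sd)
  profiles <- expit(sweep(shift, 2L, logit(base), "+"))
  profiles <- pmin(pmax(profiles, 0.02), 0.98)
  cell_types <- cord_cell_types(n_celltypes)
  dimnames(profiles) <- list(cell_types, probe_ids)

  ## --- mixing proportions, Dirichlet around cord-blood-like means
  alpha <- cord_cell_means(n_celltypes) * 60
  g <- matrix(stats::rgamma(n_samples * n_celltypes, shape = rep(alpha, each = n_samples)),
              n_samples, n_celltypes)
  mixing <- g / rowSums(g)
  dimnames(mixing) <- list(sample_ids, cell_types)

  ## --- phenotype
  outcome <- sample(names(prevalence), n_samples, replace = TRUE, prob = prevalence)
  sex <- sample(c("M", "F"), n_samples, replace = TRUE)
  batch <- sample(paste0("B", seq_len(n_batches)), n_samples, replace = TRUE)
  site <- sample(paste0("Site", seq_len(n_sites)), n_samples, replace = TRUE)
  sheet <- data.frame(
    sample_id = sample_ids,
    outcome = outcome, sex = sex, recorded_sex = sex,
    batch = batch, site = site,
    maternal_age = round(stats::rnorm(n_samples, 33.6, 4.7), 1),
    mean_log2_intensity = round(stats::rnorm(n_samples, 12, 0.3), 3),
    stringsAsFactors = FALSE
  )
  sheet <- validate_sample_sheet(sheet)

  ## --- latent factors; factor 1 tracks batch so PC/batch scans are exercised
  scores <- matrix(0, n_samples, max(k_latent, 0L))
  loadings <- matrix(0, max(k_latent, 0L), n_cpgs)
  if (k_latent >= 1L) {
    dx0 <- as.numeric(scale(as.numeric(outcome == "ASD")))
    for (l in seq_len(k_latent)) {
      f <- if (l == 1L) as.numeric(scale(as.integer(factor(batch)))) + stats::rnorm(n_samples, 0, 0.3)
           else stats::rnorm(n_samples)
      f <- as.numeric(scale(f))
      if (confounding != 0) {
        f <- sqrt(1 - confounding^2) * f + confounding * dx0
      }
      scores[, l] <- as.numeric(scale(f))
      hit <- stats::runif(n_cpgs) < latent_prob
      loadings[l, hit] <- stats::rnorm(sum(hit), 0, latent_sd)
    }
  }

  ## --- diagnosis effect at a spiked subset of risk-gene CpGs
  gene_list <- split_genes(annotation$genes)
  in_risk <- vapply(gene_list, function(g) any(g %in% risk_genes$genes), logical(1))
  risk_cpgs <- probe_ids[in_risk & !is_sex_chrom(chrom)]
  n_eff <- round(spike_fraction * length(risk_cpgs))
  effect_cpgs <- sort(sample(risk_cpgs, n_eff))
  dlogit <- logit(0.5 + delta / 2) - logit(0.5 - delta / 2)
  delta_j <- numeric(n_cpgs)
  names(delta_j) <- probe_ids
  delta_j[effect_cpgs] <- dlogit * sample(c(1, -1), n_eff, replace = TRUE, prob = c(0.7, 0.3))

  ## --- assemble on the logit scale
  mu <- mixing %*% profiles                       # n_samples x n_cpgs
  eta <- logit(pmin(pmax(mu, 0.02), 0.98))

  ## sex blocks: overwrite the X/Y baselines with sex-dimorphic levels
  xi <- which(chrom == "X"); yi <- which(chrom == "Y")
  male <- sex == "M"
  eta[male, xi] <- logit(0.20); eta[!male, xi] <- logit(0.50)
  eta[male, yi] <- logit(0.70); eta[!male, yi] <- logit(0.05)

  if (k_latent >= 1L) eta <- eta + scores %*% loadings
  dx <- as.numeric(outcome == "ASD")
  eta <- eta + outer(dx, delta_j)
  if (noise_sd > 0) eta <- eta + matrix(stats::rnorm(n_samples * n_cpgs, 0, noise_sd),
                                        n_samples, n_cpgs)
  beta <- t(expit(eta))
  dimnames(beta) <- list(probe_ids, sample_ids)

  ## --- detection p-values: background-level, with rare planted failures
  detp <- matrix(stats::runif(n_cpgs * n_samples, 0, 0.005), n_cpgs, n_samples,
                 dimnames = dimnames(beta))
  n_fail <- stats::rbinom(1L, n_cpgs * n_samples, detection_fail_rate)
  if (n_fail > 0) {
    idx <- sample.int(n_cpgs * n_samples, n_fail)
    detp[idx] <- stats::runif(n_fail, 0.02, 0.5)
  }

  truth <- list(cell_profiles = profiles, mixing = mixing,
                latent_scores = scores, latent_loadings = loadings,
                effect_cpgs = effect_cpgs, delta = delta, delta_logit = delta_j,
                risk_genes = risk_genes, seed = seed)
  list(beta = beta, detp = detp, annotation = annotation, sheet = sheet,
       risk_genes = risk_genes, truth = truth)
}

cord_cell_types <- function(n) {
  base <- c("Gran", "CD4T", "CD8T", "Bcell", "nRBC", "Mono", "NK")
  if (n <= length(base)) base[seq_len(n)] else c(base, sprintf("Cell%d", seq_len(n - length(base))))
}

# Cord-blood-like mean proportions for the first seven types; uniform beyond.
cord_cell_means <- function(n) {
  base <- c(0.43, 0.19, 0.13, 0.11, 0.10, 0.08, 0.01)
  m <- if (n <= length(base)) base[seq_len(n)] else c(base, rep(0.05, n - length(base)))
  m / sum(m)
}

#' Build a cell-type reference panel from simulation truth
#'
#' Restricts the true cell-type profiles to probes with large between-type
#' contrast, emulating a sorted-cell reference signature panel.
#'
#' @param truth `truth` element from [simulate_dataset()].
#' @param per_type Discriminating probes kept per cell type and direction.
#' @return List with `profiles` (cell-type-by-probe betas at the selected
#'   probes) and `probes`.
#' @export
make_reference_panel <- function(truth, per_type = 50) {
  profiles <- truth$cell_profiles
  if (nrow(profiles) < 2L) stop2("need at least 2 cell types")
  probes <- select_discriminating_probes(profiles, per_type = per_type,
                                         min_contrast = 0.05)
  list(profiles = profiles[, probes, drop = FALSE], probes = probes)
}

#' Write a simulated dataset to a directory of delimited text files
#'
#' Writes the beta matrix, detection p-values, annotation, sample sheet and
#' risk-gene list in the same formats the readers consume; the truth object
#' is serialized as YAML-style text for recovery tests.
#'
#' @param sim Output of [simulate_dataset()].
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_dataset <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_beta_matrix(sim$beta, file.path(dir, "beta.tsv"))
  write_beta_matrix(sim$detp, file.path(dir, "detection_p.tsv"))
  write_cpg_annotation(sim$annotation, file.path(dir, "annotation.tsv"))
  write_sample_sheet(sim$sheet, file.path(dir, "samples.tsv"))
  writeLines(sim$risk_genes$genes, file.path(dir, "risk_genes.txt"))
  panel <- make_reference_panel(sim$truth)
  write_beta_matrix(panel$profiles, file.path(dir, "reference.tsv"),
                    id_col = "cell_type")
  writeLines(yaml::as.yaml(list(seed = sim$truth$seed, delta = sim$truth$delta,
                                effect_cpgs = sim$truth$effect_cpgs)),
             file.path(dir, "truth.yaml"))
  invisible(dir)
}
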