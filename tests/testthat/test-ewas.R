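test_that("two-group fit without covariates equals the difference of group means", {
  sim <- simulate_dataset(n_samples = 50, n_cpgs = 500, k_latent = 0, seed = 14)
  res <- fit_sitewise(sim$beta, sim$sheet, moderate = FALSE)
  sheet <- sim$sheet
  asd <- sheet$sample_id[sheet$outcome == "ASD"]
  td <- sheet$sample_id[sheet$outcome == "TD"]
  manual <- (rowMeans(sim$beta[, asd]) - rowMeans(sim$beta[, td])) * 100
  expect_equal(res$effect_percent, unname(manual), tolerance = 1e-10)
  expect_equal(res$n_used, rep(length(asd) + length(td), 500))
  # nonTD contrast drops the ASD group instead
  res2 <- fit_sitewise(sim$beta, sim$sheet, contrast = "nonTD-vs-TD",
                       moderate = FALSE)
  nontd <- sheet$sample_id[sheet$outcome == "nonTD"]
  manual2 <- (rowMeans(sim$beta[, nontd]) - rowMeans(sim$beta[, td])) * 100
  expect_equal(res2$effect_percent, unname(manual2), tolerance = 1e-10)
  expect_equal(attr(res2, "contrast"), "nonTD-vs-TD")
})

test_that("a probe with identical group values gives zero effect and p near 1", {
  b <- rand_beta(20, 30, seed = 15)
  sheet <- tiny_sheet(rep(c("ASD", "TD"), each = 15))
  colnames(b) <- sheet$sample_id
  vals <- seq(0.3, 0.39, length.out = 15)
  b[1, sheet$outcome == "ASD"] <- vals      # identical values in both groups
  b[1, sheet$outcome == "TD"] <- vals
  res <- fit_sitewise(b, sheet, moderate = FALSE)
  expect_equal(res$effect_percent[1], 0, tolerance = 1e-10)
  expect_equal(res$t_moderated[1], 0, tolerance = 1e-10)
  expect_equal(res$p_value[1], 1, tolerance = 1e-10)
})

test_that("planted effects are recovered at mid-methylation CpGs", {
  sim <- simulate_dataset(n_samples = 120, n_cpgs = 6000, k_latent = 0,
                          spike_fraction = 0.3, delta = 0.05, seed = 7)
  res <- fit_sitewise(sim$beta, sim$sheet)
  eff <- sim$truth$effect_cpgs
  idx <- match(eff, res$probe_id)
  mid <- res$mean_percent[idx] > 35 & res$mean_percent[idx] < 65
  sgn <- sign(sim$truth$delta_logit[eff])
  est <- res$effect_percent[idx] * sgn
  expect_gt(sum(mid), 10)
  expect_true(median(est[mid]) > 4 && median(est[mid]) < 6)
})

test_that("moderation hyperparameters are recovered and match limma", {
  set.seed(42)
  d <- 16
  sigma2 <- 4 * 0.04 / rchisq(10000, 4)          # scaled-inv-chisq(d0=4, s0^2=0.04)
  s2 <- sigma2 * rchisq(10000, d) / d
  mod <- moderate_variances(s2, d)
  expect_gt(mod$d0, 3); expect_lt(mod$d0, 5)
  expect_gt(mod$s0_sq, 0.035); expect_lt(mod$s0_sq, 0.045)
  sq <- limma::squeezeVar(s2, d)
  expect_equal(mod$d0, sq$df.prior, tolerance = 1e-6)
  expect_equal(mod$s0_sq, sq$var.prior, tolerance = 1e-6)
  expect_equal(mod$post_var, sq$var.post, tolerance = 1e-8)
})

test_that("moderation limits behave as theory dictates", {
  # homogeneous variances: infinite prior df, posterior equals the common value
  mod <- moderate_variances(rep(0.04, 500), 10)
  expect_equal(mod$d0, Inf)
  expect_equal(mod$s0_sq, 0.04)
  expect_equal(mod$post_var, rep(0.04, 500), tolerance = 1e-10)
  # no-shrinkage limit: with the prior df forced to 0 the posterior variance
  # is the per-probe variance, so t is the ordinary t
  s2 <- rexp(100) + 0.01
  expect_equal((0 * 1 + 8 * s2) / (0 + 8), s2)
  # excluded nonpositive variances keep finite output length
  s2 <- c(0, NA, rexp(200) + 0.01)
  mod2 <- moderate_variances(s2, 8)
  expect_equal(length(mod2$post_var), length(s2))
})

test_that("moderated tests agree with the limma pipeline end to end", {
  sim <- simulate_dataset(n_samples = 60, n_cpgs = 1000, k_latent = 0, seed = 16)
  res <- fit_sitewise(sim$beta, sim$sheet)
  sheet <- sim$sheet
  use <- sheet$outcome %in% c("ASD", "TD")
  design <- cbind(1, as.numeric(sheet$outcome[use] == "ASD"))
  fit <- limma::eBayes(limma::lmFit(sim$beta[, use], design))
  expect_equal(res$t_moderated, unname(fit$t[, 2]), tolerance = 1e-8)
  expect_equal(res$p_value, unname(fit$p.value[, 2]), tolerance = 1e-8)
})

test_that("summaries report nominal counts and methylation direction", {
  res <- data.frame(probe_id = sprintf("cg%d", 1:10),
                    effect_percent = c(rep(2, 4), rep(-1, 2), rep(0.5, 4)),
                    p_value = c(rep(0.01, 4), rep(0.2, 6)))
  s <- summarize_ewas(res)
  expect_equal(s$n_nominal, 4)
  expect_equal(s$pct_hyper, 100)
  # null simulation: nominal fraction near 5%
  sim <- simulate_dataset(n_samples = 120, n_cpgs = 8000, k_latent = 0,
                          delta = 0, seed = 17)
  r0 <- fit_sitewise(sim$beta, sim$sheet, adjustment = sim$truth$mixing[, -1])
  auto <- !sim$annotation$chrom %in% c("X", "Y")
  frac <- mean(r0$p_value[auto] < 0.05)
  expect_lt(abs(frac - 0.05), 3 * sqrt(0.05 * 0.95 / sum(auto)) + 0.003)
})

test_that("spiked-positive simulations skew hypermethylated among nominal sites", {
  sim <- simulate_dataset(n_samples = 120, n_cpgs = 8000, k_latent = 0,
                          spike_fraction = 0.5, delta = 0.06, seed = 18)
  res <- fit_sitewise(sim$beta, sim$sheet)
  s <- summarize_ewas(res)
  # spiked effects are 70% hypermethylated by construction; nominal sites
  # should lean the same way, as reported for cord blood
  expect_gt(s$pct_hyper, 55)
})

test_that("cross-model effect correlations behave like Pearson r", {
  sim <- simulate_dataset(n_samples = 80, n_cpgs = 3000, k_latent = 0,
                          spike_fraction = 0.5, delta = 0.08, seed = 19)
  res <- fit_sitewise(sim$beta, sim$sheet)
  expect_equal(cross_model_correlation(res, res), 1.0)
  expect_error(cross_model_correlation(res, res[0, ]), "shared probes")
  # beta-scale and M-scale effects are nearly proportional on the same data
  resM <- fit_sitewise(beta_to_m(sim$beta), sim$sheet, scale = "M")
  expect_gt(cross_model_correlation(res, resM), 0.9)
})

test_that("rank-deficient designs error with the aliased term named", {
  sim <- simulate_dataset(n_samples = 30, n_cpgs = 200, seed = 20)
  use <- sim$sheet$outcome %in% c("ASD", "TD")
  dup <- matrix(as.numeric(sim$sheet$outcome == "ASD"), ncol = 1,
                dimnames = list(NULL, "dup_group"))
  expect_error(fit_sitewise(sim$beta, sim$sheet, adjustment = dup),
               "rank-deficient")
})

test_that("BH q-values in results are monotone consistent with p-values", {
  sim <- simulate_dataset(n_samples = 40, n_cpgs = 1000, seed = 21)
  res <- fit_sitewise(sim$beta, sim$sheet)
  o <- order(res$p_value)
  expect_true(all(diff(res$fdr_q[o]) >= -1e-12))
  expect_true(all(res$fdr_q >= res$p_value - 1e-12))
})

test_that("known-covariate adjustment drops incomplete samples per model", {
  sim <- simulate_dataset(n_samples = 60, n_cpgs = 400, k_latent = 0, seed = 26)
  sheet <- sim$sheet
  sheet$maternal_age[1:3] <- NA
  res <- fit_sitewise(sim$beta, sheet,
                      adjustment = c("sex", "batch", "maternal_age"))
  use <- sheet$outcome %in% c("ASD", "TD")
  n_complete <- sum(use & !is.na(sheet$maternal_age))
  expect_equal(unique(res$n_used), n_complete)
  # autosomal effects correlate with the unadjusted fit (sex probes swing
  # wildly once sex enters the model, so they are excluded here)
  res0 <- fit_sitewise(sim$beta, sheet)
  auto <- !sim$annotation$chrom %in% c("X", "Y")
  expect_gt(cross_model_correlation(res[auto, ], res0[auto, ]), 0.8)
  expect_error(fit_sitewise(sim$beta, sheet, adjustment = "not_a_column"),
               "not in sheet")
})
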