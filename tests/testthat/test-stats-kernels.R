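test_that("chi-square test matches the closed 2x2 formula and cohort tables", {
  # proportional table: perfect independence
  prop <- chi_square_test(rbind(c(10, 20), c(5, 10)))
  expect_equal(prop$chi2, 0, tolerance = 1e-12)
  expect_equal(prop$p_value, 1)
  # brute-force closed form N(ad-bc)^2/(r1 r2 c1 c2) on random 2x2 tables
  set.seed(31)
  for (i in 1:20) {
    t2 <- matrix(rpois(4, 40) + 1, 2)
    ours <- chi_square_test(t2)
    closed <- sum(t2) * (t2[1, 1] * t2[2, 2] - t2[1, 2] * t2[2, 1])^2 /
      prod(rowSums(t2)) / prod(colSums(t2))
    expect_equal(ours$chi2, closed, tolerance = 1e-10)
    expect_equal(rowSums(ours$expected), rowSums(t2))
    expect_equal(colSums(ours$expected), colSums(t2))
  }
  big <- chi_square_test(rbind(c(488, 351), c(7742, 10432)))
  expect_equal(big$chi2, 79.1, tolerance = 0.05)
  expect_error(chi_square_test(rbind(c(0, 0), c(1, 2))), "zero margin")
})

test_that("trend test handles extreme, null and constant inputs", {
  # perfectly monotone proportions across 3 groups at large n
  score <- rep(0:2, each = 400)
  v <- c(rbinom(400, 1, 0.1), rbinom(400, 1, 0.5), rbinom(400, 1, 0.9))
  expect_lt(trend_test(score, v)$p_value, 1e-6)
  expect_equal(trend_test(score, rep(1, 1200))$p_value, 1)
  expect_equal(trend_test(score, rep("x", 1200))$p_value, 1)
  # continuous variable uses the regression slope
  set.seed(32)
  tt <- trend_test(rep(0:2, each = 50), rnorm(150) + rep(0:2, each = 50))
  expect_lt(tt$p_value, 1e-6)
  expect_equal(tt$type, "continuous")
})

test_that("trend test is calibrated under an exchangeable null", {
  set.seed(33)
  score <- rep(0:2, times = c(35, 43, 22))
  # continuous variable: p-values exactly uniform under exchangeability
  pv <- replicate(500, trend_test(score, rnorm(100))$p_value)
  expect_gt(stats::ks.test(pv, "punif")$p.value, 0.01)
  # binary variable: discrete statistic, level near nominal
  pv2 <- replicate(500, trend_test(score, rbinom(100, 1, 0.4))$p_value)
  expect_lt(abs(mean(pv2 < 0.05) - 0.05), 3 * sqrt(0.05 * 0.95 / 500) + 0.01)
})

test_that("BH q-values match hand computation and are order invariant", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.04)), c(0.03, 0.03, 0.04))
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  expect_equal(bh_fdr(0.01), 0.01)
  expect_error(bh_fdr(c(0.5, -0.1)), "\\(0, 1\\]")
  p <- c(0.2, NA, 0.001, 0.5)
  q <- bh_fdr(p)
  expect_true(is.na(q[2]))
  set.seed(34)
  p <- runif(200)
  perm <- sample(200)
  expect_equal(bh_fdr(p)[perm], bh_fdr(p[perm]))
})

test_that("inflation lambda matches its definition and planted inflation", {
  expect_equal(inflation_lambda(rep(0.5, 200)), 1.0, tolerance = 1e-6)
  set.seed(35)
  expect_equal(inflation_lambda(runif(10000)), 1.0, tolerance = 0.05)
  # chi-squares inflated by 1.2 -> lambda near 1.2
  chi <- rchisq(10000, 1) * 1.2
  p <- pchisq(chi, 1, lower.tail = FALSE)
  expect_equal(inflation_lambda(p), 1.2, tolerance = 0.05)
  expect_warning(inflation_lambda(runif(50)), "unstable")
})

test_that("Wallenius reduces to the hypergeometric at odds 1", {
  # spec'd worked case: universe 10, category 4, selected 5, observed 4;
  # enumeration over all choose(10,5) = 252 draws
  draws <- combn(10, 5)
  hits <- colSums(draws <= 4)          # genes 1-4 are the category
  p_enum <- mean(hits >= 4)
  expect_equal(wallenius_test(4, 4, 5, 10, odds = 1), p_enum, tolerance = 1e-8)
  # all universes up to 12 genes
  for (N in c(8, 10, 12)) {
    m1 <- 4; n <- 5
    for (x in 0:4) {
      expect_equal(wallenius_test(x, m1, n, N, odds = 1),
                   phyper(x - 1, m1, N - m1, n, lower.tail = FALSE),
                   tolerance = 1e-8)
    }
  }
  # large counts stay accurate
  expect_equal(wallenius_test(488, 839, 8230, 19013, odds = 1),
               phyper(487, 839, 19013 - 839, 8230, lower.tail = FALSE),
               tolerance = 1e-6)
})

test_that("Wallenius with biased odds matches exact urn enumeration", {
  for (pars in list(c(4, 6, 5, 2), c(5, 7, 6, 0.5), c(6, 6, 8, 3))) {
    m1 <- pars[1]; m2 <- pars[2]; n <- pars[3]; w <- pars[4]
    pmf <- wallenius_urn_pmf(m1, m2, n, w)
    for (x in 0:min(m1, n)) {
      expect_equal(wallenius_test(x, m1, n, m1 + m2, odds = w),
                   sum(pmf[(x + 1):(n + 1)]), tolerance = 1e-6)
    }
  }
  # upper-tail probability is monotone nondecreasing in the odds
  ps <- vapply(c(0.2, 0.5, 1, 2, 5, 20),
               function(w) wallenius_test(8, 20, 30, 100, odds = w), numeric(1))
  expect_true(all(diff(ps) > 0))
  expect_error(wallenius_test(2, 4, 5, 10, odds = 0), "positive")
  expect_error(wallenius_test(6, 4, 5, 10), "inconsistent")
})

test_that("cohort summary reproduces printed-style tables and null calibration", {
  set.seed(36)
  n <- 150
  sheet <- tiny_sheet(sample(c("TD", "nonTD", "ASD"), n, replace = TRUE,
                             prob = c(0.35, 0.43, 0.22)),
                      sex = sample(c("M", "F"), n, replace = TRUE))
  sheet$batch <- sample(c("B1", "B2"), n, replace = TRUE)
  sheet$maternal_age <- rnorm(n, 33, 5)
  out <- summarize_cohort(sheet, covariates = c("sex", "batch", "maternal_age"))
  expect_setequal(names(out$p_values), c("sex", "batch", "maternal_age"))
  expect_true(all(out$p_values > 0 & out$p_values <= 1))
  expect_true(all(c("TD", "nonTD", "ASD") %in% colnames(out$table)))
  # independent covariates give roughly uniform p-values
  pv <- replicate(200, {
    sh <- tiny_sheet(sample(c("TD", "nonTD", "ASD"), 120, replace = TRUE),
                     sex = sample(c("M", "F"), 120, replace = TRUE))
    summarize_cohort(sh, covariates = "sex")$p_values[["sex"]]
  })
  expect_gt(suppressWarnings(stats::ks.test(pv, "punif"))$p.value, 0.01)
})
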