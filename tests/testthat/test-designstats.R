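test_that("block correction recenters blocks on the grand mean", {
  x <- c(1, 3, 5, 7)
  b <- c("A", "A", "B", "B")
  got <- block_correct(x, b)
  expect_equal(got, c(3, 5, 3, 5))
  # grand mean preserved, block means equal the grand mean
  expect_equal(mean(got), mean(x))
  expect_equal(as.numeric(tapply(got, b, mean)), c(4, 4))
  # idempotent
  expect_equal(block_correct(got, b), got)
  # a single block is already centred
  expect_equal(block_correct(x, rep("A", 4)), x)
  expect_error(block_correct(c(1, NA), c("A", "B")),
               class = "degenerate_design")
})

test_that("significance codes map boundaries to the stronger code", {
  expect_identical(significance_code(c(0.0005, 0.001, 0.01, 0.05, 0.1, 0.5)),
                   c("***", "***", "**", "*", "\u2020", ""))
  expect_error(significance_code(1.2), class = "invalid_p")
  expect_error(significance_code(-0.1), class = "invalid_p")
})

test_that("mixed-model fit recovers a noiseless linear signal", {
  d <- noise_plots(seed = 31)
  d$y <- 2 + 1.5 * log(d$psr_sown) + rnorm(nrow(d), 0, 1e-8)
  d$psr_log <- log(d$psr_sown)
  fit <- fit_lmm(d, "y", "psr_log")
  expect_equal(fit$coefficients$estimate[fit$coefficients$term == "psr_log"],
               1.5, tolerance = 1e-6)
  expect_s3_class(fit, "micdiv_lmm")
})

test_that("mixed-model fit recovers simulated variance components", {
  set.seed(32)
  n_per_block <- 20
  d <- data.frame(block = rep(1:4, each = n_per_block))
  d$x <- rnorm(nrow(d))
  d$y <- 0.5 * d$x + rnorm(4, 0, 1)[d$block] + rnorm(nrow(d), 0, 0.1)
  fit <- fit_lmm(d, "y", "x")
  expect_lt(abs(fit$varcomp[["resid_sd"]] - 0.1) / 0.1, 0.5)
  expect_gt(fit$varcomp[["block_sd"]], 0.1)
})

test_that("mixed-model fit rejects degenerate designs", {
  d <- noise_plots(seed = 33)
  d$x1 <- rnorm(nrow(d))
  d$x2 <- 2 * d$x1
  expect_error(fit_lmm(d, "y", c("x1", "x2")), class = "collinear_terms")
  d1 <- d[d$block == 1, ]
  expect_error(fit_lmm(d1, "y", "x1"), class = "degenerate_design")
  expect_error(fit_lmm(d, "y", "nope"), class = "schema_error")
})

test_that("likelihood-ratio statistics are nonnegative and nested-monotone", {
  d <- noise_plots(seed = 34)
  d$psr_log <- log(d$psr_sown)
  m0 <- fit_lmm(d, "y")
  m1 <- fit_lmm(d, "y", "psr_log")
  expect_gte(m1$logLik, m0$logLik - 1e-8)
  lt <- lr_test(m1, m0)
  expect_gte(lt$L, 0)
  expect_true(lt$p >= 0 && lt$p <= 1)
})

test_that("sequential tests flag a planted richness effect and only it", {
  ds <- generate_synthetic_dataset(synth_config(seed = 35))
  d <- merge(ds$plots, ds$truth$latent[c("plot_id", "growth", "cmic")])
  res <- sequential_lr_tests(d, "cmic", transforms = NULL)
  expect_identical(res$term, c("PSR_log", "PFGR", "SH", "TH", "GR", "LEG"))
  expect_identical(res$df, rep(1L, 6))
  psr <- res[res$term == "PSR_log", ]
  expect_lt(psr$p, 0.001)
  expect_identical(psr$direction, 1)
  # reversed order still finds the richness effect
  rev <- sequential_lr_tests(d, "cmic", order = "pfgr-first", transforms = NULL)
  expect_lt(rev[rev$term == "PSR_log", "p"], 0.001)
  expect_error(sequential_lr_tests(d[setdiff(names(d), "pfgr")], "cmic"),
               "pfgr", class = "schema_error")
})

test_that("a constant response yields zero likelihood-ratio statistics", {
  d <- noise_plots(seed = 36)
  d$flat <- 10
  res <- sequential_lr_tests(d, "flat", transforms = NULL)
  expect_equal(res$L, rep(0, 6))
  expect_equal(res$p, rep(1, 6))
  expect_equal(res$direction, rep(0, 6))
})

test_that("likelihood-ratio test of richness holds its nominal size", {
  set.seed(37)
  cfg <- synth_config(seed = 37)
  d <- generate_design(cfg)
  d$psr_log <- log(d$psr_sown)
  reps <- 500
  rej <- logical(reps)
  for (r in seq_len(reps)) {
    d$y <- rnorm(nrow(d))
    lt <- lr_test(fit_lmm(d, "y", "psr_log"), fit_lmm(d, "y"))
    rej[r] <- lt$p < 0.05
  }
  expect_gte(mean(rej), 0.03)
  expect_lte(mean(rej), 0.08)
})

test_that("correlation matrix is symmetric with t-based p-values", {
  set.seed(38)
  d <- data.frame(x = rnorm(30))
  d$y <- -d$x
  d$z <- rnorm(30)
  cm <- correlation_matrix(d, c("x", "y", "z"))
  expect_equal(diag(cm$r), c(x = 1, y = 1, z = 1))
  expect_equal(cm$r, t(cm$r))
  expect_equal(cm$r["x", "y"], -1)
  expect_lt(cm$p["x", "y"], 1e-12)
  # independent noise: moderate r, two-sided t p-value matches cor.test
  ct <- cor.test(d$x, d$z)
  expect_equal(cm$p["x", "z"], ct$p.value)
  d$const <- 1
  expect_error(correlation_matrix(d, c("x", "const")),
               "const", class = "undefined_correlation")
  expect_error(correlation_matrix(d[1:2, ], c("x", "y")),
               class = "degenerate_design")
})

test_that("biomass and soil carbon dominate the generated correlation matrix", {
  ds <- generate_synthetic_dataset(synth_config(seed = 39))
  res <- run_pipeline(ds$plots, ds$incubation, ds$isotope, ds$cfe, ds$dna,
                      ds$aminosugars, lmm_responses = "soc")
  r <- res$correlations$r
  expect_gt(r["cmic", "soc"], 0)
  # biomass is soil carbon's strongest correlate
  soc_r <- r["soc", setdiff(colnames(r), "soc")]
  expect_equal(names(which.max(soc_r)), "cmic")
})
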