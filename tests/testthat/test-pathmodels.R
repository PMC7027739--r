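test_that("path models parse edges and reject cycles", {
  m <- path_model(c("a -> b", "b -> c"))
  expect_identical(m$vertices, c("a", "b", "c"))
  expect_identical(m$parents$c, "b")
  expect_identical(m$exogenous, "a")
  expect_error(path_model(c("a -> b", "b -> a")), class = "not_a_dag")
  expect_error(path_model("a -> a"), class = "not_a_dag")
  expect_error(path_model("a -- b"), class = "parse_error")
})

test_that("path model files round-trip edges and the transform header", {
  f <- tempfile(fileext = ".txt")
  on.exit(unlink(f))
  writeLines(c("# transforms: psr_sown=log root_c=log",
               "# a comment",
               "psr_sown -> root_c",
               "root_c -> soc"), f)
  m <- read_path_model(f)
  expect_identical(nrow(m$edges), 2L)
  expect_identical(m$transforms[["root_c"]], "log")
})

test_that("basis set handles the textbook chain and the saturated triangle", {
  chain <- path_model(c("a -> b", "b -> c"))
  claims <- basis_set(chain)
  expect_length(claims, 1L)
  expect_identical(claims[[1]]$x, "a")
  expect_identical(claims[[1]]$y, "c")
  expect_identical(claims[[1]]$cond, "b")

  full <- path_model(c("a -> b", "a -> c", "b -> c"))
  expect_length(basis_set(full), 0L)
})

test_that("the default causal chain implies seven independence claims", {
  m <- default_path_model()
  claims <- basis_set(m)
  expect_length(claims, 7L)
  expect_identical(canonical_claims(claims),
                   oracle_basis_claims(m$vertices, m$edges))
})

test_that("basis set equals brute-force enumeration on all 4-vertex DAGs", {
  dags <- enumerate_dags(c("a", "b", "c", "d"))
  expect_gt(length(dags), 500)   # 543 labeled DAGs minus the empty graph
  for (edges in dags) {
    m <- path_model(edges)
    expect_identical(canonical_claims(basis_set(m)),
                     oracle_basis_claims(m$vertices, edges))
  }
})

test_that("Fisher's C follows the -2 sum log p arithmetic", {
  expect_equal(fishers_c(rep(1, 5)), list(C = 0, df = 10L, p = 1))
  fc <- fishers_c(rep(exp(-1), 7))
  expect_equal(fc$C, 14)
  expect_identical(fc$df, 14L)
  expect_equal(fc$p, pchisq(14, 14, lower.tail = FALSE))
  expect_error(fishers_c(numeric(0)), class = "invalid_p")
  expect_error(fishers_c(c(0.5, 1.2)), class = "invalid_p")
  expect_warning(fc0 <- fishers_c(c(0, 0.5)), class = "p_floor_warning")
  expect_true(is.finite(fc0$C))
})

test_that("d-separation p-values detect dependence and respect mediation", {
  d <- noise_plots(seed = 51)
  d$x <- rnorm(nrow(d))
  d$yy <- d$x
  p_dep <- dsep_pvalue(list(x = "x", y = "yy", cond = character(0)), d)
  expect_lt(as.numeric(p_dep), 1e-12)
  # y depends on x only through m: conditioning on m removes the signal
  d$m <- 0.8 * d$x + rnorm(nrow(d), 0, 0.6)
  d$y2 <- 0.8 * d$m + rnorm(nrow(d), 0, 0.6)
  p_med <- dsep_pvalue(list(x = "x", y = "y2", cond = "m"), d)
  expect_gt(as.numeric(p_med), 1e-4)
})

test_that("SEM fit exposes standardized coefficients and fit indices", {
  ds <- generate_synthetic_dataset(synth_config(seed = 52))
  fit <- sem_fit(default_path_model(), ds$truth$latent)
  pc <- fit$path_coefficients
  # standardization identity: beta = raw x SD(parent)/SD(child)
  expect_equal(pc$std_beta,
               pc$estimate * fit$sds[pc$from] / fit$sds[pc$to],
               ignore_attr = TRUE)
  expect_identical(fit$fisher_c$df, 14L)
  expect_gte(fit$fisher_c$C, 0)
  expect_identical(fit$K, 13L)   # 5 intercepts + 8 slopes
  expect_equal(fit$aic, fit$fisher_c$C + 2 * 13)
  expect_gt(fit$aicc, fit$aic)
  expect_true(all(fit$r2[, "r2_conditional"] >= fit$r2[, "r2_marginal"]))
  expect_true(all(fit$r2 >= 0 & fit$r2 <= 1))
})

test_that("a saturated model reports the perfect-fit sentinel", {
  set.seed(53)
  d <- data.frame(a = rnorm(40), block = rep(1:4, 10))
  d$b <- 0.5 * d$a + rnorm(40, 0, 0.5)
  d$c <- 0.5 * d$b + 0.3 * d$a + rnorm(40, 0, 0.5)
  fit <- sem_fit(path_model(c("a -> b", "a -> c", "b -> c")), d)
  expect_equal(fit$fisher_c$C, 0)
  expect_identical(fit$fisher_c$df, 0L)
  expect_true(is.na(fit$fisher_c$p))
})

test_that("an omitted true path surfaces as a candidate missing path", {
  ds <- generate_synthetic_dataset(synth_config(seed = 54))
  # drop the biomass -> SOC edge from the fitted structure
  m <- path_model(c("psr_sown -> root_c", "psr_sown -> growth",
                    "psr_sown -> cmic", "root_c -> growth", "root_c -> cmic",
                    "growth -> cmic", "growth -> resp", "psr_sown -> soc"),
                  transforms = sem_default_transforms())
  fit <- sem_fit(m, ds$truth$latent)
  expect_true(any(with(fit$missing_paths,
                       (x == "cmic" & y == "soc") | (x == "soc" & y == "cmic"))))
})

test_that("indirect effects multiply standardized coefficients along paths", {
  mock <- structure(list(
    model = path_model(c("a -> b", "b -> c", "a -> c")),
    path_coefficients = data.frame(
      from = c("a", "b", "a"), to = c("b", "c", "c"),
      std_beta = c(0.5, 0.4, 0.2), stringsAsFactors = FALSE)
  ), class = "micdiv_sem")
  ie <- indirect_effects(mock, "a", "c")
  expect_equal(nrow(ie$paths), 1L)   # the direct edge is not an indirect path
  expect_equal(ie$total, 0.2)
  expect_equal(indirect_effects(mock, "a", "a")$total, 0)
  expect_equal(nrow(indirect_effects(mock, "b", "a")$paths), 0L)
  expect_error(indirect_effects(mock, "a", "zzz"), class = "unknown_vertex")
})

test_that("richness-to-biomass mediation splits into its two channels", {
  ds <- generate_synthetic_dataset(synth_config(seed = 55))
  fit <- sem_fit(default_path_model(), ds$truth$latent)
  ie <- indirect_effects(fit, "psr_sown", "cmic")
  expect_identical(sort(ie$paths$path), sort(c(
    "psr_sown -> growth -> cmic",
    "psr_sown -> root_c -> cmic",
    "psr_sown -> root_c -> growth -> cmic")))
  expect_equal(ie$total, sum(ie$paths$effect))
})
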