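test_that("the default design reproduces the experimental layout", {
  d <- generate_design(synth_config(seed = 61))
  expect_identical(nrow(d), 81L)
  expect_identical(sort(unique(d$psr_sown)), c(1L, 2L, 4L, 8L, 16L, 60L))
  expect_identical(unname(table(d$psr_sown)[c("1", "2", "4", "8", "16", "60")]),
                   table(rep(1:6, c(15, 16, 16, 16, 14, 4)))[1:6],
                   ignore_attr = TRUE)
  expect_identical(sort(unique(d$block)), 1:4)
  # every block spans the richness gradient
  expect_true(all(tapply(d$psr_sown, d$block, function(x) length(unique(x))) == 6))
  # functional-group richness consistent with species richness and flags
  expect_true(all(d$pfgr >= 1 & d$pfgr <= pmin(d$psr_sown, 4)))
  flags <- d[c("has_grasses", "has_legumes", "has_small_herbs", "has_tall_herbs")]
  expect_identical(rowSums(flags), as.numeric(d$pfgr))
  mono <- d[d$psr_sown == 1, ]
  expect_true(all(mono$pfgr == 1))
})

test_that("generation is deterministic under a fixed seed", {
  a <- generate_synthetic_dataset(synth_config(seed = 62))
  b <- generate_synthetic_dataset(synth_config(seed = 62))
  expect_identical(a, b)
  c <- generate_synthetic_dataset(synth_config(seed = 63))
  expect_false(identical(a$plots$soc, c$plots$soc))
})

test_that("latent variables match their target scales and stay positive", {
  cfg <- synth_config(seed = 64)
  lat <- generate_latent(generate_design(cfg), cfg)
  sp <- cfg$scale_params
  for (v in sp$variable) {
    expect_true(all(lat[[v]] > 0), info = v)
    tgt <- sp[sp$variable == v, ]
    expect_lt(abs(mean(lat[[v]]) - tgt$mean) / tgt$sd, 0.6)
  }
  expect_true(all(lat$cue > 0 & lat$cue < 1))
})

test_that("generated means rise monotonically from monoculture to mixture", {
  ds <- generate_synthetic_dataset(synth_config(seed = 65))
  lat <- ds$truth$latent
  sm <- summarize_by_psr(lat, c("soc", "cmic", "growth", "necromass_fungal"))
  for (v in c("soc", "cmic", "growth", "necromass_fungal")) {
    m <- sm[[paste0(v, "_mean")]]
    expect_gt(m[length(m)], m[1])
  }
})

test_that("a null configuration generates no causal signal", {
  pb <- default_path_beta()
  pb[] <- 0
  ds <- generate_synthetic_dataset(synth_config(seed = 66, path_beta = pb))
  lat <- ds$truth$latent
  expect_lt(abs(cor(lat$cmic, lat$soc)), 0.3)
  fit <- sem_fit(default_path_model(), lat)
  expect_lte(sum(fit$path_coefficients$p < 0.05), 2L)
})

test_that("raw tables invert the measurement equations exactly", {
  cfg <- synth_config(seed = 67)
  ds <- generate_synthetic_dataset(cfg)
  lat <- ds$truth$latent
  # the written DCO2 equals the ideal-gas inverse of the latent respiration
  back <- oracle_respiration(ds$incubation$dco2_ppm, cfg$dw_g, cfg$t_hr,
                             cfg$p_kpa, cfg$temp_k, cfg$vhs_l)
  expect_equal(back, lat$resp, tolerance = 1e-12)
  # zero latent growth would need zero at% excess
  expect_equal(ds$isotope$atpct_labeled - ds$isotope$atpct_na > 0,
               lat$growth > 0)
})

test_that("pipeline recovery of the latent truth is exact per plot", {
  ds <- generate_synthetic_dataset(synth_config(seed = 68))
  res <- run_pipeline(ds$plots, ds$incubation, ds$isotope, ds$cfe, ds$dna,
                      ds$aminosugars, lmm_responses = "soc")
  tr <- ds$truth$latent
  m <- res$plot_data[match(tr$plot_id, res$plot_data$plot_id), ]
  rel <- function(a, b) max(abs(a - b) / pmax(abs(b), .Machine$double.eps))
  expect_lt(rel(m$respiration, tr$resp), 1e-9)
  expect_lt(rel(m$growth, tr$growth), 1e-9)
  expect_lt(rel(m$cmic, tr$cmic), 1e-9)
  expect_lt(rel(m$cue, tr$cue), 1e-9)
  expect_lt(rel(m$necromass_fungal, tr$necromass_fungal), 1e-9)
  expect_lt(rel(m$necromass_bacterial, tr$necromass_bacterial), 1e-9)
})

test_that("infeasible configurations are rejected up front", {
  expect_error(synth_config(seed = -5), class = "invalid_config")
  pb <- default_path_beta()
  pb["cmic->soc"] <- 1.2
  expect_error(synth_config(path_beta = pb), class = "invalid_config")
  # jointly infeasible coefficients: implied variance above one
  pb <- default_path_beta()
  pb["psr_sown->growth"] <- 0.8
  pb["root_c->growth"] <- 0.8
  cfg <- synth_config(seed = 69, path_beta = pb)
  expect_error(generate_latent(generate_design(cfg), cfg),
               class = "invalid_config")
  # growth unrepresentable with a nearly empty DNA extract
  cfg2 <- synth_config(seed = 70, o_total_ug = 1e-3)
  lat <- generate_latent(generate_design(cfg2), cfg2)
  expect_error(generate_raw_tables(lat, cfg2), class = "config_scale")
})

test_that("datasets round-trip through CSV serialisation", {
  ds <- generate_synthetic_dataset(synth_config(seed = 71))
  dir <- tempfile("synth")
  on.exit(unlink(dir, recursive = TRUE))
  write_synthetic_dataset(ds, dir)
  expect_true(all(file.exists(file.path(dir, c(
    "plots.csv", "incubation.csv", "isotope.csv", "cfe.csv", "dna.csv",
    "aminosugars.csv", "truth.json")))))
  inc <- read.csv(file.path(dir, "incubation.csv"))
  expect_equal(inc$dco2_ppm, ds$incubation$dco2_ppm, tolerance = 1e-12)
})
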