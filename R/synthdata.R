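# Synthetic-data generator: experimental design, latent causal variables,
# and instrument-level raw tables obtained by inverting the measurement
# equations, so that the full pipeline round-trips exactly.

#' Default standardized path coefficients for the generator
#'
#' Direct effects of log species richness on root carbon, growth and
#' microbial biomass; root carbon feeding growth and biomass; growth
#' feeding biomass and respiration; biomass driving soil organic carbon and
#' (together with richness) fungal necromass. The root-carbon coefficients
#' are set so that the mediated effects (richness via root carbon on
#' growth, and via root carbon / via growth on biomass) take realistic
#' magnitudes of about .15, .06 and .09.
#'
#' @return Named numeric vector, names of the form `"from->to"`.
#' @export
default_path_beta <- function() {
  c("psr_sown->root_c" = 0.40,
    "psr_sown->growth" = 0.25,
    "root_c->growth" = 0.375,
    "psr_sown->cmic" = 0.42,
    "root_c->cmic" = 0.15,
    "growth->cmic" = 0.36,
    "growth->resp" = 0.41,
    "cmic->soc" = 0.68,
    "psr_sown->necromass_fungal" = 0.30,
    "cmic->necromass_fungal" = 0.30,
    "psr_sown->soil_cn" = 0.30,
    "psr_sown->root_cn" = 0.20,
    "psr_sown->doc" = 0.20)
}

#' Default target scales for the generated variables
#'
#' Each generated variable is rescaled from the standardized latent scale
#' to a target mean and SD. Where the reference summary
#' ([psr_reference_summary()]) covers a variable, its pooled (within +
#' between PSR level) moments are used; bacterial necromass and dissolved
#' organic carbon, which the reference table does not report, use typical
#' temperate-grassland topsoil values. Root biomass carbon is generated
#' log-normally (its distribution is strongly right-skewed, coefficient of
#' variation near 0.8); all other variables are Gaussian with positivity
#' enforced by resampling.
#'
#' @return Data frame with columns `variable`, `mean`, `sd`, `dist`.
#' @export
default_scale_params <- function() {
  ref <- psr_reference_summary()
  vars <- c("soc", "soil_cn", "root_c", "root_cn", "cmic", "growth", "resp",
            "necromass_fungal")
  mom <- t(vapply(vars, function(v) pooled_moments(ref, v), c(mean = 0, sd = 0)))
  out <- data.frame(variable = vars, mean = mom[, "mean"], sd = mom[, "sd"],
                    dist = "normal", row.names = NULL,
                    stringsAsFactors = FALSE)
  out$dist[out$variable == "root_c"] <- "lognormal"
  rbind(out,
        data.frame(variable = c("necromass_bacterial", "doc"),
                   mean = c(1.2, 100), sd = c(0.25, 25),
                   dist = "normal", stringsAsFactors = FALSE))
}

#' Configuration for the synthetic-data generator
#'
#' @param seed Integer root seed; all randomness in the generator flows
#'   from it through fixed per-stage substreams.
#' @param n_per_psr Named integer vector: number of plots per sown species
#'   richness level.
#' @param n_blocks Number of blocks in the randomized block design.
#' @param path_beta Standardized causal coefficients, see
#'   [default_path_beta()].
#' @param block_sd SD of the per-vertex block intercepts on the
#'   standardized scale.
#' @param scale_params Target means/SDs per variable, see
#'   [default_scale_params()].
#' @param identity_effects If `TRUE`, adds opposite functional-group
#'   identity effects on root carbon (grasses positive, legumes negative)
#'   of magnitude `identity_delta` on the standardized scale.
#' @param identity_delta Size of the identity effects.
#' @param f_dna Target DNA-to-biomass conversion factor, ug C per ug DNA.
#' @param k_ec Fumigation extraction efficiency factor.
#' @param t_hr,temp_k,p_kpa,vhs_l,dw_g Incubation geometry: time (hours),
#'   gas temperature (K), pressure (kPa), headspace volume (L), soil dry
#'   mass (g).
#' @param atpct_label 18O enrichment of soil water, at%.
#' @param atpct_na Natural-abundance at% 18O of control DNA.
#' @param o_total_ug Total oxygen in the dried DNA extract, ug.
#' @param c_unfumigated Mean extractable organic C of unfumigated samples,
#'   ug C g^-1 dry weight.
#' @return Object of class `micdiv_synth_config`.
#' @export
synth_config <- function(seed = 1L,
                         n_per_psr = c("1" = 15L, "2" = 16L, "4" = 16L,
                                       "8" = 16L, "16" = 14L, "60" = 4L),
                         n_blocks = 4L,
                         path_beta = default_path_beta(),
                         block_sd = 0.15,
                         scale_params = default_scale_params(),
                         identity_effects = FALSE,
                         identity_delta = 0.3,
                         f_dna = 50,
                         k_ec = 0.45,
                         t_hr = 24,
                         temp_k = 295.15,
                         p_kpa = 101.325,
                         vhs_l = 0.02,
                         dw_g = 2,
                         atpct_label = 97,
                         atpct_na = 0.2,
                         o_total_ug = 25,
                         c_unfumigated = 140) {
  seed <- as.integer(seed)
  if (is.na(seed) || seed < 0L || seed > .Machine$integer.max - 10L) {
    md_stop("seed must be a nonnegative 32-bit integer", "invalid_config")
  }
  if (any(n_per_psr <= 0) || is.null(names(n_per_psr))) {
    md_stop("n_per_psr must be a named vector of positive counts",
            "invalid_config")
  }
  if (any(abs(path_beta) >= 1)) {
    md_stop("standardized path coefficients must satisfy |beta| < 1",
            "invalid_config")
  }
  if (block_sd < 0 || any(scale_params$sd <= 0) ||
      f_dna <= 0 || k_ec <= 0 || k_ec > 1 ||
      any(c(t_hr, temp_k, p_kpa, vhs_l, dw_g, atpct_label, o_total_ug) <= 0)) {
    md_stop("scale, measurement and design parameters must be positive",
            "invalid_config")
  }
  structure(list(
    seed = seed, n_per_psr = n_per_psr, n_blocks = as.integer(n_blocks),
    path_beta = path_beta, block_sd = block_sd, scale_params = scale_params,
    identity_effects = identity_effects, identity_delta = identity_delta,
    f_dna = f_dna, k_ec = k_ec, t_hr = t_hr, temp_k = temp_k, p_kpa = p_kpa,
    vhs_l = vhs_l, dw_g = dw_g, atpct_label = atpct_label,
    atpct_na = atpct_na, o_total_ug = o_total_ug,
    c_unfumigated = c_unfumigated
  ), class = "micdiv_synth_config")
}

#' Generate the experimental design table
#'
#' Plots at each sown species richness level are spread round-robin over
#' the blocks (so every block covers the whole richness gradient);
#' functional-group richness is drawn uniformly from 1..min(PSR, 4) and the
#' identity flags mark exactly that many distinct functional groups.
#'
#' @param cfg A [synth_config()].
#' @return Data frame of plot records: `plot_id`, `block`, `psr_sown`,
#'   `pfgr`, `has_grasses`, `has_legumes`, `has_small_herbs`,
#'   `has_tall_herbs`.
#' @export
generate_design <- function(cfg) {
  set.seed(cfg$seed + 1L)
  psr_levels <- as.integer(names(cfg$n_per_psr))
  psr <- rep(psr_levels, times = cfg$n_per_psr)
  n <- length(psr)
  block <- integer(n)
  for (lv in psr_levels) {
    idx <- which(psr == lv)
    block[idx] <- rep(sample.int(cfg$n_blocks), length.out = length(idx))
  }
  pfgr <- vapply(psr, function(s) sample.int(min(s, 4L), 1L), 0L)
  groups <- c("has_grasses", "has_legumes", "has_small_herbs", "has_tall_herbs")
  flags <- matrix(FALSE, n, 4L, dimnames = list(NULL, groups))
  for (i in seq_len(n)) flags[i, sample.int(4L, pfgr[i])] <- TRUE
  data.frame(plot_id = sprintf("P%03d", seq_len(n)), block = block,
             psr_sown = psr, pfgr = pfgr, flags,
             stringsAsFactors = FALSE)
}

#' Generate latent plot-level variables from the causal system
#'
#' A linear recursive system on the standardized scale: each endogenous
#' variable is a beta-weighted sum of its (standardized) parents plus an
#' independent block intercept and residual noise, with the residual
#' variance chosen so that every variable has unit variance on the latent
#' scale. Standardized values are then rescaled to the target means/SDs of
#' the configuration; Gaussian variables are kept positive by redrawing the
#' residual of offending plots, log-normal variables are positive by
#' construction. Variables with no incoming path coefficient are pure
#' block + noise.
#'
#' @param design Output of [generate_design()].
#' @param cfg A [synth_config()].
#' @return The design data frame extended with the latent variables
#'   (`root_c`, `growth`, `resp`, `cmic`, `soc`, `necromass_fungal`,
#'   `necromass_bacterial`, `soil_cn`, `root_cn`, `doc`) and derived `cue`.
#' @export
generate_latent <- function(design, cfg) {
  set.seed(cfg$seed + 2L)
  n <- nrow(design)
  pb <- cfg$path_beta
  ft <- strsplit(names(pb), "->", fixed = TRUE)
  edges <- data.frame(from = vapply(ft, `[`, "", 1L),
                      to = vapply(ft, `[`, "", 2L),
                      beta = as.numeric(pb), stringsAsFactors = FALSE)
  vars <- cfg$scale_params$variable
  order_all <- topological_order(unique(c("psr_sown", edges$from, edges$to, vars)),
                                 edges[c("from", "to")])
  order_latent <- setdiff(order_all, "psr_sown")
  missing_scale <- setdiff(order_latent, vars)
  if (length(missing_scale) > 0L) {
    md_stop(sprintf("no scale parameters for variable(s): %s",
                    paste(missing_scale, collapse = ", ")), "invalid_config")
  }

  z <- list(psr_sown = as.numeric(scale(log(design$psr_sown))))
  sigma <- matrix(1, 1, 1, dimnames = list("psr_sown", "psr_sown"))
  out <- design

  for (v in order_latent) {
    pa <- edges$from[edges$to == v]
    b <- edges$beta[edges$to == v]
    explained <- if (length(pa)) {
      as.numeric(t(b) %*% sigma[pa, pa, drop = FALSE] %*% b)
    } else 0
    eps2 <- 1 - explained - cfg$block_sd^2
    if (eps2 <= 0) {
      md_stop(sprintf(
        "path coefficients for '%s' imply variance > 1 (explained = %.3f)",
        v, explained + cfg$block_sd^2), "invalid_config")
    }
    mu_v <- if (length(pa)) {
      as.numeric(as.matrix(as.data.frame(z[pa])) %*% b)
    } else rep(0, n)
    if (cfg$identity_effects && v == "root_c") {
      mu_v <- mu_v + cfg$identity_delta * (design$has_grasses - design$has_legumes)
    }
    be <- stats::rnorm(cfg$n_blocks, 0, cfg$block_sd)[design$block]
    eps <- stats::rnorm(n, 0, sqrt(eps2))
    zv <- mu_v + be + eps

    sp <- cfg$scale_params[cfg$scale_params$variable == v, ]
    if (sp$dist == "lognormal") {
      s2 <- log(1 + (sp$sd / sp$mean)^2)
      val <- exp(log(sp$mean) - s2 / 2 + sqrt(s2) * zv)
    } else {
      val <- sp$mean + sp$sd * zv
      tries <- 0L
      while (any(val <= 0)) {
        tries <- tries + 1L
        if (tries > 1000L) {
          md_stop(sprintf("cannot keep '%s' positive at the configured scale", v),
                  "config_scale")
        }
        bad <- which(val <= 0)
        eps[bad] <- stats::rnorm(length(bad), 0, sqrt(eps2))
        zv <- mu_v + be + eps
        val <- sp$mean + sp$sd * zv
      }
    }
    z[[v]] <- zv
    out[[v]] <- val

    # extend the implied covariance bookkeeping (nominal, pre-truncation)
    prev <- rownames(sigma)
    cov_new <- if (length(pa)) {
      as.numeric(sigma[prev, pa, drop = FALSE] %*% b)
    } else rep(0, length(prev))
    sigma <- rbind(cbind(sigma, cov_new), c(cov_new, 1))
    rownames(sigma)[nrow(sigma)] <- v
    colnames(sigma)[ncol(sigma)] <- v
  }
  out$cue <- cue(out$growth, out$resp)
  out
}

#' Invert the measurement equations into instrument-level raw tables
#'
#' Writes the raw tables the measurement and stoichiometry modules consume,
#' chosen so that re-running the pipeline recovers the latent values
#' exactly: headspace CO2 from the ideal-gas inverse of the respiration
#' equation, at% excess and DNA production from the growth chain given the
#' target DNA-to-biomass factor, fumigation pairs and DNA content from the
#' biomass, and amino sugars from the necromass split.
#'
#' @param latent Output of [generate_latent()].
#' @param cfg A [synth_config()].
#' @param consts Physical constants, see [physical_constants()].
#' @return List of data frames: `incubation`, `isotope`, `cfe`, `dna`,
#'   `aminosugars` (one sample per plot, `sample_id` = `plot_id`).
#' @export
generate_raw_tables <- function(latent, cfg, consts = physical_constants()) {
  set.seed(cfg$seed + 3L)
  id <- latent$plot_id
  n <- length(id)
  n_gas <- cfg$p_kpa * cfg$vhs_l / (consts$R * cfg$temp_k)

  dco2 <- latent$resp * cfg$dw_g * (cfg$t_hr / 24) / (n_gas * consts$M_C)
  incubation <- data.frame(
    sample_id = id, plot_id = id, dco2_ppm = dco2, dw_g = cfg$dw_g,
    t_hr = cfg$t_hr, p_kpa = cfg$p_kpa, temp_k = cfg$temp_k,
    vhs_l = cfg$vhs_l, stringsAsFactors = FALSE
  )

  dna_prod <- latent$growth * cfg$dw_g * (cfg$t_hr / 24) / cfg$f_dna
  excess <- dna_prod * 100 /
    (cfg$o_total_ug * (100 / cfg$atpct_label) * (100 / consts$f_O_DNA))
  if (any(excess > cfg$atpct_label - cfg$atpct_na)) {
    md_stop("required at% excess exceeds the label strength; growth too high for the configured isotope geometry",
            "config_scale")
  }
  isotope <- data.frame(
    sample_id = id, o_total_ug = cfg$o_total_ug,
    atpct_labeled = cfg$atpct_na + excess, atpct_na = cfg$atpct_na,
    atpct_label = cfg$atpct_label, stringsAsFactors = FALSE
  )

  c_unfum <- pmax(cfg$c_unfumigated + stats::rnorm(n, 0, cfg$c_unfumigated / 10), 0)
  cfe <- data.frame(
    sample_id = id, c_fumigated = c_unfum + latent$cmic * cfg$k_ec,
    c_unfumigated = c_unfum, k_ec = cfg$k_ec, stringsAsFactors = FALSE
  )

  dna <- data.frame(sample_id = id, dna_ug_g = latent$cmic / cfg$f_dna,
                    stringsAsFactors = FALSE)

  m_mur <- 251.23
  m_glcn <- 179.17
  muramic <- latent$necromass_bacterial * 1000 / 45
  fungal_glcn <- latent$necromass_fungal * 1000 / 9
  aminosugars <- data.frame(
    sample_id = id, muramic_acid_ug_g = muramic,
    glucosamine_total_ug_g = fungal_glcn + muramic / m_mur * m_glcn,
    stringsAsFactors = FALSE
  )

  list(incubation = incubation, isotope = isotope, cfe = cfe, dna = dna,
       aminosugars = aminosugars)
}

#' Generate a complete synthetic dataset
#'
#' Runs [generate_design()], [generate_latent()] and
#' [generate_raw_tables()] under the configuration's seed and returns the
#' plot table (design plus directly measured covariates), the five raw
#' instrument tables, and the ground truth for recovery tests.
#'
#' @param cfg A [synth_config()].
#' @return List with `plots` (design + `soc`, `soil_cn`, `doc`, `root_c`,
#'   `root_cn`), `incubation`, `isotope`, `cfe`, `dna`, `aminosugars`, and
#'   `truth` (the full latent table and the path coefficients).
#' @export
generate_synthetic_dataset <- function(cfg = synth_config()) {
  design <- generate_design(cfg)
  latent <- generate_latent(design, cfg)
  raw <- generate_raw_tables(latent, cfg)
  plots <- latent[c("plot_id", "block", "psr_sown", "pfgr", "has_grasses",
                    "has_legumes", "has_small_herbs", "has_tall_herbs",
                    "soc", "soil_cn", "doc", "root_c", "root_cn")]
  c(list(plots = plots, truth = list(latent = latent,
                                     path_beta = cfg$path_beta,
                                     seed = cfg$seed)),
    raw)
}

#' Write a synthetic dataset to CSV files
#'
#' @param dataset Output of [generate_synthetic_dataset()].
#' @param dir Output directory (created if absent).
#' @return Invisibly, the paths written.
#' @export
write_synthetic_dataset <- function(dataset, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  tables <- c("plots", "incubation", "isotope", "cfe", "dna", "aminosugars")
  paths <- character(0)
  for (tb in tables) {
    p <- file.path(dir, paste0(tb, ".csv"))
    utils::write.csv(dataset[[tb]], p, row.names = FALSE)
    paths <- c(paths, p)
  }
  truth_path <- file.path(dir, "truth.json")
  jsonlite::write_json(dataset$truth, truth_path, auto_unbox = TRUE,
                       digits = NA, dataframe = "columns")
  invisible(c(paths, truth_path))
}
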