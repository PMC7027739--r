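# Reference summary statistics used to calibrate the synthetic-data
# generator and as a worked input for the PSR contrast computations.

#' Reference plot-level summary statistics by sown species richness
#'
#' Means and standard deviations of soil, plant and microbial variables by
#' sown plant species richness (PSR) level, as published for a long-term
#' grassland biodiversity field experiment with a randomized block design
#' (4 blocks, 81 vegetated plots, PSR levels 1-60). Units: `soc` mg C g^-1
#' soil dry weight; `root_c` g C m^-2; `cmic` ug C g^-1 dry weight;
#' `growth` and `resp` ug C g^-1 dry weight day^-1; `necromass_fungal`
#' mg C g^-1 dry weight; `soil_cn` and `root_cn` dimensionless.
#'
#' These values are the calibration targets of [synth_config()]: the
#' generator rescales its latent variables so that the synthetic plot
#' population matches this table's pooled means and SDs.
#'
#' @return Data frame with one row per PSR level: `psr`, `n`, and
#'   `<variable>_mean` / `<variable>_sd` columns.
#' @export
psr_reference_summary <- function() {
  data.frame(
    psr = c(1L, 2L, 4L, 8L, 16L, 60L),
    n = c(15L, 16L, 16L, 16L, 14L, 4L),
    soc_mean = c(20.4, 20.8, 22.2, 21.9, 24.1, 26.3),
    soc_sd = c(2.7, 2.6, 2.3, 1.9, 2.4, 2.9),
    soil_cn_mean = c(10.7, 10.8, 10.8, 10.9, 11.1, 11.1),
    soil_cn_sd = c(0.5, 0.6, 0.4, 0.5, 0.7, 0.2),
    root_c_mean = c(17.2, 26.5, 41.7, 23.9, 47.7, 49.1),
    root_c_sd = c(10.9, 24.1, 33.6, 15.3, 25.1, 28.5),
    root_cn_mean = c(40.4, 40.8, 45.0, 46.2, 44.7, 46.3),
    root_cn_sd = c(11.9, 10.1, 10.1, 9.6, 11.2, 2.6),
    cmic_mean = c(744.2, 838.1, 958.8, 952.0, 1103.8, 1175.8),
    cmic_sd = c(167.6, 122.0, 142.5, 130.5, 118.4, 103.9),
    growth_mean = c(7.0, 10.1, 10.8, 10.8, 12.1, 13.9),
    growth_sd = c(4.6, 4.4, 3.5, 4.6, 3.2, 2.3),
    resp_mean = c(14.6, 18.2, 16.6, 19.8, 19.8, 21.1),
    resp_sd = c(6.0, 4.4, 7.2, 6.1, 5.4, 7.4),
    necromass_fungal_mean = c(3.9, 4.0, 4.4, 4.3, 4.7, 5.1),
    necromass_fungal_sd = c(0.6, 0.4, 0.5, 0.5, 0.6, 0.7)
  )
}

pooled_moments <- function(summary, variable) {
  m <- summary[[paste0(variable, "_mean")]]
  s <- summary[[paste0(variable, "_sd")]]
  w <- summary$n / sum(summary$n)
  mu <- sum(w * m)
  # total variance = mean within-level variance + between-level variance
  sigma2 <- sum(w * s^2) + sum(w * (m - mu)^2)
  c(mean = mu, sd = sqrt(sigma2))
}
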