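# 18O-water tracer equations: from raw incubation measurements to microbial
# respiration, gross growth, carbon uptake, CUE, biomass-specific rates and
# turnover time.

#' Physical constants for the tracer calculations
#'
#' @param R Ideal gas constant, J mol^-1 K^-1.
#' @param M_C Molar mass of carbon, g/mol.
#' @param f_O_DNA Mass fraction of oxygen in double-stranded DNA, percent.
#' @return A named list of constants.
#' @export
physical_constants <- function(R = 8.314, M_C = 12.01, f_O_DNA = 31.21) {
  if (any(c(R, M_C, f_O_DNA) <= 0)) {
    md_stop("physical constants must be strictly positive", "invalid_constant")
  }
  list(R = R, M_C = M_C, f_O_DNA = f_O_DNA)
}

#' Microbial respiration rate from headspace CO2 accumulation
#'
#' Converts the CO2 increase in the headspace of a sealed incubation vial
#' into a soil-mass-based respiration rate. The headspace gas amount follows
#' from the ideal gas law (p in kPa times volume in L over RT gives moles
#' directly); the CO2 mixing ratio increase (ppm) then yields moles of
#' CO2-C, which are expressed per g soil dry weight and scaled from the
#' incubation time to a per-day basis.
#'
#' @param dco2_ppm Increase in headspace CO2 mixing ratio over the
#'   incubation, ppm.
#' @param dw_g Soil dry mass, g.
#' @param t_hr Incubation time, hours.
#' @param p_kpa Atmospheric pressure, kPa.
#' @param temp_k Gas temperature, K.
#' @param vhs_l Headspace volume, L.
#' @param consts Physical constants, see [physical_constants()].
#' @return Respiration rate, ug CO2-C g^-1 dry weight day^-1.
#' @export
respiration_rate <- function(dco2_ppm, dw_g, t_hr, p_kpa, temp_k, vhs_l,
                             consts = physical_constants()) {
  if (any(dw_g <= 0) || any(t_hr <= 0) || any(p_kpa <= 0) ||
      any(temp_k <= 0) || any(vhs_l <= 0)) {
    md_stop("dw_g, t_hr, p_kpa, temp_k and vhs_l must all be strictly positive",
            "invalid_measurement")
  }
  if (any(dco2_ppm < 0)) {
    md_stop("negative headspace CO2 increase (dco2_ppm < 0)", "negative_flux")
  }
  # kPa * L = J, so n = pV/RT is in mol without further unit juggling.
  n_gas <- p_kpa * vhs_l / (consts$R * temp_k)
  # mol gas * (ppm * 1e-6) * g/mol = g C; * 1e6 -> ug C. The 1e-6/1e6 cancel.
  n_gas * dco2_ppm * consts$M_C / dw_g * (24 / t_hr)
}

#' DNA produced during an 18O incubation
#'
#' Amount of newly synthesised double-stranded DNA inferred from the excess
#' 18O of the labeled DNA extract relative to natural-abundance controls,
#' corrected for the 18O enrichment of soil water and the oxygen content of
#' DNA.
#'
#' @param o_total_ug Total oxygen in the dried DNA extract, ug.
#' @param atpct_labeled at% 18O of the labeled sample.
#' @param atpct_na Mean at% 18O of natural-abundance control samples.
#' @param atpct_label 18O enrichment of soil water during incubation, at%.
#' @param consts Physical constants, see [physical_constants()].
#' @param negative_excess Policy when `atpct_labeled < atpct_na` (possible
#'   under measurement noise): `"clamp"` truncates the excess at 0 with a
#'   warning, `"error"` aborts.
#' @return DNA produced, ug dsDNA.
#' @export
dna_produced <- function(o_total_ug, atpct_labeled, atpct_na, atpct_label,
                         consts = physical_constants(),
                         negative_excess = c("clamp", "error")) {
  negative_excess <- match.arg(negative_excess)
  if (any(atpct_label <= 0)) {
    md_stop("atpct_label must be strictly positive", "invalid_label")
  }
  if (any(atpct_label > 100) || any(atpct_na < 0) || any(o_total_ug < 0)) {
    md_stop("isotope measurement outside valid range", "invalid_measurement")
  }
  excess <- atpct_labeled - atpct_na
  if (any(excess < 0)) {
    if (negative_excess == "error") {
      md_stop("labeled at% 18O below natural abundance (negative excess)",
              "negative_excess")
    }
    md_warn(sprintf("%d sample(s) with at%% excess < 0 clamped to 0",
                    sum(excess < 0)), "negative_excess_warning")
    excess <- pmax(excess, 0)
  }
  o_total_ug * (excess / 100) * (100 / atpct_label) * (100 / consts$f_O_DNA)
}

#' Microbial gross growth rate
#'
#' Converts DNA production over the incubation into microbial biomass carbon
#' production per g soil and day, using the sample-specific DNA-to-biomass
#' conversion factor (see [f_dna()]).
#'
#' @param dna_prod_ug DNA produced during the incubation, ug.
#' @param f_dna Conversion factor, ug microbial biomass C per ug DNA.
#' @param dw_g Soil dry mass, g.
#' @param t_hr Incubation time, hours.
#' @return Growth rate, ug C g^-1 dry weight day^-1.
#' @export
growth_rate <- function(dna_prod_ug, f_dna, dw_g, t_hr) {
  if (any(f_dna <= 0) || any(dw_g <= 0) || any(t_hr <= 0)) {
    md_stop("f_dna, dw_g and t_hr must be strictly positive", "invalid_parameter")
  }
  if (any(dna_prod_ug < 0)) {
    md_stop("dna_prod_ug must be nonnegative", "invalid_parameter")
  }
  f_dna * dna_prod_ug / dw_g * (24 / t_hr)
}

#' Microbial organic carbon uptake
#'
#' @param growth Growth rate, ug C g^-1 dry weight day^-1.
#' @param respiration Respiration rate, same units.
#' @return Uptake (growth + respiration), same units.
#' @export
carbon_uptake <- function(growth, respiration) {
  if (any(growth < 0) || any(respiration < 0)) {
    md_stop("growth and respiration must be nonnegative", "invalid_rate")
  }
  growth + respiration
}

#' Microbial carbon use efficiency
#'
#' Fraction of organic carbon uptake allocated to growth,
#' growth / (growth + respiration).
#'
#' @inheritParams carbon_uptake
#' @return CUE, a dimensionless fraction in \[0, 1).
#' @export
cue <- function(growth, respiration) {
  if (any(growth < 0) || any(respiration < 0)) {
    md_stop("growth and respiration must be nonnegative", "invalid_rate")
  }
  if (any(growth + respiration == 0)) {
    md_stop("CUE undefined where growth + respiration = 0", "undefined_cue")
  }
  growth / (growth + respiration)
}

#' Biomass-specific rate
#'
#' Expresses a soil-mass-based rate per unit microbial biomass carbon,
#' in ng C per ug biomass C per day. Applied uniformly to growth (qGrowth),
#' respiration (qCO2) and uptake.
#'
#' @param rate Rate, ug C g^-1 dry weight day^-1.
#' @param cmic_ug_g Microbial biomass carbon, ug C g^-1 dry weight.
#' @return Biomass-specific rate, ng C ug^-1 biomass C day^-1.
#' @export
biomass_specific <- function(rate, cmic_ug_g) {
  if (any(cmic_ug_g <= 0)) {
    md_stop("microbial biomass carbon must be strictly positive", "invalid_biomass")
  }
  rate / cmic_ug_g * 1000
}

#' Microbial biomass turnover time
#'
#' At steady state the biomass-specific growth rate equals the biomass
#' turnover rate, so its reciprocal is the mean residence time of carbon in
#' living microbial biomass. With q_growth in ng C ug^-1 biomass C day^-1,
#' the per-day biomass fraction is q_growth/1000 and turnover time is
#' 1000/q_growth days.
#'
#' @param q_growth Biomass-specific growth, ng C ug^-1 biomass C day^-1.
#' @return Turnover time, days.
#' @export
turnover_time <- function(q_growth) {
  if (any(q_growth <= 0)) {
    md_stop("turnover time undefined for q_growth <= 0", "undefined_turnover")
  }
  1000 / q_growth
}

#' Per-sample microbial physiology from raw measurement tables
#'
#' Joins the four raw tables by `sample_id` and runs the full measurement
#' chain: respiration from headspace CO2, microbial biomass carbon from
#' fumigation extracts, the per-sample DNA-to-biomass factor, growth from
#' 18O incorporation, then uptake, CUE, biomass-specific rates and turnover
#' time.
#'
#' @param incubation Data frame with columns `sample_id`, `dco2_ppm`, `dw_g`,
#'   `t_hr`, `p_kpa`, `temp_k`, `vhs_l` (and optionally `plot_id`).
#' @param isotope Data frame with columns `sample_id`, `o_total_ug`,
#'   `atpct_labeled`, `atpct_na`, `atpct_label`.
#' @param cfe Data frame with columns `sample_id`, `c_fumigated`,
#'   `c_unfumigated` (optionally `k_ec`).
#' @param dna Data frame with columns `sample_id`, `dna_ug_g`.
#' @param consts Physical constants, see [physical_constants()].
#' @param mode `"lenient"` clamps negative at% excess and negative fumigation
#'   flushes to zero with warnings; `"strict"` turns both into errors.
#' @return Data frame with one row per sample: respiration, growth, uptake,
#'   cue, cmic, f_dna, q_growth, q_resp, q_uptake, turnover_time.
#' @export
compute_physiology <- function(incubation, isotope, cfe, dna,
                               consts = physical_constants(),
                               mode = c("lenient", "strict")) {
  mode <- match.arg(mode)
  check_columns(incubation,
                c("sample_id", "dco2_ppm", "dw_g", "t_hr", "p_kpa", "temp_k", "vhs_l"),
                "incubation")
  check_columns(isotope,
                c("sample_id", "o_total_ug", "atpct_labeled", "atpct_na", "atpct_label"),
                "isotope")
  check_columns(cfe, c("sample_id", "c_fumigated", "c_unfumigated"), "cfe")
  check_columns(dna, c("sample_id", "dna_ug_g"), "dna")

  d <- merge(incubation, isotope, by = "sample_id")
  d <- merge(d, cfe, by = "sample_id")
  d <- merge(d, dna, by = "sample_id")
  if (nrow(d) == 0L) {
    md_stop("no samples shared across the raw tables", "schema_error")
  }

  k_ec <- if ("k_ec" %in% names(d)) d$k_ec else 0.45
  cmic <- cfe_biomass_c(d$c_fumigated, d$c_unfumigated, k_ec, mode = mode)
  fdna <- f_dna(cmic, d$dna_ug_g)

  resp <- respiration_rate(d$dco2_ppm, d$dw_g, d$t_hr, d$p_kpa, d$temp_k,
                           d$vhs_l, consts)
  dnap <- dna_produced(d$o_total_ug, d$atpct_labeled, d$atpct_na, d$atpct_label,
                       consts,
                       negative_excess = if (mode == "strict") "error" else "clamp")
  growth <- growth_rate(dnap, fdna, d$dw_g, d$t_hr)

  out <- data.frame(
    sample_id = d$sample_id,
    respiration = resp,
    growth = growth,
    uptake = carbon_uptake(growth, resp),
    cue = cue(growth, resp),
    cmic = cmic,
    f_dna = fdna,
    q_growth = biomass_specific(growth, cmic),
    q_resp = biomass_specific(resp, cmic),
    q_uptake = biomass_specific(carbon_uptake(growth, resp), cmic),
    stringsAsFactors = FALSE
  )
  out$turnover_time <- ifelse(out$q_growth > 0, 1000 / out$q_growth, NA_real_)
  if ("plot_id" %in% names(d)) out$plot_id <- d$plot_id
  out
}

#' Aggregate per-sample physiology to plot level
#'
#' Plots measured with replicate cores are summarised by the arithmetic mean
#' of each derived quantity; ratio quantities (cue, turnover_time) are
#' recomputed from the aggregated rates so that the uptake and reciprocal
#' identities hold at plot level too.
#'
#' @param physiology Output of [compute_physiology()], with a `plot_id`
#'   column.
#' @return Data frame with one row per plot.
#' @export
aggregate_physiology <- function(physiology) {
  check_columns(physiology, c("plot_id", "respiration", "growth", "cmic"),
                "physiology")
  num <- c("respiration", "growth", "cmic", "f_dna")
  num <- intersect(num, names(physiology))
  agg <- stats::aggregate(physiology[num], by = list(plot_id = physiology$plot_id),
                          FUN = mean)
  agg$uptake <- carbon_uptake(agg$growth, agg$respiration)
  agg$cue <- cue(agg$growth, agg$respiration)
  agg$q_growth <- biomass_specific(agg$growth, agg$cmic)
  agg$q_resp <- biomass_specific(agg$respiration, agg$cmic)
  agg$q_uptake <- biomass_specific(agg$uptake, agg$cmic)
  agg$turnover_time <- ifelse(agg$q_growth > 0, 1000 / agg$q_growth, NA_real_)
  agg
}
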