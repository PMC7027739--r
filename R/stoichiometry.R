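# Fumigation-extraction biomass carbon, the DNA-to-biomass conversion
# factor, and amino-sugar necromass partitioning.

#' Microbial biomass carbon from chloroform fumigation extraction
#'
#' The extractable organic carbon flush (fumigated minus unfumigated) is
#' divided by the extraction efficiency factor k_EC, the standard CFE
#' convention.
#'
#' @param c_fumigated Extractable organic C of the fumigated sample,
#'   ug C g^-1 dry weight.
#' @param c_unfumigated Same for the unfumigated sample.
#' @param k_ec Extraction efficiency factor, in (0, 1]. Default 0.45.
#' @param mode `"strict"` treats a negative flush (unfumigated above
#'   fumigated) as an error; `"lenient"` clamps it to zero with a warning.
#' @return Microbial biomass carbon, ug C g^-1 dry weight.
#' @export
cfe_biomass_c <- function(c_fumigated, c_unfumigated, k_ec = 0.45,
                          mode = c("lenient", "strict")) {
  mode <- match.arg(mode)
  if (any(k_ec <= 0) || any(k_ec > 1)) {
    md_stop("k_ec must lie in (0, 1]", "invalid_parameter")
  }
  if (any(c_unfumigated < 0)) {
    md_stop("extractable carbon must be nonnegative", "invalid_measurement")
  }
  flush <- c_fumigated - c_unfumigated
  if (any(flush < 0)) {
    if (mode == "strict") {
      md_stop("fumigated extract below unfumigated extract (negative flush)",
              "fumigation_order")
    }
    md_warn(sprintf("%d sample(s) with negative fumigation flush clamped to 0",
                    sum(flush < 0)), "fumigation_order_warning")
    flush <- pmax(flush, 0)
  }
  flush / k_ec
}

#' Per-sample DNA-to-biomass conversion factor
#'
#' Ratio of microbial biomass carbon to soil DNA content, both per g soil
#' dry weight. It is a per-sample quantity, not a global constant.
#'
#' @param cmic_ug_g Microbial biomass carbon, ug C g^-1 dry weight.
#' @param dna_ug_g Soil DNA content, ug DNA g^-1 dry weight.
#' @return Conversion factor, ug biomass C per ug DNA.
#' @export
f_dna <- function(cmic_ug_g, dna_ug_g) {
  if (any(dna_ug_g <= 0)) {
    md_stop("DNA content must be strictly positive", "invalid_dna")
  }
  if (any(cmic_ug_g < 0)) {
    md_stop("microbial biomass carbon must be nonnegative", "invalid_measurement")
  }
  cmic_ug_g / dna_ug_g
}

#' Partition amino sugars into bacterial and fungal necromass carbon
#'
#' Muramic acid occurs only in bacterial cell walls, where muramic acid and
#' glucosamine occur at a 1:1 molar ratio. Bacterial glucosamine (molar
#' equivalent of muramic acid) is therefore subtracted from total
#' glucosamine to yield fungal glucosamine. Necromass carbon follows from
#' mass-based conversion factors: muramic acid x 45 (bacterial) and fungal
#' glucosamine x 9.
#'
#' @param muramic_acid_ug_g Muramic acid, ug g^-1 dry weight.
#' @param glucosamine_total_ug_g Total glucosamine, ug g^-1 dry weight.
#' @param m_mur Molar mass of muramic acid, g/mol.
#' @param m_glcn Molar mass of glucosamine, g/mol.
#' @param conv_bacterial Mass conversion factor from muramic acid to
#'   bacterial necromass C.
#' @param conv_fungal Mass conversion factor from fungal glucosamine to
#'   fungal necromass C.
#' @return Data frame with columns `necromass_bacterial`, `necromass_fungal`
#'   and `necromass_total`, all in mg C g^-1 dry weight.
#' @export
necromass_partition <- function(muramic_acid_ug_g, glucosamine_total_ug_g,
                                m_mur = 251.23, m_glcn = 179.17,
                                conv_bacterial = 45, conv_fungal = 9) {
  if (any(muramic_acid_ug_g < 0) || any(glucosamine_total_ug_g < 0)) {
    md_stop("amino sugar concentrations must be nonnegative", "invalid_measurement")
  }
  if (m_mur <= 0 || m_glcn <= 0) {
    md_stop("molar masses must be strictly positive", "invalid_parameter")
  }
  mol_mur <- muramic_acid_ug_g / m_mur    # umol g^-1
  mol_glcn <- glucosamine_total_ug_g / m_glcn
  if (any(mol_glcn < mol_mur)) {
    md_stop("molar glucosamine below molar muramic acid (negative fungal share)",
            "negative_fungal_share")
  }
  fungal_glcn_ug <- (mol_glcn - mol_mur) * m_glcn
  bacterial <- muramic_acid_ug_g * conv_bacterial / 1000   # -> mg C g^-1
  fungal <- fungal_glcn_ug * conv_fungal / 1000
  data.frame(
    necromass_bacterial = bacterial,
    necromass_fungal = fungal,
    necromass_total = bacterial + fungal
  )
}

#' Fungal to bacterial necromass carbon ratio
#'
#' @param necromass Data frame with columns `necromass_fungal` and
#'   `necromass_bacterial` (as returned by [necromass_partition()]).
#' @return Dimensionless ratio vector.
#' @export
fb_necromass_ratio <- function(necromass) {
  check_columns(necromass, c("necromass_fungal", "necromass_bacterial"),
                "necromass")
  if (any(necromass$necromass_bacterial <= 0)) {
    md_stop("F:B ratio undefined where bacterial necromass is zero",
            "undefined_ratio")
  }
  necromass$necromass_fungal / necromass$necromass_bacterial
}

#' Per-sample biomass and necromass from raw stoichiometry tables
#'
#' @param cfe Data frame with `sample_id`, `c_fumigated`, `c_unfumigated`
#'   (optionally `k_ec`).
#' @param aminosugars Data frame with `sample_id`, `muramic_acid_ug_g`,
#'   `glucosamine_total_ug_g`.
#' @param dna Data frame with `sample_id`, `dna_ug_g`.
#' @param mode Passed to [cfe_biomass_c()].
#' @return Data frame with cmic, f_dna and the necromass partition per
#'   sample.
#' @export
compute_biomass_necromass <- function(cfe, aminosugars, dna,
                                      mode = c("lenient", "strict")) {
  mode <- match.arg(mode)
  check_columns(cfe, c("sample_id", "c_fumigated", "c_unfumigated"), "cfe")
  check_columns(aminosugars,
                c("sample_id", "muramic_acid_ug_g", "glucosamine_total_ug_g"),
                "aminosugars")
  check_columns(dna, c("sample_id", "dna_ug_g"), "dna")
  d <- merge(merge(cfe, aminosugars, by = "sample_id"), dna, by = "sample_id")
  k_ec <- if ("k_ec" %in% names(d)) d$k_ec else 0.45
  cmic <- cfe_biomass_c(d$c_fumigated, d$c_unfumigated, k_ec, mode = mode)
  nec <- necromass_partition(d$muramic_acid_ug_g, d$glucosamine_total_ug_g)
  out <- data.frame(sample_id = d$sample_id, cmic = cmic,
                    f_dna = f_dna(cmic, d$dna_ug_g), nec,
                    stringsAsFactors = FALSE)
  out$fb_ratio <- fb_necromass_ratio(nec)
  out
}
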