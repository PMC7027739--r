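# micdiv

Soil microbial physiology along plant diversity gradients: from raw
incubation measurements to causal path models of soil organic carbon (SOC)
accumulation.

## The scientific problem

Species-rich grassland communities store more soil carbon than monocultures,
and soil microbes sit in the middle of that link: plant carbon inputs are
either respired back to CO₂ or incorporated into microbial biomass, whose
residues (necromass) feed the SOC pool. Disentangling the anabolic and
catabolic sides of microbial metabolism requires substrate-independent rate
measurements and an inference chain that respects the randomized block
design of diversity experiments. `micdiv` implements that chain end to end
for experiments with sown plant species richness (PSR) gradients:

1. **Measurements** — ¹⁸O-water tracer physiology. Respiration from
   headspace CO₂ accumulation via the ideal gas law,

   C_resp = (p·V_hs)/(R·T) · ΔCO₂·10⁻⁶ · M_C / DW · 24/t  (µg C g⁻¹ DW d⁻¹),

   gross growth from ¹⁸O incorporation into genomic DNA,

   DNA_prod = O_total · (at%_excess/100) · (100/at%_label) · (100/31.21),
   C_growth = f_DNA · DNA_prod / DW · 24/t,

   and derived quantities: uptake = growth + respiration, carbon use
   efficiency CUE = growth/(growth + respiration), biomass-specific rates
   (qGrowth, qCO₂) and microbial turnover time = 1/qGrowth.
2. **Stoichiometry** — microbial biomass carbon from chloroform fumigation
   extraction, C_mic = ΔEOC/k_EC (k_EC = 0.45); the per-sample DNA-to-biomass
   factor f_DNA = C_mic/DNA; and bacterial/fungal necromass carbon from
   muramic acid and glucosamine (1:1 molar bacterial subtraction; mass
   conversion factors 45 and 9).
3. **Design statistics** — block correction (recentring each block on the
   grand mean), sequential likelihood-ratio tests in ML linear mixed models
   with a block random intercept (PSR log-transformed, then functional group
   richness, then each functional-group identity flag), and a block-corrected
   Pearson correlation matrix with t-based p-values.
4. **Path models** — piecewise structural equation models built from the
   same mixed models: Shipley's d-separation basis set, Fisher's
   C = −2Σln(p) on 2k df, likelihood-free AIC = C + 2K and AICc,
   standardized path coefficients β = b·SD(x)/SD(y), indirect effects as
   products of β along directed paths, and marginal/conditional R².
5. **Synthetic data** — a generator that emulates the experimental design
   (4 blocks, 81 plots, PSR ∈ {1,2,4,8,16,60} with replication
   15/16/16/16/14/4), simulates a standardized linear causal chain
   PSR → root C → growth → biomass → SOC, rescales to published summary
   moments, and **inverts the measurement equations** down to
   instrument-level raw tables so the full pipeline round-trips exactly.

## Worked example

```r
library(micdiv)

# a single respiration measurement: 50 ppm CO2 increase, 2 g soil, 24 h,
# 101.325 kPa, 295.15 K, 20 ml headspace
respiration_rate(50, 2, 24, 101.325, 295.15, 0.02)
#> [1] 0.2479573    # ug CO2-C per g dry soil per day

# a complete synthetic experiment, analysed end to end
ds  <- generate_synthetic_dataset(synth_config(seed = 7))
res <- run_pipeline(ds$plots, ds$incubation, ds$isotope, ds$cfe, ds$dna,
                    ds$aminosugars)
print(res$sem)
#> Piecewise SEM: 6 vertices, 8 paths, n = 81
#>
#>      from     to  estimate       se        p std_beta code
#>  psr_sown root_c   0.27800  0.06130 2.10e-05    0.455  ***
#>  psr_sown growth   1.66300  0.34500 7.21e-06    0.474  ***
#>    root_c growth   1.47500  0.56400 1.07e-02    0.257    *
#>  psr_sown   cmic  70.41000 15.70000 2.57e-05    0.455  ***
#>    root_c   cmic -25.87000 23.50000 2.75e-01   -0.102
#>    growth   cmic  17.60000  4.52000 2.17e-04    0.399  ***
#>    growth   resp   0.45910  0.16500 6.96e-03    0.297   **
#>      cmic    soc   0.01025  0.00114 1.40e-13    0.705  ***
#>
#> Fisher's C = 15.50, df = 14, p = 0.345
#> AIC = 41.50, AICc = 46.93 (K = 13)
```

A nonsignificant Fisher's C (p = .345 here) means the data are consistent
with the independencies the causal structure implies. The standardized
coefficients are read as SD-for-SD effects: one SD more log-richness is
associated with ~0.46 SD more microbial biomass carbon directly, and the
biomass → SOC path (β = .71) carries the carbon-storage signal. Indirect
effects decompose the mediation:

```r
indirect_effects(res$sem, "psr_sown", "cmic")$paths
#>                                   path      effect
#> 1 psr_sown -> root_c -> growth -> cmic  0.04664783
#> 2           psr_sown -> root_c -> cmic -0.04650806
#> 3           psr_sown -> growth -> cmic  0.18917891
```

Per-level summaries and gradient contrasts work on any plot table,
including the published reference summary shipped with the package:

```r
psr_change(psr_reference_summary(), "soc")
#>        low        high pct_increase  fold_change
#>  20.400000   26.300000    28.921569     1.289216
```

— SOC rises by 29% from monocultures to 60-species mixtures, microbial
biomass by 58%, growth twofold and respiration 1.5-fold.

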