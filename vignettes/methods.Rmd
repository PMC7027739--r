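---
title: "Methods: tracer physiology, block-design inference and piecewise SEM"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: tracer physiology, block-design inference and piecewise SEM}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(micdiv)
```

`micdiv` implements the full computational chain of a grassland
plant-diversity soil study: raw incubation measurements are converted into
microbial physiology metrics, these are joined to the plot design, and the
plot table is pushed through block-aware mixed-model inference and a
piecewise structural equation model (SEM). A synthetic-data generator
emulates the experimental design so every stage can be validated without
field data. This vignette explains the science in each stage, the
conventions and defaults chosen where the methods literature leaves
latitude, and what the validation does and does not demonstrate.

## Measurement model

### Respiration

A sealed vial of fresh soil accumulates CO₂ in its headspace. With
pressure $p$ (kPa), headspace volume $V_{hs}$ (L) and temperature $T$ (K),
the ideal gas law gives the molar amount of headspace gas directly as
$n = pV_{hs}/(RT)$ (kPa·L = J). The mixing-ratio increase $\Delta CO_2$
(ppm) then yields the CO₂-C produced, expressed per g soil dry weight (DW)
and normalised from the incubation time $t$ (hours) to a daily rate:

$$C_{resp} = \frac{p V_{hs}}{R T}\,\Delta CO_2 \cdot 10^{-6}\, M_C
  \;/\; DW \cdot \frac{24}{t}
  \quad [\mu g\ C\ g^{-1}\ DW\ d^{-1}].$$

Published formulations of this equation often carry a bare "×1,000" whose
unit role depends on local conventions for volume and mass units. We
instead define the contract dimensionally — the implementation must agree
with an independent step-by-step SI computation to a relative error below
$10^{-10}$, which the test suite enforces on 1,000 random instruments —
and state units explicitly in every signature. For the package's default
24 h incubations the $24/t$ factor is exactly 1, so the distinction
between "per day" and "per incubation" vanishes at the study's own
geometry.

### Growth by ¹⁸O incorporation

Microbial gross growth is measured substrate-independently by incubating
soil with ¹⁸O-labeled water (default 97 at%) and quantifying the tracer in
newly synthesised genomic DNA. With $O_{total}$ the oxygen content (µg) of
the dried DNA extract, the excess at% ¹⁸O over natural-abundance controls,
the label strength of the soil water, and the oxygen mass fraction of
dsDNA (31.21%):

$$DNA_{prod} = O_{total}\cdot\frac{at\%_{excess}}{100}
  \cdot\frac{100}{at\%_{label}}\cdot\frac{100}{31.21} \quad [\mu g],$$

$$C_{growth} = f_{DNA}\, DNA_{prod} / DW \cdot \frac{24}{t}.$$

$f_{DNA}$ (µg microbial biomass C per µg DNA) is deliberately a
*per-sample* quantity — biomass C from fumigation extraction divided by
soil DNA content — because community composition and extraction efficiency
vary across plots.

Negative at% excess can arise from instrument noise when true growth is
near zero. The default policy clamps it to zero with a logged warning
(tracer studies routinely truncate at natural abundance); `mode = "strict"`
turns it into an error instead. The same lenient/strict switch governs
negative fumigation flushes.

### Derived physiology

Uptake is the exact sum of growth and respiration; CUE is
growth/(growth + respiration), undefined (an error, never a silent zero)
when both are zero. Biomass-specific rates divide by microbial biomass C
and are reported in ng C µg⁻¹ C~mic~ d⁻¹; at steady state over the 24 h
incubation, biomass-specific growth equals the biomass turnover rate, so
turnover time is $1000/q_{growth}$ days on that unit basis. These
identities are enforced as machine-precision invariants in the tests, and
they are preserved under plot aggregation because ratio quantities are
recomputed from aggregated rates rather than averaged.

## Stoichiometry conventions

**Fumigation extraction.** $C_{mic} = (EOC_{fum} - EOC_{unfum})/k_{EC}$
with $k_{EC}=0.45$. The phrase "using an extraction factor" is ambiguous
between multiplication and division; division is the standard CFE
convention (the flush underestimates biomass, so the correction must
inflate it) and is what the package implements.

**Necromass partition.** Muramic acid is exclusively bacterial; bacterial
cell walls contain muramic acid and glucosamine at 1:1 *molar* ratio.
The package therefore subtracts on the molar scale (M = 251.23 and
179.17 g/mol, both configurable), converts the fungal glucosamine
remainder back to mass, and applies the mass-based conversion factors 45
(muramic acid → bacterial necromass C) and 9 (fungal glucosamine → fungal
necromass C). The factors target necromass *carbon*, and outputs are
reported in mg C g⁻¹ DW. Totals are exact sums of the two pools, and the
fungal:bacterial ratio is an error when the bacterial pool is zero.

## Design statistics

**Block correction.** The field layout is a randomized block design (four
blocks tracking a soil texture gradient). Correction recenters each block
on the grand mean: $x_i' = x_i - (\bar x_{b(i)} - \bar x)$. A literal
reading of the usual verbal description ("the difference between block
mean and grand mean is added") would *amplify* block effects for blocks
above the mean; recentring is the only reading consistent with the purpose
of removing them. The operation preserves the grand mean and within-block
deviations and is idempotent — all tested invariants.

**Mixed models and sequential tests.** All inference uses ML (not REML)
linear mixed models with a block random intercept, because REML
likelihoods are not comparable across fixed-effect specifications. The
sequential scheme tests log(PSR) against the intercept-only model,
functional-group richness after PSR, and each functional-group identity
flag in a separate model already containing both richness terms; each test
is a 1-df likelihood-ratio test against $\chi^2_1$, reported with
significance codes (boundaries take the stronger code, e.g. p = .05 is
`*`). The reversed order (richness of functional groups first) is
available via `order = "pfgr-first"`. Internally the response is z-scaled
before fitting and every reported quantity back-transformed — likelihood
differences are invariant to this, and it keeps the optimizer stable on
extreme response scales; a strictly constant response short-circuits to
L = 0, p = 1 for all terms.

**Transforms.** A registry maps variables to `"log"`/`"sqrt"`/identity.
The default registry for the LR tests linearises the right-skewed
variables: root biomass carbon (log), growth (sqrt), biomass-specific
growth and turnover time (log), fungal:bacterial ratio (log). Because
turnover time is the reciprocal of biomass-specific growth, their
log-scale tests yield identical L statistics — a useful internal
consistency check.

**Correlations.** The Pearson matrix operates on block-corrected
variables (correction is the caller's step, so one corrected table can
feed several analyses); two-sided p-values come from the t distribution
with n − 2 df, and zero-variance variables are an error rather than NaN.

## Piecewise SEM

Each endogenous vertex of a user-specified DAG is regressed on its parents
in the same ML mixed-model machinery. Conventions, each configurable where
the literature varies:

* **Basis set.** One independence claim per non-adjacent vertex pair; the
  conditioning set is the union of both vertices' parents, and the vertex
  later in a topological order is the response (Shipley's convention). The
  implementation is validated against brute-force enumeration over *all*
  labeled DAGs of up to five vertices (~29,800 graphs).
* **Fisher's C.** $C = -2\sum \ln p_i$ on $2k$ df. Claim p-values of
  exactly zero are floored at a configurable $10^{-16}$ with a warning so
  C stays finite. A saturated model (empty basis set) reports the
  perfect-fit sentinel C = 0, df = 0, p = NA.
* **Information criteria.** The likelihood-free forms AIC = C + 2K and
  AICc = C + 2K·n/(n − K − 1), with K counting fixed-effect coefficients
  *including intercepts* across submodels and excluding random-intercept
  variances — the dominant convention in the piecewise framework; AICc is
  an error when n ≤ K + 1.
* **Standardization.** $\beta = b\,\mathrm{SD}(x)/\mathrm{SD}(y)$ with
  sample SDs of the transformed variables; binary exogenous flags are
  standardized the same way for comparability. Indirect effects multiply
  standardized coefficients along every directed path with at least one
  mediator and report each path separately plus the sum.
* **R².** Variance-partitioning marginal/conditional R² for
  Gaussian random-intercept models: fixed-effect variance over
  fixed + block + residual, and fixed + block over the same total.
* **Missing paths.** Basis-set claims with p < .05 are *reported* as
  candidate edges, never added automatically — whether an edge is
  mechanistically meaningful is a judgment the software should not make.

The SEM transform registry defaults to log(PSR) and log(root biomass
carbon) only. This differs from the regression-diagnostic registry used in
the LR tests, deliberately: standardized path coefficients are defined on
the scale on which the causal system is linear, and the package's
generative model (below) is linear on the measurement scale for all
vertices except root carbon, whose strongly right-skewed distribution
(coefficient of variation ≈ 0.8) is modeled log-normally. Applying
additional sqrt/log transforms at the SEM stage would bias coefficient
recovery against the generator's own truth. Users fitting field data can
supply any registry through the model file's `# transforms:` header.

## Synthetic-data generator

The generator defines the study conditions the validation runs under:

* **Design.** 81 vegetated plots in 4 blocks; sown richness levels
  {1, 2, 4, 8, 16, 60} with replication (15, 16, 16, 16, 14, 4); each
  block spans the full gradient (round-robin assignment); functional-group
  richness uniform on 1..min(PSR, 4) with exactly that many identity flags
  set.
* **Causal system.** On the standardized scale, each endogenous variable
  is a β-weighted sum of its parents plus an independent per-vertex block
  intercept (SD 0.15, a modest design effect consistent with a corrected
  block layout) and residual noise sized so the latent variance is exactly
  one; an implied variance above one is a configuration error. Default
  coefficients: PSR→rootC .40, PSR→growth .25, rootC→growth .375,
  PSR→C~mic~ .42, rootC→C~mic~ .15, growth→C~mic~ .36, growth→resp .41,
  C~mic~→SOC .68. The three key direct effects (.25, .42, .68) are the
  study-condition values; the root-carbon coefficients are solved from the
  reported mediated-effect magnitudes (PSR via rootC on growth ≈ .15; via
  rootC and via growth on biomass ≈ .06 and .09), and growth→resp matches
  the observed growth–respiration correlation (.41). Fungal necromass
  (β = .30 from PSR and .30 from biomass) mirrors the observed pattern of
  a PSR-driven fungal pool correlated ≈ .5 with biomass, while bacterial
  necromass is pure block + noise — the pattern behind rising
  fungal:bacterial ratios.
* **Rescaling.** Latent values are mapped to measurement units using the
  pooled (within + between level) means and SDs of the reference summary
  table; bacterial necromass (1.2 ± 0.25 mg C g⁻¹) and DOC (100 ± 25
  µg C g⁻¹), absent from that table, use typical temperate-grassland
  topsoil values. Gaussian variables are kept positive by redrawing the
  residual of offending plots (truncated resampling, not clipping, so the
  linear structure is not distorted by censoring mass at zero); root
  carbon is log-normal and positive by construction.
* **Inversion.** Instrument-level tables are computed by inverting each
  measurement equation (headspace CO₂ from the gas law; at% excess and DNA
  content from the growth chain at $f_{DNA} = 50$; fumigation pairs at
  $k_{EC} = 0.45$; amino sugars from the necromass split), so
  pipeline ∘ generator is the identity up to floating-point error — the
  suite requires relative error below $10^{-9}$, and observes ~$10^{-15}$.
  A latent value that is not representable (e.g. a growth rate requiring
  more at% excess than the label strength) is a configuration-scale error.
* **Determinism.** All randomness flows from one root seed through fixed
  per-stage substreams (design, latent, raw), so identical configurations
  give byte-identical datasets.

## What the validation shows — and what it does not

The test suite and the acceptance script establish, under the generator's
conditions: exact algebraic identities of the measurement chain; oracle
equivalence of the gas-law arithmetic; exact round-trip recovery;
unbiased recovery of standardized path coefficients at n = 200 (mean
absolute bias < 0.05 over 200 replicates, observed ≈ 0.01); detection of
the richness→biomass and biomass→SOC paths in well over 80% of replicates
at the field sample size n = 81; calibration of the Fisher's C test
(rejection rate within [0.03, 0.08] at α = .05 and C consistent with
$\chi^2_{14}$ by Kolmogorov–Smirnov over 500 replicates); and nominal
type-I error of the sequential LR tests under a null response. Problem
sizes — 81, 200 and 1,000 plots, 100–500 replicates — are the package's
validation choices, matching the field design where the claim concerns
the field design and scaling up only where a sharper statistical statement
is needed.

The generator emulates the *statistical* structure of such experiments,
not their full complexity: it has no spatial soil-texture gradient beyond
the block intercepts, no temporal dynamics, no species-level community
assembly, linear-Gaussian relations on the (transformed) measurement
scale, and homoscedastic instrument noise. Passing tests therefore
demonstrate correctness of the computational chain and the calibration of
its inference under its stated assumptions — not that those assumptions
hold in any particular field dataset. Real-data features the generator
does not produce (nonlinear dose–response shapes, heavy-tailed instrument
error, missing plots, realized-richness drift from the sown design) should
be kept in mind when interpreting field results; realized richness is
supported as an input column but never generated.

## Known limitations

* Variance–covariance SEM (RMSEA/SRMR-style absolute fit) is out of
  scope; the fitted submodels expose what an external tool needs.
* No latent variables or correlated-error (bidirectional) edges in the
  path models.
* No multiple-testing correction across responses in the LR-test tables
  (matching the field's reporting convention); users comparing many
  responses should apply their own.
* Mixed models assume Gaussian responses after the registry transform;
  other distributions are not supported.
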