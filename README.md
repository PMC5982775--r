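# kinpen

Age-specific cancer penetrance for BRCA1/2 mutation carriers from
family-registry data, estimated under the kin-cohort design.

## The problem

Hereditary breast–ovarian cancer registries recruit probands — women who are
affected and genotyped — and record the cancer histories of their female
first-degree relatives (mother, sisters, daughters). Those relatives form a
retrospective cohort whose follow-up identifies the age-specific cumulative
risk (penetrance) `F(t)` of breast and ovarian cancer separately for
mutation carriers and non-carriers. The catch is that most relatives were
never genotyped: their carrier status is known only probabilistically, via
Mendelian transmission from the proband.

kinpen is aimed at statistical geneticists and cancer epidemiologists who
need to (i) estimate carrier/non-carrier penetrance from such a registry
export, (ii) attach confidence intervals that respect the family structure,
(iii) pool their estimates with published ones, and (iv) validate the whole
pipeline on synthetic registries with known truth.

## The model

Each relative *i* contributes a follow-up pair (tᵢ, δᵢ): age at diagnosis
(δᵢ = 1) or at censoring (δᵢ = 0; competing cancer, risk-reducing surgery,
last follow-up, or death). Her carrier probability — the *mixing weight*
pᵢ — is 1 or 0 if she was genotyped, and otherwise the exact Mendelian
conditional P(carrier | proband genotype, relationship, q) computed by
enumeration under Hardy–Weinberg equilibrium at allele frequency q (taken
as half the carrier frequency among probands unless supplied).

The estimator maximises the genotype-mixture marginal likelihood

    L = ∏ᵢ [ pᵢ · L₁(tᵢ, δᵢ) + (1 − pᵢ) · L₀(tᵢ, δᵢ) ],

where `L_g(t, δ) = λ_g(t)^δ ∏_{t_k < t} (1 − λ_g(t_k)) ·
(1 − λ_g(t))^{(1−δ)[t ∈ grid]}` is the discrete-time survival likelihood
with nonparametric yearly hazards λ_g on the grid of observed event ages,
for carrier (g = 1) and non-carrier (g = 0) classes. An EM algorithm
alternates posterior carrier probabilities (E-step) with weighted
occurrence/exposure hazard updates (M-step); the penetrance is the
product-limit transform `F_g(t) = 1 − ∏_{t₀ < t_k ≤ t} (1 − λ_g(t_k))`
from the reporting origin t₀ (age 20 for breast, 30 for ovarian).
Confidence intervals come from a bootstrap that resamples whole families.
Published per-study estimates are pooled with DerSimonian–Laird
random-effects meta-analysis on the logit scale.

## Worked example

Simulate the default registry scenario (1600 families, allele frequency
0.02, true carrier breast-cancer risk 0.50 by age 70 against 0.16 for
non-carriers, 30% of relatives genotyped), then estimate penetrance:

```r
library(kinpen)

cfg <- read_simulation_config(
  system.file("extdata", "default_scenario.yaml", package = "kinpen"))
sim <- simulate_families(cfg)
sim$families
#> kin_cohort: 1600 families, 5793 first-degree relatives (gene under analysis: BRCA1 )
#>   proband status: BRCA1=189, BRCA2=0, negative=1411
#>   relative genotypes (BRCA1): carrier=137, noncarrier=1603, untested=4053

fit <- fit_penetrance(sim$families, "breast",
                      estimator_config(B = 200, seed = 7))
fit
#> Age-specific penetrance of breast cancer -- BRCA1 (x100 scale)
#>   allele frequency q = 0.05906 ; relatives = 5793 ; events = 695
#>   20-40 years: carrier  23.3 (18.8-28.1) | non-carrier   5.7 (4.9-6.4)
#>   20-50 years: carrier  31.2 (27.4-38.5) | non-carrier   8.7 (7.5-9.6)
#>   20-60 years: carrier  38.9 (33.6-46.2) | non-carrier  11.3 (10.1-12.5)
#>   20-70 years: carrier  48.1 (41.5-56.7) | non-carrier  14.5 (12.8-15.9)
#>   bootstrap: B = 200 ; seed = 7 ; zero-event replicates = 0
```

The carrier column is the cumulative risk ×100 between age 20 and the row
age with its percentile family-bootstrap 95% CI; the fitted 48.1% by age 70
brackets the generator's truth of 50%. Note the reported allele frequency
(0.059) is the proband-based plug-in, which under registry-style
ascertainment exceeds the population value — see the methods vignette for
why the estimator tolerates this.

Pooling the three published Asian estimates of BRCA1 breast-cancer
penetrance by age 70:

```r
st <- read_study_table(
  system.file("extdata", "asian_brca_penetrance_studies.csv",
              package = "kinpen"))
dl_pool(st[st$gene == "BRCA1" & st$age_interval == "20-70", ], "logit")
#> DL random-effects pooled estimate (logit scale): 44.5 (95% CI 32.8-56.9)
#>   k = 3; Q = 1.521 on 2 df (p = 0.467); tau2 = 0
```

A command-line front-end with `simulate` / `estimate` / `meta` /
`incidence` subcommands ships at `inst/cli/kinpen.R`.

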