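---
title: "Kin-cohort penetrance estimation: models, choices, and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Kin-cohort penetrance estimation: models, choices, and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kinpen)
```

## The design and the data

A kin-cohort study recruits *probands* — here, women affected with breast
cancer whose BRCA1/2 genotype is known — and treats their female
first-degree relatives as a retrospective cohort. The relative's outcome
history is observed (through the registry's questionnaires and records),
but her genotype usually is not. Because a first-degree relative shares
half her alleles with the proband, her carrier probability given the
proband's genotype is determined by Mendelian transmission, and the
observed follow-up of many relatives identifies carrier and non-carrier
risk separately.

kinpen's data unit is the *kin-cohort table*: one row per individual with
family id, role (`proband`, `mother`, `sister`, `daughter`), genotype for a
named gene (`carrier` / `noncarrier` / `untested`), and ages at breast and
ovarian diagnosis, risk-reducing salpingo-oophorectomy (RRSO),
risk-reducing mastectomy (RRM), and last follow-up or death. Ages are
whole years. Male relatives and relatives beyond first degree are outside
the model: distant roles are dropped with a warning, and relatives with no
usable time-to-event data are excluded with a logged count; the package
reports its own exclusion arithmetic rather than reconciling external
tallies.

### Follow-up derivation

For **breast cancer**, a relative is followed from birth to diagnosis and
otherwise censored at the earliest of: ovarian cancer diagnosis, RRSO, RRM,
last follow-up, or death. For **ovarian cancer**, follow-up ends at
diagnosis or the earliest of RRSO, last follow-up, or death — a breast
diagnosis or RRM does *not* end ovarian follow-up. Two conventions worth
stating:

* **Ties are event-first.** With whole-year ages, a diagnosis recorded at
  the same age as a censoring cause counts as an event. The alternative
  (censor-first) silently discards observed diagnoses; since diagnoses are
  actively ascertained while censoring ages are often administrative, we
  prefer to keep them.
* **RRM censors only non-cases.** A breast diagnosis before mastectomy is
  an event; the surgery can only end the follow-up of a woman still free of
  the disease.

## The genotype mixture and its weights

For the gene under analysis, each relative carries a *mixing weight*
`p_i`: her probability of being a carrier. Observed genotypes override
everything (`p_i` is 0 or 1). For untested relatives, `p_i` is the exact
conditional probability given the proband's carrier status, the
relationship, and the allele frequency `q`, computed by enumerating the
joint genotype distribution under Hardy–Weinberg equilibrium (HWE):
parent–offspring pairs share one transmitted allele with a random HWE
mate; full siblings are independent transmissions from two HWE parents. A
"carrier" proband is the HWE mixture of heterozygote and homozygote, and
carriers are pooled dominantly — standard for rare alleles, and all that
the two-class hazard model distinguishes anyway.

We use relation-specific exact probabilities rather than the classical
first-degree value of 1/2 (for a carrier proband): the sibling and
parent–offspring conditionals differ once `q > 0`, exactness costs
nothing, and it is testable against an independent allele-level
enumeration oracle (the test suite does so to 1e−12). The 1/2
approximation remains available via `transmission = "half"` in
`estimator_config()`, since published analyses do not always state which
convention they used.

Analyses are per gene: the BRCA1 analysis contrasts BRCA1-positive
families with mutation-negative families (BRCA2 families are set aside,
and vice versa). Relatives in negative families still get a small positive
weight — the noncarrier-proband conditional — and a genotyped carrier in a
negative family (which real registries do contain) is handled by the
observed-genotype override.

### The allele frequency plug-in

`q` is estimated as half the carrier frequency among probands, the
established plug-in for kin-cohort analyses. Two caveats are documented
deliberately. First, with 66 carrier probands among 1635 the formula gives
2.02%, not the 2.1% sometimes printed from the same counts; kinpen reports
its own arithmetic and does not force agreement with any external
rounding. Second, under registry-style ascertainment (probands enter
*because* they are affected) the proband carrier frequency is enriched
relative to the population, so the plug-in overestimates the population
`q`. Its influence on the estimator is confined to the mixing weights,
where it enters the carrier-proband conditionals only at order `q` and the
negative-family weights linearly; empirically (and in the recovery tests)
the EM's posterior updating absorbs the misspecification, with the mean
recovered carrier risk at age 70 well within 0.05 of truth even when the
plug-in is three times the generating value. Users with an external
population estimate can pass it via the `q` argument of
`fit_penetrance()`.

## The estimator

The parameters are nonparametric discrete-time hazards
`λ_g(t_k) ∈ [0, 1]` for carrier (`g = 1`) and non-carrier (`g = 0`)
classes on the grid of distinct observed event ages (tied events pool at
their shared age). A relative with follow-up `(t, δ)` contributes the
class likelihood

    L_g(t, δ) = λ_g(t)^δ · ∏_{t_k < t} (1 − λ_g(t_k)) · (1 − λ_g(t))^{(1−δ)[t ∈ grid]}

and the sample marginal log-likelihood is
`Σ_i log[p_i L₁ + (1 − p_i) L₀]`. The EM algorithm:

* **E-step** — posterior carrier probability
  `π_i = p_i L₁ / (p_i L₁ + (1 − p_i) L₀)` from each relative's full
  follow-up;
* **M-step** — `λ₁(t_k)` is the π-weighted events over π-weighted risk set
  at `t_k`, and symmetrically with `1 − π` for `λ₀`.

Iterations provably never decrease the log-likelihood (the tests assert
the trace on every dataset they fit), and on small instances the fixed
point matches direct numerical maximisation of the marginal likelihood by
a general-purpose optimizer — except in coordinates with zero posterior
risk mass, where the likelihood is flat and any value is a convention
(kinpen uses 0, with a warning when a weighted risk set empties).

Numerical choices: both classes initialise at the pooled
occurrence/exposure hazards; convergence is declared when the
log-likelihood improves by less than `tol = 1e−8` (default), with
`max_iter = 5000` and a non-convergence flag rather than a silent return.
The iteration runs in compiled code; at registry scale (≈6000 relatives,
≈60 grid ages) a fit takes milliseconds.

Penetrance is reported as cumulative risk from an origin age `t₀` (20 for
breast, 30 for ovarian, matching how such tables are conventionally
labelled): `F_g(t) = 1 − ∏_{t₀ < t_k ≤ t} (1 − λ_g(t_k))`. Hazards before
the origin exist in the fit but do not enter the reported product. No
order constraint forces `F₁ ≥ F₀`; crossing estimates are reported with a
warning rather than silenced, since a crossing is diagnostic of sparse
data or weight misspecification.

### Family bootstrap

Relatives within a family share a proband and are not independent, so the
bootstrap resamples *families* with replacement (the same number as
observed, including families contributing no relative follow-up), refits
the EM on each resample with its own event-age grid, and takes percentile
2.5/97.5 bounds of `F` at the report ages. `B = 1000` by default; the seed
is mandatory and the resampling indices are drawn once, so results are
bit-reproducible. A replicate with no events is recorded as a zero curve
and counted in the run log. When a genotype class has fewer than
`min_events_ci = 10` expected events (the π-weighted event count), its
band is suppressed: percentile intervals from a handful of events are not
meaningful, which is also why published tables leave such cells blank.

## Meta-analysis

Published penetrance estimates arrive as a point estimate with a 95% CI on
the percentage scale. `se_from_ci()` moves them to a working scale and
recovers `se = (transform(hi) − transform(lo)) / (2 × 1.96)` — the
full-width formula, because published intervals are asymmetric around the
estimate and choosing one half-width would discard that information.
`dl_pool()` then applies the DerSimonian–Laird moment estimator: fixed
weights `1/se²` give the heterogeneity statistic `Q` (χ², k−1 df);
`τ² = max(0, (Q − (k−1)) / (Σw − Σw²/Σw))`; random weights `1/(se² + τ²)`
give the pooled estimate and normal CI, back-transformed without bias
correction.

The default working scale is the **logit**: penetrance is a proportion,
and the strongly asymmetric published intervals (e.g. 49 with CI 11–98)
are far more normal on the logit scale than the raw one. The source
studies do not state their transform, so log and identity scales are kept
as sensitivity options; a bound at exactly 0 or 100 cannot be logit/log
transformed and the pooling refuses it with a pointer to continuity
adjustment rather than guessing one. On the logit default, the pooled
values for the four intervals with interior bounds land within 1.2
percentage points of the published pooled column, which is the agreement
the acceptance checks assert.

## The synthetic registry generator

`simulate_families()` provides ground truth for every estimator property.
Per family: two HWE founders produce the proband and her sisters by
Mendelian transmission; the mother is a founder; daughters are children of
the proband and a random HWE mate. Each woman's breast and ovarian onset
ages are drawn from her genotype class's discrete yearly hazards; last
contact ages are drawn per generation (mothers ≈ N(75, 8), sisters ≈
N(50, 12), daughters ≈ N(30, 8), truncated to 18–90), with RRSO/RRM at
low rates (3% / 1%) and 15% of last ages being deaths. A family is
retained only if the proband's breast cancer is observed before any of
her censoring ages — the registry's entry route — and relatives are then
genotyped independently with probability γ.

The default scenario (`inst/extdata/default_scenario.yaml`) is 1600
families at `q = 0.02`, γ = 0.3, constant yearly hazards calibrated so
carriers reach 50% breast-cancer risk by age 70 (from age 20) against 16%
for non-carriers, and 21.5% vs 1.4% for ovarian risk (from age 30). These
magnitudes mirror the registry-scale analyses the package targets: ≈190
carrier-proband families, ≈5800 relatives, ≈700 breast events, and ≈30%
of relatives genotyped.

What the generator deliberately does **not** emulate: enrichment beyond
the affected-proband condition (real registries select on triple-negative
disease and family history, which enriches carriers further), cohort
effects in mothers' hazards, residual familial correlation beyond
genotype, competing mortality beyond censoring, and mutation-specific
effects. Passing recovery tests therefore show the estimator is correct
*under its own assumptions* — genotype-conditional independence and
Mendelian weights — not that those assumptions hold in any particular
registry.

## Validation sizes

The test suite validates at the scale of the default scenario: 50
replicate registries of 1600 families for bias (mean recovered carrier
risk at 70 within 0.05 of truth) and for the efficiency property (the
Monte-Carlo SD of the estimate at γ = 0.3 does not exceed that at γ = 0,
compared on identical registries masked two ways), and a 200-replicate
family bootstrap per registry for interval coverage (observed coverage of
the true value within 90–99% at nominal 95%). Small-instance correctness
(EM vs direct maximisation, Mendelian conditionals vs allele-level
enumeration, DerSimonian–Laird vs an independent reference implementation)
is exact to stated tolerances.

## Known limitations

* The marginal likelihood treats relatives as independent given their
  weights (a composite likelihood); standard errors must come from the
  family bootstrap, never from the likelihood curvature.
* Ascertainment is corrected only through the kin-cohort construction
  itself; proband phenotypes are not modelled, so proband data contribute
  genotype information only.
* The two-class dominant model ignores homozygote excess risk.
* Meta-analytic reproduction of published pooled values depends on the
  unstated transform of the source analysis; kinpen reports its own scale
  and offers alternatives rather than claiming exact replication.
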