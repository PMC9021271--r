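---
title: "From respirometry to ecosystem energy flux: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From respirometry to ecosystem energy flux: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plastflux)
```

## The problem

Metabolic rate sets the energetic cost of living, and in ectotherms it scales
with body mass and responds steeply to temperature. The classical
Boltzmann–Arrhenius description,

$$I = I_0\, M^{b}\, e^{E_A T_A},$$

treats the allometric exponent $b$ and the activation energy $E_A$ as
universal constants. But organisms that live for a long time at different
temperatures can acclimate or adapt — *metabolic plasticity*. This package
implements a modelling chain built around a plastic extension of that model
and carries the consequences all the way to ecosystem-level energy fluxes in
stream food webs under a +2 °C warming scenario.

Temperatures enter all models as standardised Arrhenius temperatures

$$T = \frac{T_{\mathrm{kelvin}} - T_0}{k\,T_{\mathrm{kelvin}}\,T_0},$$

with $T_0 = 283.15$ K and $k = 8.618\times10^{-5}$ eV K$^{-1}$, so the value
is 0 at 10 °C and has units of eV$^{-1}$ (`arrhenius_temp()`). $T_A$ is the
acute (experimental) temperature; $T_C$ is the chronic temperature — the
long-term average of the organism's home stream. The plastic rate model is

$$\ln I = \ln I_0 + b \ln M + E_A T_A + E_C T_C + b_C \ln M\, T_C +
E_{AC} T_A T_C.$$

The two interaction terms are the substance of the plasticity hypothesis:
$b_C < 0$ means the mass-scaling exponent *declines* with chronic warming
(small organisms elevate their metabolism after long-term warm exposure more
than large ones), and $E_{AC} > 0$ means thermal sensitivity *rises* with
chronic warming. `effective_scaling_exponent()` and
`effective_activation_energy()` expose $b + b_C T_C$ and $E_A + E_{AC} T_C$
directly.

Two coefficient sets ship with the package (`default_coefficients()`): a
"plasticity" set and a classical "no-plasticity" set, taken at printed
precision from a published field study of invertebrates in geothermally
heated Icelandic streams. They are exchange values, not package estimates:
the `lmm` machinery below refits everything from data.

## Respirometry processing

Individual rates come from closed-chamber respirometry: ~330 s of 1 Hz
dissolved-oxygen readings per animal, with one animal-free chamber per batch
as a drift control. `trace_to_rate()` takes the OLS slope through the whole
trace, scales by chamber volume, subtracts the volume-scaled control slope
and converts to µmol O₂ h⁻¹; `o2_rate_to_joules()` converts to J h⁻¹ through
the molar mass of O₂ (31.9988 g mol⁻¹), its gas density (1.429 g L⁻¹), and
the oxycalorific equivalent (20.1 J ml⁻¹), i.e. ≈0.4501 J h⁻¹ per
µmol O₂ h⁻¹. A trace that falls below 70 % of its initial oxygen
concentration is flagged (oxygen limitation), and a control exceeding 5 % of
the animal signal triggers a warning (contaminated chamber).

Population-level quality control (`population_regressions()`, `qc_filter()`)
refits the two-term log-linear model per species × stream population and
excludes populations with $n < 10$, $r^2 < 0.5$, or any slope term with
$p > 0.05$. The exclusion sentence could be read conjunctively; we apply it
disjunctively (any failure excludes) because the intent is to remove
poor-quality populations — a `rule = "all"` switch provides the conjunctive
reading. The $p$-value rule is applied to the two slope terms; the intercept
is exempt, since an intercept indistinguishable from zero carries no signal
about fit quality.

## Mixed-model selection

`fit_lmm()` fits Gaussian linear mixed-effects models of log rate with
species-level random effects, via lme4. The candidate fixed terms are the
three main effects, their three two-way interactions, and the three-way
interaction; `enumerate_fixed_structures()` lists every subset respecting
the marginality principle — an interaction never enters without all of its
lower-order terms — which gives the classical 19 candidate models for three
crossed factors.
Selection follows the two-stage protocol standard for mixed models: first
the random structure (all subsets of
`~ 1 + ln M + T_A + T_C | species`, plus a no-random-effect OLS baseline)
with the full fixed structure held constant, then the fixed structure with
the chosen random structure, both compared by maximum-likelihood AIC. ML is
used on both sides of the random-structure comparison so the OLS baseline's
likelihood is commensurable; the number of free parameters is reported
explicitly in every comparison table. The winner is refitted with REML
before coefficients are reported (Satterthwaite p-values via lmerTest).

Ties are resolved conservatively: among candidates within 2 AIC of the
minimum the model with fewest parameters wins. This mirrors the common
practice of rejecting a ΔAIC < 2 competitor that differs only by a
non-significant term, and it is what makes the selection experiments below
sharp: a superset of the true model must beat it by more than 2 AIC to be
chosen.

Numerical choices: lme4's default optimiser with derivative checks disabled
(`calc.derivs = FALSE`) for speed across simulation scans; singular
random-effect covariances are flagged on the result, not silently accepted;
optimiser failure is an error carrying the optimiser's message. The
random-effect covariance is unstructured by default, as the grouped formula
implies; `diagonal_covariance = TRUE` constrains intercept and slopes to be
independent. The diagonal option matters for hard designs: with 16 species
an unstructured 4×4 covariance asks for six correlations from sixteen
draws, fits frequently end on the boundary, and Wald standard errors of the
chronic-temperature effects are then slightly understated. A caveat in the
same vein: tests of cross-level interactions (log mass and chronic
temperature cluster within species and streams, so the effective
replication is the number of species, not of individuals) are mildly
anti-conservative under AIC; expect occasional spurious entry of an extra
interaction at slightly above its nominal χ² rate in selection
experiments.

`partial_residuals()` returns observed log rate minus every fitted component
except the terms involving one focal variable, with species random effects
removed — the quantity plotted when visualising a single effect.

## Food-web energy flux

At energetic steady state every consumer's assimilated gain balances its
losses:

$$\sum_{k \in R_i} e_{ki} w_{ki} F_{ki} \;=\; Z_i + \sum_{j \in C_i} w_{ij}
F_{ij},$$

with preferences $w$ proportional to resource biomass
(`biomass_preferences()`), assimilation efficiencies $e$ set by the
*resource's* type (plant, detritus, animal) with a logit-linear temperature
response (`assimilation_efficiencies()`), and losses $Z$ from the metabolic
model. Writing $x_j$ for consumer $j$'s total influx, each link's feeding
rate is $F_{ij} = w_{ij} x_j$ and the balance becomes a linear system in
$x$, which `solve_fluxes()` solves directly (webs here have tens of nodes; a
damped fixed-point iteration serves as an independent oracle in the test
suite, not as the solver). A negative solved flux means no steady state
exists for the given parameters and is reported as an infeasibility error
naming the nodes. Energy-balance residuals are checked to $10^{-8}$
relative.

The per-node loss is the individual rate predicted at the node's mean body
mass scaled to areal density, $Z = e^{\ln I}\,B/M$ (J h⁻¹ m⁻²) — our
reading of "individual metabolic rate approximates population loss" at the
population level; a mass-specific alternative ($e^{\ln I}/M \cdot B$,
identical for the default but kept for other conventions) sits behind
`per_mg = TRUE`. Efficiency defaults (plant 0.545, detritus 0.158, animal
0.906 at the reference temperature; logit-scale thermal sensitivity
0.164 eV) follow the published efficiency syntheses conventionally used with
this flux framework; they are not estimated here and every value is
overridable through `efficiency_config()`. Fish consumers use the same
(invertebrate-fitted) metabolic coefficients unless a separate set is
supplied — a documented extrapolation.

`total_flux()` sums assimilated flux $e\,w\,F$ over links;
`trophic_decomposition()` partitions it by resource type into herbivory
($F_H$), detritivory ($F_D$) and predation ($F_P$), which sum exactly to the
total.

## The warming scenario

`warming_scenario()` compares two models of the same web under +2 °C: the
no-plasticity model feels warming only through the acute temperature, while
the plasticity model also experiences a warmed chronic temperature,
engaging $E_C$, $b_C$ and $E_{AC}$. Assimilation efficiencies are *not*
re-evaluated at the warmed temperature by default — the scenario perturbs
the metabolic equations; a `warm_efficiencies` flag enables the sensitivity
variant. `compare_warming()` assembles per-web changes ΔF (and per-group
ΔF_H, ΔF_D, ΔF_P), tests whether the plasticity model responds more
strongly with an exact one-sided paired Wilcoxon signed-rank test, and
summarises the relative amplification
$a = 100\,(\Delta F_{\mathrm{plastic}} - \Delta F_{\mathrm{fixed}})/\Delta
F_{\mathrm{fixed}}$ as mean ± standard error across webs, excluding (and
reporting) webs whose no-plasticity response is not positive.

`wilcoxon_exact()` computes the exact null distribution of the signed-rank
statistic from the complete set of $2^n$ sign assignments, accumulated rank
by rank (identical to brute-force enumeration; the test suite verifies this
against a literal enumeration for all statistics at $n \le 10$ and against
the reference distribution). Zero differences are dropped before ranking
and counted; ties take midranks and downgrade the exactness flag with a
warning; above $n = 25$ a continuity-corrected normal approximation is
used. One-sided "less" is the direction relevant here: if the plasticity
model dominates, the fixed-minus-plastic differences are negative and $V$
is small.

A note on when amplification is positive. The chronic terms pull in
opposite directions: $E_C < 0$ and $b_C \ln M < 0$ (for $M > 1$ mg) damp
the warming response, while $E_{AC} > 0$ boosts it. At a chronic
temperature of 14 °C the plastic response exceeds the fixed one for
consumers lighter than roughly 1 mg, so the ensemble-level amplification is
positive exactly when community flux is dominated by small consumers — which
is the configuration of the stream communities this model describes, and the
mechanism (flux to herbivores near the base of the web) by which the
empirical amplification arises. The synthetic-web generator therefore uses a
small-bodied community (below); webs dominated by large consumers can show
negative amplification, and the package reports whatever the web implies.

## Spatial diagnostics

Because chronic temperature varies across sites, spatial autocorrelation
could masquerade as a temperature effect. `great_circle_matrix()` computes
haversine distances (radius 6378.137 km); `mantel_test()` correlates the
upper triangles of two distance matrices with a one-sided permutation
p-value (999 permutations by default, observed arrangement included in the
null set; an exhaustive mode enumerates all $n!$ permutations for
$n \le 8$). `morans_i()` is the classical statistic with inverse-distance
weights by default (the weighting scheme is a convention choice; row
standardisation is optional), with a permutation test in `morans_i_test()`;
`semivariogram_cloud()` emits half squared residual differences against
pairwise distance. Residuals feed in at the stream level
(`stream_residuals()`: conditional residuals of the REML winner averaged per
stream), since the mapping of individual residuals to sites is otherwise
ambiguous. Pearson correlation is used in the Mantel test.

## What the synthetic data emulate — and what they do not

`simulate_metabolic_dataset()` generates the study design the mixed model
assumes: 16 species across 9 streams whose chronic temperatures span
5–20 °C, acute exposures drawn from {5, 10, 15, 20, 25} °C, lognormal
body masses, species-level random intercepts and slopes around the
plasticity fixed effects, and Gaussian residual noise on log rate. Species
occupy each stream with probability 0.35 (species are not found in every
stream), and with ~31 individuals per population the default dataset has
roughly 1400–1550 individuals — the scale of the curated field dataset.

Defaults the field data do not pin down, chosen once and documented here:

* **Random-effect SDs.** Slope SDs default to 25 % of the corresponding
  fixed effect. The intercept SD is 0.3 log units rather than 25 % of the
  intercept: 25 % of a log intercept near −11 would be 2.8 log units,
  i.e. ~16-fold scatter among species after mass and temperature correction,
  which is biologically implausible; 0.3 corresponds to ±35 % species-level
  scatter.
* **Residual SD** is 0.30 on the log scale — consistent with populations
  that pass an $r^2 > 0.5$ quality filter in this kind of respirometry.
* **Random-effect correlations** default to zero (the fitted covariance is
  unstructured regardless).

`simulate_web()` builds niche-ordered acyclic webs: basal plants and
detritus, consumers feeding on lower-ranked nodes with configurable
connectance, body mass increasing along the niche axis over
$10^{-3}$–$10^{1}$ mg dry mass, and biomass declining with body mass as
$M^{-0.25}$. The mass span describes a community dominated by small larval
invertebrates (chironomids, simuliids, copepods) with snail-sized consumers
at the top — the community structure of the small geothermal streams this
chain models, and, per the note above, the regime in which plasticity
amplifies warming responses. Webs are rejection-sampled until the flux
balance is feasible at reference conditions (acyclic webs essentially always
are). `simulate_o2_trace()` produces paired animal/control 1 Hz traces with
known rate, drift and noise.

What passing tests on these data do **not** show about real data: the
generator draws from exactly the model family the fitting machinery
assumes (no model misspecification, no measurement error in mass or
temperature, no phylogenetic covariance among species, no within-stream
temperature variability), its webs are acyclic with biomass-power-law
structure rather than empirically assembled, and the efficiency defaults
are literature conventions. Recovery and selection results on synthetic
data are therefore a check of correctness, not of robustness.

## Problem sizes and determinism

Every generator is a pure function of its configuration and seed;
byte-identical reruns are tested. The test suite works at these scales:
parameter-recovery coverage uses 200 simulated datasets of ~1550
individuals; AIC term-set selection uses 100 of them with the full 19-model
scan; solver cross-validation uses 100 random webs of up to 12 nodes plus
20 further property-test webs; the warming ensemble uses 14 webs, matching
the number of empirical study webs; Mantel calibration enumerates all 120
permutations of 5 sites. Convergence tolerances: energy-balance residuals
$10^{-8}$ relative; solver-versus-oracle agreement $10^{-6}$; preference
normalisation $10^{-12}$.

## Known limitations

* Steady-state only: no dynamic (ODE) food-web simulation, and the loss
  term uses routine metabolic rate, which understates total losses — fluxes
  are correspondingly conservative.
* The Boltzmann–Arrhenius form is monotone in temperature; no unimodal
  thermal-performance curves, so extrapolation beyond ~5–25 °C is
  unsupported.
* Links are inputs; the package does not infer diets.
* No phylogenetic covariance in the mixed models; species are exchangeable
  given their random effects.
* ΔT is a scalar scenario; no emissions-scenario library, and confidence
  intervals for the amplification are analytic SEs, not bootstrap.
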