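# plastflux

Metabolic plasticity and food-web energy flux under warming.

`plastflux` is for ecologists and ecophysiologists who work with
respirometry data and food-web energetics. It implements a complete analysis
chain from individual oxygen-consumption measurements to ecosystem-level
predictions:

1. **Respirometry processing** — closed-chamber dissolved-oxygen traces to
   individual metabolic rates (OLS slope, volume scaling, drift-control
   correction, unit conversion to J h⁻¹) with a population-level
   quality-control filter.
2. **Metabolic-rate models** — the Boltzmann–Arrhenius model
   `ln I = ln I₀ + b ln M + E_A T_A`, and its *plastic* extension

   ```
   ln I = ln I₀ + b ln M + E_A T_A + E_C T_C + b_C ln M T_C + E_AC T_A T_C
   ```

   where `T_A` and `T_C` are standardised Arrhenius temperatures
   (`(T − T₀)/(k T T₀)`, zero at 283.15 K) for acute (experimental) and
   chronic (home-stream) exposure. With `b_C < 0` the allometric exponent
   declines with chronic warming; with `E_AC > 0` thermal sensitivity
   rises — the two signatures of metabolic plasticity.
3. **Mixed-model selection** — species-level random intercepts and slopes,
   marginality-respecting enumeration of candidate fixed structures, AIC
   selection (ML), REML reporting, partial residuals.
4. **Food-web flux balance** — steady-state energy fluxes on binary webs
   with biomass-proportional preferences, resource-type assimilation
   efficiencies, and metabolic losses; a direct linear solve with energy
   balance verified to 10⁻⁸.
5. **Warming scenarios** — +2 °C comparisons between the plastic and
   non-plastic models, exact paired Wilcoxon signed-rank tests, and the
   relative amplification of the flux response (mean ± SE across webs).
6. **Spatial diagnostics** — great-circle distances, Mantel permutation
   test, Moran's I, semivariogram cloud.
7. **Synthetic data** — generators for respirometry datasets, oxygen traces
   and solvable food webs, so the whole chain is testable without field
   data.

See the vignette (`vignettes/metabolic-plasticity-flux.Rmd`) for the models,
assumptions, parameter choices and limitations.

## Worked example

Score the packaged plasticity coefficients, then compare warming responses
across an ensemble of 14 synthetic stream webs:

```r
library(plastflux)

co <- default_coefficients("plasticity")
co
#> Metabolic coefficients (with plasticity)
#>    ln_I0        b      E_A      E_C      b_C     E_AC
#> -11.0300   0.6307   0.7217  -0.1709  -0.0741   0.1124

# plasticity flattens mass scaling and steepens thermal sensitivity
effective_scaling_exponent(co, arrhenius_temp(celsius_to_kelvin(c(5, 20))))
#> 0.685 (5 °C)  ->  0.527 (20 °C)
effective_activation_energy(co, arrhenius_temp(celsius_to_kelvin(c(5, 20))))
#> 0.639 (5 °C)  ->  0.879 (20 °C)

webs <- lapply(1:14, function(i) simulate_web(web_sim_config(seed = 100 + i)))
cmps <- lapply(webs, warming_scenario,
               coeffs_plastic = co,
               coeffs_fixed = default_coefficients("no_plasticity"),
               T_acute_K = celsius_to_kelvin(14),
               T_chronic_K = celsius_to_kelvin(14))  # dT_C = 2 by default
res <- compare_warming(cmps)
res$amplification$mean; res$amplification$se
#> amplification: 42.1 +/- 4.5 % (n = 14 webs)
res$tests$total
#> Paired Wilcoxon signed-rank test (less): V = 0, n = 14, p = 6.104e-05 (exact)
```

Warming increases total flux through every web under both models, and the
model with metabolic plasticity predicts a ~40 % larger increase in these
small-consumer-dominated communities; the exact one-sided paired Wilcoxon
test (V = 0 here: the plastic response dominates on all 14 webs) confirms
the direction. A single web solves and decomposes like this:

```r
sol <- solve_fluxes(webs[[1]], flux_parameters(webs[[1]],
         metabolic_losses(webs[[1]], co, arrhenius_temp(celsius_to_kelvin(14)),
                          arrhenius_temp(celsius_to_kelvin(14))),
         assimilation_efficiencies(webs[[1]], celsius_to_kelvin(14)),
         biomass_preferences(webs[[1]])))
sol
#> Flux solution: 57 links, total flux 0.1365 J h^-1 m^-2, max |residual| 3.47e-18
trophic_decomposition(sol)
#>    F_H    F_D    F_P
#> 0.1005 0.0179 0.0182
```

Here total flux is in J h⁻¹ m⁻², partitioned into herbivory, detritivory and
predation; the residual line reports the worst violation of per-consumer
energy balance (machine zero for a direct solve).

`run_pipeline()` chains simulate → QC → model selection → warming →
spatial stages and writes CSV/JSON artefacts plus a checksummed manifest.

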