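# defaunatr

Hurdle mixed models and mapping of hunting-induced mammal defaunation.

Tropical hunting suppresses mammal populations in ways remote sensing
cannot see: forests stay green while their large fauna is depleted or
locally extirpated. `defaunatr` implements, end to end, the statistical
pipeline used to upscale local hunted-versus-unhunted abundance
contrasts into pantropical defaunation maps:

1. **Ratio database.** Each record compares a species' abundance in a
   hunted site (X_h) with a matched unhunted control (X_c). The response
   ratio is RR = ln(X_h / X_c); X_h = 0 marks a local extirpation and is
   modelled separately.
2. **Hurdle mixed model.** A binomial (logit) stage models persistence
   (1) versus extirpation (0); a Gaussian stage models the nonzero RRs.
   Both stages carry crossed random intercepts for country, study and
   species (estimation via lme4: Laplace approximation, ML for model
   selection, REML for coefficients) over socioeconomic drivers —
   distance to hunters' access points, human population density,
   stunting prevalence, travel time, livestock biomass, protection
   status — plus body mass and diet as vulnerability traits. All-subsets
   BIC selection (supported set ΔBIC ≤ 2), marginal/conditional and
   semi-partial R², and 5-fold cross-validation over three defaunation
   categories (low DI ≤ 0.1 < moderate ≤ 0.7 < high) are built in.
3. **Projection.** Per species s and grid cell,
   `DI_s = 1 − p_persist · min(exp(RR_hat), 1)` in [0, 1]; the composite
   defaunation index is the per-cell mean `DI = Σ DI_s / S` over the S
   species in range. Size-class and trophic-guild composites, hotspot
   detection (≥ 1/3 of species with DI_s > 0.7), MESS extrapolation
   screening, and intact-forest / wilderness (HF ≤ 2) / protected-area /
   country overlays complete the map stack.
4. **Synthetic worlds.** A seeded generator produces record databases
   and raster landscapes from known parameters, so every stage is
   testable offline with ground truth.

## Worked example

```r
library(defaunatr)

cfg <- synthetic_config(n_studies = 40, records_per_study = 15,
                        n_species = 60, n_countries = 10)
db  <- generate_database(cfg, seed = 7)
summarize_database(db$records)
#> $n_records  600
#> $n_zero     109
#> $n_nonzero  491
#> $n_studies  40 ... (109/600 = 18% local extirpations)

fits <- list(
  binomial = fit_binomial_stage(db$records, default_formulas()$binomial),
  gaussian = fit_gaussian_stage(db$records, default_formulas()$gaussian))
fits$gaussian
#> hurdle_stage [gaussian, REML]
#>   fixed:  (Intercept)=-0.4351, distance_access=0.02566,
#>           log_body_mass=-0.2398, hpd=-0.005054,
#>           distance_access:log_body_mass=0.004445
#>   random SD: country=0.202, study=0.439, species=0.307  resid=0.813
```

The fitted decline per km of remoteness (+0.026 on the log-ratio
scale), the body-mass penalty (−0.24 per log-kg) and the positive
mass-by-distance interaction recover the generator's truth (0.03,
−0.25, 0.005) within two standard errors.

```r
ls  <- generate_landscape(cfg, seed = 7)
di  <- lapply(ls$species, function(s) project_species(fits, s, ls$stack))
agg <- aggregate_di(di, ls$species)
mean(agg$di, na.rm = TRUE)
#> [1] 0.6856904    # a heavily hunted synthetic landscape

rep <- evaluate_hurdle(db$records, k = 5, seed = 1)
rep
#> overall sensitivity 0.544, specificity 0.777, balanced accuracy 0.660
#> pseudo-R2 0.359
```

Cross-validated category accuracy and pseudo-R² are the same metrics
used to benchmark the published pantropical models (which report
balanced accuracy ≈ 0.6 and cross-validated pseudo-R² ≈ 0.24 on the
empirical database).

A full configured run (simulate → fit → cross-validate → project →
MESS → overlays, with a manifest of checksummed outputs):

```r
run_pipeline(list(simulate = list()), out_dir = "out", seed = 1)
```

or from the shell via the CLI wrapper:

```sh
Rscript inst/cli/defaunation run --seed 1 --out out
Rscript inst/cli/defaunation validate out/records.csv
```

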