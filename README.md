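# dmrslac

Compartmental modeling of brain lactate from diffusion-weighted MR
spectroscopy (dMRS).

## The problem

Lactate occupies a special place in brain energy metabolism: it is thought
to shuttle from astrocytes through the extracellular space into neurons.
Conventional MRS measures total lactate only. Diffusion-weighted MRS can do
better, because extracellular lactate diffuses fast and almost freely while
intracellular lactate is restricted by cell geometry — but only if the
intracellular contribution can be predicted rather than guessed. `dmrslac`
implements a three-step biophysical pipeline that does exactly that, for
attenuation curves S(b) acquired over b = 0.02–20 ms/µm² at a fixed
diffusion time (53.2 ms):

1. **Microstructure.** Pool the normalised attenuations of purely
   intracellular metabolites (NAA, myo-inositol) and fit a
   sticks-and-spheres model (neurites + somas, as in SANDI-style
   modeling) for the intracellular diffusivity `D_intra`, soma radius
   `r_soma` and sphere signal fraction `f_sphere`.
2. **Prediction.** Evaluate the same geometry with diffusivity
   `λ·D_intra` (λ = 1.3 by default: lactate is smaller and diffuses ~30%
   faster than NAA or Ins) to predict the intracellular lactate
   attenuation `S_intra_Lac(b)`.
3. **Two-pool fit.** Fit the measured lactate curve with

   ```
   S(b) = f_extra · exp(−b · D_extra) + (1 − f_extra) · S_intra_Lac(b)
   ```

   for the extracellular lactate fraction `f_extra` and the (Gaussian)
   extracellular diffusivity `D_extra`.

The package also provides the closed-form diffusion models behind the fits
(powder-averaged sticks, Gaussian-phase-distribution spheres and
cylinders), a Monte Carlo random-walk simulator used to validate them, a
synthetic two-group cohort generator with realistic noise and
between-animal variability, first-principles unpaired t tests for group
comparisons, the phenomenological biexponential comparator, and CSV/TSV
readers/writers for attenuation tables. It targets researchers analysing
dMRS metabolite attenuations — or testing analysis strategies on simulated
cohorts — in R.

## Worked example

```r
library(dmrslac)

# a synthetic cohort at the reference conditions: 5 control vs 5 APP/PS1
# animals, truth f_extra 0.36 vs 0.23, shared microstructure
curves <- generate_cohort(cohort_config(seed = 7))

res <- run_pipeline(curves, n_boot = 0)
res$summary |> dplyr::filter(parameter == "f_extra")
#> # A tibble: 2 × 5
#>   group   parameter  mean     sd     n
#>   <chr>   <chr>     <dbl>  <dbl> <int>
#> 1 APP/PS1 f_extra   0.206 0.0522     5
#> 2 control f_extra   0.354 0.0418     5

res$comparison |> dplyr::filter(quantity == "f_extra") |>
  dplyr::select(mean_a, mean_b, t_stat, p_value)
#> # A tibble: 1 × 4
#>   mean_a mean_b t_stat p_value
#>    <dbl>  <dbl>  <dbl>   <dbl>
#> 1  0.354  0.206   4.94 0.00114
```

The recovered extracellular fractions (35% in control, 21% in the
disease-model group) bracket the generating truth, and the unpaired t test
on the per-animal estimates flags the group difference. `autoplot(res)`
shows the per-animal estimates; `tidy()`/`glance()` methods expose every
fitted object as a tibble.

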