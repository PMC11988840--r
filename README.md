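# lamellar

Analysis of lamellar neutron diffraction from oriented lipid multilayer
films, with a forward simulator for verification by parameter recovery.

## The problem

Stacked membranes deposited on a solid support and hydrated from vapour
diffract a cold neutron beam into a small number of Bragg reflections at
`q_h = 2πh/d`, where `d` is the lamellar repeat (membrane + water layer)
and `h = 1…4` for typical lipid films. From the positions and integrated
intensities of those reflections one reconstructs the one-dimensional
neutron scattering length density (NSLD) profile `ρ(z)` of the repeat
unit and, from it, the structural quantities that report on membrane
stability:

* **d-spacing** `d = 2π/slope` from a weighted linear fit of
  `q_h = 4π sin(θ_h)/λ` versus order `h` (single-peak fallback
  `d = 2π/q_1`), with `σ_d` propagated from the slope error;
* **corrected structure factors**
  `|F_h| = sqrt(I_h · C_abs · C_Lor · C_flux)` with
  `C_abs = α/(1−e^{−α})`, `α = 2µt/sinθ`; `C_Lor = sin 2θ`;
  `C_flux = 1/erf(L sinθ / (√8 δ))`;
* **phases**: in a centrosymmetric stack each `F_h` needs only a sign
  `V_h ∈ {−1,+1}`; the 2^n hypotheses are screened against physical
  constraints (minimum at z = 0, maxima in the polar-head window) and
  ranked by the density they leave in the water gap, which is null at the
  8% D2O contrast;
* **profile** `ρ(z) = (2/d) Σ_h V_h F_h cos(2πhz/d)`;
* **metrics**: Gibbs–Luzzati bilayer thickness `d_b` (head-peak to
  head-peak), water layer `d_w = d − d_b`, midplane trough depth and
  hydrocarbon "hump", and a constrained decomposition into headgroup /
  CH2 / CH3 / water component curves (water from 100%−8% D2O contrast
  variation).

The package is written for structural biophysicists working with
archaeal-type films — diether bilayers (D), membrane-spanning tetraether
monolayers (T) and their mixtures (D/T) — but the chain is generic to any
lamellar stack. A forward simulator (`fixture_preset`, `build_profile`,
`synth_diffractogram`, `synth_omega_map`) renders noisy diffraction
patterns from parametric ground-truth profiles so every step is testable
by round trip.

## Worked example

Simulate a D/T (1:1) mixture at 60 °C / 95% RH / 8% D2O, add Poisson
counting noise, and run the full chain:

```r
library(lamellar)

cond <- sample_condition(60, 95, 0.08)
spec <- fixture_preset("DT11", cond)
sf   <- structure_factors_from_profile(build_profile(spec), spec$n_orders)
inst <- instrument_config()                       # lambda = 4.487 A
dg   <- synth_diffractogram(sf, inst, noise = "poisson", seed = 42)

res <- analyze_diffractogram(dg, inst, condition = cond, label = "DT11")
res
#> <membrane_analysis> DT11: d = 55.00 A (4 orders), d_b = 41.42 A, d_w = 13.58 A
res$phase
#> <phase_search_result> 8 hypotheses with rho(0) <= 0, 4 passing
#>   signs gap_density     rho0 pass_min pass_head  pass
#> 1  --+-     0.07403 -1.00000     TRUE      TRUE  TRUE
#> 2  ----     0.23110 -1.00000     TRUE      TRUE  TRUE
#> ...
```

The recovered repeat distance (55.00 Å) equals the generating period; the
winning sign vector `[−, −, +, −]` is the phase assignment expected for
these films; `d_b = 41.4 Å` is the head-to-head distance of the 4-order
reconstruction (the truncation biases it ~1.5 Å below the generator's
43 Å — see the methods vignette), and `d_w = d − d_b` exactly. Batch
analysis over many conditions: `analyze_condition_grid()`; file formats
(TSV + JSON sidecars, YAML config): `write_diffractogram()`,
`read_map()`, `write_metrics()`, `write_config()`.

A command-line interface wraps the same chain:

```sh
Rscript inst/cli/lamellar simulate --preset DT11 --rh 95 --temp 60 \
        --seed 42 --out dt11.tsv
Rscript inst/cli/lamellar dspacing --in dt11.tsv
#> d = 55.0000 +/- 0.000415 A (linear_fit, 4 orders)
```

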