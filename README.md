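# scatterprint

Multi-scale structural characterisation of dairy and plant-based emulsions
from X-ray and light scattering.

Commercial milk, yoghurt and cream products — dairy or plant-based — are
hierarchical colloids: micrometre oil droplets, protein particles and
carbohydrate networks at hundreds of Ångström, and triglyceride crystal
packing at a few Ångström. Combined USAXS, SAXS and WAXS measurements cover
momentum transfers *Q* from 3×10⁻⁴ to 3 Å⁻¹, probing real-space lengths
2π/*Q* from about 2 µm down to 2 Å in a single composite curve.
`scatterprint` provides the analysis layer for such data: it is written for
food-structure and soft-matter researchers who have reduced 1D curves in
hand and want reproducible, model-light structural read-outs.

The package implements:

- **Curve handling** — reading/writing plain-text reduced curves, background
  subtraction, angle→*Q* conversion (*Q* = (4π/λ) sin(θ/2)), and
  least-squares log-space merging of multi-configuration curves (default
  overlap window 0.0052–0.0055 Å⁻¹).
- **Slit smearing and desmearing** — forward infinite-slit (Bonse–Hart)
  smearing *I*ₛ(*Q*) = (1/L)∫₀ᴸ I(√(Q²+u²)) du with slit length
  L = 0.015 Å⁻¹, and its inversion by Lake iteration. Smearing lowers a
  Porod *Q*⁻⁴ tail to *Q*⁻³, the signature of sharp-interface scattering in
  raw Bonse–Hart data.
- **Porod analysis** — the specific surface area from the Porod plateau,
  *S* = *I Q*⁴ / 2π(Δρ)², and the equivalent droplet radius *r* = 3/*S*
  (spheres), with Δρ the X-ray scattering-length-density contrast between
  oil and water.
- **Peak analysis** — baseline-aware peak detection, d = 2π/*Q* spacings,
  and assignment of triglyceride polymorphs (α hexagonal, β′ orthorhombic,
  β triclinic) and the 42 Å 2L lamellar repeat from a reference catalogue.
- **Structural fingerprints** — per-sample maps of normalised intensity and
  |d ln I / d ln Q| on a 100-point log-*Q* grid, rendered as heat maps on a
  linear 0 (black) to 4 (white) scale.
- **Composition correlations** — Spearman rank correlations (exact
  permutation p-values at small n) between intensity read-outs at probe *Q*
  values and fat/carbohydrate content.
- **Colloid formulae** — DLS cumulant polydispersity PDI = 2a₂/a₁²,
  Stokes–Einstein sizing r = k_BT/6πηD, Henry/Smoluchowski zeta potential
  ζ = 3U_Eη / 2εf(κr_p), and % w/w → molarity conversion.
- **Synthetic data** — a forward generator for emulsion-like curves
  (polydisperse-sphere Porod term, power laws, lamellar and crystal peaks,
  water halo, counting noise) and DLS correlation functions with planted
  ground truth, so the full pipeline is testable without any measured data.

## Worked example

A synthetic cream-like emulsion (36% w/w fat as 0.5 µm droplets), measured
through the slit-smeared USAXS chain and analysed back to a droplet radius:

```r
library(scatterprint)

model <- emulsion_model(
  porod_sphere(radius_um = 0.5, polydispersity = 0.2,
               volume_fraction = fat_volume_fraction(36), delta_rho = 7.7e-7),
  q_range = c(3e-4, 5e-3), n_points = 150
)
usaxs <- generate_emulsion_curve(model, technique = "USAXS")

smeared   <- slit_smear(usaxs, slit_length = 0.015)  # Bonse-Hart geometry
desmeared <- desmear(smeared)                        # Lake iteration

result <- specific_surface(porod_plateau(desmeared), delta_rho = 7.7e-7,
                           dispersed_volume_fraction = fat_volume_fraction(36))
dplyr::select(result, specific_surface_area, equivalent_radius_um)
#> # A tibble: 1 × 2
#>   specific_surface_area equivalent_radius_um
#>                   <dbl>                <dbl>
#> 1                54552.                0.550
```

The recovered radius (0.550 µm) matches the surface-weighted radius of the
planted lognormal distribution. WAXS peak positions identify the fat crystal
polymorph — a complete β (triclinic) set at 1.37, 1.65 and 1.70 Å⁻¹:

```r
assign_polymorph(c(1.37, 1.65, 1.70)) |>
  dplyr::filter(supported) |>
  dplyr::distinct(polymorph, q_position, d_spacing)
#> # A tibble: 3 × 3
#>   polymorph      q_position d_spacing
#>   <chr>               <dbl>     <dbl>
#> 1 beta_triclinic       1.37      4.59
#> 2 beta_triclinic       1.65      3.81
#> 3 beta_triclinic       1.7       3.70
```

and a synthetic DLS correlation function analysed by cumulants returns the
planted polydispersity:

```r
g2 <- generate_dls_correlation(median_radius = 1500, spread = 0.3)
glance(cumulant_pdi(g2))
#> # A tibble: 1 × 7
#>      pdi    a1     a2 floored window_min window_max     n
#>    <dbl> <dbl>  <dbl> <lgl>        <dbl>      <dbl> <int>
#> 1 0.0902  692. 21621. FALSE    0.0000001    0.00345   130
```

Fingerprint heat maps come from `build_fingerprint()` +
`autoplot()`; sample sets with planted composition–intensity links from
`generate_sample_set()` + `correlate_composition()`.

## Vignette

`vignettes/structural-fingerprints.Rmd` describes the models, the numerical
choices (quadrature, extrapolation, iteration defaults, fit windows) and
what the synthetic-data generator does and does not emulate.
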