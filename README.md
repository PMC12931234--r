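# aggrekin

Mechanistic analysis of amyloid self-assembly kinetics from
complementary biophysical assays: thioflavin-T (ThT) progress curves,
dynamic light scattering (DLS), negative-stain TEM morphometry,
native-MS binding data and SEC peak fractions. Built for studies of
ataxin-3 (the spinocerebellar-ataxia-type-3 protein) and
aggregation-modulating ligands such as the molecular tweezer CLR01,
but the machinery is generic.

## The model

Aggregation is described by a two-population nucleation-and-growth
moment model. With α(t) the aggregate mass fraction and P(t) a
normalized particle number,

    dα/dt = (kn·Δµ0 + k2·Δµ0·α)(1−α) + k+·Δµ0·P·(1−α)
    dP/dt = (kn·Δµ0 + k2·Δµ0·α)(1−α)

whose three rate products (h⁻¹) quantify primary nucleation
(kn·Δµ0), elongation (k+·Δµ0) and fibril-surface-catalysed secondary
nucleation (k2·Δµ0); only products with the initial supersaturation
Δµ0 are identifiable. Aggregate mass is split between a small (R2) and
a large (R1) population whose Rayleigh-weighted (mass·R³) scattering
shares are compared with DLS intensity distributions. `fit_joint()`
estimates the three products from ThT curves and DLS shares
simultaneously; per-curve half-times t50 and growth rates v50 come
from the closed-form autocatalytic sigmoid fit of
`fit_progress_curve()`.

Supporting tools: CONTIN-style regularized inversion of DLS
autocorrelation functions (`invert_acf()`), the ImageJ-style TEM
particle pipeline (`tem_preprocess()`, `measure_particles()`,
`classify_particles()`), K_D from native-MS abundances
(`kd_from_abundances()`), and seeded synthetic-data generators for
every assay (`generate_*`).

## Worked example

Simulate a wild-type-like joint dataset from published control
parameters and recover the mechanism:

```r
library(aggrekin)

truth <- kin_params(kn_dmu0 = 12.3e-5, k2_dmu0 = 0.14, r2 = 15, r1 = 150)
ds <- generate_joint_dataset(truth, noise_sigma = 0.02, dls_snr = 100,
                             dls_times = c(0, 16, 24, 48, 72), seed = 1)
fit <- fit_joint(ds$data, seed = 1)
fit
#> Joint ThT + DLS nucleation-and-growth fit
#>   kn*dmu0    = 0.0001308 h^-1  (se 9.88e-06)
#>   kplus*dmu0 = 0 h^-1  (se NA)
#>   k2*dmu0    = 0.1378 h^-1  (se 0.00214)
#>   rss: ThT 1.602, DLS 0.001273; regime: secondary-nucleation-dominated
```

The fitted products match the generating values (kn·Δµ0 = 1.23e-4,
k2·Δµ0 = 0.14 h⁻¹) within a few percent; elongation, absent from the
truth, is reported as exactly 0 (a bound hit); and the regime label
identifies secondary nucleation as the dominant pathway. The fitted
constants also reproduce the per-curve ThT half-times:

```r
tht_fits <- lapply(split(ds$data$tht, ds$data$tht$well_id), function(cv)
  fit_progress_curve(cv[, c("time_h", "fluorescence")]))
check_halftime_consistency(fit, tht_fits)$max_rel_dev
#> [1] 0.007360703
```

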