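# catchcurve

Length-converted catch-curve analysis for data-poor benthic fisheries:
estimate total instantaneous mortality *Z* from shell-length records,
compare it across management regimes, sites and years, and decompose it
against a no-take natural-mortality reference to quantify fishing pressure
— including illegal fishing pressure in strata where extraction is banned.

## Who this is for

Stock-assessment and marine-ecology analysts working with the kind of data
artisanal fisheries actually produce: one row per measured individual
(species, site, management regime, fishing ground, year, length in mm) and
nothing else. The motivating system is the central-Chilean benthic fishery
— territorial-use-rights areas (TURFs/MAs) embedded in open-access grounds
(OAAs), with a single no-take area (NT) as the unfished control — and its
two flagship resources, loco (*Concholepas concholepas*, banned from
open-access extraction) and keyhole limpets (*Fissurella* spp.).

## The method

Under constant recruitment and mortality, cohort abundance decays as
*e*^(−*Z a*), so the log catch frequency at age is linear in age:

    log C = −Z · A + B

1. Lengths are aged by inverting the von Bertalanffy growth curve
   *L(a) = L∞ (1 − e^(−K(a − t₀)))* (K = 0.433/yr loco, 0.160/yr limpets;
   L∞, t₀ supplied by configuration). Over-asymptote lengths are dropped
   and counted (or clamped, by flag).
2. Ages are binned into half-open 0.2-yr classes; stray right-tail
   observations behind a gap of ≥ 4 empty classes are excluded.
3. The age of full recruitment is the maximum of a GCV smoothing spline
   through the catch curve, located on a dense grid.
4. OLS of log count on age over the descending limb gives *Z* (slope
   magnitude), its SE, 95% CI and R².
5. Regime/site/year contrasts are ANCOVAs on the stacked limbs (the
   `level:age` interaction tests slope homogeneity, Type II sums of
   squares), with single-df post-hoc slope contrasts, a year-trend
   regression and a pooled-variance species t-test.
6. `decompose_mortality()` splits *Z* into the no-take reference *M* and
   *F = Z − M*; for a banned species, *F* > 0 in open access is the
   catch-curve signature of illegal fishing.

An equilibrium cohort simulator (logistic selectivity × exponential
survival, von Bertalanffy growth with individual length variability)
generates synthetic length records shaped like the original survey
(3 regimes, 3 sites, 5 managed areas, 1999–2013, per-cell sample sizes
73–6,753), so the whole pipeline is testable without any data download.

## Worked example

```r
library(catchcurve)

gp  <- growth_params(linf = 150, k = 0.433, t0 = 0)
cfg <- sim_config(m = 0.98, f = 0.9, n = 2000, growth = gp,
                  recruit_age = 2.5, seed = 42)
fit <- catch_curve(simulate_cohort(cfg), gp)
fit
#> Catch-curve fit (log C = -Z A + B)
#>   Z = 1.260 /yr (SE 0.078, 95% CI 1.099-1.420), R2 = 0.920
#>   full recruitment at 2.53 yr; 25 limb classes; 1999 records (1 dropped)
```

The generating truth is *Z* = *M* + *F* = 1.88/yr; the estimate (1.26,
CI 1.10–1.42) illustrates the attenuation that sparse right-tail classes
and ageing error impose on length-converted catch curves — see the methods
vignette for why absolute *Z* values should be read as comparative indices.

The full regional comparison on a synthetic study fixture:

```r
des  <- study_design("loco")
recs <- make_study_fixture(study_fixture_spec(des[des$year == 2013, ],
                                              seed = 42, n_per_cell = 2000))
rep <- run_regional(recs, species = "loco")
rep$loco$fits[, 1:5]
#>   group         z       se_z     ci_lo     ci_hi
#> 1    NT 0.6493354 0.03454123 0.5794692 0.7192017
#> 2    MA 0.8346465 0.04452320 0.7447301 0.9245629
#> 3   OAA 1.1415112 0.07751348 0.9827320 1.3002903
rep$loco$comparison
#> Slope comparison (regime): interaction F = 18.69 on (2, 108) df, p = 1.072e-07
#>   per-level Z: NT = 0.649, MA = 0.835, OAA = 1.142
rep$loco$decomposition$OAA$f_est      # fishing mortality in open access
#> [1] 0.4921758
rep$loco$illegal_fishing_inferred     # banned species, F > 0 in OAA
#> [1] TRUE
```

Mortality is lowest in the no-take area, intermediate in co-managed areas
and highest in open access, and the positive open-access *F* for a banned
species is reported as inferred illegal fishing — the qualitative pattern
the method exists to detect.

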