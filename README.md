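# lakesar

Multimodel island species–area relationship (ISAR) analysis for
postglacial lake fish communities.

## What it does, and for whom

Lakes behave as "inverted islands": larger lakes hold more fish species.
For young postglacial lake archipelagos — the peri-Alpine lakes of the
Rhine, Rhône, Po and Danube catchments are the motivating system — the
questions are (i) which functional form best describes the ISAR of the
pre-1900 native fauna, (ii) whether the relationship exceeds what passive
sampling from a regional pool would produce, (iii) how fast such a
relationship can assemble at all, and (iv) how species introductions and
extirpations have reshaped it. `lakesar` is for macroecologists and
biogeographers who want that full pipeline as tested, scriptable R
functions.

The core statistical machinery is multimodel inference over a catalogue of
SAR forms *S* = *f*(*A*; θ) — 24 enabled by default, including the power
model *S* = *cA*^*z*, the rational function

    S = (c + zA) / (1 + dA),   asymptote  S → z/d  as  A → ∞,

persistence, Monod, Gompertz, Lomolino, Weibull and beta-P curves, and four
piecewise threshold forms on ln *A*. Each model is fitted by Poisson
maximum likelihood on the untransformed richness scale (10 seeded random
starts, bounded simplex search), then ranked by AICc with Akaike weights.
Around it sit community scenarios (OC, OC+Int, OC−Ext, CC), a
leave-one-catchment-out robustness check, the log–log power fit
ln *S* = *c* + *z* ln *A*, a hypergeometric rarefaction null model, a
Gillespie colonisation–speciation–extinction simulator, and a
synthetic-data generator that emulates the system's statistical structure.

## Worked example

```r
library(lakesar)

d <- generate_dataset(seed = 11)          # 79 synthetic peri-Alpine lakes
rich <- scenario_richness(d$occurrences, d$lakes, "OC")$richness
range(rich)
#> [1]  4 46

rk <- sar_fit_all(d$lakes$area_km2, rich, seed = 42)
head(as.data.frame(rk)[1:7], 3)
#>      model shape_class k      logL     AICc delta_AICc    weight
#> 1 rational  asymptotic 3 -212.3787 431.0774   0.000000 0.4334827
#> 2 pw_cont1   piecewise 4 -212.2033 432.9463   1.868904 0.1702823
#> 3    asymp  asymptotic 3 -213.5126 433.3467   2.269281 0.1393873

attr(rk, "fits")$rational
#> SAR fit: rational  (k = 3, n = 79)
#>   theta: c = 7.658, z = 1.136, d = 0.03066
#>   logL = -212.3787, AICc = 431.0774, converged starts = 5
```

The data were generated from a rational curve, and the rational function
wins the AICc ranking (weight 0.43); its fitted parameters imply a
richness ceiling of ẑ/d̂ ≈ 37 species. The log–log power fit gives the
slope and intercept used for between-catchment comparison:

```r
fit_linear_power(d$lakes$area_km2, rich, d$lakes$catchment)[1:2, c(1, 4, 5)]
#>   group intercept slope
#> 1   all     2.245 0.222
#> 2 Rhine     2.256 0.211
```

a slope *z* ≈ 0.22 on the natural-log scale. Scenario comparison refits
everything under the human-modified communities:

```r
cmp <- compare_scenarios(d$lakes, d$occurrences, seed = 42)
cmp[cmp$group == "all", ]
#>        scenario group best_model intercept slope d_intercept d_slope
#> 1            OC   all   rational     2.245 0.222       0.000   0.000
#> 6   OC_plus_Int   all   rational     2.501 0.222       0.255   0.000
#> 11 OC_minus_Ext   all   rational     2.112 0.245      -0.133   0.023
#> 16           CC   all   rational     2.399 0.239       0.154   0.017
```

Introductions proportional to richness raise the intercept (+0.26 ≈
ln 1.3) and leave the slope untouched — the generator's introduction model
made visible. The simulator asks how long such a relationship needs to
assemble:

```r
zslope_vs_age(sim_config(), d$lakes$area_km2, ages = c(0.015, 1, 5),
  reps = 20, seed = 2)[, 1:2]
#>     age      mean_z
#> 1 0.015 0.000000000
#> 2 1.000 0.012283
#> 3 5.000 0.126874
```

— essentially flat at the 15 ky postglacial age, still shallow at 1 My.

A command-line front end wrapping these functions is installed at
`inst/cli/lakesar.R` (`fit`, `scenario`, `null`, `simulate`, `synth`
subcommands).

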