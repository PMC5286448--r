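# smipp

Decompose the trend and inter-annual variability of annual gross primary
productivity (GPP) into the contributions of plant **phenology** — the
start (GS_start) and end (GS_end) of the growing season — and plant
**physiology** — the seasonal maximum of daily GPP (GPP_max). The package
is aimed at carbon-flux and land-surface-phenology analysts working with
8-day gridded GPP products or daily flux-tower GPP, together with
co-registered daily climate.

## The model

Per pixel or site, yearly anomalies (Δ, departures from the record mean)
of annual GPP are regressed on the anomalies of the three indicators:

```
ΔGPP = η_start·ΔGS_start + η_max·ΔGPP_max + η_end·ΔGS_end + ε
```

with ΔGS_start counted positive when the start *advances* and ΔGS_end
positive when the end *delays*. The fitted η are sensitivity coefficients
(g C m⁻² per day of advance/delay; g C m⁻² yr⁻¹ per g C m⁻² d⁻¹). Each
year's anomaly then splits into three components η_x·Δx whose trends and
consistency-weighted shares attribute the long-term trend and the
inter-annual variability of annual GPP to the three indicators.

Indicators come from smoothed seasonal curves — a sixth-degree polynomial
in DOY for 8-day composites, singular spectrum analysis (4 leading
eigentriples) for daily series — thresholded at 10% of the long-term mean
GPP_max. Climate sensitivity relates GS_start/GS_end to the mean
temperature of the 30 days preceding their long-term mean dates, and
GPP_max to June–July–August means.

A seeded synthetic generator (`simulate_site()`, `simulate_grid()`)
produces daily/8-day GPP and daily climate with exact, analytically
placed ground truth, so every stage has a recovery test without any
external data.

## Worked example

```r
library(smipp)

site <- simulate_site(truth_params(seed = 42))      # 15 synthetic years
ind  <- extract_phenology(site$gpp, cadence = "daily")
head(ind[, c("year", "gs_start", "gpp_max", "gs_end", "annual_gpp")], 4)
#>   year gs_start   gpp_max gs_end annual_gpp
#> 1 2000      117  9.957164    281   1066.735
#> 2 2001      122 10.251817    287   1106.921
#> 3 2002      116 10.629765    276   1091.325
#> 4 2003      123 10.248919    285   1057.364

fit <- fit_smipp(build_anomalies(ind))
fit
#> SMIPP fit (15 years)
#>   eta_start:    6.595 g C m-2 per day of advance (p = 3.53e-07)
#>   eta_max:     80.475 g C m-2 yr-1 per g C m-2 d-1 (p = 1.06e-08)
#>   eta_end:      6.190 g C m-2 per day of delay (p = 3.55e-06)
#>   R-squared: 0.9744

ia <- iav_contributions(decompose_anomalies(fit))
sprintf("IAV shares: start %.1f%%  max %.1f%%  end %.1f%%",
        ia$c_start, ia$c_max, ia$c_end)
#> "IAV shares: start 22.4%  max 61.9%  end 15.7%"
```

Reading: at this synthetic site a one-day earlier start adds ~6.6 g C m⁻²
to the annual total, one extra unit of peak daily GPP adds ~80 g C m⁻²,
and the regression explains 97% of the year-to-year variance; the peak's
component alone accounts for ~62% of the inter-annual variability (the
shares sum to 100 by construction). An end-to-end gridded run —
simulate → smooth → indicators → fit → attribute → sensitivity — is
available as `run_pipeline(pipeline_config(...))`, or from the shell via
`inst/scripts/run-pipeline.R`.

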