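# fibrildyn

Quantitative analysis of monomer–fibril exchange, fibril stability and
aggregation kinetics for functional amyloids such as the *E. coli* curli
subunit CsgA and its Asp "gatekeeper" mutants.

Functional amyloids polymerize under tight control: gatekeeper residues
suppress nucleation while mature fibrils stay extremely stable. Probing
that behaviour quantitatively takes four very different measurements, and
this package implements the analysis for all of them:

* **DEST NMR** (dark-state exchange saturation transfer): a two-site
  Bloch–McConnell model of the visible monomer ⇌ fibril-bound dark state
  exchange. Off-resonance continuous-wave irradiation saturates the dark
  state (transverse relaxation rate R₂ᵈᵃʳᵏ ≈ 31,000 s⁻¹); exchange carries
  the saturation to the visible pool and attenuates its signal. Fitting
  the attenuation profiles I(ω)/I₀ at two RF field strengths yields the
  dissociation rate k_off, and p_B = k_onᵃᵖᵖ/(k_onᵃᵖᵖ + k_off) gives the
  transiently bound fraction.
* **Relaxation**: mono-exponential CPMG decays I = I₀e^(−R₂τ) and
  inversion recovery I(t) = I∞(1 − 2a·e^(−R₁t)); the fibril-induced R₂
  increase is the apparent association rate,
  k_onᵃᵖᵖ = R₂(+fibrils) − R₂(monomer).
* **Chemical stability**: the two-state formic-acid dissolution model
  y_diss = 100 / (1 + 10^(−m_FA([FA]₅₀ − [FA])/1.36)), giving the
  midpoint FA50, the m-value and ΔG = |m_FA|·FA50.
* **Kinetics**: lag time, growth rate and plateau from sigmoidal ThT
  traces (with principled flagging of non-aggregating traces), and
  single-fibril elongation rates from TIRF length/time series.

Every stage has a seeded synthetic-data generator, so the full pipeline is
testable end to end with no external data. See the methods vignette
(`vignettes/monomer-fibril-exchange.Rmd`) for the models, conventions and
limitations.

## Worked example

```r
library(fibrildyn)

## forward-simulate a noisy two-field DEST dataset for a wild-type-like
## variant (koff = 900 /s) and fit koff back
params <- exchange_parameters(kon_app = 4.3, koff = 900,
                              r1_free = 3, r2_free = 9.1, r2_dark = 31000)
scheme <- saturation_scheme()      # 700 ms, 180/350 Hz, 15 offsets ±35 kHz
dat <- gen_dest_dataset(params, scheme,
                        noise_spec("additive", 0.01,
                                   seed = derive_seed(1, "wt")))
fit_dest(dat, scheme, dest_default_profile()$fixed)
#> DEST two-site exchange fit
#>   koff = 1000 +/- 62.2 /s  (bound fraction 0.4282%)
#>   residual RMS = 0.00968 over 30 points; converged: TRUE

## the apparent association rate from the fibril-induced R2 increase
estimate_kon_app(13.4, 9.1)$kon_app
#> [1] 4.3

## formic-acid stability of the mature fibrils
s <- normalize_to_reference(
  gen_dissolution(60, -0.8,
                  noise = noise_spec("multiplicative", 0.05, seed = 11)))
fit_dissolution(s$fa_percent, s$y_diss)
#> Two-state formic-acid dissolution fit
#>   FA50 = 59.899 +/- 0.044 %  |m_FA| = 1.049 +/- 0.24 kcal/mol/%FA
#>   dG = 62.8 +/- 14 kcal/mol  residual RMS = 1.54

## ThT kinetics and single-fibril elongation
fit_sigmoid(gen_tht(lag = 30, rate = 80, plateau = 800,
                    noise = noise_spec("additive", 8, seed = 2)))
#> ThT features: lag = 30 h, growth = 80.5 a.u./h, plateau = 800.8, t1/2 = 35 h
growth_rate_tirf(fibril_length_series(c(0, 10800), c(0, 20.088)))$rate_nm_s
#> [1] 1.86
```

Reading the numbers: the fitted k_off of 1000 ± 62 s⁻¹ recovers the
generating 900 s⁻¹ within the scatter expected at σ = 0.01 attenuation
noise, and corresponds to ~0.43% of monomers transiently fibril-bound;
the dissolution midpoint of 59.9% FA sits in the observed 55–65%
transition window; the 20.088 µm / 3 h fibril gives the canonical
1.86 nm/s elongation rate.

## Command line

```sh
exec/fibrildyn simulate --scenario wt --kind dest --sigma 0.01 --seed 1 --out wt.csv
exec/fibrildyn fit-dest --input wt.csv --out wt_fit.json
exec/fibrildyn report --config config.json --seed 1 --out report_dir
```

Subcommands: `simulate`, `fit-dest`, `fit-relaxation`, `fit-dissolution`,
`tht-features`, `tirf-rate`, `report`. Scenario presets `wt`, `dm`, `tm`,
`qm` carry the standard fixed parameters (k_onᵃᵖᵖ = 4.3 s⁻¹, R₁ = 3 s⁻¹,
R₂ = 9.1 s⁻¹, R₂ᵈᵃʳᵏ = 31,000 s⁻¹).

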