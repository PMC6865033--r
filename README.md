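# netaging

Fits and simulates a parsimonious gene-network reliability model of
cellular aging for replicative lifespan (RLS) data — the number of
divisions a yeast mother cell completes before senescence.

## The science

Aging is quantified by the mortality rate μ(t) = −d ln S(t)/dt; the
classical description is the Gompertz hazard μ(t) = R·e^(Gt). This
package implements a null model in which Gompertz-like aging emerges from
parts that individually do not age: a cell is m essential modules in
series, each an essential gene with n parallel interactions whose
strength decays exponentially at constant rate λ, each interaction active
at birth with probability p. A module dies when its last interaction
decays; any module death kills the cell. For t ≪ 1/λ the network hazard
has the closed form

    μ_net(t) = R (1 + t/t0)^(n−1),   t0 = (1−p)/(pλ),
    R = c·m·n·(pλ)^n·t0^(n−1),       c = 1/(1−(1−p)^n)

with survival S_net(t) = exp((R·t0/n)(1 − (1+t/t0)^n)). For t ≪ t0 this
approaches Gompertz with G = (n−1)/t0, so a fitted (R, t0, n) splits the
rate of aging into a network-configuration part (n, the apparent average
number of lifespan-influencing interactions per essential node) and a
reliability part (t0, the "initial virtual age" of a partially wired
network). The package provides:

* closed-form hazard/survival/density for the network, Gompertz and
  Weibull models, plus the explicit binomial-sum hazard and the
  mechanistic ↔ phenomenological parameter mappings (`R/core-models.R`);
* maximum-likelihood fitting with multi-start Nelder–Mead, AIC model
  comparison and bootstrap uncertainty (`fit_mle()`, `compare_models()`,
  `bootstrap_fit()`);
* exact inverse-CDF and mechanistic cell-by-cell simulators with
  empirical-hazard diagnostics (`sample_closed_form()`,
  `simulate_mechanistic()`, `empirical_hazard()`);
* cross-strain analyses over fitted parameter tables: Strehler–Mildvan
  correlation, mediation of the correlation through t0, and interaction
  decay-time summaries (`strehler_mildvan()`, `mediation_test()`,
  `decay_summary()`), with a bundled table for 15 wild yeast isolates
  (`wild_isolates()`);
* a command-line interface (`aging_cli()`, wrapper in `inst/exec/`).

See `vignettes/network-aging-model.Rmd` for assumptions, numerical
choices and known limitations (in particular: t0 and n are individually
weakly identified along the Gompertz-limit ridge; always report bootstrap
spread).

## Worked example

Simulate one strain from the model, compare the three models by AIC, and
bootstrap the network fit:

```r
library(netaging)
d <- sample_closed_form(network_params(R = 0.0047, t0 = 56.2, n = 7.9),
                        1000, seed = 42, strain = "demo")
d
#> Lifespan dataset 'demo': 1000 cells, mean RLS 26.64 (range 0.315176-56.8747)
compare_models(d, seed = 1)
#> Model comparison (lower AIC is better)
#>      model k   loglik     aic converged delta_aic
#> 1  network 3 -3795.36 7596.72      TRUE   0.00000
#> 2 gompertz 2 -3799.96 7603.91      TRUE   7.18826
#> 3  weibull 2 -3830.25 7664.50      TRUE  67.78050
bootstrap_fit("network", d, B = 100, seed = 42)
#> network model bootstrap (100/100 converged resamples, seed 42)
#>         mean        sd
#> R   0.004212  0.000742
#> t0 52.524341 36.662048
#> n   7.542416  3.258964
#>   AIC 7595.03 +/- 38.12
```

The three-parameter network model recovers the generating parameters
(R = 0.0047, t0 = 56.2, n = 7.9) within the bootstrap spread and beats
the two-parameter Gompertz fit by ΔAIC ≈ 7 on its own data; the wide
bootstrap sd on t0 is the expected ridge effect, not a failure.

Cross-strain analyses on the bundled wild-isolate table:

```r
column_summary(wild_isolates())
#>         mean  min  max
#> t0      45.4 30.7 74.0
#> n        7.0  6.1  8.0
#> avg_rls 31.3 23.9 44.1
s <- decay_summary(wild_isolates(), p_assumed = 0.7)
#> mean 1/lambda = 106, range 72-173 cell divisions
strehler_mildvan(wild_isolates())
#> Correlation gomp_G ~ gomp_R over 15 strains
#>   slope -0.05047, intercept -0.01857
#>   r = -0.633, R^2 = 0.401, p = 0.01133
mediation_test(wild_isolates(), B = 1000, seed = 1)
#> Mediation of gomp_R -> gomp_G through t0 (15 strains)
#>   total -0.05047 = direct -0.004019 + indirect -0.04645
#>   proportion mediated 92.0% (95% CI 70.3%-127.4%, B = 1000)
```

Interpretation: across the isolates the rate of aging G falls with
log10(R) (Strehler–Mildvan), log10(R) rises with t0, and most of the
G–log10(R) association is transmitted through t0 — interaction
reliability, not network configuration, mediates the correlation. The
mean interaction survival time of ~106 divisions (at assumed p = 0.7) is
well above the ~31-division average lifespan, validating the t ≪ 1/λ
working regime.

Command line (after install):

```sh
Rscript inst/exec/netaging simulate --model network --R 0.005 --t0 50 \
    --n 7 --n-samples 1000 --seed 1 --out lifespans.csv
Rscript inst/exec/netaging compare --input lifespans.csv --seed 1
Rscript inst/exec/netaging decay-summary --p-assumed 0.7
```

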