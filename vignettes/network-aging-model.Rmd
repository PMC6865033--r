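---
title: "A gene-network reliability model of cellular aging"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A gene-network reliability model of cellular aging}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netaging)
```

## The model

Replicative aging of budding yeast is quantified by the mortality rate
$\mu(t) = -\mathrm{d}\ln S(t)/\mathrm{d}t$, with $t$ counted in cell
divisions. The classical description is the Gompertz hazard
$\mu(t) = R\,e^{Gt}$: $R$ is the initial mortality rate (lifespan
potential at birth) and $G$ the rate of aging. `netaging` implements a
parsimonious network model in which Gompertz-like aging *emerges* from
parts that do not age at all.

The cell is modelled as $m$ essential modules in series: each consists of
one essential gene plus $n$ lifespan-relevant interactions in parallel.
Every interaction is a non-aging component — its strength decays
exponentially with constant rate $\lambda$, like radioactive decay — and
an interaction is active at birth only with probability $p$ (binomial
activation, reflecting stochastic gene expression). A module fails when
its last interaction decays, which is equivalent to deleting an essential
gene; failure of any module kills the cell.

For ages well inside the interaction decay scale ($t \ll 1/\lambda$) the
network hazard collapses, via the binomial theorem, to a three-parameter
closed form

$$\mu_{net}(t) = R\,(1 + t/t_0)^{n-1}, \qquad
  t_0 = \frac{1-p}{p\lambda}, \qquad
  R = c\,m\,n\,(p\lambda)^n t_0^{\,n-1},$$

with $c = 1/(1-(1-p)^n)$ the normalization that conditions on modules
being born functional. $t_0$ is the *initial virtual age of the system*
(IVAS): a partially wired network ($p<1$) is born looking already aged.
Survival and density follow as
$S_{net}(t) = \exp\!\big(\tfrac{Rt_0}{n}(1 - (1+t/t_0)^n)\big)$ and
$f_{net} = S_{net}\,\mu_{net}$. For $t \ll t_0$ the hazard approaches the
Gompertz form with $G = (n-1)/t_0$, so the model is a mechanistically
interpretable extension of the Gompertz model: $n$ reports network
configuration, $t_0$ reports interaction reliability.

Two routes to the hazard are kept deliberately distinct in the code: the
explicit binomial sum over connection patterns
(`network_hazard_binomial()`, integer $n$ only) and the closed form
(`network_hazard()`, real $n > 1$). Their equality to $10^{-10}$ relative
error over an integer grid is a standing test of the algebra.

## Parameters and defaults

| parameter | meaning | unit | typical fitted range |
|---|---|---|---|
| $R$ | initial mortality rate | per division | 0.002–0.007 |
| $t_0$ | initial virtual age (IVAS) | divisions | 16–120 |
| $n$ | interactions per essential node | — | 6–8 |
| $m$ | essential modules | — | ~1000 (17% of ~6600 genes); simulations default to 500–1000 and expose it |
| $p$ | activation probability at birth | — | assumed 0.5–0.9 |
| $\lambda$ | interaction decay rate | per division | implied: $1/\lambda$ ~ 70–670 |

$m$, $p$ and $\lambda$ are not separately identifiable from a fitted
$(R, t_0, n)$: they enter $R$ only as a composite. The package therefore
exposes the mapping in both directions given an *assumed* $p$
(`as_network_params()`, `decay_rate_from_t0()`), mirroring how the mean
interaction survival time $1/\lambda = p\,t_0/(1-p)$ is back-calculated
for the wild isolates (mean 106 divisions at $p=0.7$).

The fitted $n$ is real-valued — an apparent average over a heterogeneous
network — so the phenomenological type accepts any $n > 1$, while the
binomial sum and the mechanistic simulator demand integer $n$. $n = 1$ is
rejected by the public constructor (it degenerates to a constant hazard;
use the Gompertz type with $G = 0$), but the mechanistic mapping permits
it, since a wiring count of one is a legal non-aging network.

## Fitting

`fit_mle()` maximizes the exact log-likelihood
$\sum_i \ln f_{net}(t_i)$ by Nelder–Mead on log-transformed coordinates
($\log R$, $\log t_0$, $\log(n-1)$; analogously for Gompertz and
Weibull), which enforces the parameter domains without a constrained
solver. Starts come from a deterministic moment-matched grid ($t_0$ over
$\{0.5,1,2,4\}\times$ mean lifespan, $n$ over $\{2,4,8,16\}$, $R$ set so
the model median equals the sample median) plus seed-controlled jittered
restarts; ties are broken first-found, so results are bit-reproducible.
Convergence tolerance is $10^{-8}$ on the objective, 2000 iterations per
start. Integer lifespans are treated as continuous draws from $f_{net}$
(no interval-censoring correction — at lifespans of 14–48 divisions the
discreteness is second order), and right-censoring is refused rather than
mishandled.

Two numerical guards matter in practice. First, everything is evaluated
in log space: $(1+t/t_0)^n$ overflows early, while
$n\log(1+t/t_0)$ does not; survival underflows cleanly to zero at extreme
ages. Second, the network likelihood has a *degenerate ridge*: as
$n, t_0 \to \infty$ at fixed $(n-1)/t_0$ the model converges to Gompertz,
and for samples whose unbounded maximum sits at that limit the optimizer
would run to infinity. `fit_mle()` bounds $n \le 30$ (user-settable
`n_max`, far above the biological 6–8); a fit pinned at the bound means
"this sample is effectively Gompertz". The same ridge makes $t_0$ and $n$
individually wide-spread estimates even at 1000 cells, while $R$ and the
implied $G = (n-1)/t_0$ are tightly identified — a caveat to keep in mind
when interpreting single-strain point estimates, and the reason the
bootstrap (`bootstrap_fit()`, default $B = 100$ resamples with
replacement, non-converged replicates dropped and counted) should always
accompany them.

Model comparison uses AIC ($2k - 2\ln\hat L$, $k = 3$ network, 2
Gompertz/Weibull), not AICc. The Weibull comparator uses the standard
shape/scale convention, hazard $(k/\sigma)(t/\sigma)^{k-1}$ — a
convention choice, since only a "Weibull AIC" column and not a formula is
conventional in such tables; Weibull AICs are therefore never treated as
exactly reproducible reference values.

## What the simulators emulate — and what they do not

`sample_closed_form()` inverts $S_{net}$ exactly (one uniform per cell),
so its draws follow the phenomenological model by construction; a
Kolmogorov–Smirnov check against $S_{net}$ is part of the test suite.

`simulate_mechanistic()` runs the generating story itself: per module a
conditioned-binomial number of active interactions (the sampling
counterpart of $c$), module failure at the maximum of that many
exponential decay times (drawn by inversion from a single uniform), cell
death at the first module failure. It emulates independence everywhere —
no interaction repair, no age-dependent $\lambda$, no correlated module
failures, no essential–essential interactions — exactly the null
hypothesis the model articulates. It does *not* emulate features of real
lifespan assays: integer-valued division counts, ascertainment error,
dissection censoring, or genotype heterogeneity within a strain. A green
simulation test therefore establishes internal consistency of model,
sampler and fitter, not fidelity to any particular laboratory dataset.

One quantitative subtlety is worth stating precisely, because it decides
what the tests can honestly assert. The binomial-sum hazard is an
early-age approximation of the exact series-system hazard: it linearizes
$1 - e^{-\lambda t} \approx \lambda t$ and drops the module-survival
denominator. Against the exact hazard (computable by quadrature) its
error at $n = 7$, $p = 0.7$, $\lambda = 0.005$ is about $+7\%$ at
$\lambda t = 0.05$, $+17\%$ at $\lambda t = 0.1$ and $+46\%$ at
$\lambda t = 0.2$. At 50,000 simulated cells the Monte-Carlo standard
error of a unit-bin hazard estimate is only 3–5%, so the simulation
distinguishes the approximation from the exact curve well before
$\lambda t = 0.2$. The simulator is validated against the *exact* hazard
(it matches within 3 SE essentially everywhere); emergence-of-Gompertz
diagnostics (`hazard_trend()`) use an early window defined as
$\lambda t \le 0.1$ (and $t$ well below $t_0$), chosen from this
truncation-error analysis so that approximation bias stays within the
stated 25% band on $\hat G$.

## Cross-strain analyses

`strehler_mildvan()` regresses $G$ on $\log_{10} R$ across strains (OLS
with Pearson $r$, $R^2$ and the slope's two-sided $p$); the Gompertz $R$
column is the default exposure, following the Strehler–Mildvan
convention. `mediation_test()` uses the classical product-of-coefficients
estimator with a percentile bootstrap over strains (default $B = 1000$):
total $c$ from outcome~exposure, direct $c'$ and mediator slope $b$ from
outcome~exposure+mediator, $a$ from mediator~exposure; indirect $=ab$,
proportion mediated $=ab/(ab+c')$. Quasi-Bayesian mediation frameworks
differ in estimator details, so proportions mediated are interpreted
directionally (is most of the association transmitted through $t_0$?),
not as exact reproductions. The bundled 15-strain wild-isolate table is
transcribed from printed (rounded) values; summaries recomputed from it
can differ from narrative figures by one unit in the last place, and only
the quantities that reproduce from the printed table are asserted
exactly.

## Known limitations

* $t_0$ and $n$ are individually weakly identified (the Gompertz-limit
  ridge); report them with bootstrap spread, and prefer $R$ and
  $(n-1)/t_0$ when comparing strains.
* The binomial closed form undercounts late-age mortality relative to the
  exact mechanism once $\lambda t \gtrsim 0.1$; fitted $n$ may
  underestimate true wiring for the same reason.
* No censoring, no frailty mixtures, no chronological-lifespan support,
  and no likelihood-ratio nested tests — the model space is deliberately
  the parsimonious null.
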