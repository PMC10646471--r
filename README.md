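# forager

Bayesian analysis of age-specific foraging returns with Cobb-Douglas trait
effects.

## What this package is for

A central question in human life-history research is why productivity rises
so steeply across childhood: is it accumulating *ecological knowledge*, or
just a bigger, stronger body?  `forager` implements a nonlinear Bayesian
structural-equation analysis of individual foraging returns for two
resource types collected largely by children and teenagers — shellfish
gathered in the intertidal zone (kg per person-trip) and snare traps set in
forest and fields (captures per trap) — separating a saturating age
component from the elasticities of knowledge, height and grip strength.
It is aimed at behavioural ecologists and quantitative anthropologists who
want the full pipeline as tested, reusable code: data schema and CSV I/O, a
synthetic-data generator matched to the study design, a 2PL item-response
model for survey-based knowledge, the return model with latent imputation
of missing traits, MCMC with convergence diagnostics, a
recovery/calibration harness, and counterfactual reports.

## The model

For individual $i$ on trip (or trap) $f$:

$$R \sim \mathrm{lognormal}\!\big(\log(\alpha\,\phi_i\,\psi_f),\ \sigma\big)
\quad\text{(shellfish)},\qquad
S \sim \mathrm{Poisson}(\alpha\,\phi_i\,\psi_f)\quad\text{(traps)}$$

$$\phi_i = e^{\iota_i}\,\big(1 - e^{-\beta a_i}\big)^{\gamma}\,
           k_i^{\zeta}\,h_i^{\eta}\,g_i^{\theta},
\qquad
\psi_f = d_f^{\xi}\,e^{t_f \tau}$$

with age $a$, knowledge $k$, height $h$, grip $g$ (unit-mean scaled),
duration/exposure $d$, tide $t$, and priors
$\alpha \sim \text{half-normal}(0,1)$,
$\beta,\gamma,\sigma \sim \text{Exponential}(1)$,
$\iota,\zeta,\eta,\theta,\xi,\tau \sim \mathcal N(0,1)$.  Knowledge comes
from a two-parameter logistic IRT model of the survey responses; missing
traits are latent variables regressed on age and sex.  The methods vignette
(`vignettes/foraging-returns-model.Rmd`) documents every convention,
parameter and design choice.

## Worked example

```r
library(forager)

d <- simulate_forage_data("table1", seed = 1)   # study-sized synthetic data
summary(d)
#> Foraging dataset summary
#>   shellfish: 39 participants, 35 trips, 156 person-trips (mean age 17.5)
#>   traps:     24 installers, 335 trips, 724 traps, 28 successful (mean age 14.7)
#>   knowledge: 27 respondents x 77 items (2079 responses)
#>   trait missingness: height 0.11, grip 0.17, knowledge 0.57

fit <- fit_foraging(d, "shellfish",
                    forage_config(chains = 2, warmup = 800, iter = 800,
                                  include_traits = FALSE, seed = 1))
fit
#> <forage_fit: shellfish model (age only), 2 chains x 800 draws>
#>       median   5.5%  94.5%
#> alpha  2.181  1.692  2.809
#> beta   0.903  0.143  3.147
#> gamma  0.622  0.050  2.731
#> sigma  0.533  0.476  0.589
#> xi     0.281  0.036  0.521
#> tau   -0.647 -0.836 -0.488
```

`alpha` is the median catch (kg) of an average forager on an average trip;
`sigma` recovers the generating value 0.5; `tau` is clearly negative —
lower tides mean more shellfish.  The age-curve parameters `beta`, `gamma`
are weakly identified at this sample size (see the vignette on the
age-curve ridge).  Counterfactual post-processing:

```r
ac <- age_curve(fit)
ac$summary[ac$age == 10, ]
#>    age  mean  q5.5 q20.0 q35.0 q50.0 q65.0 q80.0 q94.5
#> 21  10 0.981 0.886 0.984 0.999     1     1     1     1

median(expected_returns(fit, duration_min = 180))   # 3 h trip, lowest tide
#> [1] 4.78
```

So on these synthetic data a 10-year-old is estimated at 98% of maximum
productivity (the generating curve was at 80% — the posterior leans on its
prior along the saturation ridge), and an average forager is expected to
collect about 4.8 kg in a three-hour trip at the lowest observed tide.

The knowledge pipeline and the trait model:

```r
irt <- fit_irt(d$knowledge, seed = 1)
fit2 <- fit_foraging(d, "shellfish", forage_config(seed = 1),
                     knowledge_prior = knowledge_prior_from_irt(irt))
trait_contrast(fit2, "height")     # phi contrast, observed min vs max height
outcome_contrast(fit2, "tide")     # kg contrast, lowest vs highest tide
```

A thin command-line wrapper over the same functions is provided in
`inst/cli/forager.R` (subcommands `simulate`, `fit-irt`, `fit`, `recover`,
`counterfactual`).

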