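# antcomp

Competition coefficients, colony demography and coexistence theory for ant
communities.

## The scientific problem

Competition coefficients — the per-capita suppressive effects of con- and
heterospecific density on a species' growth rate in the Lotka–Volterra model

    (1/N_i) dN_i/dt = r_i (1 − α_ii N_i − α_ij N_j)

are the basic currency of coexistence theory, yet they are almost never
measured in terrestrial animals. Ground-nesting ants with trappable,
monodomous colonies make it possible: a whole colony can be censused,
marked, released at a new point for one week, and recaptured, giving direct
colony-level birth and death rates as a function of the local ant community
around the release point. `antcomp` implements that pipeline for ecologists
working with such mark–recapture colony experiments:

* **Demography** — per-worker survival `S = W2/W1`, brood production
  `P = (B2 − B1)/W1`, net colony growth
  `G = [(M·W3 + B4) − (M·W1 + B3)]/W1` and its per-worker-weight form
  `Gw = G/M`, from validated census tables; local densities from persistent
  nest counts (present on all survey days within the foraging radius) and
  pitfall biomass proxies (catch × mean wet weight).
* **Inference** — standardized density-dependence regressions (binomial
  worker survival with a colony random intercept; weighted Gaussian brood
  and growth models with a month random intercept), downward stepwise AIC
  selection with a marginality rule, Fisher's combined test, and the
  Lotka–Volterra fit `fit_lv()`: OLS of `Gw` on standardized con- and
  heterospecific densities, whose slopes are the competition coefficients
  α_ii and α_ij and whose ratio measures the intra/inter asymmetry.
* **Theory** — a consumer–resource (chemostat) model in which the dominant
  competitor suffers conspecific density-dependent excess mortality δ·N
  from interference, with closed-form R*, interior equilibrium and critical
  δ for stable coexistence; and an inclusive-fitness model of territorial
  aggression predicting a threshold defense distance
  `d* = (1/λ) log(p0 q r_b V / (μ v_w))`.
* **Synthetic experiments** — `generate_experiment()` builds complete
  census/pitfall/nest-map tables with known ground truth (defaults set to
  the field-estimated effect sizes), used to verify parameter recovery of
  every inference stage.

## Worked example

```r
library(antcomp)

truth <- true_parameters()                      # field-estimate effect sizes
ex    <- generate_experiment(120, truth, seed = 42)
rates <- colony_rates(ex$censuses, ex$densities)
fit   <- fit_lv(rates)                          # Lotka-Volterra coefficients
fit
#> Lotka-Volterra competition-coefficient fit
#>   conspecific metric: colony_count; n = 120 colonies
#>   standardized coefficients (negative = suppressive):
#>     intra (alpha_ii):  -0.0574   inter (alpha_ij):  -0.0145
#>     ratio alpha_ii / alpha_ij: 3.95
#>   raw scale: r = 0.2306 /week, alpha_ii = 0.18, alpha_ij = 0.000814
```

The standardized slopes recover the generating values (−0.06 and −0.013 per
SD of density): intraspecific competition is several-fold stronger than
interspecific — at 120 colonies the ratio estimate (here 3.95) is still
noisy around its generating value of 4.6. `summary(fit)` adds SEs and
t-tests; `predict`, `residuals`, `simulate` and `plot` methods behave as for
other R model objects.

The theory side, with the documented reference parameters:

```r
sys <- cr_system(D = 1, S_supply = 2,
                 species = data.frame(g = c(2, 1.6), K = 1, m = 0.5,
                                      c = c(2, 1.6), delta = c(0.1, 0)))
rstar(sys)                          # 0.333 0.455 -> species 1 wins if delta = 0
coexistence_threshold(sys)$delta_crit
#> [1] 0.05055149                    # excess mortality needed for coexistence

sc <- aggression_scenario(p0 = 1, lam = 1, V = 100, r_b = 0.75,
                          mu = 0.5, q = 1, v_w = 10)
threshold_distance(sc)
#> [1] 2.70805                       # fight within ~2.7 m of the nest
```

A thin command-line wrapper (`inst/scripts/antcomp`, driving
`cli_run()`) exposes `simulate`, `demography`, `fit-density`, `fit-lv`,
`coexist` and `aggression` subcommands over the same functions.

See `vignettes/ant-competition-methods.Rmd` for the models, assumptions,
parameter meanings and design decisions.

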