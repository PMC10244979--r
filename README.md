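# kindyn — kinship dynamics of mother–offspring social bonds

`kindyn` quantifies how mother–offspring social relationships in matrilineal
cetacean societies change with offspring age and sex, from raw
photo-identification encounter tables all the way to a Bayesian model of bond
dynamics. It was built for the analysis pattern of long-term killer-whale
photo-ID studies — in particular Bigg's (mammal-eating) killer whales, where
male philopatry and female-biased *budding* dispersal (a daughter leaving her
natal unit with her own offspring after first reproduction) shape the
opportunities for late-life helping by post-reproductive females.

Intended users: behavioural ecologists and biostatisticians working with
longitudinal individual-identification data who need a tested, reproducible
implementation of this analysis chain, with a synthetic-data generator that
provides exact ground truth for every stage.

## The analysis chain

1. **Validation and filtering.** Demography (`id, sex, birth_year,
   death_year, mother_id`) and encounter tables are validated against their
   invariants. Encounters are retained from 2005 onward only when flagged as
   *full encounters*; earlier encounters only from the central repositories
   (DFO/CWR) with the minimum estimated group size not exceeding the number
   identified.
2. **Annual simple-ratio association index.** For a dyad alive in a year,
   `SRI = x / d`: `x` joint-encounter days, `d` days at least one member was
   identified. Exactly validated against a brute-force day-by-day oracle.
3. **Lagged association rate.** `g(tau)` = probability that a dyad
   associated on day `t` is associated again at lag `tau`, conditioned on
   both members being identified then; yearly lag bins up to 10 years,
   delete-one-year jackknife SEs, strata for mother × {adult son, adult
   daughter, juvenile} × reproductive status (adult: female > 12 y, male
   > 14 y, strict).
4. **Bond classification.** Annual `(x, d)` counts are fitted with a
   3-component beta-binomial mixture (EM, 20 restarts, components sorted by
   mean): *weak* / *casual* / *constant* tiers; `select_K()` tabulates
   log-likelihood, BIC and ICL over K = 2..5.
5. **Bond dynamics.** Mother–offspring dyad-years feed a Bayesian
   categorical additive mixed model (weak tier as reference):

   `logit p[i,K] = beta[sex,K] + f[sex,K](age) + eps[dyad,K]`, K = 2, 3

   with penalized-spline age smooths, a shared random-effect SD, priors
   `beta ~ N(0, 2)`, `sigma ~ half-t(3, scale 2)`, MCMC via JAGS, and 100
   multiple imputations of unknown offspring sex (`p_male = 0.5`).
6. **Synthetic truth.** `sim_config()` / `make_benchmark()` simulate a
   48-year matrilineal population (three association tiers ≈ 0.90 / 0.11 /
   0.01, budding dispersal hazard 0.08 after first birth, 5% roving sons,
   60 photo-ID days/year) with the true tier of every dyad-year.

See `vignettes/kinship-bond-dynamics.Rmd` for the models, priors, estimator
conventions and their rationale.

## Worked example

Classify dyads from the three-tier benchmark and recover the generator's
parameters:

```r
library(kindyn)

b <- make_benchmark("fig1_tiers", seed = 7)   # 3000 dyads, known tiers
fit <- fit_mixture(b$x, b$d, K = 3, n_restarts = 20, seed = 1)
fit
#> betabinom mixture, K = 3, n = 3000 dyads
#>       pi     mu    rho
#> 1 0.9638 0.0109 0.0091
#> 2 0.0245 0.1082 0.0096
#> 3 0.0117 0.9079 0.0161
#> loglik -2858.00  BIC 5780.05  ICL 6114.55  converged

cls <- classify_bonds(fit)
mean(as.integer(cls$category) == b$truth_component)
#> [1] 0.9747
```

The three component means (0.011, 0.108, 0.908) recover the generated tiers
(0.01, 0.11, 0.90): the population splits into rare constant companions
(about 1%, association probability ≈ 0.9 — maternal-unit members), a small
casual tier, and a weak remainder covering ~95% of dyads. 97.5% of dyads are
assigned their true tier.

## The analysis workflow

The full study is a numbered script chain under `analysis/`, each a thin
driver over package functions, writing its tables under `results/`:

```sh
Rscript analysis/01_simulate.R --seed 11      # population + encounters + truth
Rscript analysis/02_associations.R            # filter + annual SRI
Rscript analysis/03_lagged_rates.R            # stratified LAR + jackknife
Rscript analysis/04_bond_classification.R --seed 11
Rscript analysis/05_bond_dynamics.R --seed 11 --preset desk
```

Sample of what they report on the default synthetic study (seed 11):

```
Simulated 223 individuals (211 with known mothers) over 48 years;
16439 encounters on 60 sampling days/year; 36 social units; 1 roving males.
Annual SRI: 123256 dyad-years over 48 years (15391 unique dyads).
Mother-offspring re-association rate: 0.95-0.99 across lags;
all other dyads: 0.64-0.81.
Adult sons re-associate at 1.00 (mean over lags) vs 0.84 for adult daughters.
Classified 123256 dyad-years: 92.0% weak, 3.1% casual, 4.9% constant.
Median component means: weak 0.009, casual 0.148, constant 0.902.
Model order by BIC on 2020: K = 3.
2115 mother-offspring dyad-year records (211 dyads, 88 of unknown sex).
Constant-companion probability with the mother (posterior mean):
  daughters: 1.00 at age 10, 0.70 at age 25, 0.08 at age 40
  sons:      1.00 at age 10, 0.98 at age 25, 0.89 at age 40
```

Stage 5 writes the posterior bond-probability curves (`results/curves.csv`,
plus a population-averaged version with the dyad random effects integrated
out): daughters' probability of having their mother as a constant companion
declines steadily after maturity while sons' stays high — the sex-biased
dispersal signature. The desk preset flags its short-chain split-R-hat
(use longer chains or `--preset full` for publication-grade intervals).

`run_pipeline(run_config(...))` runs the same chain programmatically and
writes a JSON manifest (config, package version, per-stage seeds) that
suffices to reproduce a run.

## Data dialects

* `demography.csv`: `id,sex,birth_year,death_year,mother_id`; sex `F`/`M`/`U`;
  empty string = missing.
* `encounters.csv`:
  `encounter_id,date,source_org,full_encounter,min_estimated_count,identified_ids`;
  ISO-8601 dates; `identified_ids` semicolon-delimited;
  `full_encounter` ∈ `TRUE,FALSE,UNRECORDED`.

Both are UTF-8 comma-separated files that round-trip through
`write_demography()` / `write_encounters()` and the loaders.

## Package layout

```
R/                  data_io, association, lar, bondmix, dynamics,
                    simulate, pipeline
analysis/           the numbered study scripts (drivers over R/)
scripts/acceptance.R
tests/testthat/     unit, property and acceptance tests
vignettes/          methods vignette
```
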