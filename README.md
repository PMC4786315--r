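# nomadsim

An agent-based simulator of mobile pastoralism on satellite-derived
resource grids, with a land-use analysis layer.

## The problem

Dryland pastoralists (the model is motivated by Fulani transhumance in
the Sudano-Sahelian zone of northeastern Nigeria) move herds over
hundreds of kilometres in yearly cycles, tracking a forage supply that
is patchy in space and erratic between seasons and years.  Direct
tracking of herds can never cover enough space-time to say anything
general about the resource access such mobility buys.  `nomadsim` takes
the complementary route: simple adaptive agents ("NOMADs") on a gridded
environment ("ENV") whose per-site, per-month grazing resources come
from monthly NDVI raster stacks (MODIS MYD13A3-style, land-cover
adjusted) or from a built-in synthetic generator, so that movement
rules, competition, and land-use constraints can be explored over tens
of thousands of simulated years.

## The model

Each agent follows a **ROUTE** ρ: a cyclic sequence of 12 monthly
camping sites, one per calendar month.  While following it, the agent
gathers information: grazing a site records the mean resource within
GRAZE RANGE; with probability SCOUTING FREQUENCY per month it also
scouts a random site within SCOUTING RANGE.  Repeat observations of a
(site, month) pair are folded into a running time-mean R_m.  Co-located
agents share a site's resources equally (three agents on a 0.6 site get
0.2 each), and a site that hosts more than CARRYING CAPACITY
agent-visits in a year serves nothing for the rest of that year.

At yearly intervals the agent considers N candidate routes — its
current one plus random recombinations of remembered sites — scored by
the potential

    H(ρ) = α ( − Σₘ R_m(ρ(m)) + Σₘ C(ρ(m), ρ(m+1)) ) + β,   ρ(13) = ρ(1)

where C is 0 for steps within MOVE RANGE and a large penalty beyond
(optionally linear per km), and α = 2, β = 1.  A route is adopted by
the softmax rule

    P(ρᵢ) = exp(−H(ρᵢ)/E) / Σⱼ exp(−H(ρⱼ)/E)

with annealing-style noise E that interpolates linearly from 1e−6 (when
the current route's potential is 0) to 1e−2 (potential 1): agents on
good routes exploit, agents on poor routes explore.  Extensions add a
tsetse-fly disruption term δ·Σₘ T_m (remembered encounter frequency) to
the potential and monthly access schedules that deny cropland resources
outside permitted months.

The analysis layer turns runs into land-use intensity maps (mean agents
per site per month per year), dry-season (Jan–Mar) / wet-season
(Jul–Sep) composites, a four-way seasonal classification
(dry-dominant / wet-dominant / not-seasonal / not-exploited), confusion
matrices and Cohen's kappa between patterns, route ranges, and resource
summaries.

## Worked example

```r
library(nomadsim)

world <- synth_params(grid_spec(64, 64), n_years = 10, seed = 42)
env   <- generate_environment(world)      # resources + land cover + tsetse
pars  <- nomad_params(population = 5)     # baseline parameters otherwise
cfg   <- run_config(pars, env, n_years = 200, burn_in_years = 50, seed = 1)

run <- run_simulation(cfg)
run
#> <run_result> 5 agents, 200 years (150 recorded)
#>   mean resource / agent / month: 0.477 (interannual SD 0.084)
#>   mean final route range: 68.6 km

base <- random_route_baseline(env, 1000, pars, seed = 1)
sprintf("random-route baseline: %.3f (SD %.3f)", base$mean, base$sd)
#> "random-route baseline: 0.434 (SD 0.080)"

cls <- classify_sites(seasonal_summary(run$intensity), land_use_threshold = 0.01)
table(cls)
#>  dry_dominant not_exploited  not_seasonal  wet_dominant
#>            91          3574           347            84

cfg13 <- cfg; cfg13$params$carrying_capacity <- 13L
cls13 <- classify_sites(seasonal_summary(run_simulation(cfg13)$intensity), 0.01)
cohen_kappa(confusion_matrix(cls, cls13))
#> 0.450
```

Adaptive agents extract 0.477 resource units per agent-month against
0.434 for non-adaptive random routes on the same world — the
adaptation gap, at desk scale.  Most sites are never camped on
(`not_exploited`), use concentrates on a few seasonal key-resource
patches, and relaxing the carrying capacity from 4 to 13 reshuffles
route details while leaving the seasonal pattern moderately similar
(kappa 0.450 on a small grid; on the full-scale published setting the
same comparison gives 0.823).

## Command-line use

`inst/scripts/nomad` is a thin Rscript front end:

```sh
nomad run             --config cfg.json --out results/
nomad ensemble        --config cfg.json --runs 20 --out results/
nomad baseline-random --config cfg.json --agents 20000 --out results/
nomad synth           --config cfg.json --out fixtures/
```

The JSON config carries the model's parameter-table names verbatim
(`"NOMAD POPULATION"`, `"MOVE RANGE"`, ...) and either a `synthetic`
environment block or paths to ASCII-grid rasters (monthly NDVI stack,
land-cover codes, optional tsetse probabilities).  Outputs are ASCII
grids (intensity, classification) and CSV summaries.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

recomputes the package's headline check from scratch — it builds the
three-agents-on-one-site sharing scenario with the package's own
scheduler and reports the measured per-agent monthly gain as JSON.
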