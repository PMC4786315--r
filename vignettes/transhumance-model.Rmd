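---
title: "The nomadsim model: assumptions, parameters, and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The nomadsim model: assumptions, parameters, and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nomadsim)
```

`nomadsim` simulates mobile pastoralist agents on a gridded dryland
whose grazing resources vary by site, month, and year.  This vignette
is the package's own account of the model: what it assumes, which knobs
matter, what the synthetic environment does and does not emulate, and
the numerical and design choices made where the behavioral description
leaves room.

## The behavioral cycle

The unit of adaptation is the ROUTE: a cyclic sequence of twelve
monthly camping sites.  A year of simulation is twelve `step_month()`
calls followed by one `step_year()`:

1. **Move.** Every agent relocates to its route's site for the month.
2. **Capacity.** Each site keeps a yearly ledger of hosted
   agent-visits.  A site whose ledger already exceeded
   `carrying_capacity` *before* this month serves a resource value of 0;
   a site pushed over capacity *by* this month's visits still pays out
   this month and serves 0 afterwards ("remaining months of the year").
3. **Share.** The month's availability field (cyclic stack layer,
   access schedule applied, capacity zeroing applied) is split among
   agents whose grazing windows overlap: each covered site's value is
   divided by the number of covering agents (`share_mode = "share"`),
   or awarded whole to one uniformly drawn covering agent
   (`"lottery"`).  An agent's monthly gain is the mean of its window
   after sharing.
4. **Learn.** Each agent records the *pre-sharing* window mean of its
   site under the current month — what is available around the area,
   not what it managed to extract; realized shares depend on who else
   showed up, which is not information about the site.  With
   probability `scouting_frequency` it also assesses one uniform site
   within `scouting_range_km` (Euclidean) the same way.  Repeat
   observations of a (site, month) pair fold into a running arithmetic
   mean.  When a tsetse map is active, every grazed or scouted site
   also yields a Bernoulli encounter draw recorded as a running
   frequency.
5. **Adapt.** At yearly intervals the agent scores its current route
   and `n_alternatives - 1` recombinations of remembered sites by the
   potential
   `H = alpha * (-sum R_m + sum C + delta * sum T_m) + beta`
   and adopts one route by the softmax rule with annealing noise
   `E = noise_min + clip01(H_current) * (noise_max - noise_min)`.

## Parameters

| name | meaning | unit | default | basis |
|---|---|---|---|---|
| `population` | number of agents | agents | 20 | **assumption** — published grid {1..50}, baseline not recoverable |
| `move_range_km` | free-movement threshold | km/month | 100 | stated baseline |
| `graze_range_km` | assessment window radius | km | 2 | **assumption** — published grid {0..10} |
| `scouting_frequency` | scouting probability | /month | 0.2 | stated baseline |
| `scouting_range_km` | scouting reach | km | 100 | stated baseline |
| `carrying_capacity` | visits before exhaustion | agents/site/year | 4 | stated baseline |
| `update_interval_years` | route-update cadence | years | 1 | stated baseline |
| `n_alternatives` | candidate routes N | count | 10 | **assumption** — published grid {2..200} |
| `penalty` | over-range step cost | potential units | 100 | stated baseline |
| `noise_min`, `noise_max` | annealing bounds | – | 1e-6, 1e-2 | stated baseline |
| `alpha`, `beta` | potential scale/offset | – | 2, 1 | fixed in the model |
| `disruption_effect` | tsetse weight δ | – | 0 (off) | extension |

The three flagged assumptions are the values the package ships where
the original baseline is not recoverable from the published table; all
are members of the published sensitivity grids, and every experiment in
the test suite sets them explicitly where they matter.

## Numerical choices

* **Unknown sites score zero.**  A route month with no memory record
  contributes `R_m = 0` to the potential.  Candidate routes are built
  from remembered sites, so this arises only for the never-updated
  initial route; treating unknown as worthless is conservative and
  pushes agents to replace unexplored routes.
* **Noise clamp.**  The linear noise schedule is defined between
  potentials 0 and 1; outside that interval E is clamped to
  `[noise_min, noise_max]` (the description fixes the endpoints and the
  linearity, not the extrapolation).
* **Stable softmax.**  Selection probabilities are computed as
  `exp(-(H - min H)/E)` renormalized, so potential gaps up to about
  1e8 noise units stay finite.  Ties need no special handling: the
  cumulative-probability draw resolves them.
* **Capacity ledger counts agent-months.**  An agent camping two
  months on one site is charged twice; "accumulated number of visitors"
  is ambiguous between this and unique agents, and agent-month counting
  makes multi-month camping costly.  `cc_counting = "unique_agents"`
  switches to the other reading.
* **Within-month simultaneity.**  Placements and ledger charges happen
  before any gain is computed, and sharing divisors are computed after
  all placements, so nothing depends on agent order within a month.
  Route updates use only the agent's own memory and its own RNG
  substream (L'Ecuyer-CMRG, one per agent), so update order cannot
  change results either — a property the test suite checks by
  reversing the order.
* **Idempotent preprocessing.**  NDVI preprocessing (clip negatives to
  0, discount non-preferred land cover by 50%) marks the stack
  `adjusted` and passes adjusted stacks through unchanged, so the
  operation can be applied defensively.  Clipping and discounting
  commute here because the discount is multiplicative and positive.
* **SD conventions.**  Inter-annual SD is the sample SD (divisor
  n−1) of within-run yearly means; across-run SD is the sample SD of
  run means.  Kappa is reported at three decimals in summaries.

## Design choices where the description was open

* **Metrics.**  "Within range" is not given a metric.  Grazing and
  scouting-assessment windows use the Chebyshev (square) window — it
  matches pixel geometry; movement distances (move range, scouting
  eligibility, route range) use Euclidean km.  Both are switchable
  (`graze_metric`, `move_metric`) so the alternative pairing can be
  tested.
* **Disruption term.**  The tsetse extension is described as an added
  component of the potential without a formula; the package adds
  `delta * sum_m T_m` inside the parenthesis, symmetric with the
  resource term, and isolates it in `route_potential()`.  This is an
  assumption and is flagged as such here.
* **Cropland denial is resource denial.**  Scheduled-out cropland
  returns value 0 but remains traversable and campable: access to
  vegetation is denied, presence is not.
* **Scouting is observation.**  Scouted sites are assessed pre-sharing
  and do not increment the visit ledger; scouting gathers information,
  it does not host a herd.
* **Classification order.**  The seasonal classification tests
  exploitation first (annual mean ≤ 0.001 → not exploited), then
  seasonal dominance against the land-use threshold.  The prose lists
  the seasonal test first, but the published per-threshold counts keep
  the not-exploited class constant across thresholds, which is only
  possible if exploitation is decided independently of the land-use
  threshold; the implementation follows the published table.  The
  "mean frequency of visits irrespective of season" is read as the
  annual mean over all 12 months.
* **Intensity counts camping sites.**  Land-use intensity counts an
  agent on the site it camps on ("grazed a given site"), not over its
  whole grazing window; `intensity_counting = "neighborhood"` switches.

## The synthetic environment

`synth_params()` states the emulated world once; the generator exists
so that every behavioral property is testable offline.  It produces:
a monthly resource stack
`clip01(base + amplitude * season(m) + patches) * yearly_mult(y) + noise`,
a land-cover mosaic thresholded from a smooth random field, and a
southern tsetse band.  Defaults: 10 years (the length of the satellite
stream the model was designed around), dry-season base 0.25 with a 0.2
north–south gradient (Sudano-Sahelian to Sudanian greening), wet-season
amplitude 0.25 peaking June–September, 10 persistent Gaussian
key-resource patches of radius 3 km and height 0.3, lognormal yearly
multipliers with CV 0.15 (Sahelian drought variability), observation
noise SD 0.02, cropland fraction 0.53 (the study area's share), tsetse
over the southern 40% of rows.  These are field-plausible round
numbers, chosen once and not tuned against any test outcome.

What the generator does **not** emulate: realistic spatial
autocorrelation spectra of NDVI, rainfall-driven timing shifts of the
green-up, correlated drought geography (yearly multipliers are
spatially uniform), land-cover change over time, or seasonal tsetse
dynamics.  A green test on synthetic worlds therefore establishes that
the *mechanisms* behave as specified (sharing, capacity, adaptation
gap, seasonality of use), not that any particular real-world number is
reproduced.  Reproducing the published full-scale numbers (mean gain
0.345 against a random-route 0.219 on the real 324×324 ten-year MODIS
stack, 20 × 20 000-year runs) requires the real rasters and hours of
compute; the configuration and CLI support it, the desk-scale suite
does not attempt it.

## Scaled test configurations

The test suite shrinks the published experiment to desk scale and says
so: intensity conservation and the adaptive-vs-random gap run on a
64×64 synthetic world with 5 agents for 200 years (ensemble of 5);
population monotonicity runs 1/5/20 agents for 120 years on 48×48 with
three seeds.  Burn-ins shrink proportionally (50 and 20 years; the
full-scale default is 1000).  These scales were chosen for runtime
only, before looking at outcomes.

## Known limitations

* Pure R inner loop: a 20 000-year, 324×324, 20-agent run is feasible
  but slow (hours); the package is tuned for desk-scale
  experimentation and correctness, not HPC throughput.
* No livestock or human demography, herd splitting, or negotiation —
  deliberately outside the behavioral rule set.
* Raster I/O is the plain-text ASCII-grid format; GeoTIFF conversion
  must happen upstream (any GIS can do it losslessly for single-band
  monthly layers).
* The random-route baseline regenerates routes by sequential rejection;
  for tiny move ranges on large grids the wrap-closure rejection rate
  rises, which can slow baseline generation (not the simulator).
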