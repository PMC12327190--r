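# atne — eco-evolutionary food-web simulation with evolving fish growth traits

Size-selective fishing does not just remove biomass: by catching fish of
particular sizes it selects on the traits that determine size, and the
response propagates through the food web. **atne** implements an allometric
trophic network with evolution (ATNE): a guild-level pelagic food-web ODE
model in which two focal fish species — a pikeperch-like piscivore fished
with gillnets and a vendace-like planktivore fished with trawls — carry
evolving von Bertalanffy growth traits on a discrete genotype grid. The
package is aimed at fisheries and eco-evolutionary modellers who want a
tested, reproducible implementation of the full pipeline: growth-model
fitting, gear-selectivity fitting, the seasonal food-web core, the
inheritance kernel, and the burn-in/fishing experiments — all exercisable
on synthetic data with known ground truth.

## The models

**Growth.** Length at fractional age follows the von Bertalanffy model
L(a) = L∞ − (L∞ − L0)e^(−ka). Observed lengths are lognormal with location
μ_t = ln E[L_t] − σ²/2, so the distribution's mean sits on the curve. The
Bayesian fit (`fit_bvbgm()`) uses uniform priors and an adaptive
random-walk Metropolis sampler with split-chain Rhat and effective-sample
diagnostics.

**Selectivity.** Gear selectivity over length is the bell curve
Ŝ(L) = δ/(√(2π)σ) · exp(−(L−μ)²/2σ²), fitted to catch biomass per 1-cm
length class by least squares (`fit_selectivity()`). Reference fits:
gillnet μ = 46.72 cm, σ = 3.44 cm; trawl μ = 12.21 cm, σ = 1.71 cm.

**Food web.** Producers grow logistically under a shared carrying
capacity; consumers feed through a Hill-exponent multi-species functional
response; metabolic rates scale as M^(−1/4). Fishing removes biomass at
rate (E/t_end) · S_norm(L) per day over a 90-day growth season, where E is
the peak instantaneous fishing mortality (1/year) and L the genotype
cell's current length.

**Evolution.** Each focal species' age guilds are subdivided over an
(L∞, k) trait grid. At spawning, the larvae trait distribution is a
mixture over parent pairs of bivariate normal kernels centred at the pair
midpoint with covariance Σ = Ω^(1/2) Λ Ω^(1/2), where Ω combines a
genotypic component (c_V times the pair's two-point variance) and an
additive phenotypic component diag(σ̃²_L∞, σ̃²_k), and Λ carries the L∞–k
correlation ρ (baseline −0.7). Heritability is tracked as H = V_G/V_P from
the larvae distribution computed with and without the additive component.

## Worked example

Recover known growth parameters from synthetic length-at-age data, fit a
gear, and run a short eco-evolutionary scenario:

```r
library(atne)

truth <- vbgm_params(87, 0.124, 1.7)          # piscivore-like growth
laa <- gen_length_at_age(truth, sigma = 0.1, n = 500, seed = 101)
post <- fit_bvbgm(laa, default_prior_bounds("pikeperch"), seed = 7)
posterior_summary(post)
#>   parameter       mean     median       lower      upper
#> 1     L_inf 87.4360582 87.3433637 83.93831456 91.3180886
#> 2         k  0.1249653  0.1249757  0.11628771  0.1334346
#> 3        L0  1.8859852  1.8877519  1.56512590  2.1952274
#> 4     sigma  0.1029090  0.1027919  0.09756261  0.1084972

gill <- fit_selectivity(gen_catch_by_length(
  selectivity_curve(46.72, 3.44, 10000), 16:73))
gill$curve
#> Selectivity curve: mu = 46.72 cm, sigma = 3.44 cm, delta = 10000

web <- toy_foodweb(grid_n = 20)               # reduced trait grids
run <- run_scenario(web, scenario_config(burn_in_years = 10,
                                         fishing_years = 5, E = 1))
tail(run$traits[run$traits$species == "prey",
                c("year", "mean_L_inf", "mean_k", "H_L_inf")], 3)
#>    year mean_L_inf    mean_k   H_L_inf
#> 25   13   15.75424 0.5428240 0.7142947
#> 27   14   15.48793 0.5448324 0.7528405
#> 29   15   15.42614 0.5451833 0.7786463
```

The posterior means sit on the generating truth (L∞ = 87 cm within 0.5%,
k = 0.124 within 0.8%), the selectivity fit recovers the gillnet curve
essentially exactly, and five years of fishing already move the prey's
oldest-guild mean L∞ off its neutral burn-in value of 15 cm (the first
response is a transient uptick while the fished cohorts work through the
age structure), with heritability of L∞ around 0.7–0.8. Over the
100-year horizon of `analysis/05_fishing_scenarios.R` the responses are
directional and opposite between gears: trawling drives the
planktivore's mean L∞ down from 15 to 10.7–11.6 cm (more at higher E)
while gillnetting pushes the piscivore's mean L∞ up from 80 to about
83 cm — smaller, faster-through-the-net prey versus growth beyond the
gillnet window. `scripts/acceptance.R` additionally isolates pure
trawl selection: a trawl centred above the oldest prey guild's mean
length at E = 2/y lowers mean L∞ by about 2.9 cm relative to an
unfished control.

## The analysis workflow

Numbered drivers under `analysis/` reproduce the study pipeline and write
tables under `results/`:

1. `01_simulate_data.R` — synthetic length-at-age and catch-by-length data;
2. `02_fit_growth.R` — Bayesian growth fits for both species;
3. `03_fit_selectivity.R` — gillnet and trawl curve fits;
4. `04_burn_in.R` — 100-year unfished burn-in to dynamic equilibrium
   (40×40 trait grids);
5. `05_fishing_scenarios.R` — 100 fished years at E ∈ {0.5, 1, 2}/y with
   trait responses and relative biomass change per reporting group;
6. `06_sensitivity.R` — the sensitivity design over (E, c_V, σ̃_L∞, σ̃_k)
   levels at three correlation levels (3⁴ = 81 combinations per species in
   full mode; a reduced grid by default).

Run them in order from the package root, e.g.
`Rscript analysis/01_simulate_data.R`.

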