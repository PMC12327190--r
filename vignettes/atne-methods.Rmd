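---
title: "Eco-evolutionary food-web simulation with evolving growth traits: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Eco-evolutionary food-web simulation with evolving growth traits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette documents the models implemented in **atne**, the assumptions
behind them, the tunable parameters with their defaults, the numerical
choices, and what the synthetic-data generators do and do not emulate. It is
the package's methodological reference; empirical behaviour is demonstrated
by the test suite and the `analysis/` drivers, not asserted here.

## The model in outline

The package simulates a pelagic food web as an allometric trophic network
(ATN): a set of functional guilds — primary producers, invertebrate
consumers, and fish species split into age guilds — whose biomasses (mg C)
follow ordinary differential equations during an annual growth season of
`t_end = 90` days. Two focal fish species additionally carry *evolving*
life-history traits: each of their age guilds is subdivided into genotype
groups, the cells of a fixed rectangular grid over the von Bertalanffy
parameters (asymptotic length \(L_\infty\), Brody's growth coefficient
\(k\)). Size-selective fishing removes biomass preferentially from genotype
cells whose current body length lies near the gear's selectivity mode, which
shifts the trait distribution; a reproduction kernel transmits the shifted
distribution to the next cohort. The annual cycle is

1. **growth season** — the ODE system (consumption, maintenance,
   reproduction allocation, fishing) integrated over 90 days;
2. **reproduction and ageing** — pooled reproductive biomass is converted
   to larvae with efficiency `u = 0.8` and distributed over genotype cells
   by the inheritance kernel; cohorts move up one age guild, the oldest
   guild being a plus group;
3. **off-season** — fish biomass decays by maintenance respiration at half
   the in-season coefficient over the remaining 275 days,
   \(\exp(-\tfrac{f_m}{2} x (365 - t_\mathrm{end}))\).

## Growth-season dynamics

Producers grow logistically with a *shared* carrying capacity \(K\):
\(r_i B_i (1 - \sum_j B_j / K)\), the sum over all producer guilds.
Consumers (zooplankton and fish) feed through a multi-species functional
response with Hill exponent \(q\) and half-saturation \(B_0\):

\[
G_j = x_j\, y_j\, B_j\, \frac{\sum_i w_{ji} B_i^q}{B_0^q + \sum_m w_{jm} B_m^q},
\]

with feeding preferences \(w\) normalized per consumer. The resource loses
the consumer's gain divided by the assimilation efficiency \(e\) of the
link (the unassimilated fraction leaves the modelled system; there is no
detritus loop). Maintenance costs \(f_m x_i B_i\) per day. Mass-specific
metabolic rates \(x_i\) scale allometrically with carbon body mass,
\(x = a_x M^{-1/4}\); for fish guilds, \(M\) comes from the species-mean
von Bertalanffy length at mid-season guild age through the length–weight
relation \(W = aL^b\) (fresh weight) and fresh-to-dry and dry-to-carbon
fractions.

Fishing delivers the annual peak instantaneous mortality \(E\) (1/year)
uniformly over the season at rate \((E/t_\mathrm{end}) \cdot S_n(L)\) per
day, where \(S_n\) is the gear's normalized bell selectivity and \(L\) the
genotype cell's current length. A guild held at the gear mode thus ends the
season at exactly \(e^{-E}\) of its starting biomass. We interpret \(E\) as
the *peak* mortality because only normalized selectivity enters the
mortality rate; the scaling parameter \(\delta\) of the fitted selectivity
curves has no dynamical role.

Mature age guilds allocate biomass to reproduction at a constant per-day
rate `ra`; the allocation is debited from the guild and credited to a
separately tracked reproductive pool per genotype cell, which fishing
depletes in proportion to the pool-to-biomass ratio.

**Per-guild versus per-cell rates.** Metabolic and allocation rates are
computed per age guild from the species-mean growth curve, not per genotype
cell. Only the fishing term differs across cells (through cell-specific
length). Two reasons: the guild is the food-web actor (its total biomass
drives the functional response), and this makes genotype cells
demographically exchangeable in the absence of fishing, so the unfished
burn-in is exactly neutral with respect to the trait distribution — the
premise of using the burn-in as an evolutionary baseline. A side benefit is
an exact factorization: with fishing off, all cells of a guild share one
per-biomass rate, so the season ODE reduces to guild totals and the cell
shares are rescaled afterwards. `integrate_growth_season()` uses this
reduced system for large genotype-resolved states whenever `E = 0`; it is
an exact reformulation, not an approximation, and the package tests verify
the two paths agree to integrator tolerance.

## The inheritance kernel

At spawning, the parent trait distribution \(P(T_P)\) is the pool-weighted
distribution of genotype lineages summed over mature age guilds. Under
random mating with independent parents, the larvae trait density is the
mixture over parent pairs \((t_1, t_2)\), weighted \(P(t_1)P(t_2)\), of
bivariate normal kernels with mean the pair midpoint and covariance

\[
\Sigma = \Omega^{1/2} \Lambda\, \Omega^{1/2}, \qquad
\Omega = \Omega_G + \Omega_A,
\]

where \(\Omega_G = c_V\, \mathrm{diag}\!\big(\tfrac{(t_{1,L}-t_{2,L})^2}{2},
\tfrac{(t_{1,k}-t_{2,k})^2}{2}\big)\) is the genotypic component —
\(c_V\) times the two-point variance of the pair, the only symmetric
variance of two values — \(\Omega_A =
\mathrm{diag}(\tilde\sigma^2_{L_\infty}, \tilde\sigma^2_k)\) is the additive
phenotypic component, and \(\Lambda\) is the correlation matrix with
off-diagonal \(\rho\) (baseline \(-0.7\); alternatives \(-0.35\), \(0\)).
Each kernel is truncated to the trait grid, renormalized to its in-grid
mass (so spawned biomass is conserved exactly), and discretized by the
bivariate normal CDF over cell rectangles.

Heritability is tracked by computing the larvae distribution twice — with
the full kernel (phenotype) and with \(\Omega_A = 0\) (genotype) — and
taking the ratio of marginal variances, \(H = V_G / V_P\), per trait. Both
variances come from the discretized, truncated distributions, so \(H > 1\)
is possible near grid boundaries, where truncation shrinks the wider
phenotype distribution more than the genotype mixture.

### Numerical implementation

Because \(\Omega\) is diagonal, every kernel shares the correlation
\(\rho\), and the kernel depends on the pair only through the absolute cell
lags; cell masses are translation-invariant up to the parity of the pair
midpoint on the half-cell lattice. The mixing engine (C++) therefore caches
one windowed template of cell masses per (lag, parity) and reduces the
yearly mixture to weighted template additions, merging the symmetric lag
directions. The bivariate normal CDF is a double-precision implementation
of Genz's Gauss–Legendre scheme. On grids of at most 1024 cells templates
span the whole grid and the mixture is exact to CDF precision (the test
suite checks agreement with a brute-force double sum to \(10^{-12}\) total
variation); on larger grids template support is truncated at 4.5 SD,
excluding under \(4\times10^{-6}\) of a kernel's mass, and the final
renormalization restores the total. Parent cells holding less than `eps_P`
(default \(10^{-8}\)) of the parent mass are pruned from the pair sum;
`eps_P = 0` gives the exact double sum. Degenerate kernels (zero variance
along an axis, which occurs in the genotype-only computation for same-cell
pairs) place their mass in the cell containing the midpoint, split evenly
when the midpoint falls on a cell edge — a measure-zero tie-break.

The trait grid is `40 x 40` cells per species by default (the full-scale
configuration of 10,000 genotype groups corresponds to `100 x 100`; the
total count, not the per-axis split, is what matters, and the working
resolution keeps a year of simulation below a second). Grid bounds follow
the population-level growth fits: \(L_\infty \in [70, 90]\) cm,
\(k \in [0.1, 0.2]\)/y for the pikeperch-like piscivore and
\(L_\infty \in [10, 20]\) cm, \(k \in [0.45, 0.65]\)/y for the vendace-like
planktivore. The initial trait distribution is a truncated bivariate normal
centred at the *middle of the grid* with SD one tenth of each axis span:
the grid middle is the stationary point of the neutral (unfished) mixing
dynamics, whereas an off-centre start would drift toward it through
truncation-renormalization until equilibrated. Centring elsewhere (e.g. at
the species' posterior-mean estimates) is supported through
`initial_trait_distribution()`.

## Bayesian growth model

Length at fractional age \(a_t\) is lognormal,
\(L_t \sim \mathrm{Lognormal}(\mu_t, \sigma)\) with
\(\mu_t = \ln E[L_t] - \sigma^2/2\) and
\(E[L_t] = L_\infty - (L_\infty - L_0)e^{-k a_t}\), so the distribution's
*mean* equals the growth curve (the location parameter is expressed in
terms of the expected value; without the \(-\sigma^2/2\) correction the
curve would be the median instead). Fractional age counts completed years
plus days since the most recent June 1 birthday over a 365-day year, leap
days ignored. Priors are independent uniforms on all four parameters;
collapsed bounds pin a parameter (the mechanism for fixing \(L_0\) at a
literature value). The posterior is sampled with an adaptive random-walk
Metropolis sampler — 4 chains, 1000 warmup and 4000 retained draws by
default, diagonal proposal scaling for the first half of warmup and
empirical-covariance proposals thereafter, adaptation frozen at the end of
warmup. Any correct MCMC would do; the model, not the sampler, is the
substance. Split-chain potential scale reduction and Geyer
initial-monotone effective sample sizes are always computed, and
non-convergence raises a warning rather than passing silently.

## Gear selectivity

Selectivity over length is the bell curve
\(\hat S(L) = \frac{\delta}{\sqrt{2\pi}\sigma} e^{-(L-\mu)^2/2\sigma^2}\),
fitted to catch biomass aggregated into 1-cm length classes (class \(c\)
covers \([c, c+1)\); the class midpoint \(c + 0.5\) is the evaluation
abscissa) by minimizing the sum of squared residuals with Nelder–Mead
simplex search from at least five starts seeded from data moments (maximal
class for \(\mu\), biomass-weighted SD for \(\sigma\)). Fitted reference
values used throughout the package: gillnet (50 mm mesh) on the piscivore
\(\mu = 46.72\) cm, \(\sigma = 3.44\) cm; trawl on the planktivore
\(\mu = 12.21\) cm, \(\sigma = 1.71\) cm. Only the normalized shape enters
the dynamics.

## Synthetic data and the toy food web

The generators produce every input the analysis needs with known ground
truth: `gen_length_at_age()` draws from exactly the lognormal observation
model above (default ages uniform on a quarter-year grid up to 12 years
plus within-quarter jitter — broad age coverage for recovery experiments;
the lognormal shape \(\sigma\) is a free input, as no fitted value is
available to adopt); `gen_catch_by_length()` adds Gaussian noise to the
selectivity curve at class midpoints, matching the least-squares fitting
criterion, and clips at zero.

`toy_foodweb()` builds a reduced, connected web: producers grazed by
zooplankton; zooplankton eaten by the planktivore level (all age guilds of
the vendace-like prey plus young piscivore guilds); the prey guilds and
young piscivores eaten by the older piscivore guilds. Its rate constants
are fixture values chosen once for a persistent, stationary unfished
equilibrium — they are documented defaults, not estimates of any real
lake. With them the unfished annual map settles to a fixed point (terminal
coefficients of variation around \(10^{-4}\)), every guild persists, and
the planktivore persists under 100 years of trawling at \(E = 2\)/y. Two
caricature features should be kept in mind when interpreting simulation
outcomes: the piscivore's plus group accumulates a large standing stock
(big fish have small allometric losses and face no other mortality in the
model, so the biomass pyramid is top-heavy), and with only four non-fish
guilds the web offers none of the redundancy of the full lake
parametrization. Passing tests on this fixture demonstrate the *mechanics*
— conservation, selection response, trophic propagation — not quantitative
lake dynamics, whose full parametrization is outside the package's scope.

## Experiments

`run_scenario()` executes the annual cycle: a 100-year unfished burn-in to
dynamic equilibrium, then 100 years of fishing at \(E \in \{0.5, 1.0,
2.0\}\)/y shared by both fished species. Runs are deterministic given the
configuration and tolerances (there is no stochastic forcing; the recorded
seed only labels the run). Extinction of a focal species terminates a run
with a labelled status and partial outputs. `sensitivity_suite()`
enumerates all combinations of the varied species' \((E, c_V,
\tilde\sigma_{L_\infty}, \tilde\sigma_k)\) levels — low/medium/high per
parameter, \(3^4 = 81\) combinations, the other species held at medium —
at each correlation level; runs are seeded per combination, so execution
order is irrelevant, and per-run CSV outputs make an interrupted suite
resumable. `relative_biomass_change()` compares terminal-window mean
biomasses (default window 20 years; an explicit choice, since "equilibrium"
could equally be read as a single final year) between fished and unfished
runs per reporting group: focal piscivore, focal planktivore, zooplankton,
phytoplankton (plus other piscivores/planktivores when the web has them).

## Numerical choices and limitations

* Season integration uses deSolve with `rtol = 1e-6`, `atol = 1e-8`:
  lsoda for small guild-level systems, the (adaptive, non-stiff) Adams
  method for genotype-resolved states, where any implicit stiff method
  would need an impractically large dense Jacobian; the seasonal dynamics
  are smooth, halving tolerances moves season-end biomasses by well under
  0.1%, and the integrator would signal step-size failure if stiffness ever
  bit. Negative excursions are clamped at zero, and biomasses below the
  extinction threshold `eps_B = 1e-6` mg C are zeroed at season end only
  (mid-season clamping would break the integrator's error control).
* Within-season growth maps day \(d\) to effective age \(a + d/t_\mathrm{end}\):
  one growth-year accrues over the 90-day season and none off-season, so
  annual increments match the growth curve at integer ages.
* The problem sizes used by the packaged checks — 40 x 40 grids, 100-year
  phases, 500-record growth fits, 50 coverage replicates, a 2-level
  sensitivity grid — were chosen so the full suite runs on a single CPU in
  minutes while leaving each check's conclusion unchanged at larger sizes.
* Not modelled: detritus and nutrient recycling, temperature forcing,
  stochastic environmental noise, density-dependent growth, evolution of
  maturation age or size, post-trawl escape mortality, and any
  individual-level genetics (the genotype groups are biomass compartments,
  not individuals; heritability is therefore a hybrid quantity, as the
  variance decomposition acts on the larvae distribution rather than on a
  pedigree).
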