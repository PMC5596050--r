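---
title: "A dynamic state variable model of winter fattening and nocturnal hypothermia"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A dynamic state variable model of winter fattening and nocturnal hypothermia}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

A 10–13 g parid wintering in the boreal forest runs its energy budget on a
knife edge. Daylight lasts eight hours, nights are sixteen, and overnight
resting metabolism consumes on the order of a gram's worth of fat — close to a
tenth of lean body mass — every single night. Carrying a larger fat reserve
buffers starvation but is not free: a heavier bird pays more to fly and forage
and is easier prey for hawks and owls, so fat is taxed by a mass-dependent
predation risk. One escape from this starvation–predation trade-off is
facultative rest-phase hypothermia: dropping body temperature a few degrees at
night cuts resting expenditure by up to roughly a third, at the cost of being
lethargic — and therefore more vulnerable — should a predator strike.

`winterbird` treats hypothermia depth as a state the bird re-decides every
five minutes, alongside its fat reserve, and asks: what sequence of behaviours
maximises the probability of surviving the whole winter? The answer is
computed exactly (up to discretisation) by stochastic dynamic programming and
then probed by forward Monte Carlo simulation of cohorts following the optimal
policy.

## The model

**States.** A bird is described by fat reserves $x \in [0, X_{max}]$ (kJ),
body-temperature depression $y \in [0, Y_{max}]$ (°C below the normothermic
42 °C; $y=0$ is normothermic), and the weather $w \in \{G, B\}$, observed at
the start of each 5-minute period $t$. A 100-day winter has $288 \times 100$
periods plus 96 extra so the horizon $T$ falls on a daybreak; period-of-day 96
is 08:00, daylight is [08:00, 16:00).

**Behaviours.** Six: (1) intensive foraging, (2) cautious foraging, (3)
resting in predator-safe cover, (4) cooling by one temperature step, (5)
rewarming by one step, (6) holding the current hypothermic depth. Foraging
requires daylight and (in the baseline) normothermia; 4 requires $y <
Y_{max}$; 5 and 6 require $y > 0$.

**Fitness recursion.** $F_w(x, y, t)$ is the maximum probability of surviving
from $t$ to the end of winter. Each period the bird picks the behaviour $i$
maximising

$$ (1-\beta_i)\, \Big[\, p_{ww}\{\lambda_i F_w(x', y', t+1) + (1-\lambda_i)
F_w(x'', y', t+1)\} + (1 - p_{ww})\{\cdots_{w^c}\} \Big], $$

where $\beta_i$ is the per-period predation hazard, $\lambda_i$ the
probability a foraging period succeeds (an unsuccessful one still yields a
fraction $\delta = 0.8$ of the gain), and $p_{ww}$ the weather persistence.
The four fat outcomes $x', \ldots$ combine the foraging lottery with the
weather branch: the expenditure term is multiplied by $\gamma = 1.2$ in
branches where the coming period is bad weather. Reserves hitting zero are
absorbing death; reserves are capped at $X_{max} = 148$ kJ (4 g of fat, far
above anything the optimal policy carries).

**Energetics.** Resting metabolism is $C_{RM} = 45$ kJ/day, charged per
period as $45/288$ kJ. Activity scales it: behaviour $i$ costs
$C_{RM}(1 + \mu_i + \mu_i x / X_{max})$ per period with $\mu = 2$ for
foraging, so a lean forager pays $3\times$ and a maximally fat one $5\times$
resting metabolism. A hypothermic bird pays
$(C_{RM} - \varepsilon C_{RM}\, y/Y_{max})\gamma_w$: at the deepest depression
and the default $\varepsilon = 0.3$ it saves 30% of resting expenditure. The
daily gross gains (80 kJ intensive, 60 kJ cautious, times the food multiplier
$\Delta$) are *expected* full-day gains: the realised gain of a successful
period is $G/(n_{day}(\lambda + (1-\lambda)\delta))$ so that the lottery
averages back to the daily figure. An optional extra warm-up cost $C_{WU}$ (0
or 6 kJ) is pro-rated over the rewarming periods.

**Thermoregulation.** Depth moves on a lattice of `n_hypo_steps` nodes, one
$\sigma = Y_{max}/6$ step per period, so a full rewarm takes six periods
(30 min). The °C axis is presentational: only the saving fraction
$\varepsilon\, y / Y_{max}$ enters the energetics. We deliberately discretise
the axis at the resolution the dynamics can traverse (7 nodes) rather than a
finer display grid — transitions then land exactly on nodes, the policy is
well defined in $y$, and a cool-then-rewarm pair is exactly reversible. The
number of rewarming periods (and with it $\sigma$) is a configuration knob,
`n_warmup_periods`.

**Predation.** Daylight hazards for normothermic behaviours are
mass-dependent and accelerate above a critical load $x_{cr} = 37$ kJ (1 g of
fat): $\beta_i(x) = \beta_{iB}(1 + ((x - x_{cr})/x_{cr})^{\alpha})$. The
exponent is not pinned by the data the model is built from; the default
$\alpha = 3$ reproduces the accelerating daily-risk curve and is exposed as
`alpha_exp` (the anchors $\beta(x_{cr}) = \beta_B$ and $\beta(2 x_{cr}) = 2
\beta_B$ hold for every $\alpha$). Daily risks convert to per-period hazards
by compounding, $\beta_p = 1 - (1-\beta_d)^{1/n}$, over the 96 daylight or
192 night periods, so per-period survival factors multiply back exactly to
the daily figure. Hypothermic birds in daylight face a high constant hazard
(5×10⁻² per day) in the baseline; two variants (`daytime_hypo_risk_mode`)
soften it to a linear-in-depth ramp above the resting risk, or all the way
down to the resting risk. At night, hypothermic birds face 3.7×10⁻⁴ per
night, while a normothermic sleeper keeps behaviour 3's own 2.5×10⁻⁴: the
~1.5× premium is the lethargy cost of hypothermia, and without it nocturnal
hypothermia would be strictly free and could never be abandoned however small
its saving. A bird that *chooses* to cool this period is exposed to the
hypothermic risk class (and pays the hypothermic cost) at its post-decision
depth the same period.

**Weather.** A two-state Markov chain, the only effect of bad weather being
the 20% expenditure surcharge. Per-period persistences are 0.9983 (good) and
0.9965 (bad); good weather is the prevailing state. The chain exists to make
the environment unpredictable rather than to simulate meteorology.

**End of winter.** Winter may end at any daybreak from day 80 onwards. The
hazard and the daybreak-only reward are reconciled by applying the end hazard
only at the candidate daybreaks (days 80 through the horizon, 22 of them),
with conditional probability $1/(\text{candidates remaining})$ — which makes
the realised end daybreak exactly uniform and reaches certainty at $T$. A
bird alive when winter ends scores 1 only if its fat covers the warm-up
requirement $x_C(y) = (y/Y_{max}) C_{WU} + \lceil y/\sigma \rceil
C_{RM}^{per}$: a hypothermic bird must still fund its return to normothermia.

## Numerics

**Fat interpolation.** Per-period fat changes (~0.1–0.9 kJ) are smaller than
the 1.48 kJ grid step, so next-period values are interpolated. Linear
interpolation — the textbook choice for dynamic state variable models — is
available (`interp_method = "linear"`) but is numerically diffusive here: at
night the fat decline is deterministic given weather, and iterating a linear
interpolant over ~29,000 periods smears that shift like a random walk with
standard deviation $\sqrt{n/6}\,\Delta x$ per night, several kJ of artificial
noise that leaks probability into the starvation boundary and biases survival
badly downward. The default is a Steffen monotonicity-limited cubic Hermite
interpolant: it can never overshoot the bracketing nodes (values stay in
$[0,1]$, monotone slices stay monotone) and suppresses the smearing, making
the backward value agree with the interpolation-free forward simulation on
the baseline 100-step grid. The convergence study is one loop:

```{r convergence}
library(winterbird)
for (nf in c(100, 200, 400)) {
  fit <- solve_policy(winter_params(n_fat_steps = nf))
  ens <- simulate_cohort(fit, n_birds = 1000, seed = 1)
  cat(nf, fit$start_survival, cohort_survival(ens)$survival, "\n")
}
```

**Tie-breaking.** Exact value ties (common in regions where survival is
already 0) resolve towards the lower-hazard behaviour, then the lower index,
so policies are deterministic and reproducible.

**Degenerate inputs.** $x \le 0$ is death everywhere including the terminal
period; transitions above $X_{max}$ are clamped (no reflected mass); rewarming
from a depth that is not a multiple of $\sigma$ clamps at normothermia via
$\eta = \min(\sigma, y)$.

**Forward simulation.** Each of the (default 1000) birds carries its own
counter-based RNG stream derived from the master seed, so trajectories are
invariant to cohort size and reproducible bit-for-bit. Fat is continuous in
the forward pass; the policy is looked up at the nearest fat node. Winter-end
daybreaks are drawn per bird from the same uniform-end hazard the solver
uses. Mid-winter summaries default to day `mid_winter_day(params)` (day 50 of
the full baseline), well clear of the start transient — the routine
stabilizes within the first week — and of the end window.

## What the simulated cohorts do and do not emulate

The forward cohorts emulate the *model* bird: identical physiology across
individuals, a two-state weather world shared in distribution but drawn
independently per bird, fixed 8-h photoperiod, no food hoarding, no
individual variation, no immune or sleep costs of hypothermia, and predation
as a memoryless hazard rather than predator encounters. Tests passing on
these cohorts therefore validate the optimisation and simulation machinery —
value/policy consistency, probability conservation, bookkeeping — not the
realism of any particular parameter; conclusions about real parids inherit
all of the structural simplifications above.

## Design decisions worth knowing about

* **Expected-gain normalisation.** The daily gains are interpreted as
  expected gross gains over a full foraging day, inclusive of the success
  lottery. Interpreting them instead as conditional-on-success totals shrinks
  every day's expected intake by 4% — enough, on this budget, to starve every
  simulated bird at every saving level, which is inconsistent with the
  behavioural regime the model is meant to produce.
* **Night risk classes.** Resting at night keeps the safe-habitat risk;
  hypothermia carries its own, ~1.5× higher, nocturnal hazard (see above).
* **End-of-winter window.** The end hazard is applied at daybreaks only and
  renormalised to keep the end date uniform; the per-period reading would
  leak terminal reward into periods where the reward is defined to be 0.
* **Cost timing for temperature changes.** A bird changing depth pays that
  period's cost, and faces that period's risk, at the post-change depth.
* **Scaled-down preset.** `preset = "ci"` ships a 20-day winter with a
  60-step fat grid and a 4-step depth lattice: small enough for sub-second
  solves, fine enough that the backward value and forward simulation agree.
  (A much coarser fat grid is numerically unresolved and the two estimates
  visibly part company — a useful canary, not a usable model.)

## Parameters at a glance

| name | default | units | meaning |
|---|---|---|---|
| `X_max`, `n_fat_steps` | 148, 100 | kJ | fat ceiling (4 g) and grid |
| `Y_max`, `n_hypo_steps` | 7, 6 | °C | max depression and depth lattice |
| `n_warmup_periods` | 6 | periods | full rewarm duration (30 min) |
| `epsilon` | 0.3 | — | max saving fraction at full depth |
| `C_RM_daily` | 45 | kJ/day | resting metabolism |
| `G_daily` | 80, 60 | kJ/day | expected daily gross gains |
| `Delta` | 1 | — | food availability multiplier |
| `lambda`, `delta` | 0.8, 0.8 | — | success probability; failure gain fraction |
| `gamma` | 1.2 | — | bad-weather expenditure multiplier |
| `beta_daily` | 2.5e-3, 1.25e-3, 2.5e-4 | /day | lean-bird daily risks, behaviours 1–3 |
| `beta_hypo_day`, `beta_hypo_night` | 5e-2, 3.7e-4 | /day | hypothermic risk classes |
| `x_cr`, `alpha_exp` | 37, 3 | kJ, — | critical fat; acceleration exponent |
| `p_GG`, `p_BB` | 0.9983, 0.9965 | /period | weather persistence |
| `C_WU` | 0 | kJ | extra warm-up cost (variant: 6) |
| `x_start`, `T_f_day` | 12, 80 | kJ, day | forward start fat; first end day |

## Calibration sensitivity and limitations

The qualitative predictions are robust across the plausible readings of the
parameter set: birds forage intensively from daybreak, ease off in the
afternoon once the dusk target is safe, drop into maximal hypothermia as soon
as darkness falls, hold it through the night, and begin rewarming half an
hour before dawn so they are flight-ready at first light; rising food
availability shifts the daylight budget from intensive to cautious foraging
and then to resting.

The *absolute* survival level is another matter: the daily energy budget sits
within a few kJ/day of breakeven, so whole-winter survival responds extremely
steeply to any constant-sized shift in daily intake or expenditure — a 5%
change in either can move survival by half its range. Several constants that
such a shift depends on (the acceleration exponent, the per-period risk
conversion, the rewarming rate) are not pinned down by the sources the model
draws on and are therefore exposed as configuration. The numbers the
acceptance script reports are computed under the documented defaults; when
comparing them against published values, the knife-edge sensitivity — not the
optimisation machinery — is the dominant source of disagreement, and the
package reports its computed values rather than adjusting inputs toward any
external figure.

## Problem sizes used by the tests

The test-suite oracles run on a 2-day toy winter (6 periods/day, 5 fat × 3
depth nodes) where the reference solver can sweep every state, and on the
20-day `ci` preset for Monte-Carlo consistency (1000 birds). The acceptance
layer solves the full 100-day baseline (~29,000 periods × 101 × 7 × 2 states)
and simulates 1000-bird cohorts, the same sizes `scripts/acceptance.R` uses.
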