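---
title: "Modelling drug-pulse schedules for a two-species bacterial population"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling drug-pulse schedules for a two-species bacterial population}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pulsedyn)
```

## The model

`pulsedyn` integrates a deterministic birth–death model of two competing
bacterial phenotypes under a bacteriostatic drug: a susceptible wild type
$w$ and a more resistant species $r$, both expressed as fractions of a
shared carrying capacity, with total population $n = w + r$. The dynamics
are

$$\dot w = [\phi_w(n) - \delta - \mu_w]\, w + \mu_r r, \qquad
  \dot r = \mu_w w + [\phi_r(n) - \delta - \mu_r]\, r,$$

where $\phi_\eta(n) = \Theta[\mathrm{MIC}_\eta - c(t)]\,\lambda_\eta (1 - n)$
is a logistic growth rate that is switched off entirely whenever the drug
concentration $c(t)$ exceeds the species' minimum inhibitory concentration
— the drug stops growth but does not kill. Both species die at a constant
rate $\delta$ and interconvert at (small) switching rates $\mu_w, \mu_r$.
Resistance carries a growth-rate cost $k$: $\lambda_r = \lambda_w - k$.

Because only the position of $c(t)$ relative to the two MICs matters, the
concentration never needs to be modelled numerically. Time segments carry
one of three labels instead:

* **free** — $c < \mathrm{MIC}_w \le \mathrm{MIC}_r$: both species grow;
* **low** — $\mathrm{MIC}_w < c < \mathrm{MIC}_r$: only the resistant
  species grows;
* **high** — $c > \mathrm{MIC}_r$: neither grows, both only die.

The free environment occurs only before treatment: its stable fixed point
(wild-type-dominated, with a tiny resistant minority
$r^* \approx \mu_w w^* / [\delta + \mu_r - \lambda_r(1 - n^*)]$ maintained
by switching) is the initial condition for every simulation. We compute
this fixed point numerically (Newton iteration on the full right-hand
side, residual below $10^{-12}$, seeded from the $\mu = 0$ closed forms)
rather than using the $\mu = 0$ approximation, because the initial
resistant abundance sensitively sets how long the resistant species needs
to take over — and therefore every onset timescale downstream.

## Parameters

All rates are in units of $\lambda_w$, so time is measured in units of
$1/\lambda_w$ and `lambda_w = 1` by default (it remains a parameter for
generality). The package defaults are the reference set used throughout:

| parameter | meaning | default |
|---|---|---|
| `lambda_w` | wild-type growth rate | 1 |
| `cost_k`   | growth-rate cost of resistance ($\lambda_r = \lambda_w - k$) | 0.1 |
| `delta`    | death rate of both species | 0.1 |
| `mu_w`     | switching $w \to r$ | $10^{-6}$ |
| `mu_r`     | switching $r \to w$ | 0 |

This combination of cost and death rate displays the full range of
qualitative behaviours of the pulse landscape; smaller costs collapse
some of its regions. Since $\mu_{w,r} \ll \delta$, the switching rates do
not affect the results qualitatively — they matter through the initial
composition.

## Pulse schedules

A single pulse of duration $\tau$ contains one connected high-stress
window of width $t_r$, placed inside the pulse by the skewness
$s = (t_w^{(i)} - t_w^{(f)})/(\tau - t_r) \in [-1, 1]$, where
$t_w^{(i)} = (1+s)(\tau - t_r)/2$ is the initial and
$t_w^{(f)} = (\tau - t_r) - t_w^{(i)}$ the final low-stress wait
($s = -1$: the pulse starts with high stress; $s = +1$: it ends with it).
A sequence of $N$ pulses splits a fixed total treatment time: each pulse
has $\tau^{(N)} = \tau/N$, $t_r^{(N)} = t_r/N$ and the same $s$, so
sequences with different $N$ expose the population to the same total high
and low stress. At $t_r = \tau$ the skewness is undefined by the formula;
we define the schedule as pure high stress and treat all $s$ as
equivalent (they produce identical schedules). Zero-length segments are
absorbed at construction so the integrator never sees an empty interval,
and segment end times are built from rational multiples of the total
duration so the schedule ends at exactly $N \tau^{(N)}$.

The constant-load variant holds $t_{\mathrm{sum}} = \tau + \alpha t_r$
fixed instead of $\tau$, with
$\alpha = (\mathrm{MIC}_r - \mathrm{MIC}_w)/\mathrm{MIC}_w$ weighting the
high window by how much more drug it requires. The model itself knows
nothing about concentrations, so $\alpha$ is a free parameter; $\alpha=1$
is the illustrative choice and $\alpha = 0$ recovers the constant-$\tau$
comparison.

## Observables

For each schedule the simulator reports:

* `n_min` — the lowest total population over the whole schedule, the
  proxy for extinction likelihood (stochastic extinction probability
  scales with $\exp(n_{\min})$, but demographic noise itself is out of
  scope here);
* per-pulse local minima and `best_pulse_index`, the pulse attaining the
  global minimum — clinically, whether continuing past the first pulse
  helps;
* `composition_end_best_pulse` — the ratio $r/w$ at the *end* of that
  pulse (treatment can be stopped after, but not during, a pulse), the
  selection-pressure readout;
* the onset timescales $t_o$ (time of the population minimum in a pure
  low environment started from the free fixed point: the moment the
  resistant species starts dominating regrowth) and $t_o^{\mathrm{final}}$
  (the same quantity for a concluding low window after a given
  low–high history).

The central empirical facts the test suite verifies: at the defaults
$t_o \approx 15$; the skewness minimizing `n_min` at fixed $t_r$ for a
single pulse keeps the initial wait pinned at $t_o$
($s_o = 2 t_o/(\tau - t_r) - 1$, rescaled to $2 N t_o/(\tau - t_r) - 1$
for $N$ pulses); for every $t_r$ the lowest minimum across skewness
belongs to a single pulse; and the end-of-pulse composition along that
optimal line stays on a plateau before dropping sharply once the final
wait becomes too short for resistant takeover ($t_r \gtrsim 30$).

## Numerical choices

* **Integration.** Each constant-environment segment is integrated with
  `deSolve::lsoda` (the right-hand side is compiled C code); the RHS is
  smooth within a segment, so the solver is restarted at every boundary
  and boundary times appear exactly in the output. Tolerances are
  `rtol = 1e-9`, `atol = 1e-12` — tightened until the $t_o$ landmark was
  stable to well under $\pm 0.01$. No stiffness arises (all rates are
  $\mathcal{O}(1)$ or smaller).
* **Dense output and minima.** Trajectories are sampled every
  `output_step = 0.01` time units by default. A segment-interior minimum
  is refined by re-integrating the bracketing interval on a 200-point
  grid, twice (time uncertainty shrinks by $\sim 10^{-2}$ per pass, far
  below the $10^{-3}$ precision we quote for $t_o$); minima at segment
  corners (high→low junctions) are legal and common and are taken from
  the exact boundary states. Halving `output_step` moves `n_min` by less
  than $10^{-9}$ relative, so sweeps can safely use coarser sampling.
* **Tie-breaking.** A minimum on a pulse boundary is attributed to the
  earlier pulse; equal `n_min` across $N$ selects the smaller $N$
  (shorter, simpler treatment); equal `n_min` across $s$ on a grid
  selects the larger $s$ (the longer initial wait, consistent with the
  $t_o$ mechanism).
* **Degenerate inputs.** $t_r = 0$ collapses to a pure low run
  (independent of $s$ and $N$); $t_r = \tau$ to a pure high run
  (independent of $s$, identical across $N$); non-viable parameter
  combinations ($\delta \ge \lambda_\eta$ for the growing species) raise
  an explicit error from the fixed-point search, as does a search horizon
  too short to contain an interior population minimum.
* **Nonnegativity.** The switching coupling is nonnegative off-diagonal,
  so exact dynamics preserve the positive quadrant; integration errors
  below $10 \times$ `atol` are clamped to zero, anything worse is a hard
  error.

## Scope of the sweeps and of the tests

The default sweep grid is $t_r = 1, 2, \ldots, 60$, $s$ from $-1$ to $1$
in steps of $0.05$, and $N \in \{1,2,3,4\}$ at $\tau = 60$ — 9\,840
schedule integrations, which the test suite runs once and slices for
several checks; structural unit tests use coarser grids and a sampling
step of $0.05$. Longer sequences only subdivide further the (already
marginal) regions where an intermediate pulse wins, so $N_{\max} = 4$ is
a presentation choice, configurable in `sweep_grid()`. The exact
boundaries between winning-$N$ regions depend on grid resolution and
tie-breaking; tests therefore assert landmarks (dominance of $N = 1$
along the optimal line, first/last-pulse corners, degeneracy at
$t_r = \tau$) rather than pixel-level region shapes.

## What the model does and does not capture

The dynamics are deterministic and continuous: conclusions about
`n_min` transfer to real populations only as far as the deterministic
minimum gauges extinction likelihood — the model never simulates
demographic noise, and passing tests say nothing about the variance of
real extinction events. The MIC cutoff is abrupt (growth drops to zero
exactly at the MIC), dead cells free their share of the carrying capacity
immediately, there are exactly two phenotypes, and the drug is purely
bacteriostatic — a bactericidal (death-rate-increasing) mode of action,
pharmacokinetics, spatial gradients and host immunity are all outside the
model. Within a pulse sequence, the environment alternates strictly
between low and high; drug-free recovery windows between pulses are not
modelled.

## A worked example

```{r example, eval = FALSE}
params <- model_params()                  # reference parameter set
init <- fixed_point("free", params)       # pre-treatment state
seqc <- build_sequence(60, 30, 0, 3)      # three symmetric pulses
res <- simulate_sequence(seqc, init, params)
res$n_min; res$best_pulse_index           # 0.0525 in pulse 2
find_t_o(params)                          # ~ 15.3
```
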