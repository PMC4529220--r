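---
title: "Evolved parietal-cortex network models of visually and memory guided reaching"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evolved parietal-cortex network models of visually and memory guided reaching}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(parietoreach)
```

## The model

`parietoreach` simulates a minimal sensorimotor system for center-out
reaching. An agent's hand starts at the center of a retinocentric reaching
space bounded at ±50° of visual angle and must reach one of eight targets
(four cardinal at 25°, four diagonal at (±25°, ±25°)) and stay there. A
trial lasts 50 timesteps of 10 ms. In the **visually guided (VG)** task the
target is illuminated for the whole trial; in the **memory guided (MG)**
task it extinguishes after 5 timesteps, so an accurate reach requires an
internally maintained motor plan rather than a sensory-driven one.

The network has four layers. Two 11×11 sensory sheets (vision,
proprioception) cover the space at 10° resolution and project onto an 11×11
posterior parietal cortex (PPC) sheet through *fixed* topographic cosine
tuning curves

$$w_{ij} = f \cdot \cos^{g}\!\left(\frac{d}{20}\right),$$

where $d$ is the Euclidean distance between the two neurons' grid indices,
$g = 200$ gives broad receptive fields, and the amplitude is $f = +2$ for
vision and $f = -4$ for proprioception. The opposite signs implement a
vector-subtraction combination of modalities: when the visual
representations of hand and target overlap the proprioceptive
representation of the hand, the drives approximately cancel. On the 11×11
grid the cosine argument never reaches $\pi/2$ (max $d \approx 14.14 <
10\pi$), so the profile needs no rectification. The variant with
$f = +4/+4$ for both modalities, used as a sensory-weight control, is
available through `sensory_projection_config()`.

PPC projects (fully, evolvable) to a 4-neuron motor layer (PMd/M1) encoding
Up, Down, Left and Right. The four architectures differ only in their
projections *onto* PPC:

| model | feedback (motor→PPC) | lateral (PPC→PPC) | evolvable weights |
|-------|----------------------|-------------------|-------------------|
| FF    | –                    | –                 | 484               |
| FB    | yes                  | –                 | 968               |
| LAT   | –                    | yes (self included) | 15125           |
| FBLAT | yes                  | yes               | 15609             |

All neurons fire through a sigmoid

$$s_i(t) = \frac{1}{1 + \exp\!\big(k\,(\Delta - I_i(t))\big)},\qquad
I_i(t) = \sum_j w_{ij}\, s_j(t-1),$$

with one evolvable bias $\Delta$ and gain $k$ per layer ($\Delta \in
[-5,5]$, $k \in [0.1,10]$; weights in $[-1,1]$). The published form of the
rate equation is typeset ambiguously (the gain appears outside the
exponential's parenthesis); because $k$ is described as a gain — a slope,
i.e. a sensitivity to input — we place it inside the exponent as above. The
update is synchronous: every term, in every layer, reads rates from the
previous timestep, which gives a one-timestep transmission lag from PPC to
the motor layer.

**Numerical note.** The sigmoid is strictly inside $(0,1)$ mathematically,
but at double precision it saturates to exactly 0 or 1 once
$|k(\Delta - I)| \gtrsim 37$. Genomes with large gains and strong drive
(sensory input reaches magnitudes of tens) routinely touch the boundary;
the test suite therefore asserts the closed interval for arbitrary genomes
and the strict interior for moderate ones.

### Sensory encoding and delays

Hand and target are encoded as unit activation masses on the sensory
sheets. Because the 25° targets sit between the 10°-spaced grid nodes, a
one-hot placement cannot represent the task's own target coordinates; the
default therefore splits the mass bilinearly over the (at most four)
surrounding nodes, conserving a total of exactly 1 per object. A
`nearest` option (degree ties rounded toward zero) is provided for
sensitivity checks. Visual activation is the sum of hand and (while
visible) target maps — a shared node carries 2 — and hand vision persists
for the whole trial in both tasks; only the target extinguishes in MG.

Sensory signals reach PPC with biologically motivated latencies:
proprioception delayed 3 timesteps (30 ms), vision 9 timesteps (90 ms). We
read "a D-timestep delay" as *first arrival on timestep D*: the PPC input
at timestep $t$ reflects the world at timestep $t-D+1$, so proprioception
first arrives on timestep 3 and vision on timestep 9, and with the
one-timestep PPC→motor lag the first target-informed movement occurs on
timestep 10. This is the only convention simultaneously consistent with
the delay descriptions, the observed movement onset, and the analytic
fitness optimum below.

### Decoding and fitness

Motor rates are decoded as a population vector with preferred directions at
$\pi/2, 3\pi/2, \pi, 0$ and scale $v = 2$:

$$\Delta x = v\,(s_\text{Right} - s_\text{Left}),\qquad
  \Delta y = v\,(s_\text{Up} - s_\text{Down}),$$

capping cardinal speed at 2°/timestep (200°/s) and diagonal speed at
$2\sqrt2 \approx 2.83$°/timestep. (A literal reading of the published
decode formula omits $v$ and flips the horizontal sign; we follow its
stated intent, validated against the printed speed caps.) The hand
position is continuous and clamped to ±50° after each displacement.

Fitness (minimized) is the hand–target distance summed over all 50
timesteps and 8 trials, recorded after each timestep's movement. The best
achievable value is computed analytically by `optimal_fitness_bound()`:
stay put through timestep 9, then move straight at the per-axis cap and
stop exactly on the target. Per cardinal trial this gives
$9\cdot25+\sum_{k=1}^{12}(25-2k) = 369$, per diagonal trial $369\sqrt2
\approx 521.85$, and $3563.38$ (printed as 3563.4) for the full task; the
value is validated in the tests against an independent dynamic-programming
search over discretized velocity schedules. Corrected fitness subtracts
this bound, so a perfect agent scores 0; the test suite checks empirically
that corrected fitness is non-negative for arbitrary genomes (stationarity
during the blind period is optimal because the eight targets are
symmetric about the start).

```{r oracle}
optimal_fitness_bound()
evaluate_agent(fixture_genomes("FF")$zero)  # the never-moving agent
```

## The evolutionary search

Weights, biases and gains are tuned by a $(\mu,\lambda)$ evolution strategy
with elitism, roulette-wheel parent selection and Gaussian mutation,
20 agents per generation, fitness evaluated on the VG task. Published
details fix the population size, the agent-level mutation probability
(0.4), the per-parameter perturbation chance (50%) and the mutation scales
(G(0, 0.3) weights, G(0, 3) biases, G(0, 1.5) gains); the remaining
operator details were open and we chose, configurably: one elite copied
unchanged per generation ($\mu = \lambda = 19$ offspring), uniform
per-parameter crossover (a one-point variant is available), parent
selection proportional to $(\text{worst} - F + \varepsilon)$ with
$\varepsilon = 10^{-6}\cdot$range (the simplest strictly positive
transform under minimization; uniform fallback for a degenerate
all-equal population), and mutated parameters clamped to their legal
ranges, which are stated as hard bounds. Runs are independent and
seed-deterministic; `run_population()` selects the champion (minimum
fitness across runs).

## The analysis suite

* `velocity_profile()` — per-timestep mean ± SD of hand speed across the 8
  trials, in °/s (displacement × 100); the speed at timestep 1 uses the
  fixed start position. `count_velocity_peaks()` makes the "single-humped
  vs double-humped" judgment concrete: a peak is a local maximum with
  topographic prominence ≥ 10% of the profile maximum — large enough to
  ignore discretization ripple, small enough to count a genuine secondary
  (corrective) sub-movement.
* `target_error()` — mean ± SD over trials of the *final-timestep*
  hand–target distance. Averaging over all timesteps would duplicate
  fitness up to scale; the final-position reading keeps the two measures
  distinct (the alternative is available as `measure =
  "mean_over_timesteps"`).
* `ipsi_contra_summary()` — mean ± SEM of feedforward or feedback weights
  grouped by whether the PPC half-grid corresponds to (ipsilateral) or
  opposes (contralateral) a motor neuron's direction. The 11-row grid has
  no even split, so the middle row/column belongs to both halves (66
  neurons each), a conservative grouping. SEM denominators use the pooled
  element count when weights are pooled across agents.
* `lateral_range_summary()` — lateral weights binned by connection length
  (index-unit distance): short < 5 ≤ medium ≤ 9 < long; self-connections
  are short. The three bins partition all 121² ordered pairs.
* `direction_selectivity()` — the published figures gate neurons at a
  maximum rate ≥ 0.1 but do not print the index formula; we use the
  standard resultant-vector index over the 8 target directions,
  $|\sum_k \bar r_k e^{i\theta_k}| / \sum_k \bar r_k$.
* `compare_groups()` — two-sided Wilcoxon rank-sum (normal approximation
  with tie correction) flagged at $\alpha/n$ (0.05/6 ≈ 0.0083 for the
  six-way battery).
* `ppc_activity_snapshot()` — 11×11 rate grids at selected timesteps with
  deltas from the timestep-1 baseline.

## What the generator emulates — and what it does not

All inputs are generated internally; there is no external data. The task
geometry, delays, trial length, decoder scale and evolutionary
hyper-parameters are the study conditions themselves, and the package's
desk-scale experiments keep them all except the search budget: 1500
generations and 5 independent runs per architecture (seeds fixed a priori
as 100·architecture-index + 1…5) instead of the published 25000 generations
and 100 runs. At this scale some qualitative findings are robust and
others are not. The ipsilateral-excitation / contralateral-inhibition
split of the evolved feedforward weights emerges in every architecture,
and the feedforward model's secondary velocity peak (the corrective
sub-movement signature of the opposed-sign sensory weights) appears on
most seeds. The *lateral-connectivity* findings — the memory-guided
accuracy advantage over FF and smooth single-peaked velocity profiles —
do **not** emerge reliably at 1500 generations: the lateral architectures
carry ~31× more parameters than FF and are still far from converged (a
validation run at 8000 generations reaches near-converged visually guided
behavior, ~1.7° target error with a nearly smooth profile, but still no
memory-guided generalization, which evidently requires search budgets
near the full scale together with champion selection over many runs).
The corresponding acceptance assertions are nevertheless stated at the
desk scale and fail honestly there. The
simulation itself is noise-free and deterministic; nothing here models
neural or motor noise, joint kinematics, gaze shifts, or withheld-go-signal
delay periods, so passing tests say nothing about those aspects of real
reaching data.

## Numerical choices and degenerate inputs

* The trial loop is implemented twice: a compiled engine (the default) and
  a pure-R reference composed from the exported primitives; they agree to
  ~1e-9 (floating-point summation order differs) and the record path and
  the fitness fast path agree to ~1e-12.
* Zeroed feedback (or lateral) weight sets reproduce the corresponding
  simpler architecture bit-exactly within an engine.
* Positions exactly on a grid node place their whole mass there; the
  `nearest` encoding rounds degree ties toward zero.
* A degenerate all-equal-fitness population makes roulette selection
  uniform; crossover of identical parents reproduces them exactly.
* `optimal_trajectory()` stops exactly on the target (per-axis displacement
  `min(v_max, |remaining|)`), so the corrected optimum is exactly 0.

## Problem sizes used by the packaged experiments

The bundled acceptance battery evolves all four architectures at the desk
scale above (~20 minutes total on one core; LAT/FBLAT dominate). The
smoke-scale preset (`test`, 50 generations) exists for pipeline checks
only and is not expected to reproduce any finding.

## Known limitations

* The desk scale cannot reproduce published *quantitative* fitness or
  target-error levels, and among the sign/shape patterns only the
  feedforward-weight laterality and the FF double-hump are reliable at
  1500 generations; the lateral-architecture behavioral patterns need far
  larger search budgets (see above).
* The exact μ/λ split, elite count and crossover operator of the original
  optimizer are unspecified; ours are documented above and configurable.
* The published tuning widths of the sensory projections (7 and 9 pixels)
  describe the effective support of the $g = 200$ cosine profile only
  loosely; the formula is taken as normative.
* Whether the original sensory placement was one-hot or interpolated is
  unknowable from the text (its stated "set to 1" cannot represent its own
  off-grid targets); bilinear is the default here, `nearest` the
  alternative.
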