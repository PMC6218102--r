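---
title: "Bursty clone dynamics: model, statistics, and inference choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bursty clone dynamics: model, statistics, and inference choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cloneburst)
```

## The model chain

`cloneburst` treats a barcoded hematopoiesis experiment as four coupled
stages, each with its own timescale:

1. **HSC clone sizes (months–centuries).**  Tagged HSCs self-renew
   stochastically after transplantation (logistic birth rate
   `p_h (1 − H/K_h)`, constant death `μ_h`).  Each clone is an
   independent linear birth–death process started from one founder
   cell; conditioned on survival, its size is geometric,
   `P(h) = (1 − λ) λ^(h−1)`.  Because the mean extinction time
   `(h/μ_h)(1 + ln(H_ss/h))` dwarfs the experiment length, the package
   holds the configuration `{h_i}` fixed during an experiment; the
   birth–death simulator (`simulate_hsc_birth_death()`) exists purely
   as a validation oracle for the geometric law, never in the
   inference path.  λ is treated as a *free static shape parameter*:
   its exact time dependence on `(p_h, K_h, μ_h)` is both poorly
   constrained by data and, as the sensitivity analysis shows,
   irrelevant to the estimate of interest.

2. **Progenitor bursts (weeks).**  One differentiation event deposits
   one generation-0 progenitor, which divides through at most `L`
   generations (`n_b^(ℓ)(t) = (2 r_n t)^ℓ/Γ(ℓ+1) e^{−(r_n+μ_n)t}`),
   matures at rate ω from the terminal generation, and dies as a
   granulocyte at rate `μ_m`.  The mature response `m_b(t)` integrates
   to `β/μ_m` with burst mass `β = 2^{L_e}`,
   `L_e = L − L log2((r_n+μ_n)/r_n) − log2((ω+μ_n^L)/ω)`.  All
   structural and rate uncertainty downstream of the HSC pool is
   absorbed into this single effective generation parameter, which is
   why the fits set `μ_n = μ_n^L = 0` and scan `L_e` directly.

3. **Clone trajectories (the experiment).**  Clone `i` fires events as
   a Poisson process of rate `α h_i`, `α = A_ss⁺/Σh_i`; its peripheral
   population is the shot-noise sum of kernel copies.  The total rate
   `A_ss⁺` is pinned to `M_ss⁺ μ_m 2^{−L_e}` so that, whatever `L_e`
   is being tried, the simulated pool matches the measured tagged
   granulocyte pool in expectation.

4. **Observation.**  A blood sample of `S⁺(t_j)` tagged cells from a
   pool `M_ss⁺` gives independent binomial counts
   `s_i ~ B(S⁺, m_i/M_ss⁺)` and abundances `f_i = s_i/S⁺`.  At
   sampling fractions of 1e-5 to 1e-4 the binomial–hypergeometric
   distinction is irrelevant.  Abundances are normalized by the
   *nominal* `S⁺`, not the realized tagged total, keeping
   `f_i = s_i/S⁺` an exact definition on both real and simulated data.

## The disappearance statistic and the objective

With few samples (J of order 8) the per-clone variance is a poor
fitting target.  Instead, each clone contributes its mean abundance
`y_i` and its absence count `z_i` (samples with `f_i = 0`, exact-zero
semantics — abundances are ratios of integer counts).  The statistic
`Y_z` is the mean of `y_i` over clones with exactly `z` absences;
empty bins are defined as 0.  The objective is
`MSE = Σ_{z=1}^{J−1} (Y_z − Ŷ_z)²`.  The `z = 0` bin is excluded: the
abundances of never-absent clones reflect the clone-size configuration,
not burstiness, so including it would couple the fit to the one thing
the method is designed to be insensitive to.  Clones absent from every
retained sample are dropped (they are unobservable), and the standard
deviation uses the population divisor J, matching the statistic's
definition.

Sample exclusion: by default the first sample is dropped when taken
before month 6, because very early samples reflect short-term
repopulating clones rather than the steady-state granulopoiesis the
model describes.  The rule is a configurable index set
(`clone_summaries(..., exclude =)`).

## Parameters

| parameter | meaning | default | rationale |
|---|---|---|---|
| `r_n` | progenitor division rate (1/day) | 2.5 | midpoint of the reported 2–3 range; fits are insensitive inside it |
| `ω` | terminal maturation rate (1/day) | 0.16 | reported 0.15–0.17 |
| `μ_n`, `μ_n^L` | progenitor death rates (1/day) | 0 | unmeasurable; absorbed into `L_e` |
| `μ_m` | granulocyte death rate (1/day) | 1 | reported 0.2–2; changes shift `L_e` by ~1, not `A_ss⁺` |
| `λ` | clone-size shape | 0.99 | broad heterogeneity; estimate insensitive for λ ≳ 0.5 |
| `C_h` | tagged clone count | 500 | order of the observed clone counts |
| `L_e` grid | effective generation | 19–28, step 0.2 | biological range; step resolves the minimum below the reported uncertainty |
| replicates | forward sims per grid point | 200 (25 desk-scale) | mean-`Y_z` noise shrinks as `1/√n` |
| `M_ss⁺` | tagged granulocyte pool | 1.664e8 | 3.2e9 granulocytes × 0.052 tagged fraction |

## Numerical choices

- **Kernel evaluation.**  For the physiological rate ordering
  `r_n + μ_n > μ_m > ω + μ_n^L`, both `n_b^(L)` and `m_b` reduce to
  closed forms in the lower incomplete gamma function (`pgamma`), valid
  for non-integer `L` via the Γ-continuation.  Outside that ordering
  the terminal and mature compartments are integrated with `deSolve`
  (`lsoda`, rtol 1e-10) forced by the analytic upstream generations.
  The two routes agree to relative 1e-6 and the ODE route doubles as a
  cross-check in the tests; the full integer-`L` generation ladder is
  an additional oracle.
- **Kernel storage.**  Uniform grid, step 0.25 day over [0, 200] days;
  for all default-range parameters `m_b(200) < 1` cell, and the
  constructor errors if a kernel is truncated above 1 cell.  Burst
  evaluation at event lags uses linear interpolation; contributions
  below 1 cell are dropped (a relative error of order 1e-7 at default
  amplification).
- **Burst width.**  Threshold crossings are bracketed on the grid and
  refined by `uniroot` on the closed-form evaluator, so the width does
  not inherit the grid step.  The default threshold is the inverse
  sampling fraction `M_ss⁺/S⁺ ≈ 2e4` cells.
- **Warm-up.**  Events start 200 days (the kernel support) before the
  first sample, so the shot-noise process is stationary at every
  observation; the warm-up convention is the package's own choice.
- **Seeding.**  A master seed spawns deterministic per-clone
  sub-streams (a fixed 32-bit mix of seed and clone index), so
  enlarging `C_h` never perturbs existing clones' draws, and every
  pipeline stage (configuration, events, sampling) draws from its own
  derived stream.  Identical spec + seed reproduces a fit bit for bit.
- **Grid search and ties.**  The optimum is the grid point with
  minimal replicate-mean `Y_z` MSE (the mean-of-`Y_z` construction,
  with per-replicate MSE dispersion reported alongside).  Exact ties
  break toward the smaller `L_e`, the conservative lower-amplification
  choice.
- **Units.**  Months external, days internal, 30.4 days/month applied
  once at the boundary.

## The synthetic generator

`synthetic_spec()`/`generate_dataset()` compose the exact forward model
(configuration → trajectories → sampling) at known truth, under a
design emulating the macaque experiments: 8 retained samples over ~60
months plus an excluded month-2 sample, per-sample tagged counts drawn
uniformly from 5e3–3e4, tagged pool 1.664e8, giving sampling fractions
3e-5–1.8e-4.  Generated data reproduce the qualitative signatures of
the real matrices — abundances spanning orders of magnitude, populated
absence bins, all-zero rows — and the truth record regenerates the
dataset bit for bit.

What the generator does *not* emulate: PCR amplification noise and tag
quantifiability filtering (observed to be sub-dominant to sampling
noise), lymphocyte dynamics, non-neutral tag effects, and slow clonal
succession.  Passing recovery tests therefore demonstrate that the
inference machinery is correct and well-calibrated *under the model's
own assumptions*; they cannot certify those assumptions against a real
animal, and the known misfit of the largest-`z` bins in real data (the
smallest, noisiest clones) is exactly where the unmodeled noise lives.

## Desk-scale test conditions

The suite runs the recovery experiment at 200 clones and 25 replicates
per grid point (truth `L_e = 23.0`, recovered exactly at grid
resolution), sensitivity checks on a narrowed grid around the truth,
and Monte-Carlo checks at 3–4 standard errors.  These sizes are the
package's chosen desk scale; production fits should use the 200
replicates and full grid of the defaults.

## Limitations

- The estimate of `L_e` is effective, not anatomical: changing fixed
  rates (e.g. `μ_m`) shifts `L_e` by design; `A_ss⁺` is the robust
  quantity.
- `Y_z` discards within-clone temporal ordering; regimes where burst
  shape (not just rate) varies across clones would need richer
  statistics.
- The published macaque estimates bundled in `reference_fits()` can be
  checked for internal consistency, but re-deriving them requires the
  original experiment's supplemental abundance tables, which are not
  distributed with the package.
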